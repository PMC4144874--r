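#' Nodal degree and strength
#'
#' Degree `K_i` is the number of nodes directly connected to node `i`
#' (positive-weight edges); strength `S_i` is the sum of the weights of the
#' links connected to `i`, the weighted analogue of degree.
#'
#' @param net A [weighted_network()].
#' @return A data.frame with columns `label`, `degree`, `strength`.
#' @export
degree_and_strength <- function(net) {
  if (!inherits(net, "weighted_network"))
    stop("`net` must be a weighted_network object", call. = FALSE)
  data.frame(label = net$labels,
             degree = as.integer(rowSums(net$weights > 0)),
             strength = rowSums(net$weights),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generalized (raw-weight) clustering coefficient
#'
#' Weighted clustering of node `i` as the mean geometric triple product over
#' its neighbour pairs,
#' `C_i = 2 / (K_i (K_i - 1)) * sum_{j<h} (w_ij w_ih w_jh)^(1/3)`,
#' computed on the original (un-normalized) edge weights. Because probabilistic
#' tractography weights have no natural ceiling, normalizing by the maximal
#' weight would reduce robustness; with raw weights the coefficient is
#' "generalized" — unbounded above and meaningful for group contrasts rather
#' than as an absolute quantity. `C_i = 0` whenever `K_i < 2`. The network
#' clustering `C(G)` is the mean of the nodal values.
#'
#' @param net A [weighted_network()].
#' @return A list with `nodal` (named numeric vector `C_i`) and `network`
#'   (scalar mean `C(G)`).
#' @export
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- 1; w[1, 3] <- 8; w[2, 3] <- 27
#' generalized_clustering(weighted_network(w + t(w)))$nodal  # all 6
generalized_clustering <- function(net) {
  if (!inherits(net, "weighted_network"))
    stop("`net` must be a weighted_network object", call. = FALSE)
  w13 <- net$weights^(1 / 3)
  # diag(w13 %*% w13 %*% w13)[i] = sum over ordered (j, h) of
  # (w_ij w_jh w_hi)^(1/3) = 2 * sum_{j<h}, zero unless a closed triangle
  tri <- diag(w13 %*% w13 %*% w13)
  k <- rowSums(net$weights > 0)
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  names(ci) <- net$labels
  list(nodal = ci, network = mean(ci))
}

#' All-pairs shortest paths under inverse-weight distances
#'
#' Edge length is the inverse of the connection weight (`1 / w_ij`), so that
#' strongly connected region pairs are "close". Returns the full distance
#' matrix (infinite for disconnected pairs, zero on the diagonal) together
#' with the number of distinct shortest paths for every ordered pair,
#' counting paths whose accumulated lengths agree within a relative
#' tolerance (floating-point path sums rarely tie exactly).
#'
#' @param net A [weighted_network()].
#' @param rel_tol Relative tolerance for treating two path lengths as equal
#'   (default 1e-12).
#' @return An object of class `shortest_path_solution`: list with `d`
#'   (N x N distances), `sigma` (N x N shortest-path counts, 1 on the
#'   diagonal), `labels`, `rel_tol`.
#' @export
shortest_paths <- function(net, rel_tol = 1e-12) {
  if (!inherits(net, "weighted_network"))
    stop("`net` must be a weighted_network object", call. = FALSE)
  if (any(net$weights < 0))
    .stop_field("weights", "must be non-negative")
  w <- net$weights
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- Inf  # no self-edges
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    alt <- outer(d[, k], d[k, ], "+")
    upd <- alt < d
    d[upd] <- alt[upd]
  }
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ds <- d[s, ]
    reach <- which(is.finite(ds) & seq_len(n) != s)
    if (!length(reach)) next
    acc <- ds + len  # acc[u, v] = d(s,u) + len(u,v), column-recycled
    sig <- numeric(n)
    sig[s] <- 1
    for (v in reach[order(ds[reach])]) {
      cand <- acc[, v]
      pred <- which(is.finite(cand) &
                      abs(cand - ds[v]) <= rel_tol * ds[v])
      sig[v] <- sum(sig[pred])
    }
    sigma[s, ] <- sig
  }
  structure(list(d = d, sigma = sigma, labels = net$labels,
                 rel_tol = rel_tol),
            class = "shortest_path_solution")
}

#' Nodal mean path length and harmonic-mean characteristic path length
#'
#' The mean shortest path length of a node is the average distance to all
#' other nodes (infinite if any pair is disconnected). The characteristic
#' path length of the network is the harmonic mean over pairs — the
#' reciprocal of the average of the reciprocal distances, with `1/Inf = 0` —
#' which stays finite when some components are disconnected.
#'
#' @param sp A [shortest_paths()] solution.
#' @return A list with `nodal` (named vector `L_i`) and `network`
#'   (scalar `L(G)`).
#' @export
path_length_metrics <- function(sp) {
  if (!inherits(sp, "shortest_path_solution"))
    stop("`sp` must be a shortest_path_solution object", call. = FALSE)
  d <- sp$d
  n <- nrow(d)
  li <- rowSums(d) / (n - 1)  # diagonal is 0; Inf propagates as specified
  names(li) <- sp$labels
  inv <- 1 / d
  diag(inv) <- 0
  lg <- 1 / (sum(inv) / (n * (n - 1)))
  list(nodal = li, network = lg)
}

#' Nodal betweenness centrality
#'
#' The number of shortest paths between other node pairs that pass through a
#' node, as a fraction of all shortest paths between that pair:
#' `BC_i = sum_{k != i != j} sigma_kj(i) / sigma_kj`. Sums run over ordered
#' pairs `(k, j)` and are not halved; on symmetric networks this doubles the
#' unordered count uniformly, a constant convention that cancels in group
#' comparisons. Endpoints are excluded; equal-length paths are detected with
#' the tolerance rule of [shortest_paths()].
#'
#' @param sp A [shortest_paths()] solution.
#' @return Named numeric vector `BC_i`.
#' @export
betweenness <- function(sp) {
  if (!inherits(sp, "shortest_path_solution"))
    stop("`sp` must be a shortest_path_solution object", call. = FALSE)
  d <- sp$d
  sig <- sp$sigma
  n <- nrow(d)
  bc <- numeric(n)
  for (i in seq_len(n)) {
    through <- outer(d[, i], d[i, ], "+")  # d(k,i) + d(i,j)
    ok <- is.finite(d) & is.finite(through) & d > 0
    ok[i, ] <- FALSE
    ok[, i] <- FALSE
    idx <- which(ok)
    if (!length(idx)) next
    on_path <- idx[abs(through[idx] - d[idx]) <= sp$rel_tol * d[idx]]
    if (!length(on_path)) next
    counts <- outer(sig[, i], sig[i, ])
    bc[i] <- sum(counts[on_path] / sig[on_path])
  }
  names(bc) <- sp$labels
  bc
}

# Global efficiency of a raw weight matrix (internal; used for subgraphs).
#' @noRd
.e_glob_matrix <- function(w) {
  n <- nrow(w)
  if (n < 2L) return(0)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- Inf
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    alt <- outer(d[, k], d[k, ], "+")
    upd <- alt < d
    d[upd] <- alt[upd]
  }
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Global and local network efficiency
#'
#' Global efficiency is the mean inverse shortest-path distance over all
#' ordered node pairs (inverse-weight distances; disconnected pairs
#' contribute zero). Local efficiency is the mean, over nodes, of the global
#' efficiency of each node's neighbour-induced subgraph (original weights,
#' the node itself excluded); nodes with fewer than two neighbours
#' contribute zero.
#'
#' @param net A [weighted_network()].
#' @param sp Optional precomputed [shortest_paths()] solution for `net`.
#' @return A list with `e_glob` and `e_loc`.
#' @export
efficiencies <- function(net, sp = NULL) {
  if (!inherits(net, "weighted_network"))
    stop("`net` must be a weighted_network object", call. = FALSE)
  n <- length(net$labels)
  if (is.null(sp)) {
    e_glob <- .e_glob_matrix(net$weights)
  } else {
    inv <- 1 / sp$d
    diag(inv) <- 0
    e_glob <- sum(inv) / (n * (n - 1))
  }
  e_loc_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(net$weights[i, ] > 0)
    if (length(nb) < 2L) next
    e_loc_i[i] <- .e_glob_matrix(net$weights[nb, nb, drop = FALSE])
  }
  list(e_glob = e_glob, e_loc = mean(e_loc_i))
}

#' Full nodal metric table
#'
#' Computes, per node: degree, strength, generalized clustering, mean
#' shortest path length and betweenness centrality.
#'
#' @param net A [weighted_network()].
#' @param sp Optional precomputed [shortest_paths()] solution.
#' @return A data.frame with columns `label`, `degree`, `strength`,
#'   `clustering`, `mean_path_length`, `betweenness`.
#' @export
nodal_metrics <- function(net, sp = NULL) {
  if (is.null(sp)) sp <- shortest_paths(net)
  ks <- degree_and_strength(net)
  cl <- generalized_clustering(net)
  pl <- path_length_metrics(sp)
  bc <- betweenness(sp)
  data.frame(label = ks$label, degree = ks$degree, strength = ks$strength,
             clustering = unname(cl$nodal),
             mean_path_length = unname(pl$nodal),
             betweenness = unname(bc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Global metric set
#'
#' Network clustering `C(G)` (mean nodal generalized clustering),
#' harmonic-mean characteristic path length `L(G)`, and global and local
#' efficiency.
#'
#' @param net A [weighted_network()].
#' @param sp Optional precomputed [shortest_paths()] solution.
#' @return A list of class `global_metrics` with elements `clustering`,
#'   `char_path_length`, `e_glob`, `e_loc`.
#' @export
global_metrics <- function(net, sp = NULL) {
  if (is.null(sp)) sp <- shortest_paths(net)
  cl <- generalized_clustering(net)
  pl <- path_length_metrics(sp)
  ef <- efficiencies(net, sp)
  structure(list(clustering = cl$network, char_path_length = pl$network,
                 e_glob = ef$e_glob, e_loc = ef$e_loc),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf("C(G) = %.4g, L(G) = %.4g, E_glob = %.4g, E_loc = %.4g\n",
              x$clustering, x$char_path_length, x$e_glob, x$e_loc))
  invisible(x)
}
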