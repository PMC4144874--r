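#' Motion quality-control thresholds
#'
#' @param max_translation Maximum tolerated absolute translation (mm),
#'   default 1.
#' @param max_rotation Maximum tolerated absolute rotation (degrees),
#'   default 1.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_translation = 1.0, max_rotation = 1.0) {
  if (!.is_number(max_translation) || max_translation <= 0)
    .stop_field("max_translation", "must be strictly positive")
  if (!.is_number(max_rotation) || max_rotation <= 0)
    .stop_field("max_rotation", "must be strictly positive")
  structure(list(max_translation = max_translation,
                 max_rotation = max_rotation), class = "qc_thresholds")
}

#' Screen a scan's motion log against head-motion thresholds
#'
#' A scan is excluded when the maximum absolute translation over volumes and
#' axes exceeds `max_translation` (mm) or the maximum absolute rotation
#' exceeds `max_rotation` (degrees) — the per-axis-maximum reading of the
#' "translation > 1 mm or rotation > 1 degree" exclusion rule.
#'
#' @param log A [motion_log()].
#' @param thr A [qc_thresholds()] (defaults: 1 mm, 1 degree).
#' @return A list with `keep` (logical), `reason` (`NA` if kept, otherwise
#'   which rule(s) fired, comma-separated), `max_translation` and
#'   `max_rotation` (the observed maxima).
#' @export
#' @examples
#' m <- motion_log(matrix(0, 10, 6))
#' screen_motion(m)$keep
screen_motion <- function(log, thr = qc_thresholds()) {
  if (!inherits(log, "motion_log"))
    stop("`log` must be a motion_log object", call. = FALSE)
  if (!inherits(thr, "qc_thresholds"))
    stop("`thr` must be a qc_thresholds object", call. = FALSE)
  mt <- max(abs(log$params[, 1:3]))
  mr <- max(abs(log$params[, 4:6]))
  fired <- c("translation", "rotation")[c(mt > thr$max_translation,
                                          mr > thr$max_rotation)]
  list(keep = length(fired) == 0L,
       reason = if (length(fired)) paste(fired, collapse = ",") else NA_character_,
       max_translation = mt, max_rotation = mr)
}

#' Symmetric weighted network
#'
#' A non-negative symmetric edge-weight matrix with a zero diagonal and
#' unique node labels — the common currency of all downstream graph
#' analysis.
#'
#' @param weights N x N symmetric non-negative numeric matrix.
#' @param labels Length-N unique node labels (defaults to the dimnames of
#'   `weights`).
#' @return An object of class `weighted_network` with elements `weights`
#'   and `labels`.
#' @export
weighted_network <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n != ncol(weights))
    .stop_field("weights", "must be a square matrix")
  if (any(!is.finite(weights)) || any(weights < 0))
    .stop_field("weights", "must be finite and non-negative")
  if (max(abs(weights - t(weights))) > 1e-12)
    .stop_field("weights", "must be symmetric (tolerance 1e-12)")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(labels)) labels <- rownames(weights)
  if (is.null(labels)) labels <- .default_labels(n)
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels))
    .stop_field("labels", "must be unique and match the matrix dimension")
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  m <- sum(x$weights > 0) / 2
  cat(sprintf("Weighted network: %d nodes, %d edges, total weight %.4g\n",
              length(x$labels), m, sum(x$weights) / 2))
  invisible(x)
}

#' @export
as.matrix.weighted_network <- function(x, ...) x$weights

#' @export
plot.weighted_network <- function(x, main = "edge weights", ...) {
  n <- length(x$labels)
  graphics::image(seq_len(n), seq_len(n), t(x$weights[n:1, ]),
                  axes = FALSE, xlab = "", ylab = "", main = main, ...)
  graphics::box()
  invisible(x)
}

#' Build a symmetric voxel-normalized weight matrix from directed counts
#'
#' The connection weight from region A to B is the directed streamline count
#' divided by the number of seed voxels in A; the edge weight between A and B
#' is the sum of the two directed weights:
#' `w_ij = counts[i,j]/voxels[i] + counts[j,i]/voxels[j]`.
#' Self-connections are excluded (the diagonal of `counts` is ignored).
#'
#' @param tc A [tract_counts()] object.
#' @return A [weighted_network()].
#' @export
#' @examples
#' tc <- tract_counts(matrix(c(0, 6, 10, 0), 2, 2), voxels = c(5, 3),
#'                    labels = c("A", "B"))
#' build_weight_matrix(tc)$weights["A", "B"]  # 10/5 + 6/3 = 4
build_weight_matrix <- function(tc) {
  if (!inherits(tc, "tract_counts"))
    stop("`tc` must be a tract_counts object", call. = FALSE)
  if (any(tc$voxels <= 0))
    .stop_field("voxels", "must be strictly positive")
  w <- tc$counts / tc$voxels + t(tc$counts / tc$voxels)
  diag(w) <- 0
  weighted_network(w, labels = tc$labels)
}

#' Average repeated-scan networks of one subject
#'
#' Entrywise arithmetic mean of the connection matrices of the scans that
#' survived motion screening; the mean matrix is the subject's final
#' network.
#'
#' @param nets Non-empty list of [weighted_network()] objects with identical
#'   node labels.
#' @return A [weighted_network()].
#' @export
average_networks <- function(nets) {
  if (!is.list(nets) || length(nets) < 1L ||
      !all(vapply(nets, inherits, TRUE, "weighted_network")))
    stop("`nets` must be a non-empty list of weighted_network objects",
         call. = FALSE)
  labs <- nets[[1]]$labels
  for (nt in nets)
    if (!identical(nt$labels, labs))
      stop("networks have mismatching node labels", call. = FALSE)
  w <- Reduce(`+`, lapply(nets, `[[`, "weights")) / length(nets)
  weighted_network(w, labels = labs)
}

#' Backbone extraction settings
#'
#' @param k Target average node degree of the backbone (default 4,
#'   balancing sparseness against efficiency). Must satisfy
#'   `k >= 2 * (N - 1) / N` so the backbone can hold a spanning tree.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(k = 4) {
  if (!.is_number(k) || k <= 0)
    .stop_field("k", "must be a positive real")
  structure(list(k = k), class = "backbone_config")
}

# Kruskal maximum spanning tree with deterministic lexicographic (i, j)
# tie-breaking. `edges` is a data.frame(i, j, w) sorted by (-w, i, j).
# Returns logical vector marking tree edges.
#' @noRd
.kruskal_mst <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  in_tree <- logical(nrow(edges))
  taken <- 0L
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges$i[e]); rj <- find(edges$j[e])
    if (ri != rj) {
      parent[ri] <- rj
      in_tree[e] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  in_tree
}

#' Extract the connectivity backbone of a weighted network
#'
#' First extracts a maximum spanning tree (the tree connecting all nodes
#' whose total weight is maximal), then adds the remaining edges in
#' descending weight order until the backbone holds `floor(N * k / 2)` edges,
#' i.e. an average node degree of `k` (180 edges for N = 90, k = 4). Kept
#' edges retain their original weights; all others are zeroed. Ties in
#' weight are broken by lexicographic node-pair order, so the backbone is
#' deterministic.
#'
#' @param net A [weighted_network()] whose positive-weight graph is
#'   connected.
#' @param cfg A [backbone_config()] (default target degree 4).
#' @return A [weighted_network()] containing exactly `floor(N * k / 2)`
#'   edges, a superset of a maximum spanning tree, connected.
#' @export
#' @examples
#' w <- matrix(0, 4, 4)
#' w[1, 2] <- 5; w[1, 3] <- 4; w[1, 4] <- 1
#' w[2, 3] <- 3; w[2, 4] <- 2; w[3, 4] <- 6
#' net <- weighted_network(w + t(w))
#' extract_backbone(net, backbone_config(k = 2))
extract_backbone <- function(net, cfg = backbone_config()) {
  if (!inherits(net, "weighted_network"))
    stop("`net` must be a weighted_network object", call. = FALSE)
  if (!inherits(cfg, "backbone_config"))
    stop("`cfg` must be a backbone_config object", call. = FALSE)
  n <- length(net$labels)
  if (cfg$k < 2 * (n - 1) / n)
    .stop_field("k", sprintf("must be >= 2(N-1)/N = %.4f for N = %d",
                             2 * (n - 1) / n, n))
  comp <- .components(net$weights)
  if (max(comp) > 1L)
    stop(sprintf(
      "positive-weight graph is disconnected: %d components with sizes %s",
      max(comp), paste(tabulate(comp), collapse = ", ")), call. = FALSE)
  m_target <- floor(n * cfg$k / 2)
  up <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
  edges <- data.frame(i = up[, 1], j = up[, 2],
                      w = net$weights[up])
  if (nrow(edges) < m_target)
    stop(sprintf(
      "cannot form a %d-edge backbone: only %d positive edges available",
      m_target, nrow(edges)), call. = FALSE)
  edges <- edges[order(-edges$w, edges$i, edges$j), , drop = FALSE]
  in_tree <- .kruskal_mst(edges, n)
  extra <- m_target - sum(in_tree)
  keep <- in_tree
  if (extra > 0) {
    non_tree <- which(!in_tree)
    keep[non_tree[seq_len(extra)]] <- TRUE  # already in descending order
  }
  w <- matrix(0, n, n)
  kept <- edges[keep, , drop = FALSE]
  w[cbind(kept$i, kept$j)] <- kept$w
  w <- w + t(w)
  out <- weighted_network(w, labels = net$labels)
  attr(out, "mst_edges") <- edges[in_tree, , drop = FALSE]
  out
}
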