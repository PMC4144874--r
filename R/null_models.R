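#' Degree-preserving random rewiring (Markov-chain edge swaps)
#'
#' Randomizes a network while preserving every node's degree: repeatedly
#' picks two edges (a, b) and (c, d) and swaps their endpoints to (a, d) and
#' (c, b), rejecting swaps that would create self-loops or duplicate edges.
#' Weights travel with their edges, so the multiset of edge weights is also
#' conserved. Connectivity is not enforced (classic Markov-chain rewiring);
#' downstream efficiency metrics handle disconnected pairs through the
#' infinite-distance convention.
#'
#' @param net A [weighted_network()].
#' @param n_swap_per_edge Attempted swaps per edge (default 10; with `M`
#'   edges, `10 * M` attempts — a common mixing heuristic).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A rewired [weighted_network()] with the same degree sequence and
#'   edge-weight multiset. A network with fewer than 2 edges is returned
#'   unchanged with a warning.
#' @export
rewire_preserving_degree <- function(net, n_swap_per_edge = 10, seed = 1L) {
  if (!inherits(net, "weighted_network"))
    stop("`net` must be a weighted_network object", call. = FALSE)
  n <- length(net$labels)
  up <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
  m <- nrow(up)
  if (m < 2L) {
    warning("fewer than 2 edges: returning the input network unchanged")
    return(net)
  }
  ei <- up[, 1]
  ej <- up[, 2]
  ew <- net$weights[up]
  adj <- net$weights > 0
  n_try <- ceiling(n_swap_per_edge * m)
  .with_seed(seed, {
    pick <- matrix(sample.int(m, 2L * n_try, replace = TRUE), ncol = 2L)
    flip <- stats::runif(n_try) < 0.5
    for (t in seq_len(n_try)) {
      e1 <- pick[t, 1L]
      e2 <- pick[t, 2L]
      if (e1 == e2) next
      a <- ei[e1]; b <- ej[e1]
      c <- ei[e2]; d <- ej[e2]
      # randomize which endpoints are exchanged so both pairings are reachable
      if (flip[t]) { tmp <- c; c <- d; d <- tmp }
      # propose (a, d) and (c, b)
      if (a == d || c == b) next
      if (adj[a, d] || adj[c, b]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c, d] <- adj[d, c] <- FALSE
      adj[a, d] <- adj[d, a] <- TRUE
      adj[c, b] <- adj[b, c] <- TRUE
      ei[e1] <- min(a, d); ej[e1] <- max(a, d)
      ei[e2] <- min(c, b); ej[e2] <- max(c, b)
    }
  })
  w <- matrix(0, n, n)
  w[cbind(ei, ej)] <- ew
  w <- w + t(w)
  weighted_network(w, labels = net$labels)
}

#' Small-world assessment against a rewired null ensemble
#'
#' Generates an ensemble of degree-preserving rewired networks, averages
#' their global and local efficiencies, and forms the ratios
#' `E_loc(G) / mean E_loc(G_random)` and `E_glob(G) / mean E_glob(G_random)`.
#' A network is classified as small-world when its global efficiency is
#' slightly below that of the matched random networks (`eglob_ratio < 1`)
#' while its local efficiency is much greater (`eloc_ratio > margin`).
#'
#' @param net A [weighted_network()].
#' @param ensemble_size Number of rewired networks (default 100).
#' @param n_swap_per_edge Attempted swaps per edge for each ensemble member
#'   (default 10).
#' @param margin Threshold on `eloc_ratio` for the small-world call
#'   (default 1; "much greater" is unquantified, so the margin is exposed).
#' @param seed Integer seed; ensemble member `k` uses a stream derived from
#'   `(seed, k)`.
#' @return An object of class `small_world`: list with `eloc_ratio`,
#'   `eglob_ratio`, `e_glob`, `e_loc`, `e_glob_random`, `e_loc_random`,
#'   `ensemble_size`, `margin`, `is_small_world`.
#' @export
small_world_assessment <- function(net, ensemble_size = 100L,
                                   n_swap_per_edge = 10, margin = 1,
                                   seed = 1L) {
  if (!inherits(net, "weighted_network"))
    stop("`net` must be a weighted_network object", call. = FALSE)
  if (!.is_count(ensemble_size))
    .stop_field("ensemble_size", "must be a positive integer")
  ef <- efficiencies(net)
  eg <- numeric(ensemble_size)
  el <- numeric(ensemble_size)
  for (k in seq_len(ensemble_size)) {
    rnd <- rewire_preserving_degree(net, n_swap_per_edge = n_swap_per_edge,
                                    seed = .substream_seed(seed, "ensemble", k))
    efr <- efficiencies(rnd)
    eg[k] <- efr$e_glob
    el[k] <- efr$e_loc
  }
  eg_bar <- mean(eg)
  el_bar <- mean(el)
  eglob_ratio <- if (eg_bar > 0) ef$e_glob / eg_bar else {
    warning("mean random global efficiency is 0; ratio reported as Inf")
    Inf
  }
  eloc_ratio <- if (el_bar > 0) ef$e_loc / el_bar else {
    warning("mean random local efficiency is 0; ratio reported as Inf")
    Inf
  }
  structure(list(eloc_ratio = eloc_ratio, eglob_ratio = eglob_ratio,
                 e_glob = ef$e_glob, e_loc = ef$e_loc,
                 e_glob_random = eg_bar, e_loc_random = el_bar,
                 ensemble_size = as.integer(ensemble_size), margin = margin,
                 is_small_world = (eglob_ratio < 1) && (eloc_ratio > margin)),
            class = "small_world")
}

#' @export
print.small_world <- function(x, ...) {
  cat(sprintf(
    "Small-world assessment (ensemble of %d rewired networks)\n", x$ensemble_size))
  cat(sprintf("  E_loc(G)/E_loc(rand)  = %.4g\n", x$eloc_ratio))
  cat(sprintf("  E_glob(G)/E_glob(rand) = %.4g\n", x$eglob_ratio))
  cat(sprintf("  small-world: %s\n", if (x$is_small_world) "yes" else "no"))
  invisible(x)
}
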