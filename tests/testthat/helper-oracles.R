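# Independent brute-force oracles used to validate the graph algorithms on
# small graphs. All of them enumerate explicitly (simple paths, triangles,
# spanning trees) and share nothing with the package implementations.

# Random symmetric weighted network on n nodes.
rand_net <- function(n, density = 0.6, seed = 1, connected = FALSE,
                     wmax = 5) {
  set.seed(seed)
  repeat {
    w <- matrix(0, n, n)
    up <- which(upper.tri(w))
    on <- up[runif(length(up)) < density]
    w[on] <- runif(length(on), 0.1, wmax)
    w <- w + t(w)
    if (!connected) break
    if (all(tractnet:::.components(w) == 1L)) break
    seed <- seed + 10007
    set.seed(seed)
  }
  weighted_network(w)
}

# All simple paths between two nodes; returns a list of node index vectors.
bf_simple_paths <- function(w, s, t) {
  n <- nrow(w)
  out <- list()
  rec <- function(path, visited) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (u in which(w[v, ] > 0)) {
      if (!visited[u]) {
        visited[u] <- TRUE
        rec(c(path, u), visited)
        visited[u] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  rec(s, visited)
  out
}

bf_path_length <- function(w, path) {
  if (length(path) < 2L) return(0)
  sum(1 / w[cbind(path[-length(path)], path[-1L])])
}

# Distances, shortest-path counts and betweenness by full path enumeration.
bf_shortest <- function(net, rel_tol = 1e-9) {
  w <- net$weights
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  bc <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      paths <- bf_simple_paths(w, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, function(p) bf_path_length(w, p), 0)
      dmin <- min(lens)
      d[s, t] <- dmin
      best <- paths[lens <= dmin * (1 + rel_tol)]
      sigma[s, t] <- length(best)
      for (p in best) {
        interior <- p[-c(1L, length(p))]
        bc[interior] <- bc[interior] + 1 / length(best)
      }
    }
  }
  list(d = d, sigma = sigma, betweenness = bc)
}

bf_clustering <- function(net) {
  w <- net$weights
  n <- nrow(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2L) next
    tot <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (b <= a) next
        j <- nb[a]; h <- nb[b]
        if (w[j, h] > 0)
          tot <- tot + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
      }
    }
    k <- length(nb)
    ci[i] <- 2 * tot / (k * (k - 1))
  }
  ci
}

bf_eglob <- function(d) {
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Maximum spanning tree weight by exhaustive enumeration over all edge
# subsets of size n-1 that span the graph (feasible for n <= 7).
bf_mst_weight <- function(net) {
  w <- net$weights
  n <- nrow(w)
  up <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(up)
  stopifnot(m >= n - 1)
  best <- -Inf
  for (comb in utils::combn(m, n - 1, simplify = FALSE)) {
    sub <- matrix(0, n, n)
    sub[up[comb, , drop = FALSE]] <- 1
    sub <- sub + t(sub)
    if (all(tractnet:::.components(sub) == 1L))
      best <- max(best, sum(w[up[comb, , drop = FALSE]]))
  }
  best
}

# Best total weight of any m-edge superset of a spanning tree (exhaustive,
# tiny graphs only): used to check backbone optimality.
bf_best_backbone_weight <- function(net, m_target) {
  w <- net$weights
  n <- nrow(w)
  up <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(up)
  stopifnot(m >= m_target)
  best <- -Inf
  for (comb in utils::combn(m, m_target, simplify = FALSE)) {
    sub <- matrix(0, n, n)
    sub[up[comb, , drop = FALSE]] <- 1
    sub <- sub + t(sub)
    if (all(tractnet:::.components(sub) == 1L)) {
      # connected with m_target >= n-1 edges => contains a spanning tree
      best <- max(best, sum(w[up[comb, , drop = FALSE]]))
    }
  }
  best
}

# Small constructed motion log with given maxima.
make_motion <- function(max_trans, max_rot, n_vol = 10) {
  m <- matrix(0, n_vol, 6)
  m[n_vol %/% 2, 1] <- max_trans
  m[n_vol %/% 2 + 1, 5] <- max_rot
  motion_log(m)
}
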