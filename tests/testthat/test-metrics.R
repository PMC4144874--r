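test_that("degree and strength match hand counts and row sums", {
  # star with 4 unit-weight leaves
  w <- matrix(0, 5, 5)
  w[1, 2:5] <- 1
  net <- weighted_network(w + t(w))
  ks <- degree_and_strength(net)
  expect_equal(ks$degree, c(4L, 1L, 1L, 1L, 1L))
  expect_equal(ks$strength, c(4, 1, 1, 1, 1))
  # empty graph
  z <- degree_and_strength(weighted_network(matrix(0, 4, 4)))
  expect_true(all(z$degree == 0) && all(z$strength == 0))
  # identity on random nets
  net <- rand_net(7, seed = 2)
  expect_equal(degree_and_strength(net)$strength, rowSums(net$weights),
               ignore_attr = TRUE)
})

test_that("generalized clustering follows the cube-root triple product", {
  # unit triangle -> all 1
  w <- matrix(0, 3, 3); w[upper.tri(w)] <- 1
  expect_equal(unname(generalized_clustering(weighted_network(w + t(w)))$nodal),
               rep(1, 3))
  # triangle with weights 1, 8, 27 -> all (1*8*27)^(1/3) = 6
  w <- matrix(0, 3, 3); w[1, 2] <- 1; w[1, 3] <- 8; w[2, 3] <- 27
  expect_equal(unname(generalized_clustering(weighted_network(w + t(w)))$nodal),
               rep(6, 3))
  # triangle-free graph -> all zero
  p <- matrix(0, 4, 4); p[1, 2] <- p[2, 3] <- p[3, 4] <- 2
  expect_equal(unname(generalized_clustering(weighted_network(p + t(p)))$nodal),
               rep(0, 4))
})

test_that("shortest paths invert weights and count equal-length routes", {
  # unit path a-b-c: d(a,c) = 2
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 3] <- 1
  sp <- shortest_paths(weighted_network(w + t(w)))
  expect_equal(sp$d[1, 3], 2)
  # direct w=0.5 edge (length 2) ties with a two-hop unit route (1+1)
  w <- matrix(0, 3, 3); w[1, 2] <- 0.5; w[1, 3] <- 1; w[3, 2] <- 1
  sp <- shortest_paths(weighted_network(w + t(w)))
  expect_equal(sp$d[1, 2], 2)
  expect_equal(sp$sigma[1, 2], 2)
  # disconnected pairs are infinite
  w <- matrix(0, 4, 4); w[1, 2] <- 1
  sp <- shortest_paths(weighted_network(w + t(w)))
  expect_true(is.infinite(sp$d[1, 3]))
})

test_that("path length metrics use means and the harmonic-mean convention", {
  # complete unit graph: all L_i = 1, L(G) = 1
  w <- matrix(1, 4, 4); diag(w) <- 0
  pl <- path_length_metrics(shortest_paths(weighted_network(w)))
  expect_equal(unname(pl$nodal), rep(1, 4))
  expect_equal(pl$network, 1)
  # 3-cycle with all weights 2 (edge length 0.5)
  w <- matrix(2, 3, 3); diag(w) <- 0
  pl <- path_length_metrics(shortest_paths(weighted_network(w)))
  expect_equal(pl$network, 0.5)
  # isolated node: nodal L infinite but L(G) finite
  w <- matrix(0, 4, 4); w[1, 2] <- w[1, 3] <- w[2, 3] <- 1
  pl <- path_length_metrics(shortest_paths(weighted_network(w + t(w))))
  expect_true(is.infinite(pl$nodal[4]))
  expect_true(is.finite(pl$network))
})

test_that("betweenness counts ordered pairs through interior nodes", {
  # unit path a-b-c: both ordered pairs (a,c), (c,a) pass through b
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 3] <- 1
  bc <- betweenness(shortest_paths(weighted_network(w + t(w))))
  expect_equal(unname(bc), c(0, 2, 0))
  # complete graph: no interior vertices
  w <- matrix(1, 5, 5); diag(w) <- 0
  expect_equal(unname(betweenness(shortest_paths(weighted_network(w)))),
               rep(0, 5))
  # tied routes split the count: diamond a-b, a-c, b-d, c-d (unit weights)
  w <- matrix(0, 4, 4); w[1, 2] <- w[1, 3] <- w[2, 4] <- w[3, 4] <- 1
  bc <- betweenness(shortest_paths(weighted_network(w + t(w))))
  expect_equal(unname(bc), c(1, 1, 1, 1))  # 2 ordered pairs x 1/2 each
})

test_that("efficiencies match their closed forms on canonical graphs", {
  # complete unit-weight graph: E_glob = 1
  w <- matrix(1, 5, 5); diag(w) <- 0
  ef <- efficiencies(weighted_network(w))
  expect_equal(ef$e_glob, 1)
  expect_equal(ef$e_loc, 1)
  # empty graph: both zero
  ef <- efficiencies(weighted_network(matrix(0, 4, 4)))
  expect_equal(ef$e_glob, 0)
  expect_equal(ef$e_loc, 0)
  # unit star: no neighbour-neighbour edges -> E_loc = 0
  w <- matrix(0, 5, 5); w[1, 2:5] <- 1
  ef <- efficiencies(weighted_network(w + t(w)))
  expect_equal(ef$e_loc, 0)
  expect_gt(ef$e_glob, 0)
})

test_that("all metrics agree with brute-force enumeration on random graphs", {
  for (seed in 1:40) {
    n <- sample(4:6, 1)
    net <- rand_net(n, density = runif(1, 0.4, 0.9), seed = seed)
    sp <- shortest_paths(net)
    bf <- bf_shortest(net)
    expect_equal(unname(sp$d), bf$d, tolerance = 1e-10)
    expect_equal(unname(sp$sigma), bf$sigma)
    # betweenness: implementation counts ordered pairs, oracle does too
    expect_equal(unname(betweenness(sp)), bf$betweenness, tolerance = 1e-9)
    expect_equal(unname(generalized_clustering(net)$nodal), bf_clustering(net),
                 tolerance = 1e-12)
    expect_equal(efficiencies(net, sp)$e_glob, bf_eglob(bf$d),
                 tolerance = 1e-10)
  }
})

test_that("unit-weight metrics match an independent graph library", {
  skip_if_not_installed("igraph")
  for (seed in 1:15) {
    net <- rand_net(7, density = 0.5, seed = 400 + seed)
    w01 <- (net$weights > 0) * 1
    net01 <- weighted_network(w01)
    g <- igraph::graph_from_adjacency_matrix(w01, mode = "undirected")
    sp <- shortest_paths(net01)
    d_ig <- igraph::distances(g)
    expect_equal(unname(sp$d), unname(d_ig))
    # ordered-pair convention doubles the unordered library value
    expect_equal(unname(betweenness(sp)),
                 2 * unname(igraph::betweenness(g)), tolerance = 1e-9)
  }
})

test_that("metrics are permutation-equivariant and scale correctly", {
  net <- rand_net(6, density = 0.7, seed = 77)
  sp <- shortest_paths(net)
  nm <- nodal_metrics(net, sp)
  set.seed(1)
  perm <- sample(6)
  net_p <- weighted_network(net$weights[perm, perm])
  nm_p <- nodal_metrics(net_p)
  for (col in c("degree", "strength", "clustering", "mean_path_length",
                "betweenness"))
    expect_equal(nm_p[[col]], nm[[col]][perm], tolerance = 1e-9)
  # scaling by c > 0: S, C, E_glob scale by c; d, L by 1/c; K, BC invariant
  cc <- 3.7
  net_s <- weighted_network(cc * net$weights)
  nm_s <- nodal_metrics(net_s)
  expect_equal(nm_s$degree, nm$degree)
  expect_equal(nm_s$strength, cc * nm$strength)
  expect_equal(nm_s$clustering, cc * nm$clustering)
  expect_equal(nm_s$mean_path_length, nm$mean_path_length / cc)
  expect_equal(nm_s$betweenness, nm$betweenness, tolerance = 1e-9)
  gm <- global_metrics(net)
  gm_s <- global_metrics(net_s)
  expect_equal(gm_s$e_glob, cc * gm$e_glob)
  expect_equal(gm_s$e_loc, cc * gm$e_loc)
  expect_equal(gm_s$char_path_length, gm$char_path_length / cc)
})
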