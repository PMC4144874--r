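test_that("motion screening applies the 1 mm / 1 degree exclusion rule", {
  thr <- qc_thresholds()
  expect_true(screen_motion(motion_log(matrix(0, 5, 6)), thr)$keep)
  r <- screen_motion(make_motion(1.2, 0.2), thr)
  expect_false(r$keep)
  expect_equal(r$reason, "translation")
  r <- screen_motion(make_motion(0.9, 1.5), thr)
  expect_false(r$keep)
  expect_equal(r$reason, "rotation")
  # boundary: exactly at threshold is kept (rule is strictly greater-than)
  expect_true(screen_motion(make_motion(1.0, 1.0), thr)$keep)
  expect_error(motion_log(matrix(0, 0, 6)), "at least one volume")
  expect_error(motion_log(matrix(0, 5, 5)), "6 columns")
})

test_that("motion screening agrees with a brute-force max-over-entries check", {
  set.seed(31)
  for (r in 1:50) {
    m <- matrix(rnorm(60, sd = 0.6), 10, 6)
    log <- motion_log(m)
    dec <- screen_motion(log)
    expect_equal(dec$keep,
                 max(abs(m[, 1:3])) <= 1 && max(abs(m[, 4:6])) <= 1)
  }
})

test_that("weight matrix combines voxel-normalized directed counts", {
  tc <- tract_counts(matrix(c(0, 6, 10, 0), 2, 2), voxels = c(5, 3),
                     labels = c("A", "B"))
  net <- build_weight_matrix(tc)
  expect_equal(net$weights["A", "B"], 10 / 5 + 6 / 3)  # 4.0
  expect_equal(net$weights, t(net$weights))
  # zero counts give the zero matrix
  z <- build_weight_matrix(tract_counts(matrix(0, 3, 3), voxels = 1:3))
  expect_true(all(z$weights == 0))
  expect_error(tract_counts(matrix(0, 2, 2), voxels = c(0, 1)),
               "strictly positive")
})

test_that("weight construction ignores self-counts and is permutation-equivariant", {
  set.seed(8)
  n <- 6
  cm <- matrix(rpois(n * n, 20), n, n)
  vox <- sample(50:500, n)
  base <- build_weight_matrix(tract_counts(cm, vox))
  cm_self <- cm
  diag(cm_self) <- 99
  expect_equal(build_weight_matrix(tract_counts(cm_self, vox))$weights,
               base$weights)
  perm <- sample(n)
  net_p <- build_weight_matrix(tract_counts(cm[perm, perm], vox[perm]))
  expect_equal(net_p$weights, unname(base$weights[perm, perm]),
               ignore_attr = TRUE)
})

test_that("averaging is the entrywise mean and validates labels", {
  w1 <- matrix(0, 3, 3); w1[1, 2] <- w1[2, 1] <- 2
  w2 <- matrix(0, 3, 3); w2[1, 2] <- w2[2, 1] <- 6
  n1 <- weighted_network(w1, labels = c("a", "b", "c"))
  n2 <- weighted_network(w2, labels = c("a", "b", "c"))
  expect_equal(average_networks(list(n1, n2))$weights["a", "b"], 4)
  expect_equal(average_networks(list(n1)), n1)
  expect_equal(average_networks(list(n2, n2, n2)), n2)
  n3 <- weighted_network(w2, labels = c("a", "b", "z"))
  expect_error(average_networks(list(n1, n3)), "labels")
  expect_error(average_networks(list()), "non-empty")
})

test_that("backbone reproduces the 4-node worked example", {
  wb <- matrix(0, 4, 4)
  wb[1, 2] <- 5; wb[1, 3] <- 4; wb[1, 4] <- 1
  wb[2, 3] <- 3; wb[2, 4] <- 2; wb[3, 4] <- 6
  net <- weighted_network(wb + t(wb))
  bb <- extract_backbone(net, backbone_config(k = 2))
  kept <- which(upper.tri(bb$weights) & bb$weights > 0, arr.ind = TRUE)
  kept <- kept[order(kept[, 1], kept[, 2]), ]
  # MST {34, 12, 13} plus strongest non-tree edge 23
  expect_equal(unname(kept),
               matrix(c(1, 2, 1, 3, 2, 3, 3, 4), ncol = 2, byrow = TRUE))
  expect_equal(bb$weights[1, 2], 5)  # original weights preserved
})

test_that("backbone keeps floor(N*k/2) edges, stays connected, holds an MST", {
  for (seed in 1:20) {
    n <- sample(5:9, 1)
    net <- rand_net(n, density = 0.8, seed = seed, connected = TRUE)
    k <- 3
    m_target <- floor(n * k / 2)
    if (sum(net$weights > 0) / 2 < m_target) next
    bb <- extract_backbone(net, backbone_config(k))
    expect_equal(sum(bb$weights > 0) / 2, m_target)
    expect_true(all(tractnet:::.components(bb$weights) == 1L))
    # kept weights are original weights
    expect_true(all((bb$weights == net$weights)[bb$weights > 0]))
  }
})

test_that("backbone spanning tree attains the brute-force maximum weight", {
  for (seed in 1:15) {
    n <- sample(4:7, 1)
    net <- rand_net(n, density = 0.7, seed = 100 + seed, connected = TRUE)
    bb <- extract_backbone(net,
                           backbone_config(k = 2 * (n - 1) / n))  # tree only
    expect_equal(sum(bb$weights) / 2, bf_mst_weight(net), tolerance = 1e-12)
  }
})

test_that("backbone total weight is maximal among same-size connected subgraphs", {
  for (seed in 1:10) {
    n <- sample(4:6, 1)
    net <- rand_net(n, density = 0.9, seed = 200 + seed, connected = TRUE)
    m <- sum(net$weights > 0) / 2
    m_target <- min(m, n)  # a spanning tree plus a few extras
    k <- 2 * m_target / n
    if (k < 2 * (n - 1) / n) next
    bb <- extract_backbone(net, backbone_config(k))
    expect_equal(sum(bb$weights) / 2, bf_best_backbone_weight(net, m_target),
                 tolerance = 1e-12)
  }
})

test_that("backbone MST total weight matches an independent library check", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    net <- rand_net(8, density = 0.6, seed = 300 + seed, connected = TRUE)
    bb <- extract_backbone(net, backbone_config(k = 2 * 7 / 8))
    g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g, weights = -igraph::E(g)$weight)
    expect_equal(sum(bb$weights) / 2, sum(igraph::E(mst)$weight),
                 tolerance = 1e-12)
  }
})

test_that("backbone errors are informative", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1  # plus isolated pair 3-4
  w[3, 4] <- w[4, 3] <- 1
  expect_error(extract_backbone(weighted_network(w)), "disconnected")
  path <- matrix(0, 4, 4)
  path[1, 2] <- path[2, 3] <- path[3, 4] <- 1
  net <- weighted_network(path + t(path))
  expect_error(extract_backbone(net, backbone_config(k = 4)),
               "only 3 positive edges")
  expect_error(extract_backbone(net, backbone_config(k = 1)), "2\\(N-1\\)/N")
  # exactly floor(N*k/2) edges forming a connected graph: output == input
  expect_equal(extract_backbone(net, backbone_config(k = 1.5))$weights,
               net$weights)
})
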