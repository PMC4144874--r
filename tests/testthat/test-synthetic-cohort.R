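test_that("cohort generation is deterministic and subsets are reproducible", {
  spec <- cohort_spec(n_per_group = 3, n_nodes = 12, n_scans = 2, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  # different seed changes the data
  c <- generate_cohort(cohort_spec(n_per_group = 3, n_nodes = 12,
                                   n_scans = 2, seed = 43))
  expect_false(identical(a$subjects[[1]]$scans[[1]]$counts$counts,
                         c$subjects[[1]]$scans[[1]]$counts$counts))
})

test_that("a shared geometry seed fixes the template but not the subjects", {
  a <- generate_cohort(cohort_spec(n_per_group = 2, n_nodes = 10, n_scans = 1,
                                   seed = 1, geometry_seed = 77))
  b <- generate_cohort(cohort_spec(n_per_group = 2, n_nodes = 10, n_scans = 1,
                                   seed = 2, geometry_seed = 77))
  expect_identical(a$geometry, b$geometry)
  expect_false(identical(a$subjects[[1]]$scans[[1]]$counts$counts,
                         b$subjects[[1]]$scans[[1]]$counts$counts))
})

test_that("invalid spec fields are rejected naming the field", {
  expect_error(cohort_spec(n_per_group = 1), "n_per_group")
  expect_error(cohort_spec(n_nodes = 2), "n_nodes")
  expect_error(cohort_spec(n_scans = 4), "n_scans")
  expect_error(cohort_spec(base_density = 1.5), "base_density")
  expect_error(cohort_spec(mean_count = -1), "mean_count")
  expect_error(cohort_spec(dispersion = 0), "dispersion")
  expect_error(cohort_spec(effect_multiplier = 0), "effect_multiplier")
  expect_error(cohort_spec(effect_nodes = "NOPE_L"), "effect_nodes")
  expect_error(cohort_spec(voxel_range = c(10, 5)), "voxel_range")
})

test_that("null cohorts draw both groups from identical distributions", {
  spec <- cohort_spec(n_per_group = 8, n_nodes = 15, n_scans = 1,
                      effect_multiplier = 1, seed = 7)
  coh <- generate_cohort(spec)
  groups <- vapply(coh$subjects, `[[`, "", "group")
  # same latent mask, voxel counts and expected counts for every subject
  expect_identical(expected_weight_matrix(spec, "control"),
                   expected_weight_matrix(spec, "musician"))
  # pooled mean count similar between groups (same distribution)
  tot <- vapply(coh$subjects, function(s) sum(s$scans[[1]]$counts$counts), 0)
  expect_gt(t.test(tot[groups == "control"], tot[groups == "musician"])$p.value,
            0.001)
})

test_that("injected effects raise expected and observed strength at effect nodes", {
  labels <- sprintf("R%03d", 1:15)
  eff <- labels[c(2, 5, 9, 14)]
  base <- list(n_per_group = 6, n_nodes = 15, n_scans = 1,
               effect_nodes = eff, seed = 99)
  s_null <- do.call(cohort_spec, c(base, effect_multiplier = 1))
  s_eff <- do.call(cohort_spec, c(base, effect_multiplier = 1.5))
  w0 <- expected_weight_matrix(s_null, "musician")
  w1 <- expected_weight_matrix(s_eff, "musician")
  idx <- match(eff, labels)
  expect_equal(w1[idx, ], 1.5 * w0[idx, ])
  # control group untouched
  expect_identical(expected_weight_matrix(s_eff, "control"), w0)
  # Monte-Carlo: group-2 mean strength at effect nodes exceeds group 1
  # in (almost) every replicate
  hits <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    sp <- do.call(cohort_spec, c(base[setdiff(names(base), "seed")],
                                 effect_multiplier = 1.5, seed = 1000 + r))
    coh <- generate_cohort(sp)
    st <- vapply(coh$subjects, function(su) {
      net <- build_weight_matrix(su$scans[[1]]$counts)
      mean(rowSums(net$weights)[idx])
    }, 0)
    grp <- vapply(coh$subjects, `[[`, "", "group")
    hits <- hits + (mean(st[grp == "musician"]) > mean(st[grp == "control"]))
  }
  expect_gte(hits, n_rep - 2L)
})

test_that("expected weight matrix matches the hand formula on a single connection", {
  # find a present connection in a realized mask and check m/v1 + m/v2
  spec <- cohort_spec(n_per_group = 2, n_nodes = 10, n_scans = 1, seed = 5)
  geom <- tractnet:::.cohort_geometry(spec)
  w <- expected_weight_matrix(spec, "control")
  idx <- which(geom$mask & upper.tri(geom$mask), arr.ind = TRUE)
  i <- idx[1, 1]; j <- idx[1, 2]
  m <- geom$mu[i, j]
  expect_equal(w[i, j], m / geom$voxels[i] + m / geom$voxels[j])
  # absent connections have zero expectation
  off <- which(!geom$mask & upper.tri(geom$mask), arr.ind = TRUE)
  if (nrow(off)) expect_equal(w[off[1, 1], off[1, 2]], 0)
  expect_error(expected_weight_matrix(spec, "patient"), "unknown group")
})

test_that("zero density yields an empty expected matrix", {
  spec <- cohort_spec(n_per_group = 2, n_nodes = 8, base_density = 0,
                      seed = 1)
  expect_true(all(expected_weight_matrix(spec, "control") == 0))
})

test_that("empirical counts match the stated mean and overdispersion", {
  spec <- cohort_spec(n_per_group = 16, n_nodes = 30, n_scans = 1,
                      mean_count = 80, dispersion = 4, seed = 21)
  coh <- generate_cohort(spec)
  geom <- coh$geometry
  idx <- which(geom$mask & upper.tri(geom$mask))
  mus <- geom$mu[idx]
  obs <- vapply(coh$subjects,
                function(su) su$scans[[1]]$counts$counts[idx],
                numeric(length(idx)))
  # standardized residuals against NB mean/variance should be ~N(0,1)
  vars <- mus + mus^2 / 4
  z <- (rowMeans(obs) - mus) / sqrt(vars / ncol(obs))
  expect_lt(abs(mean(z)), 0.15)
  # pooled variance should reflect overdispersion (far above Poisson)
  ratio <- mean(apply(obs, 1, var) / vars)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("motion logs are random walks and qc_fail_rate forces violations", {
  spec <- cohort_spec(n_per_group = 8, n_nodes = 10, n_scans = 1,
                      motion_sd = 0.05, qc_fail_rate = 1, seed = 3)
  coh <- generate_cohort(spec)
  keeps <- vapply(coh$subjects,
                  function(su) screen_motion(su$scans[[1]]$motion)$keep, TRUE)
  expect_true(all(!keeps))
  spec0 <- cohort_spec(n_per_group = 8, n_nodes = 10, n_scans = 1,
                       motion_sd = 0.01, qc_fail_rate = 0, seed = 3)
  coh0 <- generate_cohort(spec0)
  keeps0 <- vapply(coh0$subjects,
                   function(su) screen_motion(su$scans[[1]]$motion)$keep, TRUE)
  expect_true(all(keeps0))
})

test_that("onset ages are uniform within range for musicians only", {
  spec <- cohort_spec(n_per_group = 10, n_nodes = 10, n_scans = 1,
                      onset_age_range = c(5, 9), seed = 12)
  coh <- generate_cohort(spec)
  onset <- vapply(coh$subjects, `[[`, 0, "onset_age")
  grp <- vapply(coh$subjects, `[[`, "", "group")
  expect_true(all(is.na(onset[grp == "control"])))
  expect_true(all(onset[grp == "musician"] >= 5 &
                    onset[grp == "musician"] <= 9))
})
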