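# Streamline bundles, cleaning, tract profiles, tract-level statistics.

demo_core <- function(n = 40) {
  s <- seq(0, 1, length.out = n)
  cbind(30 + 120 * s, 90 - 15 * sin(pi * s), rep(6, n))
}

test_that("bundle generation is deterministic with controlled spread", {
  b0 <- generate_bundle(demo_core(), 20, spread_mm = 0, outlier_frac = 0, seed = 1)
  expect_true(all(vapply(b0$streamlines, function(p) max(abs(p - demo_core())), 0) < 1e-12))
  b1 <- generate_bundle(demo_core(), 30, spread_mm = 2, seed = 5)
  b2 <- generate_bundle(demo_core(), 30, spread_mm = 2, seed = 5)
  expect_identical(b1$streamlines, b2$streamlines)
  expect_error(generate_bundle(demo_core(5), 10), ">= 20")
})

test_that("planted outliers exceed the cleaning threshold by construction", {
  b <- generate_bundle(demo_core(), 50, spread_mm = 2, outlier_frac = 0.1, seed = 3)
  rs <- lapply(b$streamlines, mrfrelia:::resample_streamline, n_nodes = 50)
  core <- apply(array(unlist(rs), c(50, 3, 50)), 1:2, mean)
  dist <- vapply(rs, function(p) mean(sqrt(rowSums((p - core)^2))), 0)
  inl <- setdiff(seq_len(50), b$planted_outliers)
  displaced <- b$planted_outliers[b$planted_outliers %% 2 == 0]
  expect_true(all(dist[displaced] > mean(dist[inl]) + 3 * sd(dist[inl])))
})

test_that("cleaning removes gross outliers and keeps inliers", {
  b <- generate_bundle(demo_core(), 50, spread_mm = 2, outlier_frac = 0.1, seed = 3)
  cl <- clean_bundle(b)
  expect_true(all(!(b$planted_outliers %in% cl$kept)))
  inliers <- setdiff(seq_len(50), b$planted_outliers)
  expect_gte(mean(inliers %in% cl$kept), 0.95)
  # idempotence and the no-op case
  cl2 <- clean_bundle(cl)
  expect_identical(cl2$kept, seq_along(cl$streamlines))
  b_raw <- clean_bundle(b, iterations = 0)
  expect_identical(b_raw$streamlines, b$streamlines)
  expect_error(clean_bundle(b, core_sd = -10, length_sd = -10), "degenerate")
})

test_that("profiles are flat on constant maps with unit node weights", {
  b <- clean_bundle(generate_bundle(demo_core(), 30, spread_mm = 2, seed = 2))
  cmap <- array(850, c(64, 64, 3))
  pr <- suppressMessages(tract_profile(b, cmap, voxel_mm = 3))
  expect_equal(pr$node_values, rep(850, 100))
  expect_equal(rowSums(pr$node_weights), rep(1, 100), tolerance = 1e-12)
  expect_equal(pr$analyzed_nodes, 11:90)
})

test_that("a linear gradient maps to a linear profile", {
  b <- clean_bundle(generate_bundle(demo_core(), 30, spread_mm = 1.5, seed = 2))
  gmap <- array(rep(seq_len(64), 64 * 3), c(64, 64, 3))
  pr <- suppressMessages(tract_profile(b, gmap, voxel_mm = 3))
  v <- pr$node_values
  lin <- seq(v[1], v[100], length.out = 100)
  expect_lt(max(abs(v - lin)), 0.01 * diff(range(v)))
})

test_that("profiles are invariant to streamline point-order reversal", {
  b <- clean_bundle(generate_bundle(demo_core(), 25, spread_mm = 2, seed = 4))
  gmap <- array(rep(seq_len(64), 64 * 3), c(64, 64, 3)) * 3
  p1 <- suppressMessages(tract_profile(b, gmap, voxel_mm = 3))
  b_rev <- b
  b_rev$streamlines <- lapply(b$streamlines, function(p) p[nrow(p):1, ])
  p2 <- suppressMessages(tract_profile(b_rev, gmap, voxel_mm = 3))
  expect_equal(p1$node_values, p2$node_values, tolerance = 1e-9)
})

test_that("profile reliability matches the variance-ratio closed form", {
  n_sub <- 25; tau <- 20; sigma <- 10
  rho <- tau^2 / (tau^2 + sigma^2)
  rs <- vapply(1:30, function(i) {
    set.seed(700 + i)
    truth <- 900 + rnorm(n_sub, 0, tau)
    base <- outer(truth, rep(1, 100))
    p1 <- base + matrix(rnorm(n_sub * 100, 0, sigma * 10), n_sub)
    p2 <- base + matrix(rnorm(n_sub * 100, 0, sigma * 10), n_sub)
    # node noise averages down by sqrt(80) over the analyzed window
    profile_reliability(p1, p2, n_boot = 10, seed = i)$tract_mean_r
  }, 0)
  rho_eff <- tau^2 / (tau^2 + (10 * sigma)^2 / 80)
  expect_lt(abs(mean(rs) - rho_eff), 0.05)
})

test_that("identical and shuffled sessions bracket the reliability range", {
  set.seed(11)
  p <- matrix(rnorm(20 * 100, 900, 25), 20)
  same <- profile_reliability(p, p, n_boot = 20, seed = 1)
  expect_equal(same$tract_mean_r, 1)
  expect_equal(same$per_node_r[11:90], rep(1, 80), tolerance = 1e-12)
  shuf <- profile_reliability(p, p[sample(20), ], n_boot = 200, seed = 2)
  expect_true(shuf$tract_mean_ci[1] < 0.3 && shuf$tract_mean_ci[2] > -0.3)
  expect_error(profile_reliability(p[1:2, ], p[1:2, ]), ">= 3")
})

test_that("age correlations recover a generative slope and control false positives", {
  spec <- cohort_spec(n_subjects = 40, seed = 2)
  tab <- simulate_cohort(spec)$subjects
  # tract means: subject WM R1 plus small independent extraction noise
  set.seed(22)
  r1m <- outer(tab$wm_r1_s1, rep(1, 6)) + matrix(rnorm(40 * 6, 0, 0.004), 40)
  res <- age_correlation(r1m, tab$age_s1)
  expect_true(all(res$r > 0))
  expect_true(any(res$significant))
  # null: zero slope, 50 replicates, family-wise FP fraction <= 5%
  fp <- vapply(1:50, function(i) {
    sp <- cohort_spec(n_subjects = 40, r1_age_slope = 0, seed = 3000 + i)
    tb <- simulate_cohort(sp)$subjects
    set.seed(5000 + i)
    m <- outer(tb$wm_r1_s1, rep(1, 6)) + matrix(rnorm(40 * 6, 0, 0.004), 40)
    mean(age_correlation(m, tb$age_s1)$significant)
  }, 0)
  expect_lte(mean(fp), 0.05)
  one <- age_correlation(r1m[, 1, drop = FALSE], tab$age_s1)
  expect_equal(one$p_fdr, one$p)
  expect_error(age_correlation(r1m, rep(10, 40)), "constant")
  expect_error(age_correlation(r1m[1:5, ], tab$age_s1[1:5]), ">= 10")
})

test_that("T1 and R1 tract analyses are rank-consistent", {
  set.seed(12)
  t1_means <- runif(15, 700, 1100)
  r1_means <- 1000 / t1_means
  expect_equal(cor(t1_means, r1_means, method = "spearman"), -1)
})

test_that("streamline bundles round-trip through the JSON container", {
  b <- clean_bundle(generate_bundle(demo_core(), 12, spread_mm = 2, seed = 6))
  path <- tempfile(fileext = ".json")
  write_streamlines_json(b, path)
  back <- read_streamlines_json(path)
  expect_equal(length(back$streamlines), length(b$streamlines))
  expect_equal(back$streamlines[[3]], unname(as.matrix(b$streamlines[[3]])),
               tolerance = 1e-12)
  expect_equal(back$name, b$name)
  expect_equal(back$orientation, b$orientation)
})
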