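# Scan-rescan statistics: voxelwise/ROI reliability, Bland-Altman, mixed model.

test_that("identical and offset maps give the expected voxelwise statistics", {
  set.seed(1)
  m1 <- array(900 + rnorm(1000, 0, 30), c(10, 10, 10))
  r_same <- voxelwise_reliability(m1, m1)
  expect_equal(r_same$pearson_r, 1)
  expect_equal(r_same$r2_identity, 1)
  expect_equal(r_same$cv_percent, 0)
  r_off <- voxelwise_reliability(m1, m1 + 100)
  expect_equal(r_off$pearson_r, 1, tolerance = 1e-12)
  expect_lt(r_off$r2_identity, 1)
  r_const <- voxelwise_reliability(array(5, c(4, 4, 1)), array(5, c(4, 4, 1)))
  expect_true(r_const$missing)
  expect_true(is.na(r_const$pearson_r))
})

test_that("estimated r recovers a known correlation of 0.85", {
  rs <- vapply(1:50, function(i) {
    set.seed(400 + i)
    x <- rnorm(1e4)
    y <- 0.85 * x + sqrt(1 - 0.85^2) * rnorm(1e4)
    voxelwise_reliability(array(x + 10, c(100, 100, 1)),
                          array(y + 10, c(100, 100, 1)))$pearson_r
  }, 0)
  expect_lt(abs(mean(rs) - 0.85), 0.02)
})

test_that("identity-line R2 never exceeds the squared correlation", {
  for (i in 1:20) {
    set.seed(i)
    x <- rnorm(500, 100, 10)
    y <- 0.8 * x + rnorm(500, 25, 5)
    v <- voxelwise_reliability(array(x, c(500, 1, 1)), array(y, c(500, 1, 1)))
    expect_lte(v$r2_identity, v$pearson_r^2 + 1e-12)
  }
})

test_that("CV is scale invariant and matches the two-point closed form", {
  lab <- array(1L, c(2, 2, 1))
  s1 <- replicate(3, array(1000, c(2, 2, 1)), simplify = FALSE)
  s2 <- replicate(3, array(1020, c(2, 2, 1)), simplify = FALSE)
  tab <- roi_reliability(s1, s2, lab, 1L)
  expect_equal(tab$cv_percent, (20 / sqrt(2)) / 1010 * 100, tolerance = 1e-6)
  expect_equal(round(tab$cv_percent, 3), 1.400)
  s1k <- lapply(s1, function(m) m * 7); s2k <- lapply(s2, function(m) m * 7)
  expect_equal(roi_reliability(s1k, s2k, lab, 1L)$cv_percent, tab$cv_percent)
})

test_that("ROI reliability recovers the classical variance-ratio form", {
  # across-subject r ~ tau^2 / (tau^2 + sigma^2)
  tau <- 30; sigma <- 15
  rho <- tau^2 / (tau^2 + sigma^2)
  rs <- vapply(1:30, function(i) {
    set.seed(500 + i)
    truth <- rnorm(25, 900, tau)
    a <- truth + rnorm(25, 0, sigma)
    b <- truth + rnorm(25, 0, sigma)
    cor(a, b)
  }, 0)
  expect_lt(abs(mean(rs) - rho), 0.05)
})

test_that("subjects missing an ROI are dropped with a log message", {
  lab1 <- array(1L, c(2, 2, 1)); lab2 <- array(2L, c(2, 2, 1))
  s1 <- list(array(1000, c(2, 2, 1)), array(900, c(2, 2, 1)), array(950, c(2, 2, 1)))
  expect_message(
    tab <- roi_reliability(s1, s1, list(lab1, lab1, lab2), 1L),
    "dropped")
  expect_equal(tab$n_subjects, 2)
})

test_that("Bland-Altman summaries match their definitions", {
  p_same <- cbind(c(1, 2, 3), c(1, 2, 3))
  ba <- bland_altman(p_same)
  expect_equal(ba$mean_difference, 0)
  expect_equal(diff(ba$loa), 0)
  ba5 <- bland_altman(cbind(c(1, 2, 3), c(6, 7, 8)))
  expect_equal(ba5$mean_difference, 5)
  set.seed(2)
  a <- rnorm(1e4, 100, 1)
  d <- rnorm(1e4, 0, 2)
  ban <- bland_altman(cbind(a, a + d))
  expect_lt(abs((ban$loa[2] - ban$mean_difference) - 3.92), 0.15)
  expect_error(bland_altman(cbind(1, 2)), ">= 2")
})

test_that("the mixed model recovers a planted duration effect", {
  make_table <- function(seed, beta_dur = 0.03, subj_sd = 0.02, res_sd = 0.005) {
    set.seed(seed)
    n <- 48
    subj <- rnorm(n, 0, subj_sd)
    age <- runif(n, 8, 13)
    grid <- expand.grid(participant = seq_len(n),
                        duration = c("2min", "4min"), b0 = c("off", "on"))
    grid$age <- age[grid$participant]
    grid$r <- 0.8 + subj[grid$participant] +
      beta_dur * (grid$duration == "4min") + rnorm(nrow(grid), 0, res_sd)
    grid
  }
  betas <- vapply(1:20, function(i) {
    fit <- fit_reliability_lmm(make_table(600 + i))
    fit$fixed$estimate[fit$fixed$term == "duration4min"]
  }, 0)
  expect_lt(abs(mean(betas) - 0.03), 0.01)
})

test_that("degenerate and permuted designs behave predictably", {
  tab <- expand.grid(participant = 1:6, duration = c("2min", "4min"),
                     b0 = c("off", "on"))
  tab$age <- 10
  tab$r <- 0.8
  fit <- fit_reliability_lmm(tab)
  est <- fit$fixed$estimate
  expect_equal(est[fit$fixed$term != "(Intercept)"], rep(0, 3), tolerance = 1e-10)
  expect_equal(fit$random_intercept_var, 0, tolerance = 1e-10)
  expect_equal(fit$residual_var, 0, tolerance = 1e-10)
  # relabeling participants in a balanced design leaves estimates unchanged
  set.seed(3)
  tab2 <- tab
  tab2$r <- 0.8 + rnorm(nrow(tab2), 0, 0.01)
  perm <- sample(6)
  tab3 <- tab2
  tab3$participant <- perm[tab3$participant]
  f2 <- fit_reliability_lmm(tab2)
  f3 <- fit_reliability_lmm(tab3)
  expect_equal(f2$fixed$estimate, f3$fixed$estimate, tolerance = 1e-8)
  expect_error(fit_reliability_lmm(tab[-1, ]), "factorial")
})
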