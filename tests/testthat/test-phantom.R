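# Digital phantom, B0 field, coil maps, and the simulated cohort.

test_that("phantoms are deterministic and physically consistent", {
  p1 <- make_phantom(c(48, 48, 2), voxel_size_mm = 4, seed = 3)
  p2 <- make_phantom(c(48, 48, 2), voxel_size_mm = 4, seed = 3)
  expect_identical(p1$t1_map, p2$t1_map)
  expect_identical(p1$label_map, p2$label_map)
  expect_identical(p1$b0_map[], p2$b0_map[])
  fg <- p1$label_map > 0
  expect_true(all(p1$t1_map[fg] > 0))
  expect_true(all(p1$t2_map[fg] <= p1$t1_map[fg]))
  expect_error(make_phantom(c(16, 16, 1)), ">= 32")
})

test_that("corpus callosum segment means follow an inverted U", {
  ph <- make_phantom(seed = 5)
  means <- vapply(4:8, function(l) mean(ph$t1_map[ph$label_map == l]), 0)
  peak <- which.max(means)
  expect_true(peak > 1 && peak < 5)
  expect_true(all(diff(means[1:peak]) > 0))
  expect_true(all(diff(means[peak:5]) < 0))
})

test_that("B0 field has a dominant localized pocket over a smooth background", {
  ph <- make_phantom(seed = 7)
  b0 <- make_b0_map(ph, pocket_amplitude_hz = 60, background_rms_hz = 5, seed = 2)
  pocket <- b0_pocket_mask(b0, dim(b0))
  expect_true(any(pocket))
  bg_rms <- sqrt(mean(b0[!pocket]^2))
  expect_gt(max(abs(b0[pocket])), 5 * bg_rms)
  # smoothness outside the pocket: finite differences bounded well below the
  # white-noise level (neighbour diffs of an unsmoothed field of this rms
  # would reach several times the rms)
  gx <- abs(diff(b0[, , 1]))
  outside <- !pocket[, , 1]
  expect_lt(max(gx[outside[-1, ] & outside[-nrow(outside), ]]), 2 * bg_rms)
  b00 <- make_b0_map(ph, pocket_amplitude_hz = 0, background_rms_hz = 0, seed = 2)
  expect_equal(max(abs(b00)), 0)
  expect_error(make_b0_map(ph, pocket_amplitude_hz = -1), ">= 0")
})

test_that("coil sensitivities are smooth with unit root-sum-of-squares", {
  maps <- make_coil_sensitivities(c(32, 32, 2), 4, seed = 1)
  rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  expect_equal(max(abs(rss - 1)), 0, tolerance = 1e-10)
  expect_identical(maps, make_coil_sensitivities(c(32, 32, 2), 4, seed = 1))
  one <- make_coil_sensitivities(c(32, 32, 1), 1, seed = 2)
  expect_equal(max(abs(Mod(one) - 1)), 0, tolerance = 1e-10)
  expect_error(make_coil_sensitivities(c(32, 32, 1), 0), ">= 1")
})

test_that("degenerate cohort settings collapse to identical subjects", {
  spec <- cohort_spec(n_subjects = 5, r1_age_slope = 0, between_subject_sd = 0,
                      motion_sd = c(0, 0), seed = 4)
  coh <- simulate_cohort(spec)
  expect_equal(diff(range(coh$subjects$wm_r1_s1)), 0)
  s2 <- realize_session(coh, 2, 2)
  expect_equal(s2$motion$angle_deg, 0)
  expect_equal(s2$motion$shift_mm, c(0, 0, 0))
})

test_that("generated age-R1 correlation matches its closed form", {
  # rho = slope * sd(age) / sqrt(slope^2 var(age) + sd_subject^2)
  spec <- cohort_spec(n_subjects = 40, r1_age_slope = 0.008,
                      between_subject_sd = 0.02)
  rs <- vapply(1:50, function(i) {
    sp <- spec; sp$seed <- 1000 + i
    tab <- simulate_cohort(sp)$subjects
    cor(tab$age_s1, tab$wm_r1_s1)
  }, 0)
  var_age <- diff(spec$age_range_y)^2 / 12
  rho <- spec$r1_age_slope * sqrt(var_age) /
    sqrt(spec$r1_age_slope^2 * var_age + spec$between_subject_sd^2)
  expect_gt(mean(rs), 0)
  expect_lt(abs(mean(rs) - rho), 0.05)
})

test_that("session realizations drift along the age slope and stay seeded", {
  spec <- cohort_spec(n_subjects = 3, seed = 11)
  coh <- simulate_cohort(spec)
  tab <- coh$subjects
  expect_equal(tab$age_s2, tab$age_s1 + tab$interval_months / 12)
  expect_true(all(tab$wm_r1_s2 > tab$wm_r1_s1))
  a <- realize_session(coh, 1, 1); b <- realize_session(coh, 1, 1)
  expect_identical(a$phantom$t1_map, b$phantom$t1_map)
})
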