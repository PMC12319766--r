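# Rigid transforms, half-way splitting, resampling, registration.

test_that("rigid group algebra is closed and consistent", {
  a <- rigid_transform(5, c(4, -2, 1))
  b <- rigid_transform(-12, c(-1, 3, 0))
  ab <- compose_rigid(a, b)
  inv <- invert_rigid(ab)
  id <- compose_rigid(ab, inv)
  expect_equal(id$angle_deg, 0, tolerance = 1e-10)
  expect_equal(id$shift_mm, c(0, 0, 0), tolerance = 1e-10)
  pts <- matrix(rnorm(30), 10, 3)
  ctr <- c(10, 10, 5)
  expect_equal(apply_rigid(ab, pts, ctr),
               apply_rigid(a, apply_rigid(b, pts, ctr), ctr), tolerance = 1e-10)
})

test_that("half-way split halves the motion and recomposes exactly", {
  tt <- rigid_transform(7, c(4, -2, 0))
  hw <- halfway_split(tt)
  back <- compose_rigid(hw$half_b, invert_rigid(hw$half_a))
  expect_equal(back$angle_deg, tt$angle_deg, tolerance = 1e-8)
  expect_equal(back$shift_mm, tt$shift_mm, tolerance = 1e-8)
  # identity and pure translation
  hid <- halfway_split(rigid_transform())
  expect_equal(hid$half_a$angle_deg, 0)
  expect_equal(hid$half_a$shift_mm, c(0, 0, 0))
  ht <- halfway_split(rigid_transform(0, c(4, 0, 0)))
  expect_equal(ht$half_a$shift_mm[1], -2)
  expect_equal(ht$half_b$shift_mm[1], 2)
  # swapping the session order exchanges the roles of the two halves
  hw_rev <- halfway_split(invert_rigid(tt))
  expect_equal(hw_rev$half_a$angle_deg, hw$half_b$angle_deg, tolerance = 1e-8)
  expect_equal(hw_rev$half_a$shift_mm, hw$half_b$shift_mm, tolerance = 1e-8)
  expect_equal(hw_rev$half_b$angle_deg, hw$half_a$angle_deg, tolerance = 1e-8)
  expect_equal(hw_rev$half_b$shift_mm, hw$half_a$shift_mm, tolerance = 1e-8)
})

test_that("resampling is exact at identity and invertible to tolerance", {
  ph <- make_phantom(c(48, 48, 2), voxel_size_mm = 4, seed = 3)
  img <- ph$t1_map
  same <- resample_image(img, rigid_transform(), 4)
  expect_equal(same[], img[], ignore_attr = TRUE)
  tr <- rigid_transform(3, c(5, -3, 0))
  fwd <- resample_image(img, tr, 4)
  back <- resample_image(fwd, invert_rigid(tr), 4)
  # interior = white matter away from tissue boundaries, where the map is
  # smooth; boundary voxels are dominated by the tissue contrast itself
  interior <- mrfrelia:::erode_inplane(mrfrelia:::erode_inplane(wm_mask(ph)))
  expect_lt(sqrt(mean((back[interior] - img[interior])^2)) /
              sqrt(mean(img[interior]^2)), 0.02)
})

test_that("coefficient maps resample with zero-filled masked edges", {
  cc <- random_coeffs(c(32, 32, 1, 3), seed = 4)
  tr <- rigid_transform(0, c(40, 0, 0))     # 5 voxels at 8 mm
  out <- resample_coefficients(cc, tr, 8)
  valid <- attr(out, "valid")
  expect_false(all(valid))
  expect_true(all(out[rep(!valid, 3)] == 0))
  idt <- resample_coefficients(cc, rigid_transform(), 8)
  expect_equal(idt[], cc[], ignore_attr = TRUE)
})

test_that("matching after resampling differs from resampling matched maps", {
  ts <- tiny_setup()
  ph <- make_phantom(c(32, 32, 1), voxel_size_mm = 6, seed = 5)
  ct <- project_phantom(ph, ts$basis, ts$protocol)
  tr <- rigid_transform(2, c(4, -7, 0))
  path_a <- template_match(resample_coefficients(ct, tr, 6), ts$cdict)$t1_map
  path_b <- resample_image(template_match(ct, ts$cdict)$t1_map, tr, 6)
  expect_gt(max(abs(path_a - path_b)), 1)
})

test_that("known rigid motions are recovered within 0.1 voxel and 0.2 degree", {
  ph <- make_phantom(c(64, 64, 3), 3, seed = 7)
  img <- ph$t1_map
  tr1 <- rigid_transform(0, c(2.3, -1.1, 0) * 3)
  e1 <- estimate_rigid(img, resample_image(img, invert_rigid(tr1), 3), 3)
  expect_lt(max(abs(e1$shift_mm - tr1$shift_mm)) / 3, 0.1)
  expect_lt(abs(e1$angle_deg), 0.2)
  tr2 <- rigid_transform(4, c(0, 0, 0))
  e2 <- estimate_rigid(img, resample_image(img, invert_rigid(tr2), 3), 3)
  expect_lt(abs(e2$angle_deg - 4), 0.2)
  expect_lt(max(abs(e2$shift_mm)) / 3, 0.1)
  e0 <- estimate_rigid(img, img, 3)
  expect_lt(abs(e0$angle_deg), 0.01)
  expect_lt(max(abs(e0$shift_mm)) / 3, 0.01)
})

test_that("averaging registered coefficients improves SNR by sqrt(2)", {
  set.seed(9)
  base <- random_coeffs(c(16, 16, 1, 2), seed = 9)
  sds <- vapply(1:20, function(i) {
    n1 <- base + random_coeffs(c(16, 16, 1, 2), seed = 100 + i) * 0.2
    n2 <- base + random_coeffs(c(16, 16, 1, 2), seed = 200 + i) * 0.2
    avg <- average_coefficient_maps(n1, n2)
    sd(Re(avg - base))
  }, 0)
  expect_lt(abs(mean(sds) / (0.2 / sqrt(2)) - 1), 0.1)
  a <- random_coeffs(c(8, 8, 1, 2), 1)
  expect_equal(average_coefficient_maps(a, a), a)
  expect_error(average_coefficient_maps(a, random_coeffs(c(8, 8, 1, 3), 2)), "shape")
})

test_that("averaging before matching raises the match correlation", {
  ts <- tiny_setup()
  ph <- make_phantom(c(32, 32, 1), voxel_size_mm = 6, seed = 5)
  truth <- project_phantom(ph, ts$basis, ts$protocol)
  wm <- wm_mask(ph)
  sigma <- 0.1 * sd(Mod(truth$c[truth$c != 0]))
  n1 <- truth$c + random_coeffs(dim(truth$c), seed = 31) * sigma
  n2 <- truth$c + random_coeffs(dim(truth$c), seed = 32) * sigma
  avg <- average_coefficient_maps(n1, n2)
  corr1 <- template_match(n1, ts$cdict, mask = wm)$match_corr_map[wm]
  corr2 <- template_match(n2, ts$cdict, mask = wm)$match_corr_map[wm]
  corr_avg <- template_match(avg, ts$cdict, mask = wm)$match_corr_map[wm]
  expect_gt(mean(corr_avg), mean(pmax(corr1, corr2)))
  expect_gt(mean(corr_avg >= corr1), 0.8)
})
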