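# Encoding operator contracts, subspace reconstruction, k-space combination.

make_ops_fixture <- function() {
  cached("ops_fixture", {
    prot <- tiny_protocol()
    dims <- c(32, 32); nz <- 2
    set.seed(42)
    list(prot = prot, dims = dims, nz = nz,
         coils = make_coil_sensitivities(c(dims, nz), 3, seed = 2),
         phi = qr.Q(qr(matrix(rnorm(80 * 4), 80, 4))),
         scheme = make_sampling_scheme(dims, prot, accel = 2, seed = 3),
         b0 = array(rnorm(prod(dims) * nz, 0, 20), c(dims, nz)))
  })
}

test_that("every encoding variant satisfies the adjoint contract", {
  fx <- make_ops_fixture()
  variants <- list(list(b0 = NULL, L = 0), list(b0 = fx$b0, L = 5),
                   list(b0 = fx$b0, L = Inf))
  set.seed(7)
  for (v in variants) {
    op <- encoding_operator(fx$scheme, fx$phi, fx$coils, b0_map = v$b0,
                            n_segments = v$L)
    x <- random_coeffs(c(op$dims, 4), seed = 7)
    y <- array(complex(real = rnorm(op$n_samples * 3 * fx$nz),
                       imaginary = rnorm(op$n_samples * 3 * fx$nz)),
               c(op$n_samples, 3, fx$nz))
    lhs <- sum(Conj(y) * op$forward(x))
    rhs <- sum(Conj(op$adjoint(y)) * x)
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
    # precomputed-kernel normal operator equals adjoint(forward(.))
    expect_lt(rel_err(op$normal(x), op$adjoint(op$forward(x))), 1e-10)
  }
})

test_that("time segmentation at the full segment count is exact", {
  fx <- make_ops_fixture()
  nd <- length(unique(fx$scheme$tau_ms))
  op_l <- encoding_operator(fx$scheme, fx$phi, fx$coils, b0_map = fx$b0,
                            n_segments = nd)
  op_ex <- encoding_operator(fx$scheme, fx$phi, fx$coils, b0_map = fx$b0,
                             n_segments = Inf)
  x <- random_coeffs(c(op_l$dims, 4), seed = 9)
  expect_lt(rel_err(op_l$forward(x), op_ex$forward(x)), 1e-10)
})

test_that("a zero B0 map reproduces the uncorrected code path", {
  fx <- make_ops_fixture()
  op0 <- encoding_operator(fx$scheme, fx$phi, fx$coils)
  opz <- encoding_operator(fx$scheme, fx$phi, fx$coils,
                           b0_map = array(0, c(fx$dims, fx$nz)), n_segments = 4)
  x <- random_coeffs(c(op0$dims, 4), seed = 5)
  expect_equal(op0$forward(x), opz$forward(x))
})

test_that("a point source gives constant-magnitude k-space with one coil", {
  fx <- make_ops_fixture()
  co1 <- make_coil_sensitivities(c(fx$dims, 1), 1, seed = 1)
  phi1 <- matrix(1 / sqrt(80), 80, 1)
  op <- encoding_operator(fx$scheme, phi1, co1)
  x <- array(0i, c(32, 32, 1, 1)); x[17, 17, 1, 1] <- 1
  y <- op$forward(x)
  expect_lt(diff(range(Mod(y))), 1e-12)
})

test_that("schemes exceeding the grid are rejected", {
  fx <- make_ops_fixture()
  bad <- fx$scheme
  bad$q[1] <- 32 * 32 + 5
  expect_error(encoding_operator(bad, fx$phi, fx$coils), "Nyquist")
})

test_that("noiseless fully sampled data with lambda 0 recover the projected truth", {
  ts <- tiny_setup()
  ph <- make_phantom(c(32, 32, 1), voxel_size_mm = 6, seed = 5)
  coils <- make_coil_sensitivities(c(32, 32, 1), 2, seed = 2)
  fsch <- full_sampling_scheme(c(32, 32), ts$protocol)
  y <- forward_model(ph, ts$basis, coils, fsch, protocol = ts$protocol)
  rec <- reconstruct_subspace(y, ts$basis, coils, fsch,
                              recon_config(lambda = 0, n_iters = 6))
  truth <- project_phantom(ph, ts$basis, ts$protocol)
  fg <- rep(ph$t1_map > 0, 5)
  expect_lt(rel_err(rec$c[fg], truth$c[fg]), 1e-3)
})

test_that("a huge lambda shrinks the solution to zero", {
  ts <- tiny_setup()
  ph <- make_phantom(c(32, 32, 1), voxel_size_mm = 6, seed = 5)
  coils <- make_coil_sensitivities(c(32, 32, 1), 2, seed = 2)
  sch <- make_sampling_scheme(c(32, 32), ts$protocol, accel = 2, seed = 4)
  y <- forward_model(project_phantom(ph, ts$basis, ts$protocol),
                     ts$basis, coils, sch)
  rec <- reconstruct_subspace(y, ts$basis, coils, sch,
                              recon_config(lambda = 1e9, n_iters = 5))
  expect_equal(max(Mod(rec$c)), 0)
})

test_that("tuned LLR regularization beats none under noisy undersampling", {
  ts <- tiny_setup()
  ph <- make_phantom(c(32, 32, 1), voxel_size_mm = 6, seed = 5)
  coils <- make_coil_sensitivities(c(32, 32, 1), 2, seed = 2)
  sch <- make_sampling_scheme(c(32, 32), ts$protocol, accel = 2, seed = 4)
  truth <- project_phantom(ph, ts$basis, ts$protocol)
  y <- forward_model(truth, ts$basis, coils, sch, noise_sd = 0, seed = 1)
  noise_sd <- 0.1 * sqrt(mean(Mod(y$samples)^2))
  y <- forward_model(truth, ts$basis, coils, sch, noise_sd = noise_sd, seed = 1)
  fg <- rep(ph$t1_map > 0, 5)
  err0 <- rel_err(reconstruct_subspace(y, ts$basis, coils, sch,
                                       recon_config(lambda = 0, n_iters = 15))$c[fg],
                  truth$c[fg])
  err1 <- rel_err(reconstruct_subspace(y, ts$basis, coils, sch,
                                       recon_config(n_iters = 15))$c[fg],
                  truth$c[fg])
  expect_lt(err1, err0)
})

test_that("the objective decreases monotonically (fixed patch grid)", {
  ts <- tiny_setup()
  ph <- make_phantom(c(32, 32, 1), voxel_size_mm = 6, seed = 6)
  coils <- make_coil_sensitivities(c(32, 32, 1), 2, seed = 2)
  sch <- make_sampling_scheme(c(32, 32), ts$protocol, accel = 2, seed = 4)
  truth <- project_phantom(ph, ts$basis, ts$protocol)
  y <- forward_model(truth, ts$basis, coils, sch,
                     noise_sd = 0.05 * sqrt(mean(Mod(forward_model(
                       truth, ts$basis, coils, sch)$samples)^2)), seed = 2)
  rec_f <- reconstruct_subspace(y, ts$basis, coils, sch,
                                recon_config(n_iters = 20, llr_shift = "fixed"))
  obj <- attr(rec_f, "objective")
  expect_true(all(diff(obj) <= 1e-9 * obj[1]))
  # cycling patch shifts perturb the regularizer only at the sub-percent level
  rec_c <- reconstruct_subspace(y, ts$basis, coils, sch,
                                recon_config(n_iters = 20))
  obj_c <- attr(rec_c, "objective")
  expect_true(all(diff(obj_c[10:20]) <= 5e-3 * obj_c[10]))
})

test_that("reconstruction error does not increase with denser sampling", {
  ts <- tiny_setup()
  ph <- make_phantom(c(32, 32, 1), voxel_size_mm = 6, seed = 8)
  coils <- make_coil_sensitivities(c(32, 32, 1), 2, seed = 2)
  truth <- project_phantom(ph, ts$basis, ts$protocol)
  fg <- rep(ph$t1_map > 0, 5)
  errs <- vapply(c(4, 2, 1.3), function(acc) {
    sch <- make_sampling_scheme(c(32, 32), ts$protocol, accel = acc, seed = 4)
    y0 <- forward_model(truth, ts$basis, coils, sch)
    nsd <- 0.05 * sqrt(mean(Mod(y0$samples)^2))
    y <- forward_model(truth, ts$basis, coils, sch, noise_sd = nsd, seed = 3)
    rel_err(reconstruct_subspace(y, ts$basis, coils, sch,
                                 recon_config(n_iters = 15))$c[fg], truth$c[fg])
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("identity-compensated combination is plain concatenation", {
  ts <- tiny_setup()
  ph <- make_phantom(c(32, 32, 1), voxel_size_mm = 6, seed = 5)
  coils <- make_coil_sensitivities(c(32, 32, 1), 2, seed = 2)
  s1 <- make_sampling_scheme(c(32, 32), ts$protocol, accel = 2, seed = 4)
  s2 <- make_sampling_scheme(c(32, 32), ts$protocol, accel = 2, seed = 5,
                             complement_of = s1)
  truth <- project_phantom(ph, ts$basis, ts$protocol)
  y1 <- forward_model(truth, ts$basis, coils, s1)
  y2 <- forward_model(truth, ts$basis, coils, s2)
  yc <- combine_acquisitions(y1, y2, rigid_transform(), voxel_mm = 6)
  expect_identical(yc$samples[seq_along(s1$q), , , drop = FALSE], y1$samples)
  expect_equal(yc$samples[length(s1$q) + seq_along(s2$q), , , drop = FALSE],
               y2$samples)
  expect_error(combine_acquisitions(y1, y2, "not a transform"), "rigid")
})

test_that("pure-translation motion is undone exactly in k-space", {
  ts <- tiny_setup()
  ph <- make_phantom(c(32, 32, 1), voxel_size_mm = 6, seed = 5)
  coils <- make_coil_sensitivities(c(32, 32, 1), 2, seed = 2)
  s1 <- make_sampling_scheme(c(32, 32), ts$protocol, accel = 2, seed = 4)
  s2 <- make_sampling_scheme(c(32, 32), ts$protocol, accel = 2, seed = 5,
                             complement_of = s1)
  truth <- project_phantom(ph, ts$basis, ts$protocol)
  tr <- rigid_transform(0, c(7.2, -3.6, 0))      # mm, sub-voxel at 6 mm
  y1 <- forward_model(truth, ts$basis, coils, s1)
  y_moved <- forward_moved(truth, ts$basis, coils, s2, transform = tr,
                           voxel_mm = 6)
  y_ref <- forward_model(truth, ts$basis, coils, s2)
  y_comp <- combine_acquisitions(y1, y_moved, tr, voxel_mm = 6)
  part2 <- y_comp$samples[length(s1$q) + seq_along(s2$q), , , drop = FALSE]
  expect_lt(rel_err(part2, y_ref$samples), 1e-3)
})
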