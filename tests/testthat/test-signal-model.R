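# EPG simulator, dictionary and subspace basis, synthetic T1w generation.

test_that("zero-flip schedule reduces to pure inversion recovery", {
  prot <- mrf_protocol(n_groups = 1, trs_per_group = 50, tr_ms = 12,
                       flip_schedule_deg = rep(0, 50))
  s <- epg_simulate(1000, 80, prot, return_mz = TRUE)
  expect_equal(max(Mod(s)), 0)
  tau <- prot$inversion_time_ms + (0:49) * prot$tr_ms + prot$te_ms
  expect_equal(attr(s, "mz"), 1 - 2 * exp(-tau / 1000), tolerance = 1e-12)
})

test_that("vanishing T2 kills the transverse signal at TE", {
  prot <- mrf_protocol(n_groups = 1, trs_per_group = 30, tr_ms = 12,
                       flip_schedule_deg = rep(40, 30))
  s <- epg_simulate(800, 1e-2, prot)
  expect_lt(max(Mod(s)), 1e-12)
})

test_that("EPG matches the isochromat Bloch oracle on a 50-TR toy schedule", {
  prot <- mrf_protocol(n_groups = 1, trs_per_group = 50, tr_ms = 12,
                       flip_schedule_deg = rep(15, 50))
  for (p in list(c(800, 60), c(1400, 90), c(300, 40))) {
    epg <- epg_simulate(p[1], p[2], prot)
    orc <- bloch_oracle(p[1], p[2], prot, n_iso = 200)
    # the oracle carries the physical global phase -i; compare after aligning
    expect_lt(rel_err(-1i * epg, orc), 0.01)
  }
})

test_that("non-physical relaxation parameters are rejected", {
  prot <- tiny_protocol()
  expect_error(epg_simulate(-100, 50, prot), "positive")
  expect_error(epg_simulate(800, 0, prot), "positive")
  expect_error(epg_simulate(100, 200, prot), "non-physical")
})

test_that("protocol validation enforces schedule length and flip range", {
  expect_error(mrf_protocol(trs_per_group = 10, flip_schedule_deg = rep(10, 9)),
               "length")
  expect_error(mrf_protocol(trs_per_group = 5, flip_schedule_deg = c(0, 10, 95, 10, 5)),
               "90")
  expect_error(mrf_protocol(rest_s = -1), "positive")
})

test_that("default T1 grid covers 20-3000 ms at 20 ms plus a coarse CSF tail", {
  g <- dictionary_grid()
  expect_equal(g$t1_values_ms, c(seq(20, 3000, by = 20), seq(3200, 5000, by = 200)))
  expect_error(dictionary_grid(t1_values_ms = numeric(0)), "empty")
  expect_error(dictionary_grid(t1_values_ms = c(100, 100, 200)), "increasing")
})

test_that("dictionary atoms are unit norm, physical, and distinguishable", {
  ts <- tiny_setup()
  dict <- ts$dict
  expect_true(all(dict$params$t2 <= dict$params$t1))
  expect_equal(max(abs(sqrt(rowSums(dict$atoms^2)) - 1)), 0, tolerance = 1e-12)
  # adjacent-T1 atoms at fixed T2 correlate below 1
  i60 <- which(dict$params$t2 == 60)
  cc <- rowSums(dict$atoms[i60[-length(i60)], ] * dict$atoms[i60[-1], ])
  expect_true(all(cc < 1))
})

test_that("subspace basis is orthonormal with energy non-decreasing in K", {
  ts <- tiny_setup()
  b5 <- ts$basis
  expect_equal(max(abs(crossprod(b5$phi) - diag(b5$k))), 0, tolerance = 1e-10)
  energies <- vapply(c(1, 3, 5, 8), function(k)
    compute_subspace(ts$dict, k)$energy_fraction, 0)
  expect_true(all(diff(energies) >= 0))
  expect_error(compute_subspace(ts$dict, 10000), "rank|n_timepoints")
})

test_that("a complete basis reproduces every atom exactly", {
  ts <- tiny_setup()
  nt <- ncol(ts$dict$atoms)
  bfull <- compute_subspace(ts$dict, nt)
  proj <- (ts$dict$atoms %*% bfull$phi) %*% t(bfull$phi)
  expect_lt(rel_err(proj, ts$dict$atoms), 1e-10)
})

test_that("synthetic T1w contrast is monotone decreasing in T1", {
  t1 <- array(seq(300, 4800, length.out = 64), c(8, 8, 1))
  t2 <- array(80, c(8, 8, 1)); pd <- array(1, c(8, 8, 1))
  img <- synthesize_t1w(t1, t2, pd)
  expect_true(all(diff(as.vector(img)[order(as.vector(t1))]) < 0))
  expect_equal(synthesize_t1w(t1, t2, pd * 0), array(0, dim(t1)))
  expect_identical(img, synthesize_t1w(t1, t2, pd))
  expect_error(synthesize_t1w(t1, t2[1:4, , , drop = FALSE], pd), "shape")
})
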