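# Undersampled multicoil encoding with off-resonance phase accrual.
#
# Forward model per k-space sample s (slice-wise 2D FFT, unitary):
#   y_s = sum_l w_l(tau_s) [ F D_l S (Phi_{t_s} c) ](q_s)
# where D_l = exp(-2i pi b0 tau_l) is the conjugate-phase factor of time
# segment l and w_l are interpolation weights. With L >= the number of
# distinct sample times the segments sit exactly on those times with one-hot
# weights, so the segmented operator equals the exact per-sample phase
# operator. Without a B0 map there is a single segment with unit weight.
#
# The normal operator A^H A is applied through a precomputed k-space kernel
#   T_{l1,l2,k1,k2}(q) = sum_s w_{l1}(s) w_{l2}(s) phi[t_s,k1] phi[t_s,k2]
# so each application costs L*K FFT pairs per coil and slice, independent of
# the number of samples.

segment_setup <- function(tau, n_segments) {
  if (is.null(n_segments) || n_segments <= 0) {
    return(list(tau_l = 0, l1 = rep(1L, length(tau)), w1 = rep(1, length(tau)),
                l2 = rep(1L, length(tau)), w2 = rep(0, length(tau)), L = 1L,
                exact = TRUE))
  }
  ut <- sort(unique(tau))
  if (n_segments >= length(ut)) {
    l <- match(tau, ut)
    return(list(tau_l = ut, l1 = l, w1 = rep(1, length(tau)),
                l2 = l, w2 = rep(0, length(tau)), L = length(ut), exact = TRUE))
  }
  ctr <- seq(min(tau), max(tau), length.out = n_segments)
  idx <- pmin(pmax(findInterval(tau, ctr), 1L), n_segments - 1L)
  w_hi <- (tau - ctr[idx]) / (ctr[idx + 1] - ctr[idx])
  list(tau_l = ctr, l1 = idx, w1 = 1 - w_hi, l2 = idx + 1L, w2 = w_hi,
       L = as.integer(n_segments), exact = FALSE)
}

# scatter-add complex values into an n-length vector by index
scatter_add <- function(n, idx, vals) {
  rs <- rowsum(cbind(Re(vals), Im(vals)), idx)
  out <- complex(n)
  out[as.integer(rownames(rs))] <- complex(real = rs[, 1], imaginary = rs[, 2])
  out
}

#' Build the encoding operator
#'
#' Packages forward, adjoint and normal-operator applications for a sampling
#' scheme, temporal basis, coil set and optional B0 map.
#'
#' @param scheme A [make_sampling_scheme()] / [full_sampling_scheme()] result.
#' @param phi Temporal basis matrix \code{[n_timepoints x K]} (or an
#'   \code{mrf_basis}).
#' @param coils Complex coil array \code{[nx, ny, nz, n_coils]}.
#' @param b0_map Optional Hz volume; \code{NULL} or all-zero means ideal
#'   on-resonance encoding.
#' @param n_segments Number of time segments L for the B0 phase model
#'   (ignored without a B0 map; \code{Inf} or >= the number of distinct
#'   sample times gives the exact operator).
#' @return List of closures \code{forward(c)}, \code{adjoint(y)},
#'   \code{normal(c)} plus geometry fields.
#' @export
encoding_operator <- function(scheme, phi, coils, b0_map = NULL, n_segments = Inf) {
  if (inherits(phi, "mrf_basis")) phi <- phi$phi
  stop_if(scheme$n_tr != nrow(phi), "basis and scheme disagree on the number of timepoints")
  nx <- scheme$dims[1]; ny <- scheme$dims[2]
  stop_if(any(scheme$q < 1 | scheme$q > nx * ny),
          "scheme samples exceed the grid Nyquist range")
  dc <- dim(coils)
  stop_if(dc[1] != nx || dc[2] != ny, "coil maps do not match the scheme grid")
  nz <- dc[3]; ncoil <- dc[4]
  K <- ncol(phi)
  np <- nx * ny
  have_b0 <- !is.null(b0_map) && any(b0_map != 0)
  if (have_b0 && is.infinite(n_segments)) n_segments <- length(unique(scheme$tau_ms))
  seg <- if (have_b0) segment_setup(scheme$tau_ms, n_segments)
         else segment_setup(scheme$tau_ms, 0)
  phi_t <- phi[scheme$tr, , drop = FALSE]
  n_s <- length(scheme$q)

  # per-segment sample lists (union of both weight columns)
  seg_samples <- lapply(seq_len(seg$L), function(l) {
    i1 <- which(seg$l1 == l & seg$w1 != 0)
    i2 <- which(seg$l2 == l & seg$w2 != 0)
    list(idx = c(i1, i2), w = c(seg$w1[i1], seg$w2[i2]))
  })
  used <- which(vapply(seg_samples, function(s) length(s$idx) > 0, TRUE))

  d_seg <- function(z, l) {
    if (!have_b0) return(1)
    exp(-2i * pi * b0_map[, , z] * seg$tau_l[l] / 1000)
  }

  forward <- function(c_arr) {
    cc <- if (inherits(c_arr, "mrf_coeffs")) c_arr$c else c_arr
    y <- array(0i, c(n_s, ncoil, nz))
    for (z in seq_len(nz)) for (co in seq_len(ncoil)) {
      X <- matrix(0i, np, K)
      for (k in seq_len(K)) X[, k] <- coils[, , z, co] * cc[, , z, k]
      for (l in used) {
        D <- d_seg(z, l)
        E <- matrix(0i, np, K)
        for (k in seq_len(K)) E[, k] <- fft2(matrix(D * X[, k], nx, ny))
        ss <- seg_samples[[l]]
        y[ss$idx, co, z] <- y[ss$idx, co, z] +
          ss$w * rowSums(phi_t[ss$idx, , drop = FALSE] * E[scheme$q[ss$idx], , drop = FALSE])
      }
    }
    y
  }

  adjoint <- function(y) {
    out <- array(0i, c(nx, ny, nz, K))
    for (z in seq_len(nz)) for (co in seq_len(ncoil)) {
      Sc <- Conj(coils[, , z, co])
      for (l in used) {
        ss <- seg_samples[[l]]
        Dc <- Conj(d_seg(z, l))
        yv <- ss$w * y[ss$idx, co, z]
        for (k in seq_len(K)) {
          grid <- scatter_add(np, scheme$q[ss$idx], yv * phi_t[ss$idx, k])
          img <- ifft2(matrix(grid, nx, ny))
          out[, , z, k] <- out[, , z, k] + Dc * Sc * img
        }
      }
    }
    out
  }

  # precomputed normal-operator kernel (identity for the fully sampled scheme)
  kernel <- NULL
  if (!scheme$full) {
    kernel <- list()
    combos <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
    acc <- new.env(parent = emptyenv())
    for (cmb in combos) {
      la <- if (cmb[1] == 1) seg$l1 else seg$l2
      wa <- if (cmb[1] == 1) seg$w1 else seg$w2
      lb <- if (cmb[2] == 1) seg$l1 else seg$l2
      wb <- if (cmb[2] == 1) seg$w1 else seg$w2
      live <- which(wa != 0 & wb != 0)
      if (!length(live)) next
      pair_id <- paste(la[live], lb[live])
      for (pid in unique(pair_id)) {
        ii <- live[pair_id == pid]
        w2 <- wa[ii] * wb[ii]
        Tm <- if (!is.null(acc[[pid]])) acc[[pid]] else array(0, c(np, K, K))
        for (k1 in seq_len(K)) for (k2 in k1:K) {
          rs <- rowsum(w2 * phi_t[ii, k1] * phi_t[ii, k2], scheme$q[ii])
          qq <- as.integer(rownames(rs))
          Tm[qq, k1, k2] <- Tm[qq, k1, k2] + rs[, 1]
          if (k2 > k1) Tm[qq, k2, k1] <- Tm[qq, k2, k1] + rs[, 1]
        }
        acc[[pid]] <- Tm
      }
    }
    for (pid in ls(acc)) {
      ll <- as.integer(strsplit(pid, " ")[[1]])
      kernel[[length(kernel) + 1]] <- list(l1 = ll[1], l2 = ll[2], T = acc[[pid]])
    }
  }

  # stacked per-(slice, coil) matrices used by the batched normal operator
  zrep <- rep(seq_len(nz), each = ncoil)
  smat_stack <- matrix(0i, np, nz * ncoil)
  for (z in seq_len(nz)) for (co in seq_len(ncoil))
    smat_stack[, (z - 1) * ncoil + co] <- coils[, , z, co]
  cmat_stack <- Conj(smat_stack)
  dmat_stack <- NULL
  if (have_b0 && !scheme$full) {
    dmat_stack <- lapply(seq_len(seg$L), function(l) {
      D <- exp(-2i * pi * seg$tau_l[l] / 1000 * b0_map)
      matrix(D, np, nz)[, zrep]
    })
  }

  normal <- function(c_arr) {
    cc <- if (inherits(c_arr, "mrf_coeffs")) c_arr$c else c_arr
    if (scheme$full) {
      # Phi^T Phi = I and RSS(coils) = 1: the normal operator is identity
      # wherever coils are defined; apply S^H S explicitly for generality.
      out <- array(0i, dim(cc))
      for (z in seq_len(nz)) {
        s2 <- apply(Mod(coils[, , z, , drop = FALSE])^2, 1:2, sum)
        for (k in seq_len(K)) out[, , z, k] <- s2 * cc[, , z, k]
      }
      return(out)
    }
    Lu <- sort(unique(c(vapply(kernel, `[[`, 1, "l1"), vapply(kernel, `[[`, 1, "l2"))))
    nzc <- nz * ncoil
    # coil-weighted coefficient columns, all (slice, coil) pairs stacked so
    # the FFTs batch and the kernel multiply vectorizes across them
    Call <- matrix(cc, np)                 # np x (nz*K), column (k-1)*nz + z
    X <- vector("list", K)
    for (k in seq_len(K)) X[[k]] <- smat_stack * Call[, (k - 1) * nz + zrep]
    # FFTs split into real/imaginary parts: the kernel is real, so the
    # accumulation runs in real arithmetic
    Er <- Ei <- vector("list", seg$L)
    for (l in Lu) {
      ErK <- EiK <- vector("list", K)
      for (k in seq_len(K)) {
        xk <- if (have_b0) dmat_stack[[l]] * X[[k]] else X[[k]]
        dim(xk) <- c(nx, ny, nzc)
        E <- fft2_batch(xk)
        dim(E) <- c(np, nzc)
        ErK[[k]] <- Re(E); EiK[[k]] <- Im(E)
      }
      Er[[l]] <- ErK; Ei[[l]] <- EiK
    }
    AccR <- AccI <- vector("list", seg$L)
    zero <- matrix(0, np, nzc)
    for (kk in kernel) {
      if (is.null(AccR[[kk$l1]])) {
        AccR[[kk$l1]] <- rep(list(zero), K)
        AccI[[kk$l1]] <- rep(list(zero), K)
      }
      for (k1 in seq_len(K)) {
        ar <- AccR[[kk$l1]][[k1]]; ai <- AccI[[kk$l1]][[k1]]
        for (k2 in seq_len(K)) {
          tk <- kk$T[, k1, k2]    # recycles down the stacked columns
          ar <- ar + tk * Er[[kk$l2]][[k2]]
          ai <- ai + tk * Ei[[kk$l2]][[k2]]
        }
        AccR[[kk$l1]][[k1]] <- ar; AccI[[kk$l1]][[k1]] <- ai
      }
    }
    out_k <- rep(list(matrix(0i, np, nz)), K)
    for (l in Lu) {
      if (is.null(AccR[[l]])) next
      for (k in seq_len(K)) {
        M <- complex(real = AccR[[l]][[k]], imaginary = AccI[[l]][[k]])
        dim(M) <- c(nx, ny, nzc)
        W <- fft2_batch(M, inverse = TRUE)
        dim(W) <- c(np, nzc)
        W <- if (have_b0) Conj(dmat_stack[[l]]) * cmat_stack * W else cmat_stack * W
        dim(W) <- c(np, ncoil, nz)
        acc <- out_k[[k]]
        for (co in seq_len(ncoil)) acc <- acc + W[, co, ]
        out_k[[k]] <- acc
      }
    }
    out <- array(0i, c(nx, ny, nz, K))
    for (k in seq_len(K)) out[, , , k] <- out_k[[k]]
    out
  }

  list(forward = forward, adjoint = adjoint, normal = normal,
       dims = c(nx, ny, nz), K = K, n_coils = ncoil, n_samples = n_s,
       segments = seg, have_b0 = have_b0)
}

#' Simulate k-space data from a phantom or coefficient maps
#'
#' In coefficient (subspace) mode the per-timepoint image is \code{Phi c};
#' in exact mode the per-voxel EPG signal evolution at the phantom's true
#' (T1, T2) is encoded timepoint by timepoint. Off-resonance phase
#' \code{exp(-2i pi b0 t)} is applied per sample (exact time segmentation);
#' exact mode with a B0 map uses the segmented model at the full segment
#' count.
#'
#' @param phantom_or_coeffs An \code{mrf_phantom} (exact mode) or a complex
#'   coefficient array / \code{mrf_coeffs} (subspace mode).
#' @param basis An \code{mrf_basis} (or \code{[n_t x K]} matrix).
#' @param coils Complex coil array.
#' @param scheme Sampling scheme.
#' @param b0_map Optional Hz volume.
#' @param noise_sd Absolute complex noise sd per sample (0 = noiseless).
#' @param seed Seed for the noise draw.
#' @param protocol Required in exact mode (EPG simulation).
#' @param n_states EPG orders in exact mode.
#' @return Object of class \code{mrf_kspace}: \code{samples}
#'   \code{[n_samples, n_coils, n_slices]}, \code{scheme}, \code{noise_sd}.
#' @export
forward_model <- function(phantom_or_coeffs, basis, coils, scheme, b0_map = NULL,
                          noise_sd = 0, seed = 1, protocol = NULL, n_states = 30L) {
  phi <- if (inherits(basis, "mrf_basis")) basis$phi else basis
  nx <- scheme$dims[1]; ny <- scheme$dims[2]
  nz <- dim(coils)[3]; ncoil <- dim(coils)[4]
  if (inherits(phantom_or_coeffs, "mrf_phantom")) {
    stop_if(is.null(protocol), "exact mode needs the acquisition protocol")
    ph <- phantom_or_coeffs
    stop_if(!identical(dim(ph$t1_map)[1:2], as.integer(scheme$dims)) &&
              !identical(dim(ph$t1_map)[1:2], scheme$dims),
            "phantom grid does not match the scheme")
    if (!is.null(b0_map) && any(b0_map != 0) && !scheme$full) {
      # exact per-voxel signals with off-resonance: encode through the
      # subspace-free per-TR path below
      y <- forward_exact(ph, coils, scheme, b0_map, protocol, n_states)
    } else {
      y <- forward_exact(ph, coils, scheme, NULL, protocol, n_states)
    }
  } else {
    op <- encoding_operator(scheme, phi, coils, b0_map = b0_map)
    y <- op$forward(phantom_or_coeffs)
  }
  if (noise_sd > 0) {
    y <- y + with_seed(derive_seed(seed, "noise"), {
      n <- length(y)
      complex(real = stats::rnorm(n, 0, noise_sd / sqrt(2)),
              imaginary = stats::rnorm(n, 0, noise_sd / sqrt(2)))
    })
  }
  structure(list(samples = y, scheme = scheme, noise_sd = noise_sd,
                 n_coils = ncoil, n_slices = nz),
            class = "mrf_kspace")
}

# exact-mode encoding: loop over TRs, 2D FFT per coil and slice
forward_exact <- function(phantom, coils, scheme, b0_map, protocol, n_states) {
  nx <- scheme$dims[1]; ny <- scheme$dims[2]
  nz <- dim(coils)[3]; ncoil <- dim(coils)[4]
  np <- nx * ny
  fg <- which(phantom$t1_map > 0)
  sig <- epg_core(phantom$t1_map[fg], phantom$t2_map[fg], protocol, n_states)$signal
  amp <- phantom$pd_map[fg]
  n_s <- length(scheme$q)
  y <- array(0i, c(n_s, ncoil, nz))
  ord <- order(scheme$tr)
  q_o <- scheme$q[ord]; tau_o <- scheme$tau_ms[ord]
  tr_breaks <- c(0, cumsum(tabulate(scheme$tr, nbins = scheme$n_tr)))
  vol <- numeric(np * nz)
  have_b0 <- !is.null(b0_map) && any(b0_map != 0)
  for (t in seq_len(scheme$n_tr)) {
    lo <- tr_breaks[t] + 1L; hi <- tr_breaks[t + 1]
    if (lo > hi) next
    ii <- ord[lo:hi]
    vol[] <- 0
    vol[fg] <- amp * sig[, t]
    dim(vol) <- c(nx, ny, nz)
    taus <- if (have_b0) unique(scheme$tau_ms[ii]) else 0
    for (tu in taus) {
      sel <- if (have_b0) ii[scheme$tau_ms[ii] == tu] else ii
      for (z in seq_len(nz)) {
        ph_fac <- if (have_b0) exp(-2i * pi * b0_map[, , z] * tu / 1000) else 1
        base <- ph_fac * vol[, , z]
        for (co in seq_len(ncoil)) {
          E <- fft2(matrix(coils[, , z, co] * base, nx, ny))
          y[sel, co, z] <- E[scheme$q[sel]]
        }
      }
    }
    dim(vol) <- NULL
  }
  y
}

#' Project a phantom's exact signal evolutions onto the subspace
#'
#' Computes per-voxel EPG fingerprints (scaled by proton density) and their
#' least-squares representation in the temporal basis: the ground-truth
#' coefficient maps used by subspace-mode simulation and error analyses.
#'
#' @param phantom An \code{mrf_phantom}.
#' @param basis An \code{mrf_basis}.
#' @param protocol The acquisition protocol.
#' @param n_states EPG orders.
#' @return An \code{mrf_coeffs} object (complex \code{[nx, ny, nz, K]}).
#' @export
project_phantom <- function(phantom, basis, protocol, n_states = 30L) {
  phi <- if (inherits(basis, "mrf_basis")) basis$phi else basis
  fg <- which(phantom$t1_map > 0)
  sig <- epg_core(phantom$t1_map[fg], phantom$t2_map[fg], protocol, n_states)$signal
  ck <- (phantom$pd_map[fg] * sig) %*% phi
  d <- dim(phantom$t1_map)
  out <- array(0i, c(d, ncol(phi)))
  np <- prod(d)
  for (k in seq_len(ncol(phi))) out[fg + (k - 1) * np] <- ck[, k]
  new_coeffs(out, voxel_mm = phantom$voxel_mm, space = "native")
}

# signed integer k-space coordinates of linear indices, rotated by angle_deg
# and re-gridded to the nearest Cartesian location; shared by the k-space
# motion model (forward_moved) and its compensation (combine_acquisitions)
# so the two are exact inverses
rotate_kcoords <- function(q, dims, angle_deg) {
  nx <- dims[1]; ny <- dims[2]
  kx <- (q - 1) %% nx
  ky <- (q - 1) %/% nx
  fx <- ifelse(kx >= nx / 2, kx - nx, kx)   # signed integer cycles / FOV
  fy <- ifelse(ky >= ny / 2, ky - ny, ky)
  a <- angle_deg * pi / 180                # image rotation rotates k-space alike
  fx2 <- round(cos(a) * fx - sin(a) * fy)
  fy2 <- round(sin(a) * fx + cos(a) * fy)
  keep <- fx2 >= -nx / 2 & fx2 <= nx / 2 - 1 & fy2 >= -ny / 2 & fy2 <= ny / 2 - 1
  list(fx2 = fx2, fy2 = fy2, keep = keep,
       q2 = as.integer((fx2 %% nx) + nx * (fy2 %% ny)) + 1L)
}

#' Simulate the acquisition of a rigidly moved object
#'
#' k-space of a rigidly moved object relates to the unmoved object's k-space
#' by the same coordinate rotation and phase ramp that motion compensation
#' applies: this helper samples the unmoved coefficients at the rotated
#' (nearest-grid) coordinates and applies the inverse phase ramp, so that
#' [combine_acquisitions()] with the same transform undoes the motion
#' exactly. Samples whose rotated coordinate leaves the grid are zero.
#'
#' @param coeffs Unmoved-object coefficient maps (\code{mrf_coeffs} or
#'   array).
#' @param basis,coils,scheme,b0_map As in [forward_model()] (pass the moved
#'   B0 map when off-resonance matters).
#' @param transform Rigid map from moved-scan coordinates to unmoved-object
#'   coordinates (the object as seen by the scan is
#'   \code{resample(object, transform)}).
#' @param voxel_mm Voxel size in mm.
#' @return An \code{mrf_kspace} on the original \code{scheme}.
#' @export
forward_moved <- function(coeffs, basis, coils, scheme, b0_map = NULL,
                          transform = rigid_transform(), voxel_mm = 1) {
  if (transform$angle_deg == 0 && all(transform$shift_mm == 0))
    return(forward_model(coeffs, basis, coils, scheme, b0_map = b0_map))
  nx <- scheme$dims[1]; ny <- scheme$dims[2]
  rc <- rotate_kcoords(scheme$q, scheme$dims, transform$angle_deg)
  scheme_g <- scheme
  scheme_g$q <- rc$q2[rc$keep]
  scheme_g$tr <- scheme$tr[rc$keep]
  scheme_g$tau_ms <- scheme$tau_ms[rc$keep]
  scheme_g$group <- scheme$group[rc$keep]
  y0 <- forward_model(coeffs, basis, coils, scheme_g, b0_map = b0_map)
  shift_vox <- transform$shift_mm[1:2] / voxel_mm
  phase <- exp(2i * pi * (rc$fx2[rc$keep] * shift_vox[1] / nx +
                          rc$fy2[rc$keep] * shift_vox[2] / ny))
  samples <- array(0i, c(length(scheme$q), dim(y0$samples)[2], dim(y0$samples)[3]))
  samples[rc$keep, , ] <- y0$samples * array(rep(phase, prod(dim(y0$samples)[2:3])),
                                             dim(y0$samples))
  structure(list(samples = samples, scheme = scheme, noise_sd = 0,
                 n_coils = y0$n_coils, n_slices = y0$n_slices),
            class = "mrf_kspace")
}

new_coeffs <- function(c_arr, voxel_mm = 1, space = "native", basis_id = NA) {
  structure(list(c = c_arr, voxel_mm = voxel_mm, space = space,
                 basis_id = basis_id, k = dim(c_arr)[4]),
            class = "mrf_coeffs")
}

#' @export
print.mrf_coeffs <- function(x, ...) {
  d <- dim(x$c)
  cat(sprintf("coefficient maps: %dx%dx%d, K = %d (%s space)\n",
              d[1], d[2], d[3], d[4], x$space))
  invisible(x)
}
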