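# k-space sampling schemes: per-group variable-density Cartesian masks whose
# samples are distributed over the TRs of the group, with per-sample readout
# times for off-resonance phase accrual. The reconstruction model (P F S Phi)
# is trajectory-agnostic; these masks stand in for 3D spiral-projection
# sampling at desk scale.

#' Generate an undersampled k-space sampling scheme
#'
#' Each acquisition group draws a variable-density random set of Cartesian
#' k-space locations (fully sampled low-frequency disk plus density-weighted
#' periphery); the group's samples are distributed cyclically over its TRs,
#' and within each readout the samples are ordered center-out with a linear
#' time ramp of \code{readout_ms}.
#'
#' @param dims In-plane grid size \code{c(nx, ny)} (mask shared across
#'   slices).
#' @param protocol An [mrf_protocol()].
#' @param accel Per-group undersampling factor.
#' @param readout_ms Readout duration; per-sample acquisition times ramp
#'   linearly from 0 to this value within each TR.
#' @param seed Integer seed.
#' @param complement_of Optional scheme whose coverage the new scheme should
#'   interleave (complementary acquisition of the second 2-min scan).
#' @return Object of class \code{sampling_scheme} with per-sample fields
#'   \code{q} (linear in-plane index), \code{tr}, \code{tau_ms}, \code{group}.
#' @export
make_sampling_scheme <- function(dims, protocol, accel = 2, readout_ms = 5,
                                 seed = 1, complement_of = NULL) {
  nx <- dims[1]; ny <- dims[2]
  G <- protocol$n_groups; TRs <- protocol$trs_per_group
  n_keep <- max(round(nx * ny / accel), 8)
  kx <- ((seq_len(nx) - 1 + nx / 2) %% nx) - nx / 2
  ky <- ((seq_len(ny) - 1 + ny / 2) %% ny) - ny / 2
  kr <- sqrt(outer(kx^2, ky^2, `+`))
  dens <- exp(-(kr / (nx / 4))^2) + 0.02
  center <- which(kr <= 3)
  other_q <- if (!is.null(complement_of)) complement_of$q else NULL
  other_g <- if (!is.null(complement_of)) complement_of$group else NULL
  qs <- trs <- grps <- integer(0); taus <- numeric(0)
  with_seed(derive_seed(seed, "scheme"), {
    for (g in seq_len(G)) {
      w <- as.vector(dens)
      if (!is.null(other_q)) {
        seen <- unique(other_q[other_g == g])
        w[seen] <- w[seen] * 0.15
      }
      w[center] <- 0
      n_extra <- max(n_keep - length(center), 0)
      picked <- c(center, sample(seq_len(nx * ny), n_extra, prob = w))
      picked <- sample(picked)                       # random TR assignment
      tr_id <- rep(seq_len(TRs), length.out = length(picked))
      # center-out ordering within each readout with a linear time ramp
      ord <- order(tr_id, kr[picked])
      picked <- picked[ord]; tr_id <- tr_id[ord]
      tau <- unlist(lapply(split(seq_along(picked), tr_id), function(ii) {
        m <- length(ii); if (m == 1) 0 else (seq_len(m) - 1) / (m - 1) * readout_ms
      }), use.names = FALSE)
      qs <- c(qs, picked)
      trs <- c(trs, (g - 1L) * TRs + tr_id)
      grps <- c(grps, rep(g, length(picked)))
      taus <- c(taus, tau)
    }
  })
  structure(list(q = qs, tr = as.integer(trs), tau_ms = taus,
                 group = as.integer(grps), dims = c(nx, ny),
                 n_tr = G * TRs, readout_ms = readout_ms, accel = accel,
                 full = FALSE, complementary = !is.null(complement_of),
                 seed = seed),
            class = "sampling_scheme")
}

#' Fully sampled scheme
#'
#' Every TR samples the complete Cartesian grid with zero readout duration
#' (idealized acquisition used for noiseless recovery benchmarks).
#'
#' @param dims In-plane grid size.
#' @param protocol An [mrf_protocol()].
#' @return A \code{sampling_scheme} with \code{full = TRUE}.
#' @export
full_sampling_scheme <- function(dims, protocol) {
  nx <- dims[1]; ny <- dims[2]
  nt <- n_timepoints(protocol)
  structure(list(q = rep(seq_len(nx * ny), nt),
                 tr = rep(seq_len(nt), each = nx * ny),
                 tau_ms = numeric(nx * ny * nt),
                 group = rep(rep(seq_len(protocol$n_groups),
                                 each = protocol$trs_per_group), each = nx * ny),
                 dims = c(nx, ny), n_tr = nt, readout_ms = 0, accel = 1,
                 full = TRUE, complementary = FALSE, seed = NA),
            class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf("sampling scheme: %d samples on %dx%d grid over %d TRs (%s)\n",
              length(x$q), x$dims[1], x$dims[2], x$n_tr,
              if (x$full) "fully sampled" else sprintf("accel %.1f", x$accel)))
  invisible(x)
}
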