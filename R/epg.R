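# Extended phase graph (EPG) simulation of the inversion-prepared
# gradient-echo fingerprinting sequence.
#
# Configuration states are tracked as (F+_k, F-_k, Z_k) for dephasing orders
# k = 0..n_states-1, with F-_k storing conj(F(-k)). All RF pulses share a
# fixed 0-degree phase axis, under which the recursion closes on the real
# representation F+ = i*f+, F- = i*f-, Z real; the simulator therefore runs
# in real arithmetic and the physical global phase factor i is dropped from
# returned signals.

# Vectorized core over atoms: t1/t2 are equal-length vectors.
# Returns list(signal [n_atoms x n_timepoints], mz [same] if requested).
epg_core <- function(t1_ms, t2_ms, protocol, n_states = 30L, return_mz = FALSE) {
  n_atoms <- length(t1_ms)
  S <- as.integer(n_states)
  TRs <- protocol$trs_per_group
  G <- protocol$n_groups
  tr <- protocol$tr_ms; te <- protocol$te_ms
  alpha <- protocol$flip_schedule_deg * pi / 180
  e1_tr <- exp(-tr / t1_ms); e2_tr <- exp(-tr / t2_ms)
  e2_te <- exp(-te / t2_ms)
  e1_te <- exp(-te / t1_ms)
  e1_ti <- exp(-protocol$inversion_time_ms / t1_ms)
  e1_rest <- exp(-protocol$rest_s * 1000 / t1_ms)
  inv <- protocol$inv_efficiency

  fp <- matrix(0, n_atoms, S)
  fm <- matrix(0, n_atoms, S)
  z <- matrix(0, n_atoms, S); z[, 1] <- 1

  sig <- matrix(0, n_atoms, G * TRs)
  mz <- if (return_mz) matrix(0, n_atoms, G * TRs) else NULL

  ca2 <- cos(alpha / 2)^2; sa2 <- sin(alpha / 2)^2
  sa <- sin(alpha); ca <- cos(alpha)

  col_seq <- seq_len(S - 1L)
  t_out <- 0L
  for (g in seq_len(G)) {
    # inversion preparation: crusher spoils transverse, Z inverted
    fp[] <- 0; fm[] <- 0
    z <- -inv * z
    # recover over TI
    z <- z * e1_ti; z[, 1] <- z[, 1] + (1 - e1_ti)
    for (t in seq_len(TRs)) {
      c2 <- ca2[t]; s2 <- sa2[t]; s1 <- sa[t]; c1 <- ca[t]
      fp_n <- c2 * fp + s2 * fm - s1 * z
      fm_n <- s2 * fp + c2 * fm + s1 * z
      z <- 0.5 * s1 * fp - 0.5 * s1 * fm + c1 * z
      t_out <- t_out + 1L
      sig[, t_out] <- fp_n[, 1] * e2_te
      if (return_mz) mz[, t_out] <- z[, 1] * e1_te + (1 - e1_te)
      # relax over the full TR, then the end-of-TR spoiler gradient shift
      fp_n <- fp_n * e2_tr
      fm_n <- fm_n * e2_tr
      z <- z * e1_tr; z[, 1] <- z[, 1] + (1 - e1_tr)
      fp <- cbind(-fm_n[, 2], fp_n[, col_seq, drop = FALSE])
      fm <- cbind(fm_n[, -1L, drop = FALSE], 0)
    }
    # free recovery between groups (transverse assumed fully spoiled)
    fp[] <- 0; fm[] <- 0
    z <- z * e1_rest; z[, 1] <- z[, 1] + (1 - e1_rest)
  }
  list(signal = sig, mz = mz)
}

#' Simulate an MRF signal evolution with the extended phase graph
#'
#' Computes the transverse signal at the echo time of every excitation of an
#' inversion-prepared gradient-echo fingerprinting sequence, including the
#' inversion at each group start and free recovery during the resting periods.
#'
#' @param t1_ms,t2_ms Relaxation times in ms; must satisfy
#'   \code{0 < t2_ms <= t1_ms}.
#' @param protocol An [mrf_protocol()].
#' @param n_states Number of EPG configuration orders to retain.
#' @param return_mz Also return the longitudinal magnetization at each echo
#'   time (attribute \code{"mz"}).
#' @return Complex vector of length \code{n_groups * trs_per_group}: the
#'   transverse magnetization at each TE. With constant-phase excitation the
#'   signal is real up to a global phase, which is dropped.
#' @export
epg_simulate <- function(t1_ms, t2_ms, protocol, n_states = 30L, return_mz = FALSE) {
  stop_if(length(t1_ms) != 1 || length(t2_ms) != 1, "t1_ms and t2_ms must be scalars")
  check_positive(t1_ms, "t1_ms"); check_positive(t2_ms, "t2_ms")
  stop_if(t2_ms > t1_ms, "t2_ms must not exceed t1_ms (non-physical pair)")
  res <- epg_core(t1_ms, t2_ms, protocol, n_states, return_mz)
  out <- as.complex(drop(res$signal))
  if (return_mz) attr(out, "mz") <- drop(res$mz)
  out
}
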