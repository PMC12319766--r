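#' MRF acquisition protocol
#'
#' Describes the inversion-prepared fingerprinting sequence: an adiabatic
#' inversion (inversion time \code{inversion_time_ms}) starts each acquisition
#' group, each group plays \code{trs_per_group} excitations with a varying
#' flip-angle schedule, and a resting period \code{rest_s} separates groups so
#' longitudinal magnetization can recover.
#'
#' @param n_groups Number of acquisition groups (16 for a single 2-min scan;
#'   the combined two-scan acquisition effectively doubles coverage).
#' @param trs_per_group Excitations per group. 500 at scan scale; smaller
#'   values give desk-scale protocols with identical structure.
#' @param tr_ms,te_ms Repetition and echo time in ms.
#' @param inversion_time_ms Delay between inversion and the first excitation.
#' @param rest_s Free-recovery time after each group, seconds.
#' @param flip_schedule_deg Flip angles (degrees), length \code{trs_per_group},
#'   repeated in every group. Defaults to a smooth ramp between 5 and 75
#'   degrees, which gives joint T1/T2 sensitivity.
#' @param inv_efficiency Inversion efficiency in [0, 1]; 1 = ideal adiabatic
#'   pulse.
#' @param group_trajectory_ids Optional integer tags for the sampling pattern
#'   used by each group.
#' @return An object of class \code{mrf_protocol}.
#' @export
mrf_protocol <- function(n_groups = 16, trs_per_group = 500, tr_ms = 12,
                         te_ms = 1.8, inversion_time_ms = 15, rest_s = 1.2,
                         flip_schedule_deg = default_flip_schedule(trs_per_group),
                         inv_efficiency = 1,
                         group_trajectory_ids = seq_len(n_groups)) {
  check_positive(n_groups, "n_groups"); check_positive(trs_per_group, "trs_per_group")
  check_positive(tr_ms, "tr_ms"); check_positive(te_ms, "te_ms")
  check_positive(inversion_time_ms, "inversion_time_ms"); check_positive(rest_s, "rest_s")
  stop_if(te_ms >= tr_ms, "te_ms must be smaller than tr_ms")
  stop_if(length(flip_schedule_deg) != trs_per_group,
          "flip_schedule_deg must have length trs_per_group")
  stop_if(any(flip_schedule_deg < 0) || any(flip_schedule_deg > 90),
          "flip angles must lie in [0, 90] degrees")
  stop_if(inv_efficiency < 0 || inv_efficiency > 1, "inv_efficiency must be in [0, 1]")
  structure(list(
    n_groups = as.integer(n_groups), trs_per_group = as.integer(trs_per_group),
    tr_ms = tr_ms, te_ms = te_ms, inversion_time_ms = inversion_time_ms,
    rest_s = rest_s, flip_schedule_deg = flip_schedule_deg,
    inv_efficiency = inv_efficiency,
    group_trajectory_ids = as.integer(group_trajectory_ids)
  ), class = "mrf_protocol")
}

#' Default varying flip-angle schedule
#'
#' Smooth half-sine-squared ramp from 5 to 75 degrees across one acquisition
#' group.
#'
#' @param n Number of excitations in the group.
#' @return Numeric vector of flip angles in degrees.
#' @export
default_flip_schedule <- function(n) {
  5 + 70 * sin(pi * (seq_len(n) - 0.5) / n)^2
}

#' Desk-scale protocol
#'
#' Same sequence structure as [mrf_protocol()] with 16 groups of 60 TRs, sized
#' so that dictionary simulation and reconstruction run in seconds.
#'
#' @param ... Overrides passed to [mrf_protocol()].
#' @return An \code{mrf_protocol}.
#' @export
desk_protocol <- function(...) {
  args <- list(...)
  defaults <- list(n_groups = 16, trs_per_group = 60)
  do.call(mrf_protocol, utils::modifyList(defaults, args))
}

n_timepoints <- function(protocol) protocol$n_groups * protocol$trs_per_group

#' @export
print.mrf_protocol <- function(x, ...) {
  cat(sprintf(
    "MRF protocol: %d groups x %d TRs (TR %.1f ms, TE %.1f ms), TI %.0f ms, rest %.1f s\n",
    x$n_groups, x$trs_per_group, x$tr_ms, x$te_ms, x$inversion_time_ms, x$rest_s))
  cat(sprintf("  flip angles: %.1f-%.1f deg, inversion efficiency %.2f\n",
              min(x$flip_schedule_deg), max(x$flip_schedule_deg), x$inv_efficiency))
  invisible(x)
}
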