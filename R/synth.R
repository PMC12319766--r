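#' Synthesize a qualitative T1-weighted (MPRAGE-like) image
#'
#' Voxelwise steady-state inversion-prepared spoiled gradient-echo signal from
#' the Bloch signal equation,
#' \deqn{S = PD \sin\alpha \,(1 - 2 e^{-TI/T1} + e^{-TR/T1})\, e^{-TE/T2},}
#' evaluated on co-registered quantitative maps. With the default timing
#' (TI 1100 ms, sequence TR 2500 ms) the signal is strictly decreasing in T1
#' across the tissue range, so white matter appears brighter than gray matter
#' and CSF, as in an MPRAGE contrast.
#'
#' @param t1_map,t2_map,pd_map Co-registered volumes (ms, ms, arbitrary units).
#' @param mprage_params List with \code{ti_ms}, \code{tr_ms}, \code{flip_deg},
#'   \code{te_ms}.
#' @return Volume of synthetic signal intensities (same shape as inputs).
#' @export
synthesize_t1w <- function(t1_map, t2_map, pd_map,
                           mprage_params = list(ti_ms = 1100, tr_ms = 2500,
                                                flip_deg = 8, te_ms = 3)) {
  stop_if(!identical(dim(t1_map), dim(t2_map)) || !identical(dim(t1_map), dim(pd_map)),
          "t1_map, t2_map and pd_map must share the same shape")
  p <- mprage_params
  out <- array(0, dim(t1_map))
  ok <- t1_map > 0 & t2_map > 0
  out[ok] <- pd_map[ok] * sin(p$flip_deg * pi / 180) *
    (1 - 2 * exp(-p$ti_ms / t1_map[ok]) + exp(-p$tr_ms / t1_map[ok])) *
    exp(-p$te_ms / t2_map[ok])
  out
}
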