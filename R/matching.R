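# Dictionary compression into the subspace and cross-correlation template
# matching of coefficient maps to quantitative T1/T2/PD maps.

#' Compress a dictionary into the temporal subspace
#'
#' Projects every atom onto the basis (K-dimensional atoms) and re-normalizes
#' rows; the per-atom projection residual (squared-norm fraction lost) is
#' stored for diagnostics.
#'
#' @param dictionary An \code{mrf_dictionary}.
#' @param basis An \code{mrf_basis} computed from the same protocol.
#' @return Object of class \code{mrf_cdict}: \code{atoms_k}
#'   (\code{n_atoms x K}, unit rows), \code{params}, \code{residual}.
#' @export
compress_dictionary <- function(dictionary, basis) {
  stop_if(!inherits(dictionary, "mrf_dictionary"), "need an mrf_dictionary")
  stop_if(!inherits(basis, "mrf_basis"), "need an mrf_basis")
  stop_if(ncol(dictionary$atoms) != basis$n_timepoints,
          "basis and dictionary were built for different protocols")
  ak <- dictionary$atoms %*% basis$phi
  nrm2 <- rowSums(ak^2)
  structure(list(atoms_k = ak / sqrt(nrm2), params = dictionary$params,
                 residual = 1 - nrm2, k = basis$k),
            class = "mrf_cdict")
}

#' Cross-correlation template matching
#'
#' Per voxel, finds the dictionary atom maximizing the magnitude of the
#' complex inner product between the voxel's coefficient vector and the
#' unit-norm compressed atom (phase-insensitive normalized
#' cross-correlation). Ties resolve to the lowest T1 (atoms are ordered by
#' T1 then T2). All-zero voxels are flagged with T1 = 0 and correlation 0.
#'
#' @param coeff_maps \code{mrf_coeffs} or complex array \code{[nx,ny,nz,K]}.
#' @param compressed_dictionary An [compress_dictionary()] result.
#' @param mask Optional logical array restricting matching.
#' @param chunk Voxels per matching block (memory control).
#' @return Object of class \code{mrf_mapset}: \code{t1_map}, \code{t2_map}
#'   (ms), \code{pd_map} (matched amplitude), \code{match_corr_map} in [0,1].
#' @export
template_match <- function(coeff_maps, compressed_dictionary, mask = NULL,
                           chunk = 4096L) {
  cd <- compressed_dictionary
  stop_if(!inherits(cd, "mrf_cdict"), "need a compressed dictionary")
  cc <- if (inherits(coeff_maps, "mrf_coeffs")) coeff_maps$c else coeff_maps
  d <- dim(cc)
  stop_if(d[4] != cd$k, "coefficient maps and dictionary disagree on K")
  np <- prod(d[1:3])
  V <- matrix(cc, np, d[4])
  sel <- if (is.null(mask)) seq_len(np) else which(as.vector(mask))
  nrm <- sqrt(rowSums(Mod(V[sel, , drop = FALSE])^2))
  live <- sel[nrm > 0]
  t1 <- t2 <- pd <- corr <- numeric(np)
  A <- t(cd$atoms_k)                       # K x n_atoms, real
  for (lo in seq(1, length(live), by = chunk)) {
    ii <- live[lo:min(lo + chunk - 1, length(live))]
    Vr <- Re(V[ii, , drop = FALSE]); Vi <- Im(V[ii, , drop = FALSE])
    ip2 <- (Vr %*% A)^2 + (Vi %*% A)^2     # |<c, a>|^2
    best <- max.col(ip2, ties.method = "first")
    amp <- sqrt(ip2[cbind(seq_along(ii), best)])
    t1[ii] <- cd$params$t1[best]
    t2[ii] <- cd$params$t2[best]
    pd[ii] <- amp
    corr[ii] <- amp / sqrt(rowSums(Vr^2 + Vi^2))
  }
  shape <- d[1:3]
  structure(list(t1_map = array(t1, shape), t2_map = array(t2, shape),
                 pd_map = array(pd, shape),
                 match_corr_map = array(pmin(corr, 1), shape),
                 n_matched = length(live)),
            class = "mrf_mapset")
}

#' Convert a T1 map (ms) to an R1 map (1/s)
#'
#' \code{R1 = 1000 / T1}; voxels flagged by matching (T1 <= 0) propagate as
#' \code{NA} and their count is recorded in attribute \code{"n_missing"}.
#'
#' @param t1_map T1 volume in ms.
#' @return R1 volume in 1/s.
#' @export
r1_map <- function(t1_map) {
  out <- array(NA_real_, dim(t1_map))
  ok <- is.finite(t1_map) & t1_map > 0
  out[ok] <- 1000 / t1_map[ok]
  structure(out, n_missing = sum(!ok))
}

#' @export
print.mrf_mapset <- function(x, ...) {
  d <- dim(x$t1_map)
  cat(sprintf("quantitative maps %dx%dx%d: %d matched voxels, T1 range %g-%g ms\n",
              d[1], d[2], d[3], x$n_matched,
              min(x$t1_map[x$t1_map > 0]), max(x$t1_map)))
  invisible(x)
}
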