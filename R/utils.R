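#' @keywords internal
"_PACKAGE"

# Shared validation and interpolation helpers.

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  stop_if(!is.numeric(x) || any(!is.finite(x)) || any(x <= 0),
          sprintf("'%s' must be positive and finite", name))
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed and stream labels
#'
#' Hashes the master seed together with arbitrary labels into a 32-bit
#' integer, so that every randomized stage of a pipeline can draw from its
#' own deterministic stream.
#'
#' @param seed Master seed (integer or string).
#' @param ... Further labels (numbers or strings).
#' @return An integer below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  labs <- c(seed, unlist(list(...)))
  h <- 0
  for (v in labs) {
    for (ch in utf8ToInt(paste0(v))) h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Unitary 2D FFT applied to a [nx, ny] matrix.
fft2 <- function(x) stats::fft(x) / sqrt(length(x))
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# Batched unitary 2D FFT over the planes of a [nx, ny, m] array (mvfft along
# each in-plane axis); returns an array of the same shape.
fft2_batch <- function(a, inverse = FALSE) {
  d <- dim(a)
  nx <- d[1]; ny <- d[2]; m <- prod(d) / (nx * ny)
  v <- stats::mvfft(matrix(a, nx), inverse = inverse)
  dim(v) <- c(nx, ny, m)
  v <- aperm(v, c(2, 1, 3))
  v <- stats::mvfft(matrix(v, ny), inverse = inverse)
  dim(v) <- c(ny, nx, m)
  v <- aperm(v, c(2, 1, 3)) / sqrt(nx * ny)
  dim(v) <- d
  v
}

# Trilinear interpolation of a [nx, ny, nz] volume at voxel-index coordinates
# (1-based, voxel centers at integers). Points outside return `fill`.
interp3 <- function(vol, xi, yi, zi, fill = NA_real_) {
  d <- dim(vol)
  nx <- d[1]; ny <- d[2]; nz <- if (length(d) >= 3) d[3] else 1L
  if (length(d) == 2) dim(vol) <- c(d, 1L)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  # clamp z for thin stacks so purely in-plane queries stay valid
  if (nz == 1L) { z0 <- rep(1, length(xi)); fz <- rep(0, length(xi)) }
  ok <- x0 >= 1 & x0 + (fx > 0) <= nx & y0 >= 1 & y0 + (fy > 0) <= ny &
    z0 >= 1 & z0 + (fz > 0) <= nz & is.finite(xi) & is.finite(yi)
  out <- rep(fill, length(xi))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  x1 <- pmin(x0 + 1, nx); y1 <- pmin(y0 + 1, ny); z1 <- pmin(z0 + 1, nz)
  idx <- function(i, j, k) ((k - 1) * ny + (j - 1)) * nx + i
  v000 <- vol[idx(x0, y0, z0)]; v100 <- vol[idx(x1, y0, z0)]
  v010 <- vol[idx(x0, y1, z0)]; v110 <- vol[idx(x1, y1, z0)]
  v001 <- vol[idx(x0, y0, z1)]; v101 <- vol[idx(x1, y0, z1)]
  v011 <- vol[idx(x0, y1, z1)]; v111 <- vol[idx(x1, y1, z1)]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  out[ok] <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
  out
}

# Nearest-neighbour lookup with the same contract as interp3.
nearest3 <- function(vol, xi, yi, zi, fill = NA_real_) {
  d <- dim(vol)
  nx <- d[1]; ny <- d[2]; nz <- if (length(d) >= 3) d[3] else 1L
  x0 <- round(xi); y0 <- round(yi); z0 <- pmin(pmax(round(zi), 1), nz)
  ok <- x0 >= 1 & x0 <= nx & y0 >= 1 & y0 <= ny & is.finite(xi) & is.finite(yi)
  out <- rep(fill, length(xi))
  if (any(ok)) out[ok] <- vol[cbind(x0[ok], y0[ok], z0[ok])]
  out
}

rel_err <- function(a, b) sqrt(sum(Mod(a - b)^2)) / max(sqrt(sum(Mod(b)^2)), .Machine$double.eps)
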