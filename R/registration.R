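# Rigid transforms (in-plane rotation about the volume center + mm
# translation), half-way splitting, image/coefficient resampling, and an
# internal multi-resolution MSE registration.
#
# Convention (used everywhere): a transform T is a point map applied to
# OUTPUT-grid coordinates; resampling pulls values from the input image at
# T(p). Composition compose_rigid(A, B)(p) = A(B(p)).

#' Rigid transform
#'
#' @param angle_deg In-plane rotation (degrees, counter-clockwise about the
#'   volume center).
#' @param shift_mm Numeric length-3 translation in mm (x, y, z).
#' @return Object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(angle_deg = 0, shift_mm = c(0, 0, 0)) {
  stop_if(!is.numeric(angle_deg) || length(angle_deg) != 1 || !is.finite(angle_deg),
          "angle_deg must be a finite scalar")
  shift_mm <- rep_len(as.numeric(shift_mm), 3)
  stop_if(any(!is.finite(shift_mm)), "shift_mm must be finite")
  structure(list(angle_deg = angle_deg, shift_mm = shift_mm),
            class = "rigid_transform")
}

rot2 <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Apply a rigid transform to points
#' @param transform A \code{rigid_transform}.
#' @param pts Matrix \code{[n x 3]} of mm coordinates.
#' @param center_mm Rotation center (mm), length 3.
#' @return Transformed points \code{[n x 3]}.
#' @export
apply_rigid <- function(transform, pts, center_mm) {
  pts <- matrix(pts, ncol = 3)
  R <- rot2(transform$angle_deg)
  xy <- sweep(pts[, 1:2, drop = FALSE], 2, center_mm[1:2]) %*% t(R)
  xy <- sweep(xy, 2, center_mm[1:2], `+`)
  cbind(xy[, 1] + transform$shift_mm[1],
        xy[, 2] + transform$shift_mm[2],
        pts[, 3] + transform$shift_mm[3])
}

#' Compose and invert rigid transforms
#'
#' \code{compose_rigid(a, b)} is the map \code{p -> a(b(p))}.
#' @param a,b,transform Rigid transforms.
#' @return A \code{rigid_transform}.
#' @export
compose_rigid <- function(a, b) {
  # a(b(p)): rotation angles add; translation t = R_a t_b + t_a (about center)
  R <- rot2(a$angle_deg)
  txy <- R %*% b$shift_mm[1:2] + a$shift_mm[1:2]
  rigid_transform(a$angle_deg + b$angle_deg,
                  c(txy, a$shift_mm[3] + b$shift_mm[3]))
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(transform) {
  R <- rot2(-transform$angle_deg)
  txy <- -R %*% transform$shift_mm[1:2]
  rigid_transform(-transform$angle_deg, c(txy, -transform$shift_mm[3]))
}

sqrt_rigid <- function(transform) {
  # S with S o S = transform: half angle; t_half = (I + R(theta/2))^-1 t_xy
  half <- transform$angle_deg / 2
  A <- diag(2) + rot2(half)
  txy <- solve(A, transform$shift_mm[1:2])
  rigid_transform(half, c(txy, transform$shift_mm[3] / 2))
}

#' Split a rigid transform into unbiased half-way transforms
#'
#' Returns transforms \code{half_a}, \code{half_b} moving each session half
#' the distance (in the rigid-group sense) into a common mid space, with
#' \code{half_b o half_a^-1} equal to the input.
#'
#' @param transform Rigid transform mapping session-1 grid points into
#'   session-2 space (the output of [estimate_rigid()] with session 1 as
#'   reference).
#' @return List with elements \code{half_a} (resamples session 1 to half-way)
#'   and \code{half_b} (resamples session 2 to half-way).
#' @export
halfway_split <- function(transform) {
  stop_if(!inherits(transform, "rigid_transform"), "input must be a rigid_transform")
  s <- sqrt_rigid(transform)
  list(half_a = invert_rigid(s), half_b = s)
}

#' Resample a volume under a rigid transform
#'
#' \code{output(p) = input(T(p))} with linear (or nearest) interpolation;
#' voxels mapping outside the input are filled with 0 and masked.
#'
#' @param img Volume \code{[nx, ny, nz]} (numeric).
#' @param transform A \code{rigid_transform}.
#' @param voxel_mm Voxel size (mm, isotropic).
#' @param interpolation \code{"linear"} or \code{"nearest"}.
#' @return Resampled volume; attribute \code{"valid"} is the in-bounds mask.
#' @export
resample_image <- function(img, transform, voxel_mm = 1,
                           interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  d <- dim(img)
  nx <- d[1]; ny <- d[2]; nz <- if (length(d) >= 3) d[3] else 1L
  ctr <- c(nx + 1, ny + 1, nz + 1) / 2 * voxel_mm
  g <- cbind(rep(seq_len(nx), times = ny * nz),
             rep(rep(seq_len(ny), each = nx), times = nz),
             rep(seq_len(nz), each = nx * ny)) * voxel_mm
  q <- apply_rigid(transform, g, ctr) / voxel_mm
  vals <- if (interpolation == "linear") interp3(img, q[, 1], q[, 2], q[, 3])
          else nearest3(img, q[, 1], q[, 2], q[, 3])
  valid <- !is.na(vals)
  vals[!valid] <- 0
  out <- array(vals, c(nx, ny, nz))
  attr(out, "valid") <- array(valid, c(nx, ny, nz))
  out
}

#' Resample coefficient maps (before template matching)
#'
#' Applies the same rigid transform to each of the K complex coefficient
#' volumes (real and imaginary parts interpolated separately). Matching must
#' run after resampling; resampling quantitative maps directly inflates
#' partial-volume error.
#'
#' @param coeffs Complex array \code{[nx, ny, nz, K]} or \code{mrf_coeffs}.
#' @param transform Rigid transform.
#' @param voxel_mm Voxel size in mm.
#' @param interpolation Interpolation scheme for [resample_image()].
#' @return Same container as the input, resampled; edge voxels are zero-filled
#'   (attribute \code{"valid"}).
#' @export
resample_coefficients <- function(coeffs, transform, voxel_mm = 1,
                                  interpolation = "linear") {
  cc <- if (inherits(coeffs, "mrf_coeffs")) coeffs$c else coeffs
  K <- dim(cc)[4]
  out <- array(0i, dim(cc))
  valid <- NULL
  for (k in seq_len(K)) {
    re <- resample_image(Re(cc[, , , k, drop = FALSE][, , , 1]), transform, voxel_mm, interpolation)
    im <- resample_image(Im(cc[, , , k, drop = FALSE][, , , 1]), transform, voxel_mm, interpolation)
    out[, , , k] <- complex(real = re, imaginary = im)
    valid <- attr(re, "valid")
  }
  if (inherits(coeffs, "mrf_coeffs")) {
    res <- coeffs; res$c <- out; res$space <- "resampled"
    attr(res, "valid") <- valid
    res
  } else structure(out, valid = valid)
}

#' Average two registered coefficient-map sets
#'
#' Voxelwise complex mean of two same-space coefficient sets; with independent
#' noise this improves SNR by sqrt(2) (the two-scan average behaves like a
#' doubled acquisition).
#'
#' @param c_a,c_b Complex arrays \code{[nx, ny, nz, K]} or \code{mrf_coeffs}.
#' @return Same container type, averaged.
#' @export
average_coefficient_maps <- function(c_a, c_b) {
  aa <- if (inherits(c_a, "mrf_coeffs")) c_a$c else c_a
  bb <- if (inherits(c_b, "mrf_coeffs")) c_b$c else c_b
  stop_if(!identical(dim(aa), dim(bb)), "coefficient maps must share shape and K")
  avg <- (aa + bb) / 2
  if (inherits(c_a, "mrf_coeffs")) { out <- c_a; out$c <- avg; out } else avg
}

# metric evaluated over valid overlap
mse_metric <- function(ref, mov, transform, voxel_mm) {
  r <- resample_image(mov, transform, voxel_mm)
  v <- attr(r, "valid")
  if (!any(v)) return(Inf)
  mean((r[v] - ref[v])^2)
}

# in-plane 3x3 binomial smoothing (edge-replicated), n passes
smooth_inplane <- function(img, n_pass = 2) {
  d <- dim(img)
  nx <- d[1]; ny <- d[2]
  for (p in seq_len(n_pass)) {
    img <- 0.5 * img +
      0.25 * (img[c(1, seq_len(nx - 1)), , , drop = FALSE] +
              img[c(seq_len(nx - 1) + 1, nx), , , drop = FALSE])
    img <- 0.5 * img +
      0.25 * (img[, c(1, seq_len(ny - 1)), , drop = FALSE] +
              img[, c(seq_len(ny - 1) + 1, ny), , drop = FALSE])
  }
  img
}

#' Estimate the rigid transform between two images
#'
#' Minimizes the mean squared intensity difference over in-plane rotation and
#' translation: both images are lightly presmoothed (which suppresses the
#' interpolation-induced bias toward the identity), a coarse grid search
#' brackets the optimum, and Nelder-Mead refines it. The returned transform
#' maps reference-grid points into the moving image, i.e.
#' \code{resample_image(img_mov, transform)} aligns the moving image to the
#' reference.
#'
#' @param img_ref,img_mov Real-valued volumes on the same grid (typically the
#'   magnitude of a high-contrast coefficient map).
#' @param voxel_mm Voxel size in mm.
#' @param max_shift_mm,max_angle_deg Search range.
#' @return A \code{rigid_transform}; attribute \code{"metric"} holds the final
#'   MSE and \code{"improved"} is FALSE (with a warning) when the optimum does
#'   not beat the identity.
#' @export
estimate_rigid <- function(img_ref, img_mov, voxel_mm = 1,
                           max_shift_mm = 8 * voxel_mm, max_angle_deg = 10) {
  stop_if(!identical(dim(img_ref), dim(img_mov)), "images must share a grid")
  if (length(dim(img_ref)) == 2) {
    dim(img_ref) <- c(dim(img_ref), 1L); dim(img_mov) <- c(dim(img_mov), 1L)
  }
  ref <- smooth_inplane(img_ref); mov <- smooth_inplane(img_mov)
  d <- dim(ref)
  ctr <- c(d + 1) / 2 * voxel_mm
  make_fn <- function(ref_img, mov_img, stride) {
    ix <- seq(1, d[1] - 1, by = stride); iy <- seq(1, d[2] - 1, by = stride)
    # the metric grid sits half a voxel off the lattice so that at the
    # identity both images are interpolated identically; this removes the
    # kink in the interpolation loss that otherwise pins the optimum to
    # integer alignments
    g <- cbind(rep(ix + 0.5, times = length(iy) * d[3]),
               rep(rep(iy + 0.5, each = length(ix)), times = d[3]),
               rep(seq_len(d[3]), each = length(ix) * length(iy))) * voxel_mm
    rv <- interp3(ref_img, g[, 1] / voxel_mm, g[, 2] / voxel_mm, g[, 3] / voxel_mm)
    gx <- g[, 1] - ctr[1]; gy <- g[, 2] - ctr[2]
    function(p) {
      a <- p[1] * pi / 180
      qx <- (cos(a) * gx - sin(a) * gy + ctr[1] + p[2]) / voxel_mm
      qy <- (sin(a) * gx + cos(a) * gy + ctr[2] + p[3]) / voxel_mm
      vals <- interp3(mov_img, qx, qy, g[, 3] / voxel_mm)
      ok <- !is.na(vals) & !is.na(rv)
      if (!any(ok)) return(Inf)
      mean((vals[ok] - rv[ok])^2)
    }
  }
  fn_coarse <- make_fn(ref, mov, 2L)
  fn <- make_fn(ref, mov, 1L)
  angs <- seq(-max_angle_deg, max_angle_deg, length.out = 9)
  shs <- seq(-max_shift_mm, max_shift_mm, length.out = 9)
  est <- c(0, 0, 0); bestv <- fn_coarse(est)
  for (a in angs) for (sx in shs) for (sy in shs) {
    v <- fn_coarse(c(a, sx, sy))
    if (v < bestv) { bestv <- v; est <- c(a, sx, sy) }
  }
  o <- stats::optim(est, fn, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 250))
  # restart once from the optimum (helps NM escape premature contraction)
  o <- stats::optim(o$par, fn, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 150))
  est <- o$par
  # numerically negligible motion is snapped to the exact identity so that
  # registering an image to itself is a strict no-op
  if (abs(est[1]) < 1e-6 && max(abs(est[2:3])) < 1e-6 * voxel_mm) est <- c(0, 0, 0)
  final <- rigid_transform(est[1], c(est[2], est[3], 0))
  m_id <- mse_metric(img_ref, img_mov, rigid_transform(), voxel_mm)
  m_fin <- mse_metric(img_ref, img_mov, final, voxel_mm)
  improved <- m_fin <= m_id + 1e-12
  if (!improved) {
    warning("registration failed to improve over identity; returning identity")
    final <- rigid_transform()
    m_fin <- m_id
  }
  attr(final, "metric") <- m_fin
  attr(final, "improved") <- improved
  final
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: %.3f deg, shift (%.3f, %.3f, %.3f) mm\n",
              x$angle_deg, x$shift_mm[1], x$shift_mm[2], x$shift_mm[3]))
  invisible(x)
}

#' Serialize a rigid transform to JSON
#' @param transform Rigid transform.
#' @param path Output path.
#' @return The path, invisibly. Angles are degrees (counter-clockwise,
#'   in-plane about the volume center), shifts mm, point-map convention
#'   output-grid to input.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(list(angle_deg = transform$angle_deg,
                            shift_mm = transform$shift_mm,
                            convention = "output-grid point map; rotation about volume center"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$angle_deg, x$shift_mm)
}
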