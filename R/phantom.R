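# Digital quantitative phantom: anatomy-like label geometry with T1/T2/PD
# maps, corpus-callosum sub-segments, tract-like bundles, a B0 field with a
# sinus-analog pocket, and coil sensitivities.

PHANTOM_LABELS <- c(background = 0L, wm = 1L, gm = 2L, csf = 3L,
                    cc1 = 4L, cc2 = 5L, cc3 = 6L, cc4 = 7L, cc5 = 8L)

# literature-style tissue defaults (config entries, not measured values)
default_tissue_params <- function() {
  list(
    t1 = c(wm = 850, gm = 1400, csf = 4200),
    t2 = c(wm = 60, gm = 80, csf = 1500),
    pd = c(wm = 0.7, gm = 0.85, csf = 1.0),
    # corpus callosum anterior -> posterior segment T1 means (ms):
    # interior maximum gives the inverted-U shape along the AP axis
    cc_t1 = c(820, 862, 890, 868, 824),
    cc_t2 = 50, cc_pd = 0.72,
    texture_sd = 0.025,   # sd of the smooth within-class texture
    texture_frac = 0.05   # hard +/- bound of the texture
  )
}

smooth_field2d <- function(nx, ny, n_pass = 3) {
  f <- matrix(stats::rnorm(nx * ny), nx, ny)
  for (i in seq_len(n_pass)) {
    f <- (f +
            rbind(f[-1, ], f[nx, ]) + rbind(f[1, ], f[-nx, ]) +
            cbind(f[, -1], f[, ny]) + cbind(f[, 1], f[, -ny])) / 5
  }
  f / stats::sd(f)
}

#' Generate a quantitative digital phantom
#'
#' Builds an anatomy-like 2D+slice phantom: an elliptical brain with a gray
#' matter ring, white matter interior, CSF ventricles, five corpus-callosum
#' segments ordered anterior to posterior whose mean T1 follows an inverted U
#' (interior maximum), and a set of tract-like core curves with mask channels.
#' Tissue values carry smooth within-class texture of bounded amplitude.
#'
#' @param shape Volume dimensions, at least 32 in-plane.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @param tissue Tissue parameter list, see \code{default_tissue_params()}.
#' @param n_tracts Number of tract-like bundles embedded in white matter.
#' @param b0_pocket_hz Amplitude passed to [make_b0_map()].
#' @return Object of class \code{mrf_phantom} with fields \code{t1_map},
#'   \code{t2_map}, \code{pd_map}, \code{b0_map}, \code{label_map},
#'   \code{tract_masks}, \code{tracts} (core curves in mm), \code{voxel_mm}.
#' @export
make_phantom <- function(shape = c(64, 64, 3), voxel_size_mm = 3, seed = 1,
                         tissue = default_tissue_params(), n_tracts = 6,
                         b0_pocket_hz = 60) {
  stop_if(length(shape) < 2 || any(shape[1:2] < 32), "in-plane shape must be >= 32")
  if (length(shape) == 2) shape <- c(shape, 1L)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  sc <- nx / 64   # geometry scale factor

  xi <- matrix(seq_len(nx), nx, ny)
  yi <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ell <- function(x0, y0, ax, ay) ((xi - x0) / ax)^2 + ((yi - y0) / ay)^2 <= 1

  brain <- ell(cx, cy, 28 * sc, 30 * ny / 64)
  inner <- ell(cx, cy, 23 * sc, 25 * ny / 64)
  # lateral ventricles, deliberately left-right asymmetric (as in real
  # anatomy); the asymmetry also makes small rotations identifiable for
  # registration, which a purely elliptical phantom would not be
  vent <- ell(cx - 6 * sc, cy + 2.5, 3.0 * sc, 6.0 * sc) |
    ell(cx + 6 * sc, cy + 1.5, 2.2 * sc, 5.0 * sc)
  # deep gray-matter nuclei (thalamus/putamen analogs), off-axis and unequal
  nuclei <- ell(cx - 10 * sc, cy - 3, 3.5 * sc, 2.5 * sc) |
    ell(cx + 10 * sc, cy - 5, 2.5 * sc, 3.5 * sc) |
    ell(cx + 7 * sc, cy + 9, 2.0 * sc, 2.0 * sc)
  cc_half <- 2.5 * sc
  cc_ylim <- c(cy - 18 * ny / 64, cy + 18 * ny / 64)
  cc <- abs(xi - cx) <= cc_half & yi >= cc_ylim[1] & yi <= cc_ylim[2] & inner &
    !vent & !nuclei

  lab2d <- matrix(PHANTOM_LABELS["background"], nx, ny)
  lab2d[brain] <- PHANTOM_LABELS["gm"]
  lab2d[inner] <- PHANTOM_LABELS["wm"]
  lab2d[nuclei & inner] <- PHANTOM_LABELS["gm"]
  lab2d[vent & inner] <- PHANTOM_LABELS["csf"]
  # five CC segments, equal spans anterior (low y) -> posterior (high y)
  edges <- seq(cc_ylim[1], cc_ylim[2], length.out = 6)
  for (s in 1:5) {
    seg <- cc & yi >= edges[s] & (if (s < 5) yi < edges[s + 1] else yi <= edges[6])
    lab2d[seg] <- PHANTOM_LABELS[[paste0("cc", s)]]
  }
  label <- array(rep(lab2d, nz), c(nx, ny, nz))

  t1 <- array(0, shape); t2 <- array(0, shape); pd <- array(0, shape)
  base_t1 <- c(NA, tissue$t1[["wm"]], tissue$t1[["gm"]], tissue$t1[["csf"]], tissue$cc_t1)
  base_t2 <- c(NA, tissue$t2[["wm"]], tissue$t2[["gm"]], tissue$t2[["csf"]], rep(tissue$cc_t2, 5))
  base_pd <- c(NA, tissue$pd[["wm"]], tissue$pd[["gm"]], tissue$pd[["csf"]], rep(tissue$cc_pd, 5))
  tex <- with_seed(derive_seed(seed, "texture"), {
    array(vapply(seq_len(nz), function(z) smooth_field2d(nx, ny), matrix(0, nx, ny)),
          shape)
  })
  tex <- pmin(pmax(tex * tissue$texture_sd, -tissue$texture_frac),
              tissue$texture_frac)
  # T1 carries the within-class texture; T2 is class-constant (and sits on
  # the default dictionary grid) so the matching benchmark isolates T1
  for (l in 1:8) {
    m <- label == l
    t1[m] <- base_t1[l + 1] * (1 + tex[m])
    t2[m] <- base_t2[l + 1]
    pd[m] <- base_pd[l + 1] * (1 + 0.5 * tex[m])
  }

  tracts <- phantom_tracts(shape, voxel_size_mm, n_tracts)
  tract_masks <- array(FALSE, c(shape, length(tracts)))
  for (j in seq_along(tracts)) {
    tm <- tract_mask_from_core(tracts[[j]]$core_mm, shape, voxel_size_mm,
                               radius_mm = 2 * voxel_size_mm)
    tract_masks[, , , j] <- tm
    # give each tract a distinct small T1 offset inside white matter
    m <- tm & label == PHANTOM_LABELS["wm"]
    t1[m] <- t1[m] * (1 + 0.015 * (j - (length(tracts) + 1) / 2) / length(tracts))
  }

  ph <- structure(list(
    t1_map = t1, t2_map = t2, pd_map = pd, label_map = label,
    tract_masks = tract_masks, tracts = tracts,
    voxel_mm = voxel_size_mm, shape = shape, seed = seed
  ), class = "mrf_phantom")
  ph$b0_map <- make_b0_map(ph, pocket_amplitude_hz = b0_pocket_hz,
                           seed = derive_seed(seed, "b0"))
  ph
}

# Tract-like core curves in mm. Half are callosal analogs (left-right arcs at
# different AP positions), half hemispheric analogs (anterior-posterior arcs).
phantom_tracts <- function(shape, voxel_mm, n_tracts) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  zmid <- (nz + 1) / 2
  s <- seq(0, 1, length.out = 40)
  mm <- function(v) v * voxel_mm
  tracts <- list()
  n_cal <- ceiling(n_tracts / 2)
  ypos <- seq(cy - 12 * ny / 64, cy + 12 * ny / 64, length.out = max(n_cal, 2))
  for (j in seq_len(n_cal)) {
    x <- cx + (s - 0.5) * 24 * nx / 64
    y <- ypos[j] - 4 * sin(pi * s)
    tracts[[j]] <- list(name = sprintf("callosal_%d", j),
                        core_mm = cbind(mm(x), mm(y), mm(rep(zmid, 40))),
                        orientation = "left_right")
  }
  n_hem <- n_tracts - n_cal
  xoff <- c(-10, 10, -14, 14, -7, 7) * nx / 64
  for (j in seq_len(n_hem)) {
    y <- cy + (s - 0.5) * 30 * ny / 64
    x <- cx + xoff[j] + 2.5 * sin(pi * s) * sign(xoff[j])
    tracts[[n_cal + j]] <- list(name = sprintf("hemispheric_%d", j),
                                core_mm = cbind(mm(x), mm(y), mm(rep(zmid, 40))),
                                orientation = "anterior_posterior")
  }
  tracts
}

tract_mask_from_core <- function(core_mm, shape, voxel_mm, radius_mm) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  mask <- array(FALSE, shape)
  core_v <- core_mm / voxel_mm   # voxel-index coordinates (centers at integers)
  r <- radius_mm / voxel_mm
  for (i in seq_len(nrow(core_v))) {
    xr <- max(1, floor(core_v[i, 1] - r)):min(nx, ceiling(core_v[i, 1] + r))
    yr <- max(1, floor(core_v[i, 2] - r)):min(ny, ceiling(core_v[i, 2] + r))
    zr <- max(1, floor(core_v[i, 3] - r)):min(nz, ceiling(core_v[i, 3] + r))
    g <- expand.grid(x = xr, y = yr, z = zr)
    d2 <- (g$x - core_v[i, 1])^2 + (g$y - core_v[i, 2])^2 + (g$z - core_v[i, 3])^2
    keep <- d2 <= r^2
    if (any(keep)) mask[cbind(g$x[keep], g$y[keep], g$z[keep])] <- TRUE
  }
  mask
}

#' White matter mask of a phantom (including corpus callosum segments)
#' @param phantom An \code{mrf_phantom}.
#' @param include_cc Include the CC segment labels.
#' @return Logical array.
#' @export
wm_mask <- function(phantom, include_cc = TRUE) {
  ids <- PHANTOM_LABELS["wm"]
  if (include_cc) ids <- c(ids, PHANTOM_LABELS[paste0("cc", 1:5)])
  array(phantom$label_map %in% ids, dim(phantom$label_map))
}

#' Generate a B0 off-resonance map
#'
#' Smooth low-amplitude background field plus one localized high-amplitude
#' pocket near the anterior brain boundary (air-filled sinus analog). The
#' pocket center and width are recorded as attributes \code{"pocket_center"}
#' (voxel indices) and \code{"pocket_sigma_vox"}.
#'
#' @param phantom An \code{mrf_phantom}.
#' @param pocket_amplitude_hz Peak pocket amplitude (Hz); 0 disables the field.
#' @param background_rms_hz RMS of the smooth background component over the
#'   brain.
#' @param smooth_scale Smoothing passes for the background field.
#' @param seed Integer seed.
#' @return Hz volume with pocket attributes.
#' @export
make_b0_map <- function(phantom, pocket_amplitude_hz = 60, background_rms_hz = 5,
                        smooth_scale = 8, seed = 1) {
  stop_if(pocket_amplitude_hz < 0, "pocket amplitude must be >= 0")
  shape <- phantom$shape
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  bg2d <- with_seed(derive_seed(seed, "b0bg"), smooth_field2d(nx, ny, smooth_scale))
  bg <- array(rep(bg2d * background_rms_hz, nz), shape)
  cx <- (nx + 1) / 2
  ctr <- c(cx, 0.17 * ny, (nz + 1) / 2)  # anterior-inferior brain boundary
  sig <- 3.5 * nx / 64
  xi <- array(rep(seq_len(nx), ny * nz), shape)
  yi <- array(rep(rep(seq_len(ny), each = nx), nz), shape)
  pocket <- pocket_amplitude_hz *
    exp(-((xi - ctr[1])^2 + (yi - ctr[2])^2) / (2 * sig^2))
  structure(bg + pocket,
            pocket_center = if (pocket_amplitude_hz > 0) ctr else NULL,
            pocket_sigma_vox = sig)
}

#' Pocket region mask of a B0 map
#' @param b0_map Map from [make_b0_map()].
#' @param shape Volume shape.
#' @param n_sigma Radius in pocket sigmas.
#' @return Logical array (all-FALSE when the map has no pocket).
#' @export
b0_pocket_mask <- function(b0_map, shape = dim(b0_map), n_sigma = 2.5) {
  ctr <- attr(b0_map, "pocket_center")
  if (is.null(ctr)) return(array(FALSE, shape))
  sig <- attr(b0_map, "pocket_sigma_vox")
  xi <- array(rep(seq_len(shape[1]), shape[2] * shape[3]), shape)
  yi <- array(rep(rep(seq_len(shape[2]), each = shape[1]), shape[3]), shape)
  (xi - ctr[1])^2 + (yi - ctr[2])^2 <= (n_sigma * sig)^2
}

#' Generate smooth complex coil sensitivity maps
#'
#' Gaussian magnitude profiles centered around the field of view with smooth
#' per-coil phase ramps, normalized so the root sum of squares equals 1 at
#' every voxel.
#'
#' @param shape Volume dimensions.
#' @param n_coils Number of receive channels.
#' @param seed Integer seed.
#' @return Complex array \code{[shape, n_coils]}.
#' @export
make_coil_sensitivities <- function(shape = c(64, 64, 3), n_coils = 4, seed = 1) {
  stop_if(n_coils < 1, "n_coils must be >= 1")
  if (length(shape) == 2) shape <- c(shape, 1L)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  xi <- array(rep(seq_len(nx), ny * nz), shape)
  yi <- array(rep(rep(seq_len(ny), each = nx), nz), shape)
  maps <- array(0i, c(shape, n_coils))
  with_seed(derive_seed(seed, "coils"), {
    ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils + stats::runif(1, 0, pi)
    for (j in seq_len(n_coils)) {
      ctr <- c((nx + 1) / 2 + 0.6 * nx / 2 * cos(ang[j]),
               (ny + 1) / 2 + 0.6 * ny / 2 * sin(ang[j]))
      mag <- exp(-((xi - ctr[1])^2 + (yi - ctr[2])^2) / (2 * (0.7 * nx)^2))
      ph <- (stats::runif(1, -1, 1) * xi / nx + stats::runif(1, -1, 1) * yi / ny) * pi / 2
      maps[, , , j] <- mag * exp(1i * ph)
    }
  })
  rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  maps / as.vector(rss)   # coil is the trailing dimension: recycles per coil
}

#' @export
print.mrf_phantom <- function(x, ...) {
  cat(sprintf("Quantitative phantom %s, voxel %.1f mm, %d tracts, seed %s\n",
              paste(x$shape, collapse = "x"), x$voxel_mm, length(x$tracts),
              format(x$seed)))
  invisible(x)
}
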