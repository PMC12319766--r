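# End-to-end experiment: simulate a two-session cohort, acquire two
# complementary scans per session, reconstruct under the four pipelines
# (2-min / 4-min x B0 off/on), register sessions into half-way space,
# match, and compute voxel-wise / ROI / tract reliability, the mixed-model
# pipeline comparison and age-R1 correlations.

#' Experiment configuration
#'
#' @param cohort A [cohort_spec()].
#' @param protocol An [mrf_protocol()] (desk scale by default).
#' @param grid Dictionary grid.
#' @param k Subspace dimension.
#' @param n_coils Number of receive coils.
#' @param recon Named list of [recon_config()]s for the four pipelines
#'   \code{2min, 2min_b0, 4min, 4min_b0}.
#' @param pipelines Subset of pipeline names to run.
#' @param out_dir Optional output directory for CSV/NIfTI artifacts.
#' @param seed Master seed (overrides the cohort seed).
#' @param verbose Print progress.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(cohort = cohort_spec(n_subjects = 8),
                       protocol = desk_protocol(),
                       grid = dictionary_grid(), k = 5, n_coils = 4,
                       recon = default_pipeline_recons(),
                       pipelines = names(recon),
                       out_dir = NULL, seed = cohort$seed, verbose = FALSE) {
  stop_if(!identical(sort(names(recon)),
                     sort(c("2min", "2min_b0", "4min", "4min_b0"))),
          "recon must have exactly the entries 2min, 2min_b0, 4min, 4min_b0")
  stop_if(!all(pipelines %in% names(recon)), "unknown pipeline name")
  cohort$seed <- seed
  structure(list(cohort = cohort, protocol = protocol, grid = grid, k = k,
                 n_coils = n_coils, recon = recon, pipelines = pipelines,
                 out_dir = out_dir, seed = seed, verbose = verbose),
            class = "run_config")
}

#' Default reconstruction settings of the four pipelines
#'
#' 20 iterations per solve: at the desk-scale problem size the objective
#' plateaus well before that, and all four pipelines use the same budget so
#' the comparison stays balanced.
#'
#' @param n_iters Iterations per reconstruction.
#' @param b0_segments Time segments for the corrected pipelines.
#' @return Named list of [recon_config()]s.
#' @export
default_pipeline_recons <- function(n_iters = 20, b0_segments = 8) {
  list(
    "2min" = recon_config(n_iters = n_iters),
    "2min_b0" = recon_config(n_iters = n_iters, b0_segments = b0_segments),
    "4min" = recon_config(n_iters = n_iters),
    "4min_b0" = recon_config(n_iters = n_iters, b0_segments = b0_segments)
  )
}

# shared per-experiment objects (dictionary, basis, coils, schemes)
experiment_setup <- function(config) {
  prot <- config$protocol
  dict <- build_dictionary(config$grid, prot)
  basis <- compute_subspace(dict, config$k)
  cdict <- compress_dictionary(dict, basis)
  shape <- config$cohort$shape
  coils <- make_coil_sensitivities(shape, config$n_coils,
                                   seed = derive_seed(config$seed, "coils"))
  scheme_a <- make_sampling_scheme(shape[1:2], prot, accel = 2,
                                   seed = derive_seed(config$seed, "schemeA"))
  scheme_b <- make_sampling_scheme(shape[1:2], prot, accel = 2,
                                   seed = derive_seed(config$seed, "schemeB"),
                                   complement_of = scheme_a)
  list(protocol = prot, dict = dict, basis = basis, cdict = cdict,
       coils = coils, scheme_a = scheme_a, scheme_b = scheme_b)
}

# one-voxel in-plane (4-neighbour) erosion of a logical mask
erode_inplane <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] & m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] & m[-1, , ]
  out[, -1, ] <- out[, -1, ] & m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] & m[, -1, ]
  out
}

# move every map of a phantom by a rigid transform (the object as seen by a
# scan acquired after motion)
move_phantom <- function(phantom, transform) {
  if (transform$angle_deg == 0 && all(transform$shift_mm == 0)) return(phantom)
  ph <- phantom
  for (f in c("t1_map", "t2_map", "pd_map", "b0_map")) {
    a <- attributes(ph[[f]])
    ph[[f]] <- resample_image(ph[[f]], transform, phantom$voxel_mm)
    attr(ph[[f]], "valid") <- NULL
    if (f == "b0_map") {
      attr(ph[[f]], "pocket_center") <- a$pocket_center
      attr(ph[[f]], "pocket_sigma_vox") <- a$pocket_sigma_vox
    }
  }
  ph$label_map <- resample_image(ph$label_map, transform, phantom$voxel_mm,
                                 interpolation = "nearest")
  attr(ph$label_map, "valid") <- NULL
  ph
}

# simulate the two complementary scans of one session and reconstruct the
# requested pipelines in native session space
recon_session <- function(session, setup, config) {
  prot <- setup$protocol
  ph <- session$phantom
  # each subject-session gets its own realization of the two complementary
  # sampling patterns: between sessions months apart the head is repositioned,
  # so the trajectory-relative sampling of the anatomy differs and the
  # undersampling residuals decorrelate, as they do in vivo
  traj_tag <- if (identical(config$cohort$session_trajectories, "fixed")) list()
              else list(session$subject, session$session)
  scheme_a <- make_sampling_scheme(dim(ph$t1_map)[1:2], prot, accel = 2,
                                   seed = do.call(derive_seed,
                                                  c(list(config$seed, "schemeA"), traj_tag)))
  scheme_b <- make_sampling_scheme(dim(ph$t1_map)[1:2], prot, accel = 2,
                                   seed = do.call(derive_seed,
                                                  c(list(config$seed, "schemeB"), traj_tag)),
                                   complement_of = scheme_a)
  setup$scheme_a <- scheme_a
  setup$scheme_b <- scheme_b
  c_true <- project_phantom(ph, setup$basis, prot)
  # the second 2-min scan sees the object after small intra-session motion;
  # its k-space is generated through the exact rigid k-space motion model
  b0_b <- ph$b0_map
  if (session$intra_motion$angle_deg != 0 || any(session$intra_motion$shift_mm != 0)) {
    b0_b <- resample_image(ph$b0_map, session$intra_motion, ph$voxel_mm)
  }
  y_a0 <- forward_model(c_true, setup$basis, setup$coils, setup$scheme_a,
                        b0_map = ph$b0_map)
  noise_sd <- session$noise_rel * sqrt(mean(Mod(y_a0$samples)^2))
  add_noise <- function(y, tag) {
    if (noise_sd == 0) return(y)
    y$samples <- y$samples + with_seed(derive_seed(session$seed, tag), {
      n <- length(y$samples)
      complex(real = stats::rnorm(n, 0, noise_sd / sqrt(2)),
              imaginary = stats::rnorm(n, 0, noise_sd / sqrt(2)))
    })
    y$noise_sd <- noise_sd
    y
  }
  y_a <- add_noise(y_a0, "noiseA")
  y_b <- add_noise(forward_moved(c_true, setup$basis, setup$coils,
                                 setup$scheme_b, b0_map = b0_b,
                                 transform = session$intra_motion,
                                 voxel_mm = ph$voxel_mm), "noiseB")

  need_4min <- any(c("4min", "4min_b0") %in% config$pipelines)
  out <- list()
  rec_a <- NULL
  if (any(c("2min", "4min") %in% config$pipelines) || need_4min) {
    rec_a <- reconstruct_subspace(y_a, setup$basis, setup$coils, setup$scheme_a,
                                  config$recon[["2min"]])
  }
  if ("2min" %in% config$pipelines) out[["2min"]] <- rec_a
  y_comb <- NULL
  if (need_4min) {
    # scan-B reconstruction is only used to estimate the intra-session
    # motion; solve it with the same budget as scan A so the registration
    # pair has matched convergence and noise texture
    rec_b <- reconstruct_subspace(y_b, setup$basis, setup$coils, setup$scheme_b,
                                  config$recon[["2min"]])
    reg_k <- min(3, dim(rec_a$c)[4])
    # estimate_rigid maps scan-A grid points into scan-B space; the k-space
    # combination needs the scan-B -> scan-A map
    t_ab <- estimate_rigid(Mod(rec_a$c[, , , reg_k]), Mod(rec_b$c[, , , reg_k]),
                           ph$voxel_mm, max_shift_mm = 4 * ph$voxel_mm,
                           max_angle_deg = 4)
    y_comb <- combine_acquisitions(y_a, y_b, invert_rigid(t_ab),
                                   voxel_mm = ph$voxel_mm)
    if ("4min" %in% config$pipelines)
      out[["4min"]] <- reconstruct_subspace(y_comb, setup$basis, setup$coils,
                                            y_comb$scheme, config$recon[["4min"]])
  }
  if ("2min_b0" %in% config$pipelines)
    out[["2min_b0"]] <- reconstruct_subspace_b0(y_a, setup$basis, setup$coils,
                                                setup$scheme_a, ph$b0_map,
                                                config$recon[["2min_b0"]])
  if ("4min_b0" %in% config$pipelines)
    out[["4min_b0"]] <- reconstruct_subspace_b0(y_comb, setup$basis, setup$coils,
                                                y_comb$scheme, ph$b0_map,
                                                config$recon[["4min_b0"]])
  list(coeffs = out, phantom = ph, noise_sd = noise_sd)
}

#' Run the full four-pipeline reliability experiment
#'
#' For every subject: realize both sessions, simulate two complementary
#' acquisitions per session, reconstruct the configured pipelines (4-min via
#' motion-compensated k-space combination), register the sessions into an
#' unbiased half-way space using the high-contrast coefficient of the 4-min
#' reconstruction (falling back to the 2-min one when the 4-min pipelines are
#' not run), match after resampling, and accumulate voxel-wise, ROI and
#' tract-level scan-rescan statistics; finally fit the mixed model and the
#' age-R1 correlations.
#'
#' @param config A [run_config()].
#' @return Object of class \code{mrf_report}: \code{voxelwise} (per
#'   subject x pipeline reliability rows), \code{roi_table}, \code{tract_table},
#'   \code{lmm}, \code{age_table}, \code{provenance}.
#' @export
run_experiment <- function(config) {
  stop_if(!inherits(config, "run_config"), "config must be a run_config")
  setup <- experiment_setup(config)
  cohort <- simulate_cohort(config$cohort)
  n_sub <- config$cohort$n_subjects
  pipes <- config$pipelines
  reg_pipe <- if ("4min" %in% pipes) "4min" else pipes[1]
  vox_rows <- list()
  roi_maps <- list()   # per pipeline: list(s1 = list of t1 maps, s2 = ..., labels = ...)
  tract_means <- list()
  tract_profiles <- list()
  cc_ids <- unname(PHANTOM_LABELS[paste0("cc", 1:5)])
  voxel_mm <- config$cohort$voxel_size_mm

  for (pp in pipes) {
    roi_maps[[pp]] <- list(s1 = list(), s2 = list(), labels = list())
    tract_means[[pp]] <- list(s1 = NULL, s2 = NULL)
  }

  for (i in seq_len(n_sub)) {
    if (config$verbose) message(sprintf("subject %d / %d", i, n_sub))
    s1 <- realize_session(cohort, i, 1)
    s2 <- realize_session(cohort, i, 2)
    r1s <- recon_session(s1, setup, config)
    r2s <- recon_session(s2, setup, config)

    reg_k <- min(3, config$k)
    t_12 <- estimate_rigid(Mod(r1s$coeffs[[reg_pipe]]$c[, , , reg_k]),
                           Mod(r2s$coeffs[[reg_pipe]]$c[, , , reg_k]),
                           voxel_mm)
    halves <- halfway_split(t_12)
    labels_h <- resample_image(r1s$phantom$label_map, halves$half_a, voxel_mm,
                               interpolation = "nearest")
    wm_h <- array(labels_h %in% c(PHANTOM_LABELS["wm"], cc_ids), dim(labels_h))
    # voxelwise statistics use a one-voxel in-plane erosion: at desk-scale
    # voxel sizes the boundary voxels are dominated by partial volume, which
    # the study avoids via conservative white-matter masks
    wm_vox <- erode_inplane(wm_h)
    truth_h <- resample_image(r1s$phantom$t1_map, halves$half_a, voxel_mm)

    # tract cores mapped into half-way space (session-1 native -> half-way)
    inv_a <- invert_rigid(halves$half_a)
    ctr_mm <- c(dim(labels_h) + 1) / 2 * voxel_mm

    subj_profiles <- list()
    for (pp in pipes) {
      c1h <- resample_coefficients(r1s$coeffs[[pp]], halves$half_a, voxel_mm)
      c2h <- resample_coefficients(r2s$coeffs[[pp]], halves$half_b, voxel_mm)
      # match white matter (incl. CC) and CSF: everything the voxelwise, ROI
      # and tract analyses touch; the GM ring is not analyzed
      match_mask <- wm_h | labels_h == PHANTOM_LABELS["csf"]
      m1 <- template_match(c1h, setup$cdict, mask = match_mask)
      m2 <- template_match(c2h, setup$cdict, mask = match_mask)
      rel <- voxelwise_reliability(m1$t1_map, m2$t1_map, wm_vox)
      vox_rows[[length(vox_rows) + 1]] <- data.frame(
        participant = i, pipeline = pp,
        duration = if (grepl("^4", pp)) "4min" else "2min",
        b0 = if (grepl("b0$", pp)) "on" else "off",
        age = s1$age, r = rel$pearson_r, r2 = rel$r2_identity,
        cv_percent = rel$cv_percent, n_voxels = rel$n,
        rmse_vs_truth = sqrt(mean((m1$t1_map[wm_vox] - truth_h[wm_vox])^2)))
      roi_maps[[pp]]$s1[[i]] <- m1$t1_map
      roi_maps[[pp]]$s2[[i]] <- m2$t1_map
      roi_maps[[pp]]$labels[[i]] <- labels_h
      # tract profiles on both sessions' half-way T1 maps
      prof1 <- prof2 <- matrix(NA_real_, length(r1s$phantom$tracts), 100)
      for (j in seq_along(r1s$phantom$tracts)) {
        tr <- r1s$phantom$tracts[[j]]
        core_h <- apply_rigid(inv_a, tr$core_mm, ctr_mm)
        bun <- generate_bundle(core_h, n_streamlines = 25, spread_mm = voxel_mm,
                               outlier_frac = 0,
                               seed = derive_seed(config$seed, "bundle", i, j),
                               name = tr$name, orientation = tr$orientation)
        p1 <- suppressMessages(tract_profile(bun, m1$t1_map, voxel_mm = voxel_mm))
        p2 <- suppressMessages(tract_profile(bun, m2$t1_map, voxel_mm = voxel_mm))
        prof1[j, ] <- p1$node_values
        prof2[j, ] <- p2$node_values
      }
      subj_profiles[[pp]] <- list(s1 = prof1, s2 = prof2)
      tract_means[[pp]]$s1 <- rbind(tract_means[[pp]]$s1,
                                    rowMeans(prof1[, 11:90, drop = FALSE], na.rm = TRUE))
      tract_means[[pp]]$s2 <- rbind(tract_means[[pp]]$s2,
                                    rowMeans(prof2[, 11:90, drop = FALSE], na.rm = TRUE))
    }
    tract_profiles[[i]] <- subj_profiles
  }

  voxelwise <- do.call(rbind, vox_rows)

  roi_table <- do.call(rbind, lapply(pipes, function(pp) {
    tab <- roi_reliability(roi_maps[[pp]]$s1, roi_maps[[pp]]$s2,
                           roi_maps[[pp]]$labels, cc_ids)
    tab$pipeline <- pp
    tab$roi_name <- paste0("cc", match(tab$roi, cc_ids))
    tab
  }))

  tract_names <- vapply(make_phantom(config$cohort$shape, voxel_mm,
                                     seed = derive_seed(config$seed, "phantom", 1))$tracts,
                        `[[`, "", "name")
  ages <- cohort$subjects$age_s1
  tract_table <- do.call(rbind, lapply(pipes, function(pp) {
    m1 <- tract_means[[pp]]$s1; m2 <- tract_means[[pp]]$s2
    do.call(rbind, lapply(seq_len(ncol(m1)), function(j) {
      ok <- is.finite(m1[, j]) & is.finite(m2[, j])
      r <- if (sum(ok) >= 3 && stats::sd(m1[ok, j]) > 0) stats::cor(m1[ok, j], m2[ok, j]) else NA_real_
      data.frame(pipeline = pp, tract = tract_names[j], pearson_r = r,
                 cv_percent = mean(two_point_cv(m1[ok, j], m2[ok, j])),
                 n_subjects = sum(ok))
    }))
  }))

  age_table <- NULL
  if (n_sub >= 10) {
    age_table <- do.call(rbind, lapply(pipes, function(pp) {
      r1m <- 1000 / tract_means[[pp]]$s1      # tract-mean T1 (ms) -> R1 (1/s)
      colnames(r1m) <- tract_names
      tab <- age_correlation(r1m, ages)
      tab$pipeline <- pp
      tab
    }))
  }

  lmm <- NULL
  if (all(c("2min", "2min_b0", "4min", "4min_b0") %in% pipes) && n_sub >= 3) {
    lmm <- fit_reliability_lmm(voxelwise[, c("participant", "duration", "b0", "age", "r")])
  }

  report <- structure(list(
    voxelwise = voxelwise, roi_table = roi_table, tract_table = tract_table,
    age_table = age_table, lmm = lmm,
    tract_profiles = tract_profiles,
    provenance = list(seed = config$seed, pipelines = pipes,
                      n_subjects = n_sub, shape = config$cohort$shape,
                      protocol = c(groups = setup$protocol$n_groups,
                                   trs = setup$protocol$trs_per_group),
                      k = config$k, n_coils = config$n_coils,
                      noise_rel = config$cohort$noise_rel,
                      version = as.character(utils::packageVersion("mrfrelia")))
  ), class = "mrf_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write the report tables of an experiment
#' @param report An \code{mrf_report}.
#' @param out_dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wr <- function(tab, name) {
    if (is.null(tab)) return()
    p <- file.path(out_dir, name)
    utils::write.csv(format(tab, digits = 10), p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$voxelwise, "reliability_voxelwise.csv")
  wr(report$roi_table, "reliability_roi.csv")
  wr(report$tract_table, "reliability_tracts.csv")
  wr(report$age_table, "age_effects.csv")
  if (!is.null(report$lmm)) wr(report$lmm$fixed, "lmm_fixed_effects.csv")
  jsonlite::write_json(report$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, file.path(out_dir, "provenance.json")))
}

#' @export
print.mrf_report <- function(x, ...) {
  cat(sprintf("MRF reliability report: %d subjects, pipelines %s\n",
              x$provenance$n_subjects, paste(x$provenance$pipelines, collapse = ", ")))
  agg <- stats::aggregate(r ~ pipeline, data = x$voxelwise, FUN = mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  voxelwise mean r (%s): %.3f\n", agg$pipeline[i], agg$r[i]))
  invisible(x)
}
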