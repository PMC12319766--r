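# Simulated two-session pediatric cohort: age-dependent white-matter R1,
# between-subject variation, inter-session developmental drift and rigid
# motion, plus small intra-session motion between the two complementary
# 2-min acquisitions of each session.

#' Cohort specification
#'
#' @param n_subjects Number of subjects.
#' @param age_range_y Age interval (years), uniform sampling.
#' @param r1_age_slope White-matter R1 increase per year (1/s/year).
#' @param r1_intercept R1 at age 0 (1/s); with the defaults a 10.5-year-old
#'   has WM R1 close to 1/0.85 s.
#' @param between_subject_sd Between-subject R1 standard deviation (1/s).
#' @param session_interval_months Interval between the two sessions (uniform).
#' @param motion_sd Inter-session rigid motion sd: \code{c(rot_deg, trans_mm)}.
#' @param intra_motion_sd Intra-session motion sd between the two 2-min scans.
#' @param noise_rel Complex k-space noise sd relative to the RMS sample
#'   magnitude of the noiseless scan.
#' @param session_trajectories \code{"redrawn"} draws a fresh realization of
#'   the sampling patterns for every subject-session (the head is
#'   repositioned between sessions, so the trajectory-relative sampling of
#'   the anatomy changes and undersampling residuals decorrelate, as in
#'   vivo); \code{"fixed"} reuses identical patterns, which makes a fully
#'   degenerate cohort (no noise, no motion, no drift) exactly repeatable.
#' @param shape,voxel_size_mm Phantom geometry.
#' @param seed Master seed; all subject/session seeds derive from it.
#' @return Object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 40, age_range_y = c(8, 13),
                        r1_age_slope = 0.008, r1_intercept = 1.092,
                        between_subject_sd = 0.015,
                        session_interval_months = c(2, 4),
                        motion_sd = c(rot_deg = 2, trans_mm = 2),
                        intra_motion_sd = c(rot_deg = 0.2, trans_mm = 0.5),
                        noise_rel = 0.15,
                        session_trajectories = c("redrawn", "fixed"),
                        shape = c(64, 64, 3), voxel_size_mm = 3, seed = 1) {
  session_trajectories <- match.arg(session_trajectories)
  stop_if(r1_age_slope < 0 || between_subject_sd < 0, "slope and sds must be >= 0")
  stop_if(any(motion_sd < 0) || any(intra_motion_sd < 0), "motion sds must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), age_range_y = age_range_y,
                 r1_age_slope = r1_age_slope, r1_intercept = r1_intercept,
                 between_subject_sd = between_subject_sd,
                 session_interval_months = session_interval_months,
                 motion_sd = motion_sd, intra_motion_sd = intra_motion_sd,
                 noise_rel = noise_rel,
                 session_trajectories = session_trajectories, shape = shape,
                 voxel_size_mm = voxel_size_mm, seed = seed),
            class = "cohort_spec")
}

#' Simulate a cohort of two-session subjects
#'
#' Draws ages, subject effects, session intervals and motion parameters. For
#' each subject, white-matter R1 at session 1 is
#' \code{r1_intercept + r1_age_slope * age + subject_effect}; session 2 ages
#' the subject by the interval so R1 drifts along the same slope.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class \code{mrf_cohort}: a data.frame \code{subjects}
#'   (ages, WM R1 per session, motion draws, derived seeds) plus the spec.
#'   Phantom volumes are realized lazily with [realize_session()].
#' @export
simulate_cohort <- function(spec) {
  stop_if(!inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  n <- spec$n_subjects
  tab <- with_seed(derive_seed(spec$seed, "cohort"), {
    age1 <- stats::runif(n, spec$age_range_y[1], spec$age_range_y[2])
    interval <- stats::runif(n, spec$session_interval_months[1],
                             spec$session_interval_months[2])
    eff <- stats::rnorm(n, 0, spec$between_subject_sd)
    rot <- stats::rnorm(n, 0, spec$motion_sd[[1]])
    tx <- stats::rnorm(n, 0, spec$motion_sd[[2]])
    ty <- stats::rnorm(n, 0, spec$motion_sd[[2]])
    rot_i <- stats::rnorm(2 * n, 0, spec$intra_motion_sd[[1]])
    tx_i <- stats::rnorm(2 * n, 0, spec$intra_motion_sd[[2]])
    ty_i <- stats::rnorm(2 * n, 0, spec$intra_motion_sd[[2]])
    age2 <- age1 + interval / 12
    data.frame(
      subject = seq_len(n), age_s1 = age1, age_s2 = age2,
      interval_months = interval, subject_effect = eff,
      wm_r1_s1 = spec$r1_intercept + spec$r1_age_slope * age1 + eff,
      wm_r1_s2 = spec$r1_intercept + spec$r1_age_slope * age2 + eff,
      motion_rot_deg = rot, motion_tx_mm = tx, motion_ty_mm = ty,
      intra_rot_s1 = rot_i[seq_len(n)], intra_tx_s1 = tx_i[seq_len(n)],
      intra_ty_s1 = ty_i[seq_len(n)],
      intra_rot_s2 = rot_i[n + seq_len(n)], intra_tx_s2 = tx_i[n + seq_len(n)],
      intra_ty_s2 = ty_i[n + seq_len(n)]
    )
  })
  tab$seed_s1 <- vapply(tab$subject, function(i) derive_seed(spec$seed, "subj", i, 1), 1L)
  tab$seed_s2 <- vapply(tab$subject, function(i) derive_seed(spec$seed, "subj", i, 2), 1L)
  structure(list(subjects = tab, spec = spec), class = "mrf_cohort")
}

#' Realize the phantom of one subject session
#'
#' Builds the subject's phantom (subject-specific texture seed), scales
#' white-matter T1 (including the CC segments) to the session's target WM R1,
#' and, for session 2, applies the inter-session rigid motion by resampling
#' all quantitative maps into the moved position.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param subject Subject index.
#' @param session 1 or 2.
#' @return List of class \code{session_realization}: \code{phantom},
#'   \code{motion} (rigid transform of this session relative to session 1),
#'   \code{intra_motion} (scan B relative to scan A within the session),
#'   \code{noise_rel}, \code{seed}, \code{age}.
#' @export
realize_session <- function(cohort, subject, session) {
  stop_if(!inherits(cohort, "mrf_cohort"), "cohort must come from simulate_cohort()")
  spec <- cohort$spec
  row <- cohort$subjects[cohort$subjects$subject == subject, ]
  stop_if(nrow(row) != 1, "unknown subject")
  ph <- make_phantom(spec$shape, spec$voxel_size_mm,
                     seed = derive_seed(spec$seed, "phantom", subject))
  r1 <- if (session == 1) row$wm_r1_s1 else row$wm_r1_s2
  wm <- wm_mask(ph)
  # scale all WM-class T1 by a common factor so the CC structure is preserved
  base_wm_t1 <- default_tissue_params()$t1[["wm"]]
  ph$t1_map[wm] <- ph$t1_map[wm] * (1000 / r1) / base_wm_t1
  motion <- rigid_transform()
  if (session == 2) {
    motion <- rigid_transform(row$motion_rot_deg,
                              c(row$motion_tx_mm, row$motion_ty_mm, 0))
    for (f in c("t1_map", "t2_map", "pd_map", "b0_map")) {
      a <- attributes(ph[[f]])
      ph[[f]] <- resample_image(ph[[f]], motion, spec$voxel_size_mm)
      attr(ph[[f]], "valid") <- NULL
      if (f == "b0_map") {
        attr(ph[[f]], "pocket_center") <- a$pocket_center
        attr(ph[[f]], "pocket_sigma_vox") <- a$pocket_sigma_vox
      }
    }
    ph$label_map <- resample_image(ph$label_map, motion, spec$voxel_size_mm,
                                   interpolation = "nearest")
    attr(ph$label_map, "valid") <- NULL
  }
  intra <- if (session == 1)
    rigid_transform(row$intra_rot_s1, c(row$intra_tx_s1, row$intra_ty_s1, 0))
  else
    rigid_transform(row$intra_rot_s2, c(row$intra_tx_s2, row$intra_ty_s2, 0))
  structure(list(phantom = ph, motion = motion, intra_motion = intra,
                 noise_rel = spec$noise_rel,
                 seed = if (session == 1) row$seed_s1 else row$seed_s2,
                 age = if (session == 1) row$age_s1 else row$age_s2,
                 subject = subject, session = session),
            class = "session_realization")
}

#' @export
print.mrf_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects, ages %.1f-%.1f y, seed %s\n",
              x$spec$n_subjects, x$spec$age_range_y[1], x$spec$age_range_y[2],
              format(x$spec$seed)))
  invisible(x)
}
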