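# Scan-rescan reliability statistics: voxel-wise and ROI-based Pearson r,
# coefficient of determination about the identity line, coefficient of
# variation, Bland-Altman summaries, and the mixed-effects pipeline
# comparison.

#' Voxel-wise scan-rescan reliability
#'
#' Pearson correlation over masked voxels, coefficient of determination about
#' the fixed line y = x, \code{R2 = 1 - sum((y-x)^2) / sum((y-ybar)^2)}
#' (can be negative; equals the Pearson-based R2 only when the best fit is
#' exactly the identity), and the mean two-point coefficient of variation.
#'
#' @param map1,map2 Volumes on the same grid (session 1 and 2).
#' @param mask Logical array of voxels to compare; voxels that are
#'   non-finite or zero-flagged in either map are excluded pairwise.
#' @return Object of class \code{reliability_result}: \code{pearson_r},
#'   \code{r2_identity}, \code{cv_percent}, \code{n}, \code{unit}.
#' @export
voxelwise_reliability <- function(map1, map2, mask = NULL) {
  stop_if(!identical(dim(map1), dim(map2)), "maps must share a grid")
  if (is.null(mask)) mask <- array(TRUE, dim(map1))
  stop_if(!any(mask), "mask is empty")
  x <- map1[mask]; y <- map2[mask]
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(pearson_r = NA_real_, r2_identity = NA_real_,
                          cv_percent = if (n > 0) mean(two_point_cv(x, y)) else NA_real_,
                          n = n, unit = "voxel-set", missing = TRUE),
                     class = "reliability_result"))
  }
  structure(list(
    pearson_r = stats::cor(x, y),
    r2_identity = 1 - sum((y - x)^2) / sum((y - mean(y))^2),
    cv_percent = mean(two_point_cv(x, y)),
    n = n, unit = "voxel-set", missing = FALSE
  ), class = "reliability_result")
}

# two-measurement CV in percent, sample (n-1) convention: sd = |a-b|/sqrt(2)
two_point_cv <- function(a, b) {
  100 * (abs(a - b) / sqrt(2)) / ((a + b) / 2)
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("reliability (%s, n = %d): r = %.3f, R2[y=x] = %.3f, CV = %.3f%%\n",
              x$unit, x$n, x$pearson_r, x$r2_identity, x$cv_percent))
  invisible(x)
}

#' ROI-based scan-rescan reliability across subjects
#'
#' Computes the mean value of each ROI per subject and session, then
#' across-subject Pearson r and identity-line R2 between sessions, plus the
#' mean per-subject two-point CV. Subjects missing an ROI are dropped from
#' that ROI.
#'
#' @param t1_session1,t1_session2 Lists of volumes (one per subject).
#' @param label_maps List of integer label volumes (or one shared volume).
#' @param roi_ids Integer ROI labels to analyze.
#' @return data.frame with one row per ROI: \code{roi}, \code{pearson_r},
#'   \code{r2_identity}, \code{cv_percent}, \code{n_subjects}.
#' @export
roi_reliability <- function(t1_session1, t1_session2, label_maps, roi_ids) {
  n_sub <- length(t1_session1)
  stop_if(length(t1_session2) != n_sub, "session lists differ in length")
  if (!is.list(label_maps)) label_maps <- rep(list(label_maps), n_sub)
  out <- lapply(roi_ids, function(roi) {
    m1 <- m2 <- rep(NA_real_, n_sub)
    for (s in seq_len(n_sub)) {
      sel <- label_maps[[s]] == roi
      v1 <- t1_session1[[s]][sel]; v2 <- t1_session2[[s]][sel]
      v1 <- v1[is.finite(v1) & v1 > 0]; v2 <- v2[is.finite(v2) & v2 > 0]
      if (length(v1) && length(v2)) { m1[s] <- mean(v1); m2[s] <- mean(v2) }
    }
    ok <- is.finite(m1) & is.finite(m2)
    if (sum(ok) < n_sub)
      message(sprintf("ROI %d: dropped %d subject(s) with missing ROI", roi, n_sub - sum(ok)))
    r <- r2 <- NA_real_
    if (sum(ok) >= 3 && stats::sd(m1[ok]) > 0 && stats::sd(m2[ok]) > 0) {
      r <- stats::cor(m1[ok], m2[ok])
      r2 <- 1 - sum((m2[ok] - m1[ok])^2) / sum((m2[ok] - mean(m2[ok]))^2)
    }
    data.frame(roi = roi, pearson_r = r, r2_identity = r2,
               cv_percent = mean(two_point_cv(m1[ok], m2[ok])),
               n_subjects = sum(ok))
  })
  do.call(rbind, out)
}

#' Bland-Altman summary of paired measurements
#'
#' @param pairs Two-column matrix (or data.frame) of paired measurements.
#' @return List: \code{mean_difference}, \code{loa} (mean difference
#'   +/- 1.96 sd), \code{sd_difference}, and a \code{table} of means vs
#'   differences for plotting.
#' @export
bland_altman <- function(pairs) {
  pairs <- as.matrix(pairs)
  stop_if(ncol(pairs) != 2 || nrow(pairs) < 2, "need >= 2 pairs of measurements")
  d <- pairs[, 2] - pairs[, 1]
  m <- rowMeans(pairs)
  sdd <- stats::sd(d)
  list(mean_difference = mean(d),
       sd_difference = sdd,
       loa = mean(d) + c(-1.96, 1.96) * sdd,
       table = data.frame(mean = m, difference = d))
}

#' Plot a Bland-Altman summary
#' @param ba Result of [bland_altman()].
#' @param ... Passed to \code{plot}.
#' @export
plot_bland_altman <- function(ba, ...) {
  plot(ba$table$mean, ba$table$difference,
       xlab = "mean of two scans", ylab = "difference (scan2 - scan1)", ...)
  graphics::abline(h = ba$mean_difference, lty = 1)
  graphics::abline(h = ba$loa, lty = 2)
  invisible(ba)
}

#' Mixed-effects comparison of reconstruction pipelines
#'
#' Fits \code{r ~ duration * b0 + age + (1 | participant)} by REML with
#' \pkg{lme4}: the per-subject reliability as a function of scan duration
#' (2 vs 4 min), B0 correction (off/on), their interaction, and age, with a
#' random intercept per participant.
#'
#' @param table data.frame with columns \code{participant}, \code{duration}
#'   (\code{"2min"}/\code{"4min"}), \code{b0} (\code{"off"}/\code{"on"}),
#'   \code{age}, \code{r}.
#' @return List: \code{fixed} (data.frame of estimates and t values),
#'   \code{random_intercept_var}, \code{residual_var}, \code{singular}
#'   (TRUE when the random-effect variance collapsed to zero), \code{model}.
#' @export
fit_reliability_lmm <- function(table) {
  need <- c("participant", "duration", "b0", "age", "r")
  stop_if(!all(need %in% names(table)), "table must have participant, duration, b0, age, r")
  tab <- table
  tab$duration <- factor(tab$duration, levels = c("2min", "4min"))
  tab$b0 <- factor(tab$b0, levels = c("off", "on"))
  counts <- base::table(tab$participant, tab$duration, tab$b0)
  stop_if(any(counts != 1), "design must be a complete factorial per participant")
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(r ~ duration * b0 + age + (1 | participant), data = tab, REML = TRUE)
  ))
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(
    fixed = data.frame(term = rownames(co), estimate = co[, "Estimate"],
                       std_error = co[, "Std. Error"], t_value = co[, "t value"],
                       row.names = NULL),
    random_intercept_var = vc$vcov[vc$grp == "participant"],
    residual_var = vc$vcov[vc$grp == "Residual"],
    singular = lme4::isSingular(fit),
    model = fit
  )
}
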