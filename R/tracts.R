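# Along-tract (tractometry) machinery: synthetic streamline bundles,
# iterative outlier cleaning, 100-node profile extraction with
# distance-weighted averaging, tract-level scan-rescan reliability and
# age-R1 correlations.

# resample a polyline to n equidistant arc-length nodes
resample_streamline <- function(pts, n_nodes) {
  pts <- as.matrix(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(pts[rep(1, n_nodes), , drop = FALSE])
  target <- seq(0, total, length.out = n_nodes)
  apply(pts, 2, function(col) stats::approx(s, col, xout = target)$y)
}

streamline_length <- function(pts) sum(sqrt(rowSums(diff(as.matrix(pts))^2)))

#' Generate a synthetic streamline bundle
#'
#' Streamlines are the core curve plus smooth low-order random perturbations
#' of point-wise standard deviation \code{spread_mm}; a fraction of them are
#' additionally displaced by at least 5 spreads or elongated, planting gross
#' outliers for the cleaning step.
#'
#' @param core_curve Matrix \code{[n x 3]} of mm coordinates (>= 20 points).
#' @param n_streamlines Number of streamlines.
#' @param spread_mm Perturbation scale (mm).
#' @param outlier_frac Fraction of planted gross outliers.
#' @param seed Integer seed.
#' @param name,orientation Tract name and orientation tag
#'   (\code{"anterior_posterior"} or \code{"left_right"}).
#' @return Object of class \code{tract_bundle}; planted outlier indices are
#'   kept in \code{planted_outliers}.
#' @export
generate_bundle <- function(core_curve, n_streamlines = 50, spread_mm = 2,
                            outlier_frac = 0, seed = 1, name = "tract",
                            orientation = "anterior_posterior") {
  core_curve <- as.matrix(core_curve)
  stop_if(nrow(core_curve) < 20, "core curve must have >= 20 points")
  n_pts <- nrow(core_curve)
  s <- seq(0, 1, length.out = n_pts)
  # smooth perturbation basis: constant, linear, low-frequency sines
  B <- cbind(1, s - 0.5, sin(pi * s), sin(2 * pi * s), sin(3 * pi * s))
  B <- sweep(B, 2, sqrt(colMeans(B^2)), `/`)   # unit RMS columns
  n_out <- round(outlier_frac * n_streamlines)
  out_idx <- if (n_out > 0) seq_len(n_out) + (n_streamlines - n_out) else integer(0)
  streamlines <- with_seed(derive_seed(seed, "bundle"), {
    sl <- vector("list", n_streamlines)
    for (i in seq_len(n_streamlines)) {
      pert <- B %*% matrix(stats::rnorm(ncol(B) * 3, 0, spread_mm / sqrt(ncol(B))),
                           ncol(B), 3)
      pts <- core_curve + pert
      if (i %in% out_idx) {
        if (i %% 2 == 0) {
          # gross displacement >= 5 spreads in a random direction
          dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
          pts <- pts + matrix(dir, n_pts, 3, byrow = TRUE) *
            (5 * max(spread_mm, 1) + stats::rexp(1, 1))
        } else {
          # elongation: extrapolate both ends by 40% of the length
          d1 <- pts[1, ] - pts[2, ]; d2 <- pts[n_pts, ] - pts[n_pts - 1, ]
          len <- streamline_length(pts)
          ext <- 0.2 * len
          head_pts <- sweep(outer(seq(ext, ext / 4, length.out = 4) / sqrt(sum(d1^2)), d1),
                            2, pts[1, ], `+`)
          tail_pts <- sweep(outer(seq(ext / 4, ext, length.out = 4) / sqrt(sum(d2^2)), d2),
                            2, pts[n_pts, ], `+`)
          pts <- rbind(head_pts, pts, tail_pts)
        }
      }
      sl[[i]] <- pts
    }
    sl
  })
  structure(list(streamlines = streamlines,
                 core_fiber = core_curve,
                 name = name, orientation = orientation,
                 planted_outliers = out_idx, seed = seed),
            class = "tract_bundle")
}

#' Clean a streamline bundle iteratively
#'
#' Repeats up to \code{iterations} times: recompute the bundle core
#' (node-wise mean of streamlines resampled to common nodes), z-score each
#' streamline's mean distance to the core and its length, and drop
#' streamlines beyond \code{core_sd} distance standard deviations or
#' \code{length_sd} length standard deviations; stops early when no
#' streamline is removed.
#'
#' @param bundle A \code{tract_bundle}.
#' @param core_sd Distance z-score threshold (default 3).
#' @param length_sd Length z-score threshold (default 4).
#' @param iterations Maximum cleaning rounds (default 5).
#' @param n_nodes Nodes used for the core computation.
#' @return Cleaned \code{tract_bundle}; \code{kept} holds the retained
#'   original indices.
#' @export
clean_bundle <- function(bundle, core_sd = 3, length_sd = 4, iterations = 5,
                         n_nodes = 100) {
  stop_if(!inherits(bundle, "tract_bundle"), "need a tract_bundle")
  keep <- seq_along(bundle$streamlines)
  if (iterations >= 1) {
    for (it in seq_len(iterations)) {
      sl <- bundle$streamlines[keep]
      rs <- lapply(sl, resample_streamline, n_nodes = n_nodes)
      arr <- array(unlist(rs), c(n_nodes, 3, length(rs)))
      core <- apply(arr, 1:2, mean)
      dist <- vapply(seq_along(rs), function(i)
        mean(sqrt(rowSums((arr[, , i] - core)^2))), 0)
      len <- vapply(sl, streamline_length, 0)
      zd <- if (stats::sd(dist) > 0) (dist - mean(dist)) / stats::sd(dist) else rep(0, length(dist))
      zl <- if (stats::sd(len) > 0) (len - mean(len)) / stats::sd(len) else rep(0, length(len))
      drop <- zd > core_sd | zl > length_sd
      if (!any(drop)) break
      keep <- keep[!drop]
      stop_if(length(keep) == 0, "cleaning removed every streamline (degenerate bundle)")
    }
  }
  out <- bundle
  out$streamlines <- bundle$streamlines[keep]
  out$kept <- keep
  rs <- lapply(out$streamlines, resample_streamline, n_nodes = n_nodes)
  out$core_fiber <- apply(array(unlist(rs), c(n_nodes, 3, length(rs))), 1:2, mean)
  out
}

#' Extract an along-tract profile
#'
#' Resamples every streamline to \code{n_nodes} equidistant arc-length nodes,
#' orients them consistently with the bundle's orientation tag, and computes
#' the node-wise weighted average of the scalar map interpolated at each
#' streamline's node position. Weights fall off as a Gaussian of the distance
#' from the node's cross-sectional centroid and sum to 1 at every node.
#'
#' @param bundle A \code{tract_bundle} (streamline coordinates in mm).
#' @param scalar_map Volume sampled by trilinear interpolation (voxel centers
#'   at \code{(i - 0.5) * voxel_mm}).
#' @param n_nodes Number of profile nodes (default 100).
#' @param voxel_mm Voxel size of \code{scalar_map}.
#' @return Object of class \code{tract_profile}: \code{node_values} (length
#'   \code{n_nodes}, NA where all streamline points leave the map),
#'   \code{node_weights} matrix, \code{analyzed_nodes} (the middle 80 nodes).
#' @export
tract_profile <- function(bundle, scalar_map, n_nodes = 100, voxel_mm = 1) {
  stop_if(!inherits(bundle, "tract_bundle"), "need a tract_bundle")
  ns <- length(bundle$streamlines)
  rs <- lapply(bundle$streamlines, resample_streamline, n_nodes = n_nodes)
  core <- resample_streamline(bundle$core_fiber, n_nodes)
  # orient the core along the tag (ascending y for AP, ascending x for LR)
  axis <- if (identical(bundle$orientation, "left_right")) 1 else 2
  if (core[1, axis] > core[n_nodes, axis]) core <- core[n_nodes:1, , drop = FALSE]
  # align each streamline with the core (flip if reversed order fits better)
  arr <- array(0, c(n_nodes, 3, ns))
  for (i in seq_len(ns)) {
    p <- rs[[i]]
    d_fwd <- sum((p - core)^2); d_rev <- sum((p[n_nodes:1, ] - core)^2)
    arr[, , i] <- if (d_rev < d_fwd) p[n_nodes:1, ] else p
  }
  centroid <- apply(arr, 1:2, mean)
  vals <- matrix(NA_real_, n_nodes, ns)
  for (i in seq_len(ns)) {
    v <- arr[, , i] / voxel_mm + 0.5          # mm -> voxel-center index
    vals[, i] <- interp3(scalar_map, v[, 1], v[, 2], v[, 3])
  }
  d2 <- sapply(seq_len(ns), function(i) rowSums((arr[, , i] - centroid)^2))
  d2 <- matrix(d2, n_nodes, ns)
  sigma2 <- pmax(rowMeans(d2), .Machine$double.eps)
  w <- exp(-d2 / (2 * sigma2))
  w[is.na(vals)] <- 0
  wsum <- rowSums(w)
  node_values <- ifelse(wsum > 0, rowSums(w * ifelse(is.na(vals), 0, vals)) / wsum, NA_real_)
  n_masked <- sum(is.na(vals))
  if (n_masked > 0)
    message(sprintf("tract_profile: %d streamline node(s) outside the map were masked", n_masked))
  structure(list(node_values = node_values,
                 node_weights = sweep(w, 1, pmax(wsum, .Machine$double.eps), `/`),
                 analyzed_nodes = 11:90,
                 n_nodes = n_nodes, name = bundle$name),
            class = "tract_profile")
}

#' Mean of a tract profile over the analyzed middle nodes
#' @param profile A \code{tract_profile}.
#' @return Scalar mean over nodes 11-90 (middle 80 of 100).
#' @export
profile_mean <- function(profile) {
  mean(profile$node_values[profile$analyzed_nodes], na.rm = TRUE)
}

#' @export
plot.tract_profile <- function(x, ...) {
  plot(seq_len(x$n_nodes), x$node_values, type = "l",
       xlab = "node (along tract)", ylab = "value", main = x$name, ...)
  graphics::abline(v = range(x$analyzed_nodes), lty = 3)
  invisible(x)
}

#' Tract-level scan-rescan reliability
#'
#' Across-subject Pearson correlation of tract means (middle 80 nodes)
#' between two sessions, per-node correlations, and a bootstrap 68%
#' percentile confidence interval over subjects for the tract-mean r.
#'
#' @param profiles_s1,profiles_s2 Matrices \code{[n_subjects x n_nodes]} of
#'   node values for the two sessions (matched subject order).
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return List: \code{tract_mean_r}, \code{tract_mean_ci} (68% percentile
#'   interval), \code{per_node_r} (NA outside the middle 80 nodes),
#'   \code{n_subjects}.
#' @export
profile_reliability <- function(profiles_s1, profiles_s2, n_boot = 500, seed = 1) {
  profiles_s1 <- as.matrix(profiles_s1); profiles_s2 <- as.matrix(profiles_s2)
  stop_if(!identical(dim(profiles_s1), dim(profiles_s2)),
          "sessions must have matched subjects and nodes")
  n_sub <- nrow(profiles_s1)
  stop_if(n_sub < 3, "need >= 3 subjects")
  n_nodes <- ncol(profiles_s1)
  mid <- 11:90
  mid <- mid[mid <= n_nodes]
  m1 <- rowMeans(profiles_s1[, mid, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(profiles_s2[, mid, drop = FALSE], na.rm = TRUE)
  r <- stats::cor(m1, m2)
  per_node <- rep(NA_real_, n_nodes)
  for (j in mid) {
    a <- profiles_s1[, j]; b <- profiles_s2[, j]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) >= 3 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0)
      per_node[j] <- stats::cor(a[ok], b[ok])
  }
  boots <- with_seed(derive_seed(seed, "boot"), {
    vapply(seq_len(n_boot), function(i) {
      ii <- sample.int(n_sub, n_sub, replace = TRUE)
      if (stats::sd(m1[ii]) == 0 || stats::sd(m2[ii]) == 0) return(NA_real_)
      stats::cor(m1[ii], m2[ii])
    }, 0)
  })
  list(tract_mean_r = r,
       tract_mean_ci = stats::quantile(boots, c(0.16, 0.84), na.rm = TRUE, names = FALSE),
       per_node_r = per_node, n_subjects = n_sub)
}

#' Age correlations of tract-mean R1 with FDR correction
#'
#' Pearson correlation between each tract's mean R1 and participant age,
#' with Benjamini-Hochberg correction across tracts.
#'
#' @param tract_r1_means Matrix \code{[n_subjects x n_tracts]} (columns may
#'   be named).
#' @param ages Numeric vector of ages (years).
#' @param fdr_q FDR level (default 0.05).
#' @return data.frame: \code{tract}, \code{r}, \code{p}, \code{p_fdr},
#'   \code{significant}.
#' @export
age_correlation <- function(tract_r1_means, ages, fdr_q = 0.05) {
  tract_r1_means <- as.matrix(tract_r1_means)
  stop_if(nrow(tract_r1_means) < 10, "need >= 10 subjects")
  stop_if(length(ages) != nrow(tract_r1_means), "ages must match rows")
  stop_if(stats::sd(ages) == 0, "ages are constant; correlation undefined")
  nt <- ncol(tract_r1_means)
  r <- p <- numeric(nt)
  for (j in seq_len(nt)) {
    ct <- stats::cor.test(tract_r1_means[, j], ages)
    r[j] <- unname(ct$estimate); p[j] <- ct$p.value
  }
  p_fdr <- stats::p.adjust(p, method = "BH")
  data.frame(tract = if (!is.null(colnames(tract_r1_means))) colnames(tract_r1_means)
                     else paste0("tract_", seq_len(nt)),
             r = r, p = p, p_fdr = p_fdr, significant = p_fdr < fdr_q)
}

#' Write / read streamlines as a JSON container
#'
#' Plain-text interchange format: per-streamline point arrays in mm with the
#' tract name and orientation tag.
#'
#' @param bundle A \code{tract_bundle}.
#' @param path File path.
#' @return \code{read_streamlines_json} returns a \code{tract_bundle}.
#' @export
write_streamlines_json <- function(bundle, path) {
  jsonlite::write_json(list(
    name = bundle$name, orientation = bundle$orientation, units = "mm",
    streamlines = lapply(bundle$streamlines, function(p) unname(as.matrix(p)))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_streamlines_json
#' @export
read_streamlines_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sl <- if (is.array(x$streamlines) && length(dim(x$streamlines)) == 3) {
    lapply(seq_len(dim(x$streamlines)[1]), function(i) x$streamlines[i, , ])
  } else {
    lapply(x$streamlines, function(m) matrix(unlist(m), ncol = 3))
  }
  n_nodes <- min(100, min(vapply(sl, nrow, 0L)))
  rs <- lapply(sl, resample_streamline, n_nodes = n_nodes)
  core <- apply(array(unlist(rs), c(n_nodes, 3, length(rs))), 1:2, mean)
  structure(list(streamlines = sl, core_fiber = core, name = x$name,
                 orientation = x$orientation, planted_outliers = integer(0)),
            class = "tract_bundle")
}

#' @export
print.tract_bundle <- function(x, ...) {
  cat(sprintf("tract bundle '%s': %d streamlines (%s)\n",
              x$name, length(x$streamlines), x$orientation))
  invisible(x)
}
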