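#' Fit a smoothing spline to a wave profile and locate peak and front
#'
#' Fits a cubic smoothing spline to signal versus position and extracts two
#' landmarks from the fitted curve on a dense grid: the *peak*, the argmax
#' restricted to positions beyond `exclusion_zone_bp` (smallest-coordinate
#' maximum on ties), and the *front*, the first position downstream of the
#' peak where the fitted curve falls below `front_frac` of the peak height.
#' In a DRB-release experiment the front is the advancing edge of labeled
#' signal and moves at the elongation speed; the exclusion zone keeps
#' residual promoter-proximal signal from dominating the argmax at
#' post-release timepoints (at t = 0 the pause peak is the wave origin, so
#' use `exclusion_zone_bp = 0` there).
#'
#' A flat or all-zero profile yields a flagged no-peak result rather than an
#' error.
#'
#' @param profile a `metagene_profile`, or a numeric signal vector (then
#'   supply `positions_bp`).
#' @param positions_bp bin-center positions (bp relative to TSS) when
#'   `profile` is a bare vector.
#' @param smoothing_df equivalent degrees of freedom of the spline; default
#'   one third of the number of bins (capped), enough to track the wave
#'   while averaging Poisson noise.
#' @param exclusion_zone_bp ignore fitted positions at or below this when
#'   locating the peak (default 500).
#' @param front_frac fraction of peak height defining the front (default
#'   0.1).
#' @param eval_step_bp dense evaluation grid step (default 10 bp).
#' @param timepoint_min optional timepoint label carried on the fit.
#' @return an object of class `wave_fit`: `smoothed` (fitted values at the
#'   input positions), `peak_pos_bp`, `peak_height`, `front_pos_bp` (`NA`
#'   if the curve never crosses the threshold inside the window),
#'   `ok` (FALSE for the no-peak case), plus the fit parameters.
#' @export
fit_wave <- function(profile, positions_bp = NULL, smoothing_df = NULL,
                     exclusion_zone_bp = 500, front_frac = 0.1,
                     eval_step_bp = 10, timepoint_min = NA_real_) {
  if (inherits(profile, "metagene_profile")) {
    positions_bp <- profile$bin_centers_bp
    if (is.na(timepoint_min)) timepoint_min <- profile$timepoint_min
    profile <- profile$mean_signal
  }
  y <- as.numeric(profile)
  x <- as.numeric(positions_bp)
  pw_check(length(y) == length(x) && length(y) >= 10,
           "polwave_param_error",
           "profile needs >= 10 bins with matching positions")
  pw_check(all(y >= 0), "polwave_param_error",
           "profile must be non-negative")
  if (is.null(smoothing_df))
    smoothing_df <- max(6, min(length(y) - 2, round(length(y) / 3)))

  no_peak <- structure(list(
    timepoint_min = timepoint_min, smoothed = rep(0, length(y)),
    peak_pos_bp = NA_real_, peak_height = NA_real_,
    front_pos_bp = NA_real_, smoothing_df = smoothing_df,
    exclusion_zone_bp = exclusion_zone_bp, front_frac = front_frac,
    ok = FALSE), class = "wave_fit")
  if (all(y == 0) || stats::var(y) == 0) return(no_peak)

  fit <- stats::smooth.spline(x, y, df = smoothing_df, cv = FALSE)
  grid <- seq(min(x), max(x), by = eval_step_bp)
  fy <- stats::predict(fit, grid)$y
  cand <- grid > exclusion_zone_bp
  if (!any(cand)) return(no_peak)
  i_peak <- which(cand)[which.max(fy[cand])]  # first max => smallest coord
  peak_h <- fy[i_peak]
  if (!is.finite(peak_h) || peak_h <= 0) return(no_peak)
  after <- seq(i_peak, length(grid))
  below <- after[fy[after] < front_frac * peak_h]
  front <- if (length(below) > 0) grid[below[1]] else NA_real_

  structure(list(
    timepoint_min = timepoint_min,
    smoothed = stats::predict(fit, x)$y,
    peak_pos_bp = grid[i_peak],
    peak_height = peak_h,
    front_pos_bp = front,
    smoothing_df = smoothing_df,
    exclusion_zone_bp = exclusion_zone_bp,
    front_frac = front_frac,
    ok = TRUE), class = "wave_fit")
}

#' @export
print.wave_fit <- function(x, ...) {
  if (!x$ok) cat("wave_fit: no peak (flat profile)\n")
  else cat(sprintf(
    "wave_fit: peak %+.0f bp (height %.3g), front %s bp [t=%s min]\n",
    x$peak_pos_bp, x$peak_height,
    if (is.na(x$front_pos_bp)) "NA" else sprintf("%+.0f", x$front_pos_bp),
    format(x$timepoint_min)))
  invisible(x)
}

wave_position <- function(fit, measure) {
  if (!fit$ok) return(NA_real_)
  if (measure == "peak") fit$peak_pos_bp else fit$front_pos_bp
}

#' Estimate elongation rate from wave fits over time
#'
#' Ordinary least squares of wave position (bp) on time after release
#' (min); the slope, in kb/min, is the elongation-rate estimate.  With
#' exactly two timepoints this reduces to the two-point slope.  The
#' regressed landmark is the wave front by default — in the labeling model
#' used here the front advances at the polymerase speed, whereas the argmax
#' of a from-release-labeled profile sits promoter-proximal — with
#' `measure = "peak"` available for hump-shaped profiles.
#'
#' @param fits list of `wave_fit`s (one per timepoint).
#' @param timepoints_min timepoints; default taken from the fits.
#' @param measure `"front"` (default) or `"peak"`.
#' @return an object of class `rate_estimate`: `rate_kb_per_min`,
#'   `intercept_bp`, `timepoints_used`, `measure`, `n_genes`.
#' @export
estimate_rate <- function(fits, timepoints_min = NULL,
                          measure = c("front", "peak")) {
  measure <- match.arg(measure)
  if (inherits(fits, "wave_fit")) fits <- list(fits)
  if (is.null(timepoints_min))
    timepoints_min <- vapply(fits, function(f) f$timepoint_min, numeric(1))
  pos <- vapply(fits, wave_position, numeric(1), measure = measure)
  ok <- is.finite(pos) & is.finite(timepoints_min)
  pw_check(sum(ok) >= 2 && length(unique(timepoints_min[ok])) >= 2,
           "polwave_estimation_error",
           "need >= 2 valid wave positions at distinct timepoints")
  fit <- stats::lm(pos[ok] ~ timepoints_min[ok])
  structure(list(
    rate_kb_per_min = unname(coef(fit)[2]) / 1000,
    intercept_bp = unname(coef(fit)[1]),
    timepoints_used = timepoints_min[ok],
    measure = measure,
    per_gene_rates = NULL, sd_across_genes = NULL,
    n_genes = NA_integer_), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("elongation rate: %.3f kb/min (wave %s, t = %s min)\n",
              x$rate_kb_per_min, x$measure,
              paste(x$timepoints_used, collapse = ", ")))
  if (!is.null(x$per_gene_rates))
    cat(sprintf("  per-gene: n = %d, sd = %.3f kb/min (%d excluded)\n",
                x$n_genes, x$sd_across_genes, x$n_excluded))
  invisible(x)
}

#' Per-gene elongation rates across a cohort
#'
#' Runs [fit_wave()] on every gene's row at every timepoint and regresses
#' each gene's own wave positions on time.  Genes with a no-peak or
#' no-front flag at any timepoint are excluded and counted.  The summary
#' rate is the mean of per-gene rates; `sd_across_genes` is their standard
#' deviation.
#'
#' @param matrices named list of `coverage_matrix` objects, one per
#'   timepoint (same gene set, same bins); names or `timepoints_min`
#'   give the times.
#' @param timepoints_min numeric timepoints; default parsed from the
#'   matrices.
#' @param measure `"front"` (default) or `"peak"`.
#' @param exclusion_zone_bp exclusion zone for t > 0 fits; t = 0 fits use 0
#'   (the pause peak is the wave origin there).
#' @param ... further arguments to [fit_wave()].
#' @return a `rate_estimate` with `per_gene_rates`, `sd_across_genes`,
#'   `n_genes`, `n_excluded`, `gene_ids`.
#' @export
per_gene_rates <- function(matrices, timepoints_min = NULL,
                           measure = c("front", "peak"),
                           exclusion_zone_bp = 500, ...) {
  measure <- match.arg(measure)
  if (is.null(timepoints_min))
    timepoints_min <- vapply(matrices, function(m) m$timepoint_min,
                             numeric(1))
  pw_check(length(matrices) >= 2, "polwave_estimation_error",
           "need matrices for >= 2 timepoints")
  ids <- matrices[[1]]$gene_ids
  for (m in matrices)
    pw_check(identical(m$gene_ids, ids), "polwave_param_error",
             "matrices must share an identical gene set")
  ctr <- bin_centers(matrices[[1]])
  n <- length(ids)
  pos <- matrix(NA_real_, nrow = n, ncol = length(matrices))
  for (k in seq_along(matrices)) {
    ez <- if (timepoints_min[k] == 0) 0 else exclusion_zone_bp
    for (g in seq_len(n)) {
      f <- fit_wave(matrices[[k]]$values[g, ], ctr,
                    exclusion_zone_bp = ez,
                    timepoint_min = timepoints_min[k], ...)
      pos[g, k] <- wave_position(f, measure)
    }
  }
  valid <- apply(is.finite(pos), 1, all)
  pw_check(any(valid), "polwave_estimation_error",
           "no gene yielded valid wave positions at every timepoint")
  tp <- timepoints_min
  rates <- apply(pos[valid, , drop = FALSE], 1, function(p)
    unname(coef(stats::lm(p ~ tp))[2]) / 1000)
  structure(list(
    rate_kb_per_min = mean(rates),
    intercept_bp = NA_real_,
    timepoints_used = tp,
    measure = measure,
    per_gene_rates = rates,
    sd_across_genes = if (length(rates) > 1) sd(rates) else 0,
    n_genes = sum(valid),
    n_excluded = sum(!valid),
    gene_ids = ids[valid]), class = "rate_estimate")
}
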