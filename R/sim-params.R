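#' Parameters of the Pol II release-elongation-termination simulator
#'
#' Formalizes a DRB-release experiment: polymerases arrested at a
#' promoter-proximal pause site are released at \eqn{t = 0}, elongate at a
#' constant speed \eqn{v} (kb/min), and terminate prematurely with a constant
#' hazard per kilobase travelled, so survival to distance \eqn{d} is
#' \eqn{e^{-\lambda d}}.  Release is instantaneous
#' (`release_rate_per_min = Inf` or `"instantaneous"`) or a Poisson process
#' with the given per-minute rate acting on the paused pool.
#'
#' @param speed_kb_per_min elongation speed \eqn{v} in kb/min (> 0).
#' @param termination_hazard_per_kb premature-termination hazard
#'   \eqn{\lambda} in 1/kb (>= 0).
#' @param release_rate_per_min fraction of the paused pool released per
#'   minute; `Inf` or the string `"instantaneous"` releases everything at
#'   \eqn{t = 0}.
#' @param pause_site_offset_bp position of the arrested polymerase,
#'   bp downstream of the TSS (default 50, a typical promoter-proximal
#'   pause position).
#' @param timepoints_min sample collection times after release, minutes,
#'   sorted ascending.
#' @param label_windows list of `c(start_min, end_min)` metabolic-labeling
#'   intervals, one per timepoint.  Default: label from release to
#'   collection, `c(0, t)` for each timepoint.
#' @param read_depth_per_kb expected sequenced reads per kb of track at unit
#'   signal (a bin synthesized through by the whole reference pool of
#'   polymerases).
#' @param speed_jitter_cv coefficient of variation of per-polymerase speed
#'   (Gaussian, truncated at 5\% of the mean); default 0, i.e. deterministic
#'   speed.
#' @param keep_terminated_rna if `TRUE` (default), labeled RNA released by a
#'   prematurely terminating polymerase still contributes to the nascent
#'   track (the transcript persists on the experiment's timescale); if
#'   `FALSE` it is dropped, modeling fast degradation.
#' @param pause_footprint_bp length of promoter-proximal nascent RNA
#'   attributed to a still-paused polymerase when the labeling window is
#'   empty (the t = 0 sample); default 50 bp.
#' @param seed integer seed for all stochastic draws.
#' @return an object of class `sim_params`.
#' @examples
#' p <- sim_params(speed_kb_per_min = 2, termination_hazard_per_kb = 0.02,
#'                 timepoints_min = c(0, 10))
#' @export
sim_params <- function(speed_kb_per_min = 2.0,
                       termination_hazard_per_kb = 0.01,
                       release_rate_per_min = Inf,
                       pause_site_offset_bp = 50L,
                       timepoints_min = c(0, 5, 10),
                       label_windows = NULL,
                       read_depth_per_kb = 50,
                       speed_jitter_cv = 0,
                       keep_terminated_rna = TRUE,
                       pause_footprint_bp = 50L,
                       seed = 1L) {
  if (identical(release_rate_per_min, "instantaneous"))
    release_rate_per_min <- Inf
  pw_check(is.numeric(speed_kb_per_min) && is.finite(speed_kb_per_min) &&
             speed_kb_per_min >= 0,
           "polwave_param_error", "speed_kb_per_min must be finite and >= 0")
  pw_check(is.numeric(termination_hazard_per_kb) &&
             is.finite(termination_hazard_per_kb) &&
             termination_hazard_per_kb >= 0,
           "polwave_param_error",
           "termination_hazard_per_kb must be finite and >= 0")
  pw_check(is.numeric(release_rate_per_min) && release_rate_per_min > 0,
           "polwave_param_error", "release_rate_per_min must be > 0")
  pw_check(pause_site_offset_bp >= 0, "polwave_param_error",
           "pause_site_offset_bp must be >= 0")
  pw_check(!is.unsorted(timepoints_min) && all(timepoints_min >= 0),
           "polwave_param_error",
           "timepoints_min must be non-negative and sorted ascending")
  if (is.null(label_windows))
    label_windows <- lapply(timepoints_min, function(t) c(0, t))
  pw_check(length(label_windows) == length(timepoints_min),
           "polwave_param_error",
           "need one label window per timepoint")
  for (i in seq_along(label_windows)) {
    w <- label_windows[[i]]
    pw_check(length(w) == 2 && w[1] <= w[2], "polwave_param_error",
             "label window %d must be c(start, end) with start <= end", i)
    pw_check(w[2] <= timepoints_min[i], "polwave_param_error",
             "label window %d ends after its collection timepoint", i)
  }
  pw_check(read_depth_per_kb >= 0, "polwave_param_error",
           "read_depth_per_kb must be >= 0")
  structure(list(
    speed_kb_per_min = speed_kb_per_min,
    termination_hazard_per_kb = termination_hazard_per_kb,
    release_rate_per_min = release_rate_per_min,
    pause_site_offset_bp = as.integer(pause_site_offset_bp),
    timepoints_min = as.numeric(timepoints_min),
    label_windows = label_windows,
    read_depth_per_kb = read_depth_per_kb,
    speed_jitter_cv = speed_jitter_cv,
    keep_terminated_rna = isTRUE(keep_terminated_rna),
    pause_footprint_bp = as.integer(pause_footprint_bp),
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Pol II release simulator parameters\n")
  cat(sprintf("  speed          : %.3g kb/min\n", x$speed_kb_per_min))
  cat(sprintf("  term. hazard   : %.3g /kb\n", x$termination_hazard_per_kb))
  cat(sprintf("  release rate   : %s /min\n",
              if (is.infinite(x$release_rate_per_min)) "instantaneous"
              else format(x$release_rate_per_min)))
  cat(sprintf("  pause offset   : %d bp\n", x$pause_site_offset_bp))
  cat(sprintf("  timepoints     : %s min\n",
              paste(x$timepoints_min, collapse = ", ")))
  cat(sprintf("  read depth     : %g reads/kb\n", x$read_depth_per_kb))
  invisible(x)
}
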