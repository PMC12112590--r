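#' Pol II occupancy time course over pause and gene-body windows
#'
#' For each timepoint's normalized Pol II matrix, averages the per-gene
#' summed signal over a promoter-proximal pause window and a gene-body
#' window (both relative to TSS).  Loss of gene-body occupancy between
#' successive timepoints, while the pause pool has already been released,
#' is the signature of premature termination, i.e. reduced processivity.
#'
#' @param matrices named list of depth-normalized `coverage_matrix`
#'   objects, one per timepoint, same gene set.
#' @param pause_window_bp `c(from, to)` bp relative to TSS (default
#'   -200..500).
#' @param body_window_bp `c(from, to)` bp relative to TSS (default
#'   2000..15000).
#' @param condition label carried on the result.
#' @return an object of class `release_timecourse`: `timepoints_min`,
#'   `gene_body_totals`, `pause_totals`, `n_genes`, windows, `condition`.
#' @export
occupancy_timecourse <- function(matrices,
                                 pause_window_bp = c(-200, 500),
                                 body_window_bp = c(2000, 15000),
                                 condition = matrices[[1]]$condition) {
  pw_check(length(matrices) >= 1, "polwave_param_error",
           "need at least one matrix")
  ids <- matrices[[1]]$gene_ids
  tps <- numeric(0); body <- numeric(0); pause <- numeric(0)
  for (m in matrices) {
    stopifnot(inherits(m, "coverage_matrix"))
    pw_check(m$normalized, "polwave_param_error",
             "occupancy_timecourse expects depth-normalized matrices")
    pw_check(identical(m$gene_ids, ids), "polwave_param_error",
             "matrices must share an identical gene set")
    ctr <- bin_centers(m)
    span <- range(m$bin_edges_bp)
    for (w in list(pause_window_bp, body_window_bp))
      pw_check(w[1] >= span[1] && w[2] <= span[2], "polwave_config_error",
               "window [%g, %g) outside matrix span [%g, %g]",
               w[1], w[2], span[1], span[2])
    sel_p <- ctr >= pause_window_bp[1] & ctr < pause_window_bp[2]
    sel_b <- ctr >= body_window_bp[1] & ctr < body_window_bp[2]
    tps <- c(tps, m$timepoint_min)
    pause <- c(pause, mean(rowSums(m$values[, sel_p, drop = FALSE])))
    body <- c(body, mean(rowSums(m$values[, sel_b, drop = FALSE])))
  }
  o <- order(tps)
  structure(list(condition = condition, timepoints_min = tps[o],
                 gene_body_totals = body[o], pause_totals = pause[o],
                 n_genes = length(ids),
                 pause_window_bp = pause_window_bp,
                 body_window_bp = body_window_bp),
            class = "release_timecourse")
}

#' @export
print.release_timecourse <- function(x, ...) {
  cat(sprintf("Pol II release timecourse (%s, %d genes)\n", x$condition,
              x$n_genes))
  print(data.frame(t_min = x$timepoints_min,
                   pause = signif(x$pause_totals, 4),
                   gene_body = signif(x$gene_body_totals, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Distal/proximal Pol II occupancy ratio (processivity index)
#'
#' The ratio of mean occupancy in a distal gene-body window to that in a
#' proximal window.  A processive polymerase population fills distal
#' positions as efficiently as proximal ones (index near 1 once the wave
#' has passed); premature termination depresses the index.  The index is a
#' scale-free operationalization of Pol II retention across coding regions
#' and is not a quantity the underlying experiments print.
#'
#' @param x a `coverage_matrix` (mean over genes is used), a
#'   `metagene_profile`, or a numeric occupancy vector (then give
#'   `positions_bp`).
#' @param proximal_window_bp,distal_window_bp `c(from, to)` bp relative to
#'   TSS; must be disjoint with proximal before distal.
#' @param positions_bp positions for a bare numeric `x`.
#' @return an object of class `occupancy_index`: `proximal_mean`,
#'   `distal_mean`, `index` (`NA` with `defined = FALSE` when the proximal
#'   mean is zero), windows and labels.
#' @export
processivity_index <- function(x, proximal_window_bp = c(0, 5000),
                               distal_window_bp = c(10000, 15000),
                               positions_bp = NULL) {
  pw_check(proximal_window_bp[1] < proximal_window_bp[2] &&
             distal_window_bp[1] < distal_window_bp[2] &&
             proximal_window_bp[2] <= distal_window_bp[1],
           "polwave_config_error",
           "windows must be disjoint and ordered proximal < distal")
  condition <- "na"; timepoint <- NA_real_
  if (inherits(x, "coverage_matrix")) {
    pw_check(x$normalized, "polwave_param_error",
             "processivity_index expects a depth-normalized matrix")
    condition <- x$condition; timepoint <- x$timepoint_min
    positions_bp <- bin_centers(x)
    x <- colMeans(x$values)
  } else if (inherits(x, "metagene_profile")) {
    condition <- x$condition; timepoint <- x$timepoint_min
    positions_bp <- x$bin_centers_bp
    x <- x$mean_signal
  }
  sel_p <- positions_bp >= proximal_window_bp[1] &
    positions_bp < proximal_window_bp[2]
  sel_d <- positions_bp >= distal_window_bp[1] &
    positions_bp < distal_window_bp[2]
  pw_check(any(sel_p) && any(sel_d), "polwave_config_error",
           "proximal/distal windows cover no bins")
  pm <- mean(x[sel_p]); dm <- mean(x[sel_d])
  defined <- pm > 0
  structure(list(condition = condition, timepoint_min = timepoint,
                 proximal_window_bp = proximal_window_bp,
                 distal_window_bp = distal_window_bp,
                 proximal_mean = pm, distal_mean = dm,
                 index = if (defined) dm / pm else NA_real_,
                 defined = defined),
            class = "occupancy_index")
}

#' @export
print.occupancy_index <- function(x, ...) {
  cat(sprintf(
    "processivity index (distal/proximal occupancy): %s  [%s, t=%s min]\n",
    if (x$defined) sprintf("%.4f", x$index) else "undefined (zero proximal)",
    x$condition, format(x$timepoint_min)))
  invisible(x)
}

#' Compare conditions: elongation rate versus processivity
#'
#' Joins the three observables that dissociate speed from processivity —
#' elongation-rate estimates, total labeled nascent signal, and gene-body
#' Pol II occupancy over the release time course — into per-timepoint
#' deltas and a three-way verdict.  By default the 20-min timepoint is
#' excluded from the headline verdict because polymerases completing a
#' full round of transcription confound it.
#'
#' @param tc_a,tc_b `release_timecourse`s for the two conditions (matched
#'   timepoints).
#' @param rates optional named list of `rate_estimate`s (same two
#'   condition names).
#' @param nascent_totals optional named numeric: total labeled nascent
#'   signal (raw library sizes) per condition.
#' @param headline_timepoint_min timepoint for the occupancy verdict
#'   (default 10).
#' @param exclude_timepoints_min timepoints excluded from the verdict but
#'   still reported (default 20).
#' @return an object of class `condition_comparison` with `deltas`
#'   (data.frame of b - a per timepoint) and `verdict` (named orderings).
#' @export
compare_conditions <- function(tc_a, tc_b, rates = NULL,
                               nascent_totals = NULL,
                               headline_timepoint_min = 10,
                               exclude_timepoints_min = 20) {
  stopifnot(inherits(tc_a, "release_timecourse"),
            inherits(tc_b, "release_timecourse"))
  pw_check(identical(tc_a$timepoints_min, tc_b$timepoints_min),
           "polwave_param_error", "timecourses have mismatched timepoints")
  la <- tc_a$condition; lb <- tc_b$condition
  deltas <- data.frame(
    timepoint_min = tc_a$timepoints_min,
    d_body = tc_b$gene_body_totals - tc_a$gene_body_totals,
    d_pause = tc_b$pause_totals - tc_a$pause_totals,
    excluded = tc_a$timepoints_min %in% exclude_timepoints_min
  )
  ord <- function(b, a) if (b > a) sprintf("%s>%s", lb, la) else
    if (b < a) sprintf("%s<%s", lb, la) else sprintf("%s=%s", lb, la)
  verdict <- list()
  if (!is.null(rates))
    verdict$rate <- ord(rates[[lb]]$rate_kb_per_min,
                        rates[[la]]$rate_kb_per_min)
  if (!is.null(nascent_totals))
    verdict$nascent_total <- ord(nascent_totals[[lb]], nascent_totals[[la]])
  ih <- match(headline_timepoint_min, tc_a$timepoints_min)
  if (!is.na(ih))
    verdict$body_occupancy <- ord(tc_b$gene_body_totals[ih],
                                  tc_a$gene_body_totals[ih])
  structure(list(condition_a = la, condition_b = lb, deltas = deltas,
                 verdict = verdict,
                 headline_timepoint_min = headline_timepoint_min),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("condition comparison: %s vs %s\n", x$condition_b,
              x$condition_a))
  for (nm in names(x$verdict))
    cat(sprintf("  %-15s %s\n", nm, x$verdict[[nm]]))
  print(x$deltas, row.names = FALSE)
  invisible(x)
}
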