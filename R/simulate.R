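#' Simulate polymerase trajectories for one gene
#'
#' Draws, for each of `n_pol` promoter-proximally paused polymerases, a
#' release time (0 if release is instantaneous, else exponential with the
#' release rate), an optional per-polymerase speed, and a premature
#' termination distance from the pause site (exponential with the
#' per-kilobase hazard, so survival past distance \eqn{d} is
#' \eqn{e^{-\lambda d}}).  A polymerase that reaches the gene end before
#' terminating runs off and completes its transcript.
#'
#' All positions are expressed in bp downstream of the TSS, strand-agnostic;
#' mapping onto genome coordinates happens at track-rendering time.
#'
#' @param params a [sim_params()] object.
#' @param gene_length_bp gene length in bp (TSS to cleavage site).
#' @param n_pol number of polymerases in the paused pool (> 0).
#' @param seed optional seed overriding `params$seed`.
#' @return a `data.frame` of class `pol_trajectories` with columns
#'   `release_min`, `speed_bp_min`, `term_dist_bp` (raw termination distance
#'   from the pause site; may exceed the gene), `end_pos_bp` (position where
#'   the polymerase stops: termination point or gene end) and `terminated`
#'   (`TRUE` if it terminated before the gene end).  The gene length and
#'   pause offset travel along as attributes.
#' @export
simulate_polymerases <- function(params, gene_length_bp, n_pol,
                                 seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  pw_check(is.finite(gene_length_bp) && gene_length_bp > 0,
           "polwave_param_error", "gene_length_bp must be finite and > 0")
  pw_check(n_pol > 0, "polwave_param_error", "n_pol must be > 0")
  n_pol <- as.integer(n_pol)
  v_bp <- params$speed_kb_per_min * 1000
  hz_bp <- params$termination_hazard_per_kb / 1000
  pause <- params$pause_site_offset_bp
  run_len <- max(gene_length_bp - pause, 0)  # distance pause -> gene end

  with_seed(seed, {
    release <- if (is.infinite(params$release_rate_per_min)) {
      numeric(n_pol)
    } else {
      rexp(n_pol, rate = params$release_rate_per_min)
    }
    speed <- rep(v_bp, n_pol)
    if (params$speed_jitter_cv > 0 && v_bp > 0) {
      speed <- rnorm(n_pol, mean = v_bp, sd = params$speed_jitter_cv * v_bp)
      speed <- pmax(speed, 0.05 * v_bp)
    }
    term_dist <- if (hz_bp > 0) rexp(n_pol, rate = hz_bp) else rep(Inf, n_pol)
    traj <- data.frame(
      release_min = release,
      speed_bp_min = speed,
      term_dist_bp = term_dist,
      end_pos_bp = pause + pmin(term_dist, run_len),
      terminated = term_dist < run_len
    )
    attr(traj, "gene_length_bp") <- gene_length_bp
    attr(traj, "pause_site_offset_bp") <- pause
    class(traj) <- c("pol_trajectories", "data.frame")
    traj
  })
}

# Position of each polymerase at time t (bp from TSS); NA once it has
# stopped (terminated or run off).  Paused, not-yet-released polymerases sit
# at the pause site.
pol_positions <- function(traj, t_min) {
  pause <- attr(traj, "pause_site_offset_bp")
  pos <- pause + traj$speed_bp_min * pmax(t_min - traj$release_min, 0)
  engaged <- pos < traj$end_pos_bp |
    (t_min <= traj$release_min)  # still paused counts as engaged
  pos <- pmin(pos, traj$end_pos_bp)
  pos[!engaged] <- NA_real_
  pos
}

# Spatial segment [s0, s1) of template synthesized by each polymerase while
# the label was on, i.e. during [w0, w1] intersected with its active life.
labeled_segments <- function(traj, w0, w1) {
  pause <- attr(traj, "pause_site_offset_bp")
  t_stop <- traj$release_min +
    (traj$end_pos_bp - pause) / pmax(traj$speed_bp_min, .Machine$double.eps)
  a <- pmax(w0, traj$release_min)
  b <- pmin(w1, t_stop)
  s0 <- pause + traj$speed_bp_min * pmax(a - traj$release_min, 0)
  s1 <- pause + traj$speed_bp_min * pmax(b - traj$release_min, 0)
  bad <- b <= a
  s0[bad] <- 0; s1[bad] <- 0
  list(s0 = s0, s1 = s1)
}

#' Render a binned nascent-RNA (TT-seq-like) track for one gene
#'
#' Expected signal in a bin is the total length of template synthesized
#' within that bin during the labeling window, across polymerases, scaled to
#' reads: a bin fully synthesized through by `pol_per_unit` polymerases has
#' expected count `read_depth_per_kb * bin_bp / 1000`.  Counts are then
#' Poisson.  RNA 5' of a termination point still counts (the released
#' labeled transcript persists) unless `params$keep_terminated_rna` is
#' `FALSE`.  For an empty labeling window (the t = 0 arrest sample), each
#' still-paused polymerase contributes its promoter-proximal footprint
#' `[0, pause + pause_footprint_bp)`.
#'
#' @param traj trajectories from [simulate_polymerases()].
#' @param params the [sim_params()] used to generate them.
#' @param timepoint collection time, one of `params$timepoints_min`.
#' @param bin_bp bin width in bp (> 0).
#' @param seed seed for the Poisson draw.
#' @param pol_per_unit reference pool size defining unit signal (default:
#'   the number of trajectories, i.e. this gene's own pool).
#' @return a list of class `binned_track`: `counts`, `expected`, `edges`
#'   (bp from TSS), `bin_bp`, `assay`, `timepoint`.
#' @export
render_nascent_track <- function(traj, params, timepoint, bin_bp = 200L,
                                 seed = params$seed,
                                 pol_per_unit = nrow(traj)) {
  stopifnot(inherits(traj, "pol_trajectories"))
  pw_check(bin_bp > 0, "polwave_param_error", "bin_bp must be > 0")
  ti <- match(timepoint, params$timepoints_min)
  pw_check(!is.na(ti), "polwave_param_error",
           "timepoint %s is not in params$timepoints_min", timepoint)
  glen <- attr(traj, "gene_length_bp")
  pause <- attr(traj, "pause_site_offset_bp")
  edges <- seq(0, ceiling(glen / bin_bp) * bin_bp, by = bin_bp)
  w <- params$label_windows[[ti]]

  if (w[2] > w[1]) {
    seg <- labeled_segments(traj, w[1], w[2])
    if (!params$keep_terminated_rna) {
      # drop labeled RNA of polymerases already terminated at collection
      t_stop <- traj$release_min + (traj$end_pos_bp - pause) /
        pmax(traj$speed_bp_min, .Machine$double.eps)
      dead <- traj$terminated & t_stop <= timepoint
      seg$s0[dead] <- 0; seg$s1[dead] <- 0
    }
  } else {
    # empty label window: residual promoter-proximal signal of paused Pol II
    paused <- traj$release_min >= timepoint
    n <- sum(paused)
    seg <- list(s0 = numeric(n),
                s1 = rep(pause + params$pause_footprint_bp, n))
  }
  labeled_bp <- binned_segment_coverage(seg$s0, seg$s1, edges)
  expected <- params$read_depth_per_kb * (bin_bp / 1000) *
    labeled_bp / (pol_per_unit * bin_bp)
  counts <- with_seed(seed, rpois(length(expected), expected))
  structure(list(counts = counts, expected = expected, edges = edges,
                 bin_bp = as.integer(bin_bp), assay = "nascent",
                 timepoint = timepoint),
            class = "binned_track")
}

#' Render a binned Pol II occupancy (ChIP-seq-like) track for one gene
#'
#' Occupancy in a bin is the number of template-engaged polymerases
#' (paused, or released and neither terminated nor run off) located in the
#' bin at the collection time, scaled to reads as in
#' [render_nascent_track()] and Poisson-sampled.
#'
#' @inheritParams render_nascent_track
#' @return a `binned_track` with `assay = "polii"`.
#' @export
render_polii_track <- function(traj, params, timepoint, bin_bp = 200L,
                               seed = params$seed,
                               pol_per_unit = nrow(traj)) {
  stopifnot(inherits(traj, "pol_trajectories"))
  pw_check(bin_bp > 0, "polwave_param_error", "bin_bp must be > 0")
  glen <- attr(traj, "gene_length_bp")
  edges <- seq(0, ceiling(glen / bin_bp) * bin_bp, by = bin_bp)
  pos <- pol_positions(traj, timepoint)
  n_in_bin <- binned_point_counts(pos[!is.na(pos)], edges)
  expected <- params$read_depth_per_kb * (bin_bp / 1000) *
    n_in_bin / pol_per_unit
  counts <- with_seed(seed, rpois(length(expected), expected))
  structure(list(counts = counts, expected = expected, edges = edges,
                 bin_bp = as.integer(bin_bp), assay = "polii",
                 timepoint = timepoint),
            class = "binned_track")
}
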