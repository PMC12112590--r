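# Default run configuration; validate_config() overlays the user file on
# this and reports every violation at once.
default_config <- function() {
  list(
    seed = 1L,
    outdir = "polwave_out",
    simulate = NULL,   # built-in simulation block (see below), or NULL
    inputs = NULL,     # annotation/chrom_sizes/tracks block, or NULL
    filter = list(min_len_bp = 30000, max_len_bp = 300000,
                  chrom_whitelist = NULL),
    windows = list(upstream_bp = 2000, downstream_bp_nascent = 30000,
                   downstream_bp_polii = 15000, bin_bp = 200),
    wave = list(timepoints_min = c(0, 10), exclusion_zone_bp = 500,
                front_frac = 0.1, measure = "front", per_gene = TRUE),
    processivity = list(pause_window_bp = c(-200, 500),
                        body_window_bp = c(2000, 15000),
                        proximal_window_bp = c(0, 5000),
                        distal_window_bp = c(10000, 15000),
                        headline_timepoint_min = 10,
                        exclude_timepoints_min = 20),
    write_tracks = FALSE,
    plots = TRUE
  )
}

default_sim_block <- function() {
  list(n_genes = 50, length_range_kb = c(30, 300), n_pol_mean = 200,
       abundance_sdlog = 0.5, timepoints_min = c(0, 5, 10),
       read_depth_per_kb = 50, conditions = c("wt", "ko"),
       wt = list(speed_kb_per_min = 2.0, termination_hazard_per_kb = 0.01,
                 release_rate_per_min = 0.5),
       ko = list(speed_kb_per_min = 2.6, termination_hazard_per_kb = 0.05,
                 release_rate_per_min = 0.5))
}

#' Validate and resolve a run configuration
#'
#' Reads a YAML or JSON configuration file (or takes a list), overlays it
#' on the package defaults, and checks it.  All violations are collected
#' and reported together, not fail-fast; unknown keys are an error listing
#' them.  Exactly one of a `simulate` block (built-in simulation) or an
#' `inputs` block (annotation + chrom.sizes + signal tracks) must be
#' present; referenced paths must exist at validation time.
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return a resolved configuration of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    pw_check(file.exists(config), "polwave_config_error",
             "config file not found: %s", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  pw_check(length(unknown) == 0, "polwave_config_error",
           "unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  if (!is.null(cfg$simulate) && !isFALSE(cfg$simulate))
    cfg$simulate <- modifyList(default_sim_block(),
                               if (is.list(cfg$simulate)) cfg$simulate
                               else list())

  violations <- character(0)
  note <- function(msg) violations <<- c(violations, msg)

  has_sim <- is.list(cfg$simulate)
  has_inp <- is.list(cfg$inputs)
  if (has_sim == has_inp)
    note("exactly one of 'simulate' or 'inputs' must be provided")
  if (has_inp) {
    for (key in c("annotation", "chrom_sizes")) {
      if (is.null(cfg$inputs[[key]]))
        note(sprintf("inputs.%s is missing", key))
      else if (!file.exists(cfg$inputs[[key]]))
        note(sprintf("inputs.%s: file not found: %s", key,
                     cfg$inputs[[key]]))
    }
    if (is.null(cfg$inputs$tracks) || length(cfg$inputs$tracks) == 0) {
      note("inputs.tracks is missing or empty")
    } else {
      for (i in seq_along(cfg$inputs$tracks)) {
        tr <- cfg$inputs$tracks[[i]]
        for (key in c("condition", "assay", "timepoint_min"))
          if (is.null(tr[[key]]))
            note(sprintf("inputs.tracks[%d].%s is missing", i, key))
        paths <- unlist(tr[intersect(names(tr),
                                     c("path", "path_plus", "path_minus"))])
        if (length(paths) == 0)
          note(sprintf("inputs.tracks[%d] has no path", i))
        for (p in paths)
          if (!file.exists(p))
            note(sprintf("inputs.tracks[%d]: file not found: %s", i, p))
      }
    }
  }
  if (has_sim) {
    if (cfg$simulate$n_genes <= 0) note("simulate.n_genes must be > 0")
    if (!all(cfg$simulate$conditions %in% c("wt", "ko")) ||
        !"wt" %in% cfg$simulate$conditions)
      note("simulate.conditions must include 'wt' (optionally 'ko')")
    for (cond in intersect(names(cfg$simulate), c("wt", "ko"))) {
      sp <- cfg$simulate[[cond]]$speed_kb_per_min
      if (!is.null(sp) && (!is.finite(sp) || sp < 0))
        note(sprintf("simulate.%s.speed_kb_per_min must be >= 0", cond))
    }
  }
  if (!cfg$wave$measure %in% c("front", "peak"))
    note("wave.measure must be 'front' or 'peak'")
  if (length(cfg$wave$timepoints_min) < 2)
    note("wave.timepoints_min needs >= 2 timepoints")
  wl <- cfg$windows
  if ((wl$upstream_bp + wl$downstream_bp_nascent) %% wl$bin_bp != 0 ||
      (wl$upstream_bp + wl$downstream_bp_polii) %% wl$bin_bp != 0)
    note("window lengths must be divisible by windows.bin_bp")

  pw_check(length(violations) == 0, "polwave_config_error",
           "invalid configuration:\n  - %s",
           paste(violations, collapse = "\n  - "))
  structure(cfg, class = c("run_config", "list"))
}

#' @export
print.run_config <- function(x, ...) {
  cat("polwave run configuration\n")
  cat(sprintf("  seed: %d  outdir: %s  source: %s\n", x$seed, x$outdir,
              if (is.list(x$simulate)) "built-in simulation"
              else "user tracks"))
  invisible(x)
}
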