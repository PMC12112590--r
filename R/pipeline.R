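run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    pw_stop("polwave_stage_error", "stage '%s' failed: %s", stage,
            conditionMessage(e))
  })
}

# Resolve configuration into annotation + chrom sizes + signal accessors.
pipeline_inputs <- function(cfg) {
  if (is.list(cfg$simulate)) {
    sb <- cfg$simulate
    mk <- function(cond) {
      p <- sb[[cond]]
      if (is.null(p) || !cond %in% sb$conditions) return(NULL)
      sim_params(
        speed_kb_per_min = p$speed_kb_per_min,
        termination_hazard_per_kb = p$termination_hazard_per_kb,
        release_rate_per_min =
          if (is.null(p$release_rate_per_min)) Inf else
            p$release_rate_per_min,
        timepoints_min = sb$timepoints_min,
        read_depth_per_kb = sb$read_depth_per_kb,
        seed = cfg$seed)
    }
    cohort <- simulate_cohort(
      params_wt = mk("wt"), params_ko = mk("ko"),
      n_genes = sb$n_genes, length_range_kb = sb$length_range_kb,
      bin_bp = cfg$windows$bin_bp, n_pol_mean = sb$n_pol_mean,
      abundance_sdlog = sb$abundance_sdlog,
      seed = derive_seed(cfg$seed, "simulate"))
    tracks <- cohort_signals(cohort)
    list(annotation = cohort$annotation,
         chrom_sizes = cohort$chrom_sizes,
         tracks = tracks,
         timepoints_min = cohort$timepoints_min,
         conditions = names(cohort$tracks),
         cohort = cohort)
  } else {
    ann <- read_annotation(cfg$inputs$annotation)
    cs <- cfg$inputs$chrom_sizes
    tracks <- list(); tps <- numeric(0)
    for (tr in cfg$inputs$tracks) {
      tl <- fmt_num(tr$timepoint_min)
      sig <- if (!is.null(tr$path_plus)) {
        signal_pair(load_signal(tr$path_plus), load_signal(tr$path_minus))
      } else load_signal(tr$path)
      tracks[[tr$condition]][[tr$assay]][[tl]] <- sig
      tps <- union(tps, tr$timepoint_min)
    }
    list(annotation = ann, chrom_sizes = cs, tracks = tracks,
         timepoints_min = sort(tps), conditions = names(tracks),
         cohort = NULL)
  }
}

#' Signal accessors for an in-memory simulated cohort
#'
#' @param cohort a [simulate_cohort()] result.
#' @return nested list `tracks[[condition]][[assay]][[timepoint]]` of
#'   `signal_track` / `signal_pair` objects.
#' @export
cohort_signals <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  out <- list()
  for (cond in names(cohort$tracks)) {
    nas <- lapply(cohort$tracks[[cond]]$nascent, function(pair)
      signal_pair(signal_track_from_granges(pair$plus, source = "sim"),
                  signal_track_from_granges(pair$minus, source = "sim")))
    pol <- lapply(cohort$tracks[[cond]]$polii, function(gr)
      signal_track_from_granges(gr, source = "sim"))
    out[[cond]] <- list(nascent = nas, polii = pol)
  }
  out
}

#' Run the full DRB-release analysis pipeline
#'
#' Chains simulation (or track loading), transcript filtering, TSS-window
#' construction, matrix computation with per-million normalization,
#' metagene profiles, wave fitting and elongation-rate estimation, and the
#' Pol II occupancy/processivity report; writes TSV/JSON artifacts and a
#' run manifest to the output directory.  Deterministic given the seed in
#' the configuration.
#'
#' @param config a [validate_config()] result, or a path / list accepted by
#'   it.
#' @param outdir optional override of the configured output directory.
#' @return invisibly, a list with all intermediate and final objects
#'   (`filtered`, `windows`, `matrices`, `metagenes`, `rates`,
#'   `timecourses`, `indices`, `comparison`, `outdir`).
#' @export
run_all <- function(config, outdir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  inp <- run_stage("inputs", pipeline_inputs(cfg))
  if (!is.null(inp$cohort) && isTRUE(cfg$write_tracks))
    run_stage("inputs", write_cohort(inp$cohort, file.path(cfg$outdir,
                                                           "tracks")))

  filtered <- run_stage("filter", filter_transcripts(
    inp$annotation, min_len_bp = cfg$filter$min_len_bp,
    max_len_bp = cfg$filter$max_len_bp,
    chrom_whitelist = cfg$filter$chrom_whitelist))
  run_stage("filter", {
    surv <- filtered$transcripts
    rtracklayer::export(surv, file.path(cfg$outdir, "filtered.bed"),
                        format = "bed")
    write.table(data.frame(rule = names(filtered$rejected),
                           n_rejected = as.integer(filtered$rejected)),
                file.path(cfg$outdir, "rejections.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  win <- run_stage("windows", list(
    nascent = make_windows(filtered, cfg$windows$upstream_bp,
                           cfg$windows$downstream_bp_nascent,
                           cfg$windows$bin_bp, inp$chrom_sizes),
    polii = make_windows(filtered, cfg$windows$upstream_bp,
                         cfg$windows$downstream_bp_polii,
                         cfg$windows$bin_bp, inp$chrom_sizes)))

  matrices <- run_stage("matrix", {
    out <- list()
    for (cond in inp$conditions) {
      for (assay in names(inp$tracks[[cond]])) {
        for (tl in names(inp$tracks[[cond]][[assay]])) {
          cm <- gene_matrix(inp$tracks[[cond]][[assay]][[tl]],
                            win[[assay]], assay = assay, condition = cond,
                            timepoint_min = as.numeric(tl))
          out[[cond]][[assay]][[tl]] <-
            if (cm$library_size > 0) normalize_depth(cm) else cm
        }
      }
    }
    out
  })

  metagenes <- run_stage("metagene", {
    out <- list()
    for (cond in inp$conditions)
      for (assay in names(matrices[[cond]]))
        for (tl in names(matrices[[cond]][[assay]])) {
          mg <- metagene(matrices[[cond]][[assay]][[tl]])
          out[[cond]][[assay]][[tl]] <- mg
          write.table(
            data.frame(bin_center_bp = mg$bin_centers_bp,
                       mean_signal = mg$mean_signal),
            file.path(cfg$outdir, sprintf("metagene_%s_%s_t%s.tsv", cond,
                                          assay, tl)),
            sep = "\t", quote = FALSE, row.names = FALSE)
        }
    out
  })

  rates <- run_stage("wave", {
    out <- list()
    tps <- cfg$wave$timepoints_min
    for (cond in inp$conditions) {
      fits <- lapply(tps, function(t) {
        tl <- fmt_num(t)
        pw_check(tl %in% names(metagenes[[cond]]$nascent),
                 "polwave_config_error",
                 "no nascent track at wave timepoint %s for %s", tl, cond)
        fit_wave(metagenes[[cond]]$nascent[[tl]],
                 exclusion_zone_bp =
                   if (t == 0) 0 else cfg$wave$exclusion_zone_bp,
                 front_frac = cfg$wave$front_frac, timepoint_min = t)
      })
      est <- estimate_rate(fits, tps, measure = cfg$wave$measure)
      est$fits <- fits
      pg <- NULL
      if (isTRUE(cfg$wave$per_gene)) {
        mats <- lapply(fmt_num(tps), function(tl)
          matrices[[cond]]$nascent[[tl]])
        pg <- per_gene_rates(mats, tps, measure = cfg$wave$measure,
                             exclusion_zone_bp = cfg$wave$exclusion_zone_bp,
                             front_frac = cfg$wave$front_frac)
      }
      out[[cond]] <- list(metagene = est, per_gene = pg)
    }
    rows <- do.call(rbind, lapply(names(out), function(cond) {
      m <- out[[cond]]$metagene; p <- out[[cond]]$per_gene
      data.frame(condition = cond, measure = m$measure,
                 rate_kb_per_min = m$rate_kb_per_min,
                 intercept_bp = m$intercept_bp,
                 per_gene_mean_rate = if (is.null(p)) NA else
                   p$rate_kb_per_min,
                 per_gene_sd = if (is.null(p)) NA else p$sd_across_genes,
                 n_genes = if (is.null(p)) NA else p$n_genes,
                 n_excluded = if (is.null(p)) NA else p$n_excluded)
    }))
    write.table(rows, file.path(cfg$outdir, "rates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out
  })

  proc <- run_stage("processivity", {
    tcs <- list(); idx <- list()
    for (cond in inp$conditions) {
      pol <- matrices[[cond]]$polii
      if (is.null(pol)) next
      tcs[[cond]] <- occupancy_timecourse(
        pol, pause_window_bp = cfg$processivity$pause_window_bp,
        body_window_bp = cfg$processivity$body_window_bp,
        condition = cond)
      idx[[cond]] <- lapply(pol, processivity_index,
                            proximal_window_bp =
                              cfg$processivity$proximal_window_bp,
                            distal_window_bp =
                              cfg$processivity$distal_window_bp)
    }
    if (length(tcs) > 0) {
      tc_rows <- do.call(rbind, lapply(names(tcs), function(cond)
        data.frame(condition = cond,
                   timepoint_min = tcs[[cond]]$timepoints_min,
                   pause_total = tcs[[cond]]$pause_totals,
                   gene_body_total = tcs[[cond]]$gene_body_totals)))
      write.table(tc_rows, file.path(cfg$outdir, "timecourse.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ix_rows <- do.call(rbind, lapply(names(idx), function(cond)
        do.call(rbind, lapply(idx[[cond]], function(oi)
          data.frame(condition = cond, timepoint_min = oi$timepoint_min,
                     proximal_mean = oi$proximal_mean,
                     distal_mean = oi$distal_mean,
                     processivity_index = oi$index)))))
      write.table(ix_rows, file.path(cfg$outdir, "indices.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    comparison <- NULL
    if (length(tcs) == 2) {
      conds <- names(tcs)
      hl <- fmt_num(cfg$processivity$headline_timepoint_min)
      nt <- sapply(conds, function(cond) {
        sig <- inp$tracks[[cond]]$nascent[[hl]]
        if (is.null(sig)) NA_real_ else sig$total
      })
      comparison <- compare_conditions(
        tcs[[conds[1]]], tcs[[conds[2]]],
        rates = lapply(rates, `[[`, "metagene"),
        nascent_totals = as.list(nt),
        headline_timepoint_min = cfg$processivity$headline_timepoint_min,
        exclude_timepoints_min = cfg$processivity$exclude_timepoints_min)
      jsonlite::write_json(
        list(conditions = conds, verdict = comparison$verdict,
             deltas = comparison$deltas),
        file.path(cfg$outdir, "verdict.json"), auto_unbox = TRUE,
        digits = NA)
    }
    list(timecourses = tcs, indices = idx, comparison = comparison)
  })

  if (isTRUE(cfg$plots))
    run_stage("report", plot_metagenes(metagenes, cfg$outdir))

  run_stage("report", {
    checksums <- list()
    if (is.list(cfg$inputs)) {
      paths <- c(cfg$inputs$annotation,
                 unlist(lapply(cfg$inputs$tracks, function(tr)
                   unlist(tr[intersect(names(tr),
                                       c("path", "path_plus",
                                         "path_minus"))]))))
      checksums <- as.list(tools::md5sum(paths))
    }
    manifest <- list(
      package = "polwave",
      version = as.character(utils::packageVersion("polwave")),
      r_version = as.character(getRversion()),
      seed = cfg$seed,
      config = unclass(cfg),
      input_checksums = checksums,
      n_transcripts_in = filtered$n_input,
      n_transcripts_kept = length(filtered$transcripts),
      rejections = as.list(filtered$rejected))
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })

  invisible(list(config = cfg, inputs = inp, filtered = filtered,
                 windows = win, matrices = matrices, metagenes = metagenes,
                 rates = rates, timecourses = proc$timecourses,
                 indices = proc$indices, comparison = proc$comparison,
                 outdir = cfg$outdir))
}

# One pdf per assay: metagene curves, conditions x timepoints overlaid.
plot_metagenes <- function(metagenes, outdir) {
  for (assay in c("nascent", "polii")) {
    curves <- list()
    for (cond in names(metagenes))
      for (tl in names(metagenes[[cond]][[assay]]))
        curves[[paste(cond, tl, sep = " t=")]] <-
          metagenes[[cond]][[assay]][[tl]]
    if (length(curves) == 0) next
    grDevices::pdf(file.path(outdir, sprintf("metagene_%s.pdf", assay)),
                   width = 7, height = 5)
    ylim <- c(0, max(vapply(curves, function(m) max(m$mean_signal),
                            numeric(1))))
    graphics::plot(NA, xlim = range(curves[[1]]$bin_centers_bp),
                   ylim = ylim, xlab = "position relative to TSS (bp)",
                   ylab = "mean signal (per million)",
                   main = sprintf("%s metagene", assay))
    cols <- grDevices::hcl.colors(length(curves), "Dark 3")
    for (i in seq_along(curves))
      graphics::lines(curves[[i]]$bin_centers_bp, curves[[i]]$mean_signal,
                      col = cols[i], lwd = 2)
    graphics::legend("topright", legend = names(curves), col = cols,
                     lwd = 2, cex = 0.7, bty = "n")
    grDevices::dev.off()
  }
  invisible(NULL)
}
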