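#' Simulate a two-condition cohort of genes with tracks and ground truth
#'
#' Lays out `n_genes` non-overlapping single-exon transcription units
#' (lengths uniform in `length_range_kb`, random strand) on synthetic
#' chromosomes with generous flanks, simulates the paused-pool release
#' kinetics of [simulate_polymerases()] per gene under one or two parameter
#' sets, and renders genome-space nascent-RNA tracks (stranded pair) and
#' Pol II occupancy tracks (unstranded) at every timepoint, plus a
#' ground-truth table of per-gene speed, hazard and termination counts.
#'
#' Per-gene paused-pool sizes are Poisson around `n_pol_mean` times a
#' log-normal abundance factor (mean 1, `abundance_sdlog` on the log scale)
#' shared between conditions, emulating the wide spread of nascent-RNA
#' abundance across genes.
#'
#' @param params_wt [sim_params()] for the first condition (`"wt"`).
#' @param params_ko optional [sim_params()] for a second condition (`"ko"`).
#' @param n_genes number of genes (> 0).
#' @param length_range_kb gene-length range in kb; default 30-300.
#' @param bin_bp track resolution in bp.
#' @param n_pol_mean mean paused-pool size per gene; also the reference pool
#'   defining unit read depth.
#' @param abundance_sdlog log-sd of the per-gene abundance factor.
#' @param flank_bp flank kept free at chromosome ends and implicitly before
#'   the first gene (>= 2 kb so upstream analysis windows fit).
#' @param gap_bp intergenic gap (> 0).
#' @param genes_per_chrom genes packed per synthetic chromosome.
#' @param max_chrom_size_bp layout guard; exceeding it raises a layout
#'   error.
#' @param seed master seed; every stochastic sub-step derives its own
#'   stream from it, so outputs are bit-reproducible.
#' @return an object of class `sim_cohort` with elements `annotation`
#'   (GRanges with `transcript_id`), `chrom_sizes` (named integer),
#'   `tracks[[condition]][[assay]][[timepoint]]` (GRanges with `score`;
#'   nascent tracks are `list(plus, minus)`), `truth` (data.frame) and the
#'   generating parameters.
#' @export
simulate_cohort <- function(params_wt,
                            params_ko = NULL,
                            n_genes = 50L,
                            length_range_kb = c(30, 300),
                            bin_bp = 200L,
                            n_pol_mean = 200,
                            abundance_sdlog = 0.5,
                            flank_bp = 5000L,
                            gap_bp = 10000L,
                            genes_per_chrom = 10L,
                            max_chrom_size_bp = Inf,
                            seed = params_wt$seed) {
  stopifnot(inherits(params_wt, "sim_params"))
  pw_check(n_genes > 0, "polwave_param_error", "n_genes must be > 0")
  pw_check(gap_bp > 0 && flank_bp >= 0, "polwave_layout_error",
           "need gap_bp > 0 and flank_bp >= 0 to place non-overlapping genes")
  conditions <- list(wt = params_wt)
  if (!is.null(params_ko)) {
    stopifnot(inherits(params_ko, "sim_params"))
    conditions$ko <- params_ko
  }

  lo <- length_range_kb[1] * 1000; hi <- length_range_kb[2] * 1000
  layout <- with_seed(derive_seed(seed, "layout"), {
    len <- round(runif(n_genes, lo, hi) / bin_bp) * bin_bp
    # keep strictly above the 30-kb filter floor and inside the stated range
    len <- pmin(pmax(len, lo + bin_bp), hi)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    mult <- rlnorm(n_genes, meanlog = -abundance_sdlog^2 / 2,
                   sdlog = abundance_sdlog)
    list(len = len, strand = strand, mult = mult)
  })

  # sequential placement, genes_per_chrom per chromosome
  chrom <- character(n_genes); gstart <- numeric(n_genes)
  pos <- flank_bp; ci <- 1L; on_chrom <- 0L
  chrom_sizes <- integer(0)
  for (g in seq_len(n_genes)) {
    if (on_chrom >= genes_per_chrom) {
      chrom_sizes[paste0("sim", ci)] <- as.integer(pos - gap_bp + flank_bp)
      ci <- ci + 1L; on_chrom <- 0L; pos <- flank_bp
    }
    chrom[g] <- paste0("sim", ci)
    gstart[g] <- pos
    pos <- pos + layout$len[g] + gap_bp
    pw_check(pos <= max_chrom_size_bp, "polwave_layout_error",
             "cannot place gene %d within max_chrom_size_bp", g)
    on_chrom <- on_chrom + 1L
  }
  chrom_sizes[paste0("sim", ci)] <- as.integer(pos - gap_bp + flank_bp)

  ids <- sprintf("g%04d", seq_len(n_genes))
  annotation <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = gstart + 1, width = layout$len),
    strand = layout$strand,
    transcript_id = ids,
    seqlengths = chrom_sizes
  )

  tps <- params_wt$timepoints_min
  for (p in conditions)
    pw_check(identical(p$timepoints_min, tps), "polwave_param_error",
             "all conditions must share timepoints_min")
  tp_lab <- fmt_num(tps)

  empty_tracks <- function() {
    tr <- list()
    for (tl in tp_lab) tr[[tl]] <- list()
    tr
  }
  tracks <- list()
  truth <- list()

  for (cond in names(conditions)) {
    par <- conditions[[cond]]
    nas_plus <- empty_tracks(); nas_minus <- empty_tracks()
    polii <- empty_tracks()
    tru <- data.frame(condition = character(0))
    for (g in seq_len(n_genes)) {
      npol <- with_seed(derive_seed(seed, paste0(cond, ":", ids[g], ":npol")),
                        max(1L, rpois(1L, n_pol_mean * layout$mult[g])))
      traj <- simulate_polymerases(
        par, gene_length_bp = layout$len[g], n_pol = npol,
        seed = derive_seed(seed, paste0(cond, ":", ids[g], ":traj")))
      for (k in seq_along(tps)) {
        nt <- render_nascent_track(
          traj, par, tps[k], bin_bp = bin_bp,
          seed = derive_seed(seed, paste0(cond, ":", ids[g], ":nas:", k)),
          pol_per_unit = n_pol_mean)
        pt <- render_polii_track(
          traj, par, tps[k], bin_bp = bin_bp,
          seed = derive_seed(seed, paste0(cond, ":", ids[g], ":pol:", k)),
          pol_per_unit = n_pol_mean)
        ngr <- track_to_genome(nt$counts, nt$edges, chrom[g], gstart[g],
                               layout$len[g], layout$strand[g], chrom_sizes)
        pgr <- track_to_genome(pt$counts, pt$edges, chrom[g], gstart[g],
                               layout$len[g], layout$strand[g], chrom_sizes)
        if (layout$strand[g] == "+") {
          nas_plus[[tp_lab[k]]][[ids[g]]] <- ngr
        } else {
          nas_minus[[tp_lab[k]]][[ids[g]]] <- ngr
        }
        polii[[tp_lab[k]]][[ids[g]]] <- pgr
      }
      tru <- rbind(tru, data.frame(
        condition = cond, transcript_id = ids[g],
        true_speed_kb_per_min = par$speed_kb_per_min,
        true_hazard_per_kb = par$termination_hazard_per_kb,
        n_polymerases_released = npol,
        n_terminated = sum(traj$terminated)
      ))
    }
    cat_tracks <- function(per_tp) {
      lapply(per_tp, function(lst) {
        if (length(lst) == 0)
          return(GenomicRanges::GRanges(seqlengths = chrom_sizes))
        sort(do.call(c, unname(lst)))
      })
    }
    tracks[[cond]] <- list(
      nascent = mapply(function(p, m) list(plus = p, minus = m),
                       cat_tracks(nas_plus), cat_tracks(nas_minus),
                       SIMPLIFY = FALSE),
      polii = cat_tracks(polii)
    )
    truth[[cond]] <- tru
  }

  structure(list(
    annotation = annotation,
    chrom_sizes = chrom_sizes,
    tracks = tracks,
    truth = do.call(rbind, unname(truth)),
    params = conditions,
    timepoints_min = tps,
    bin_bp = as.integer(bin_bp),
    n_pol_mean = n_pol_mean,
    seed = as.integer(seed)
  ), class = "sim_cohort")
}

# Map a TSS-relative binned count vector onto genome coordinates as a
# GRanges of nonzero bins with a `score` column (bedGraph semantics).
track_to_genome <- function(counts, edges, chrom, gstart_0based, gene_len,
                            strand, chrom_sizes) {
  nz <- which(counts > 0)
  if (length(nz) == 0)
    return(GenomicRanges::GRanges(seqlengths = chrom_sizes))
  rel0 <- edges[nz]; rel1 <- edges[nz + 1L]
  if (strand == "+") {
    s <- gstart_0based + rel0
    e <- gstart_0based + rel1
  } else {
    gend <- gstart_0based + gene_len
    s <- gend - rel1
    e <- gend - rel0
  }
  o <- order(s)
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = s[o] + 1, end = e[o]),
    score = as.numeric(counts[nz][o]),
    seqlengths = chrom_sizes
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort: %d genes on %d chromosomes, conditions: %s\n",
    length(x$annotation), length(x$chrom_sizes),
    paste(names(x$params), collapse = ", ")))
  cat(sprintf("  timepoints: %s min; bin: %d bp; mean pool: %g polymerases\n",
              paste(x$timepoints_min, collapse = ", "), x$bin_bp,
              x$n_pol_mean))
  invisible(x)
}

#' Write a simulated cohort to disk as plain-text genomics formats
#'
#' Writes BED12 annotation, a two-column chrom.sizes file, 4-column
#' bedGraph tracks per condition/assay/timepoint (nascent as `_plus` /
#' `_minus` pair), and a tab-separated ground-truth table.  Output bytes are
#' a pure function of the cohort object, so fixed seeds give identical
#' files.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param outdir output directory (created if missing).
#' @return invisibly, a character vector of the written paths.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  ann <- cohort$annotation
  bed <- ann
  S4Vectors::mcols(bed) <- NULL
  bed$name <- ann$transcript_id
  bed$score <- 0L
  bed$thick <- IRanges::ranges(ann)
  bed$blocks <- IRanges::IRangesList(
    lapply(GenomicRanges::width(ann), function(w) IRanges::IRanges(1, w)))
  p <- file.path(outdir, "annotation.bed")
  rtracklayer::export(bed, p, format = "bed")
  paths <- c(paths, p)

  p <- file.path(outdir, "chrom.sizes")
  write.table(data.frame(names(cohort$chrom_sizes),
                         unname(cohort$chrom_sizes)),
              p, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  paths <- c(paths, p)

  for (cond in names(cohort$tracks)) {
    for (tl in names(cohort$tracks[[cond]]$nascent)) {
      pair <- cohort$tracks[[cond]]$nascent[[tl]]
      for (str in c("plus", "minus")) {
        p <- file.path(outdir,
                       sprintf("%s_nascent_t%s_%s.bedGraph", cond, tl, str))
        rtracklayer::export(pair[[str]], p, format = "bedGraph")
        paths <- c(paths, p)
      }
      p <- file.path(outdir, sprintf("%s_polii_t%s.bedGraph", cond, tl))
      rtracklayer::export(cohort$tracks[[cond]]$polii[[tl]], p,
                          format = "bedGraph")
      paths <- c(paths, p)
    }
  }

  p <- file.path(outdir, "truth.tsv")
  write.table(cohort$truth, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
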