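# Shared fixture builders.  Everything is generated in code at test time;
# heavier cohorts are cached per session so multiple test files can reuse
# them without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small two-condition cohort for module-level tests
small_cohort <- function() cached("small_cohort", function() {
  wt <- sim_params(speed_kb_per_min = 2.0, termination_hazard_per_kb = 0.01,
                   release_rate_per_min = 0.5,
                   timepoints_min = c(0, 5, 10), seed = 11)
  ko <- sim_params(speed_kb_per_min = 2.6, termination_hazard_per_kb = 0.05,
                   release_rate_per_min = 0.5,
                   timepoints_min = c(0, 5, 10), seed = 11)
  simulate_cohort(wt, ko, n_genes = 20, seed = 11)
})

# matrices for one condition/assay of a cohort, depth-normalized
cohort_matrices <- function(cohort, cond = "wt", assay = "nascent",
                            downstream_bp = 30000) {
  sig <- cohort_signals(cohort)
  fl <- filter_transcripts(cohort$annotation)
  w <- make_windows(fl, 2000, downstream_bp, cohort$bin_bp,
                    cohort$chrom_sizes)
  tls <- names(sig[[cond]][[assay]])
  mats <- lapply(tls, function(tl)
    normalize_depth(gene_matrix(sig[[cond]][[assay]][[tl]], w,
                                assay = assay, condition = cond,
                                timepoint_min = as.numeric(tl))))
  stats::setNames(mats, tls)
}

# a plain bedGraph file from (chrom, start0, end0, value) rows
write_bedgraph <- function(rows, path = tempfile(fileext = ".bedGraph")) {
  writeLines(apply(rows, 1, function(r)
    paste(r[1],
          format(as.numeric(r[2]), scientific = FALSE),
          format(as.numeric(r[3]), scientific = FALSE),
          r[4], sep = "\t")), path)
  path
}

toy_annotation_path <- function()
  system.file("extdata", "toy_annotation.bed", package = "polwave")
toy_chrom_sizes_path <- function()
  system.file("extdata", "toy_chrom.sizes", package = "polwave")
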