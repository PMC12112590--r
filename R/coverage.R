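#' Load a genome-wide signal track
#'
#' Reads bedGraph, bigWig, or BED read-intervals into an exact run-length
#' signal accessor.  For value tracks (bedGraph/bigWig) the signal at a base
#' is the track value and the library size is \eqn{\sum value \times span};
#' for BED intervals each read contributes 1 over its span and the library
#' size is the read count.  bedGraph intervals must be non-overlapping.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bedGraph"`, `"bigWig"` or
#'   `"bed"`.
#' @return an object of class `signal_track`: `cov` (RleList), `total`
#'   (library size), `source`.
#' @export
load_signal <- function(path, format = c("auto", "bedGraph", "bigWig",
                                         "bed")) {
  format <- match.arg(format)
  pw_check(file.exists(path), "polwave_parse_error",
           "signal file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE))
      "bigWig"
    else if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
    else "bedGraph"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = switch(format, bigWig = "bigWig",
                                              bed = "bed", "bedGraph")),
    error = function(e) pw_stop("polwave_parse_error", "%s: %s", path,
                                conditionMessage(e)))
  if (format == "bed") {
    signal_track_from_granges(gr, weighted = FALSE, source = path)
  } else {
    pw_check(GenomicRanges::isDisjoint(gr), "polwave_format_error",
             "%s: overlapping intervals in value track", path)
    signal_track_from_granges(gr, weighted = TRUE, source = path)
  }
}

#' Build a signal track from an in-memory GRanges
#'
#' @param gr `GRanges`; if `weighted`, with a numeric `score` column
#'   (bedGraph semantics), else each range counts 1 (read intervals).
#' @param weighted use the `score` column as interval value.
#' @param source label recorded on the object.
#' @return a `signal_track`.
#' @export
signal_track_from_granges <- function(gr, weighted = TRUE,
                                      source = "granges") {
  if (weighted && length(gr) > 0) {
    cov <- GenomicRanges::coverage(gr, weight = "score")
    total <- sum(as.numeric(gr$score) * GenomicRanges::width(gr))
  } else {
    cov <- GenomicRanges::coverage(gr)
    total <- length(gr)
  }
  structure(list(cov = cov, total = as.numeric(total), source = source),
            class = "signal_track")
}

#' Pair strand-specific signal tracks
#'
#' Stranded nascent-RNA assays are carried as a plus/minus pair; the
#' library size is the pooled total.
#'
#' @param plus,minus `signal_track`s.
#' @return an object of class `signal_pair`.
#' @export
signal_pair <- function(plus, minus) {
  stopifnot(inherits(plus, "signal_track"), inherits(minus, "signal_track"))
  structure(list(plus = plus, minus = minus,
                 total = plus$total + minus$total),
            class = "signal_pair")
}

# Exact per-bin sums of a signal track over half-open genomic bins
# [start0 + (i-1)*bin, start0 + i*bin) on one chromosome.  Queries beyond
# the covered region return 0; unknown chromosomes return 0 with a warning.
bin_sums_chrom <- function(track, chrom, start0, n_bins, bin_bp) {
  if (!chrom %in% names(track$cov)) {
    warning("chromosome ", chrom, " not in signal track; returning zeros")
    return(matrix(0, nrow = length(start0), ncol = n_bins))
  }
  rle <- track$cov[[chrom]]
  need <- max(start0) + n_bins * bin_bp
  if (length(rle) < need)
    rle <- c(rle, S4Vectors::Rle(0, need - length(rle)))
  starts <- rep(start0, each = n_bins) +
    rep(seq_len(n_bins) - 1L, times = length(start0)) * bin_bp + 1L
  v <- IRanges::Views(rle, start = starts, width = bin_bp)
  matrix(IRanges::viewSums(v), ncol = n_bins, byrow = TRUE)
}

#' TSS-anchored gene x bin coverage matrix
#'
#' Sums signal in each bin of each analysis window.  Rows of minus-strand
#' genes are reversed so that bin 1 is the most upstream position
#' (transcription orientation) for every gene.  With a `signal_pair`, each
#' gene reads from the track matching its strand; a single `signal_track`
#' is treated as unstranded.
#'
#' @param signal a `signal_track` or `signal_pair`.
#' @param windows an [make_windows()] result.
#' @param assay,condition,timepoint_min labels carried on the matrix.
#' @return an object of class `coverage_matrix`: `values` (genes x bins),
#'   `gene_ids`, `bin_edges_bp` (relative to TSS), `bin_bp`, `assay`,
#'   `condition`, `timepoint_min`, `normalized`, `library_size`.
#' @export
gene_matrix <- function(signal, windows, assay = "nascent",
                        condition = "na", timepoint_min = NA_real_) {
  stopifnot(inherits(windows, "analysis_windows"))
  win <- windows$windows
  nb <- windows$n_bins
  n <- length(win)
  vals <- matrix(0, nrow = n, ncol = nb)
  lib <- if (inherits(signal, "signal_pair")) signal$total else signal$total
  if (n > 0) {
    strand <- as.character(GenomicRanges::strand(win))
    chroms <- as.character(GenomicRanges::seqnames(win))
    start0 <- GenomicRanges::start(win) - 1L
    pick_track <- function(i) {
      if (inherits(signal, "signal_pair")) {
        if (strand[i] == "-") signal$minus else signal$plus
      } else signal
    }
    for (ch in unique(chroms)) {
      for (str in unique(strand)) {
        idx <- which(chroms == ch & strand == str)
        if (length(idx) == 0) next
        m <- bin_sums_chrom(pick_track(idx[1]), ch, start0[idx], nb,
                            windows$bin_bp)
        if (str == "-") m <- m[, nb:1, drop = FALSE]
        vals[idx, ] <- m
      }
    }
  }
  structure(list(
    values = vals,
    gene_ids = if (n > 0) win$transcript_id else character(0),
    bin_edges_bp = seq(-windows$upstream_bp, windows$downstream_bp,
                       by = windows$bin_bp),
    bin_bp = windows$bin_bp,
    assay = assay, condition = condition,
    timepoint_min = timepoint_min,
    normalized = FALSE,
    library_size = lib
  ), class = "coverage_matrix")
}

bin_centers <- function(cm) {
  e <- cm$bin_edges_bp
  (e[-length(e)] + e[-1]) / 2
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf(
    "coverage_matrix: %d genes x %d bins (%s, %s, t=%s min)%s\n",
    nrow(x$values), ncol(x$values), x$assay, x$condition,
    format(x$timepoint_min),
    if (x$normalized) " [per-million]" else ""))
  invisible(x)
}

#' Depth-normalize a coverage matrix to signal per million
#'
#' Scales every entry by `1e6 / library_size` (total mapped signal of the
#' originating track), the usual per-million normalization.  Normalizing an
#' already normalized matrix is an error.
#'
#' @param cm a `coverage_matrix`.
#' @param library_size override for the recorded library size.
#' @return the normalized `coverage_matrix`.
#' @export
normalize_depth <- function(cm, library_size = cm$library_size) {
  stopifnot(inherits(cm, "coverage_matrix"))
  pw_check(!cm$normalized, "polwave_param_error",
           "matrix is already depth-normalized")
  pw_check(is.finite(library_size) && library_size > 0,
           "polwave_param_error", "library_size must be > 0")
  cm$values <- cm$values * (1e6 / library_size)
  cm$library_size <- library_size
  cm$normalized <- TRUE
  cm
}

#' Average signal profile over genes
#'
#' @param cm a `coverage_matrix` with at least one gene.
#' @param stat `"mean"` (standard metagene) or `"median"`.
#' @return an object of class `metagene_profile`: `bin_centers_bp`,
#'   `mean_signal`, `n_genes`, plus the matrix labels.
#' @export
metagene <- function(cm, stat = c("mean", "median")) {
  stopifnot(inherits(cm, "coverage_matrix"))
  stat <- match.arg(stat)
  pw_check(nrow(cm$values) >= 1, "polwave_param_error",
           "metagene needs at least one gene")
  sig <- if (stat == "mean") colMeans(cm$values) else
    apply(cm$values, 2, stats::median)
  structure(list(bin_centers_bp = bin_centers(cm), mean_signal = sig,
                 n_genes = nrow(cm$values), assay = cm$assay,
                 condition = cm$condition, timepoint_min = cm$timepoint_min),
            class = "metagene_profile")
}

#' Sort matrix rows for heatmap display
#'
#' Stable sort by row mean, descending (high average signal first).
#'
#' @param cm a `coverage_matrix`.
#' @return the reordered `coverage_matrix`.
#' @export
heatmap_sort <- function(cm) {
  stopifnot(inherits(cm, "coverage_matrix"))
  rm <- rowMeans(cm$values)
  o <- order(-rm, seq_along(rm))  # explicit index tiebreak => stable
  cm$values <- cm$values[o, , drop = FALSE]
  cm$gene_ids <- cm$gene_ids[o]
  cm
}

#' Classify genes by gene-body occupancy into High / Low / No groups
#'
#' Computes each gene's mean signal over a gene-body window and splits the
#' set at two thresholds.  By default the thresholds are the tertile
#' boundaries of the genes with nonzero body signal; zero-signal genes are
#' always `No`.
#'
#' @param cm a depth-normalized `coverage_matrix`.
#' @param thresholds `c(low, high)` on the body-mean scale, or `NULL` for
#'   tertiles of the nonzero genes.
#' @param body_window_bp `c(from, to)` relative to TSS over which the body
#'   mean is taken.
#' @return a data.frame with `transcript_id`, `body_mean`, `group`
#'   (factor High/Low/No), plus the thresholds as an attribute.
#' @export
classify_by_occupancy <- function(cm, thresholds = NULL,
                                  body_window_bp = c(2000, 15000)) {
  stopifnot(inherits(cm, "coverage_matrix"))
  pw_check(cm$normalized, "polwave_param_error",
           "classify_by_occupancy expects a depth-normalized matrix")
  ctr <- bin_centers(cm)
  sel <- ctr >= body_window_bp[1] & ctr < body_window_bp[2]
  pw_check(any(sel), "polwave_config_error",
           "body window [%g, %g) covers no bins", body_window_bp[1],
           body_window_bp[2])
  bm <- rowMeans(cm$values[, sel, drop = FALSE])
  if (is.null(thresholds)) {
    nz <- bm[bm > 0]
    if (length(nz) == 0) {
      warning("all genes have zero body signal; all classified No")
      thresholds <- c(Inf, Inf)
    } else {
      thresholds <- unname(stats::quantile(nz, c(1 / 3, 2 / 3)))
    }
  }
  group <- ifelse(bm <= 0, "No",
                  ifelse(bm > thresholds[2], "High",
                         ifelse(bm > thresholds[1], "Low", "No")))
  out <- data.frame(transcript_id = cm$gene_ids, body_mean = bm,
                    group = factor(group, levels = c("High", "Low", "No")))
  attr(out, "thresholds") <- thresholds
  out
}
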