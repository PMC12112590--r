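#' Read transcript annotation from BED or GTF
#'
#' Returns one range per transcription unit as a `GRanges` with a
#' `transcript_id` metadata column.  BED input (BED6/BED12; 0-based
#' half-open) and GTF input (1-based closed) are both normalized to the
#' usual `GRanges` 1-based representation, so downstream code never sees a
#' coordinate dialect.  For GTF with multiple isoforms per gene, one unit
#' per locus is kept: the longest isoform, ties broken by lexicographically
#' smallest transcript id.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @return `GRanges` with `transcript_id`.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  pw_check(file.exists(path), "polwave_parse_error",
           "annotation file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff|gff3)(\\.gz)?$", path,
                        ignore.case = TRUE)) "gtf" else "bed"
  }
  if (file.size(path) == 0 ||
      length(readLines(path, n = 1L, warn = FALSE)) == 0) {
    warning("empty annotation file: ", path)
    return(GenomicRanges::GRanges(transcript_id = character(0)))
  }
  if (format == "bed") read_annotation_bed(path) else read_annotation_gtf(path)
}

read_annotation_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(body)) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) < 4)
      pw_stop("polwave_parse_error",
              "%s line %d: BED record needs >= 4 fields", path, i)
    if (anyNA(suppressWarnings(as.numeric(f[2:3]))) ||
        as.numeric(f[2]) >= as.numeric(f[3]))
      pw_stop("polwave_parse_error",
              "%s line %d: invalid BED interval '%s %s'", path, i, f[2], f[3])
  }
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e)
                   pw_stop("polwave_parse_error", "%s: %s", path,
                           conditionMessage(e)))
  gr$transcript_id <- if (!is.null(gr$name)) gr$name else
    sprintf("tx%04d", seq_along(gr))
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)["transcript_id"]
  gr
}

read_annotation_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   pw_stop("polwave_parse_error", "%s: %s", path,
                           conditionMessage(e)))
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "transcript")) {
    gr <- gr[gr$type == "transcript"]
  }
  tid <- if (!is.null(gr$transcript_id)) gr$transcript_id else
    sprintf("tx%04d", seq_along(gr))
  gid <- if (!is.null(gr$gene_id)) gr$gene_id else tid
  gr$transcript_id <- tid
  # one unit per locus: longest isoform, tie -> smallest transcript_id
  o <- order(gid, -GenomicRanges::width(gr), tid)
  gr <- gr[o]
  gr <- gr[!duplicated(gid[o])]
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)["transcript_id"]
  sort(gr)
}

#' Filter transcripts to long, non-overlapping units on allowed chromosomes
#'
#' Applies, in order: chromosome whitelist; length strictly greater than
#' `min_len_bp` and at most `max_len_bp`; and removal of every transcript
#' that overlaps any other input transcript (strand-blind — both members of
#' an overlapping pair are removed, since read-through or antisense signal
#' contaminates both).  Rejection counts attribute each removed transcript
#' to its first failing rule.
#'
#' @param transcripts `GRanges` with `transcript_id`.
#' @param min_len_bp keep length > this (default 30000, i.e. "> 30 kb").
#' @param max_len_bp keep length <= this (default 300000).
#' @param chrom_whitelist chromosomes to keep; `NULL` keeps all.
#' @return a list of class `filtered_transcripts`: `transcripts`
#'   (survivors), `rejected` (named counts: chrom, length, overlap),
#'   `n_input`.
#' @export
filter_transcripts <- function(transcripts, min_len_bp = 30000,
                               max_len_bp = 300000,
                               chrom_whitelist = NULL) {
  gr <- transcripts
  n <- length(gr)
  ok_chrom <- if (is.null(chrom_whitelist)) rep(TRUE, n) else
    as.character(GenomicRanges::seqnames(gr)) %in% chrom_whitelist
  len <- GenomicRanges::width(gr)
  ok_len <- len > min_len_bp & len <= max_len_bp
  ok_ovl <- GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE) <= 1L
  first_fail <- ifelse(!ok_chrom, "chrom",
                       ifelse(!ok_len, "length",
                              ifelse(!ok_ovl, "overlap", NA)))
  keep <- ok_chrom & ok_len & ok_ovl
  rejected <- c(chrom = sum(first_fail == "chrom", na.rm = TRUE),
                length = sum(first_fail == "length", na.rm = TRUE),
                overlap = sum(first_fail == "overlap", na.rm = TRUE))
  structure(list(transcripts = gr[keep], rejected = rejected, n_input = n),
            class = "filtered_transcripts")
}

#' @export
print.filtered_transcripts <- function(x, ...) {
  cat(sprintf("%d / %d transcripts kept (rejected: %s)\n",
              length(x$transcripts), x$n_input,
              paste(names(x$rejected), x$rejected,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Build TSS-anchored, strand-oriented analysis windows
#'
#' Extends each transcript's TSS by `upstream_bp` upstream and
#' `downstream_bp` downstream in the transcription direction (for minus
#' strand, upstream is genomically rightward).  A transcript whose extended
#' window leaves `[0, chrom_size)` is dropped, not clipped, and counted.
#'
#' @param transcripts `GRanges` with `transcript_id` (or a
#'   `filtered_transcripts` result).
#' @param upstream_bp,downstream_bp window extent, bp; their sum must be a
#'   multiple of `bin_bp`.
#' @param bin_bp bin width in bp.
#' @param chrom_sizes named numeric vector of chromosome sizes, or path to
#'   a two-column chrom.sizes file; must cover every chromosome present.
#' @return a list of class `analysis_windows`: `windows` (`GRanges`, one per
#'   kept transcript, strand carried), `upstream_bp`, `downstream_bp`,
#'   `bin_bp`, `n_bins`, `n_dropped`.
#' @export
make_windows <- function(transcripts, upstream_bp = 2000,
                         downstream_bp = 30000, bin_bp = 200,
                         chrom_sizes = NULL) {
  if (inherits(transcripts, "filtered_transcripts"))
    transcripts <- transcripts$transcripts
  gr <- transcripts
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1) {
    tab <- read.table(chrom_sizes, sep = "\t", header = FALSE,
                      col.names = c("chrom", "size"))
    chrom_sizes <- stats::setNames(tab$size, tab$chrom)
  }
  pw_check(!is.null(chrom_sizes), "polwave_config_error",
           "chrom_sizes is required")
  win_len <- upstream_bp + downstream_bp
  pw_check(win_len %% bin_bp == 0, "polwave_param_error",
           "window length (%d) must be divisible by bin_bp (%d)",
           win_len, bin_bp)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  miss <- setdiff(unique(chroms), names(chrom_sizes))
  pw_check(length(miss) == 0, "polwave_config_error",
           "chrom_sizes missing chromosomes: %s",
           paste(miss, collapse = ", "))
  strand <- as.character(GenomicRanges::strand(gr))
  # 0-based TSS anchor: start of the range for +, half-open end for -
  tss0 <- ifelse(strand == "-", GenomicRanges::end(gr),
                 GenomicRanges::start(gr) - 1L)
  w0 <- ifelse(strand == "-", tss0 - downstream_bp, tss0 - upstream_bp)
  w1 <- ifelse(strand == "-", tss0 + upstream_bp, tss0 + downstream_bp)
  inside <- w0 >= 0 & w1 <= chrom_sizes[chroms]
  win <- GenomicRanges::GRanges(
    seqnames = chroms[inside],
    ranges = IRanges::IRanges(start = w0[inside] + 1, end = w1[inside]),
    strand = strand[inside],
    transcript_id = gr$transcript_id[inside],
    tss_0based = tss0[inside]
  )
  structure(list(windows = win,
                 upstream_bp = as.integer(upstream_bp),
                 downstream_bp = as.integer(downstream_bp),
                 bin_bp = as.integer(bin_bp),
                 n_bins = as.integer(win_len / bin_bp),
                 n_dropped = sum(!inside)),
            class = "analysis_windows")
}

#' @export
print.analysis_windows <- function(x, ...) {
  cat(sprintf(
    "%d TSS windows [-%d, +%d) bp, %d bins of %d bp (%d dropped at edges)\n",
    length(x$windows), x$upstream_bp, x$downstream_bp, x$n_bins, x$bin_bp,
    x$n_dropped))
  invisible(x)
}
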