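test_that("bedGraph loading: totals, exactness, additivity, errors", {
  p <- write_bedgraph(rbind(c("chr1", 0, 100, 2.0)))
  st <- load_signal(p)
  expect_equal(st$total, 200)  # value x span
  # exact partition sums: any binning of [0, 100) adds back to 200
  expect_equal(sum(polwave:::bin_sums_chrom(st, "chr1", 0L, 10L, 10L)), 200)
  expect_equal(sum(polwave:::bin_sums_chrom(st, "chr1", 0L, 4L, 25L)), 200)
  # beyond the covered region: zero
  expect_equal(as.numeric(polwave:::bin_sums_chrom(st, "chr1", 1000L, 2L,
                                                   50L)),
               c(0, 0))
  expect_warning(z <- polwave:::bin_sums_chrom(st, "chrZ", 0L, 2L, 50L),
                 "not in signal track")
  expect_true(all(z == 0))

  ovl <- write_bedgraph(rbind(c("chr1", 0, 100, 1), c("chr1", 50, 150, 1)))
  expect_error(load_signal(ovl), class = "polwave_format_error")
})

make_simple_windows <- function(ranges, strands, cs = c(chr1 = 1e6)) {
  gr <- GenomicRanges::GRanges(rep("chr1", length(strands)), ranges,
                               strand = strands,
                               transcript_id = sprintf("t%d",
                                                       seq_along(strands)))
  make_windows(gr, 2000, 30000, 200, cs)
}

test_that("gene_matrix: uniform signal, strand reversal, linearity", {
  p <- write_bedgraph(rbind(c("chr1", 0, 1000000, 1.0)))
  st <- load_signal(p)
  w <- make_simple_windows(IRanges::IRanges(c(10001, 500001),
                                            c(50000, 540000)),
                           c("+", "-"))
  cm <- gene_matrix(st, w)
  expect_equal(dim(cm$values), c(2, 160))
  expect_true(all(cm$values == 200))    # bin_bp x 1.0

  # asymmetric signal: minus-strand rows are read 5'->3'
  p2 <- write_bedgraph(rbind(c("chr1", 10000, 10200, 5)))  # +TSS..+200 of t1
  st2 <- load_signal(p2)
  # t1 TSS0 = 10000 (+): signal sits in bins 11 (rel 0..200)
  cm2 <- gene_matrix(st2, w)
  expect_equal(which(cm2$values[1, ] > 0), 11L)
  # place the same relative signal for the minus-strand gene:
  # TSS0 = 540000, rel [0,200) = genomic [539800, 540000)
  p3 <- write_bedgraph(rbind(c("chr1", 539800, 540000, 5)))
  cm3 <- gene_matrix(load_signal(p3), w)
  expect_equal(which(cm3$values[2, ] > 0), 11L)
  expect_equal(cm3$values[2, 11], cm2$values[1, 11])

  # linearity in the underlying signal
  p4 <- write_bedgraph(rbind(c("chr1", 0, 1000000, 3.0)))
  cm4 <- gene_matrix(load_signal(p4), w)
  expect_equal(cm4$values, 3 * cm$values)

  # empty window set
  w0 <- make_simple_windows(IRanges::IRanges(1, 2)[0], character(0))
  expect_equal(nrow(gene_matrix(st, w0)$values), 0)
})

test_that("stranded pairs route each gene to its strand's track", {
  w <- make_simple_windows(IRanges::IRanges(c(10001, 500001),
                                            c(50000, 540000)),
                           c("+", "-"))
  plus <- load_signal(write_bedgraph(rbind(c("chr1", 0, 1000000, 1))))
  minus <- load_signal(write_bedgraph(rbind(c("chr1", 0, 1000000, 9))))
  cm <- gene_matrix(signal_pair(plus, minus), w)
  expect_true(all(cm$values[1, ] == 200))
  expect_true(all(cm$values[2, ] == 1800))
  expect_equal(cm$library_size, plus$total + minus$total)
})

test_that("depth normalization: scaling, idempotence guard, invariance", {
  w <- make_simple_windows(IRanges::IRanges(10001, 50000), "+")
  st <- load_signal(write_bedgraph(rbind(c("chr1", 0, 1000000, 2))))
  cm <- gene_matrix(st, w)
  nm <- normalize_depth(cm)
  expect_equal(nm$values, cm$values * 1e6 / cm$library_size)
  expect_error(normalize_depth(nm), class = "polwave_param_error")
  expect_error(normalize_depth(cm, library_size = 0),
               class = "polwave_param_error")
  # scaling raw signal and library by c leaves normalized values unchanged
  st7 <- load_signal(write_bedgraph(rbind(c("chr1", 0, 1000000, 14))))
  nm7 <- normalize_depth(gene_matrix(st7, w))
  expect_equal(nm7$values, nm$values)
})

test_that("metagene and heatmap_sort arithmetic", {
  cm <- structure(list(values = rbind(c(1, 2), c(3, 4)),
                       gene_ids = c("g1", "g2"),
                       bin_edges_bp = c(0, 200, 400), bin_bp = 200L,
                       assay = "nascent", condition = "wt",
                       timepoint_min = 5, normalized = TRUE,
                       library_size = 1e6),
                  class = "coverage_matrix")
  mg <- metagene(cm)
  expect_equal(mg$mean_signal, c(2, 3))
  expect_equal(mg$n_genes, 2)
  hs <- heatmap_sort(cm)
  expect_equal(hs$gene_ids, c("g2", "g1"))
  # all-identical rows: metagene equals any row; sort is stable
  cm$values <- rbind(c(7, 7), c(7, 7))
  expect_equal(metagene(cm)$mean_signal, c(7, 7))
  expect_equal(heatmap_sort(cm)$gene_ids, c("g1", "g2"))
  cm$values <- cm$values[0, , drop = FALSE]
  cm$gene_ids <- character(0)
  expect_error(metagene(cm), class = "polwave_param_error")
})

test_that("occupancy classification partitions the gene set", {
  mk <- function(body_means) {
    nb <- 160
    ctr <- seq(-2000, 30000, 200)[-1] - 100
    v <- matrix(0, length(body_means), nb)
    sel <- ctr >= 2000 & ctr < 15000
    for (i in seq_along(body_means)) v[i, sel] <- body_means[i]
    structure(list(values = v,
                   gene_ids = sprintf("g%d", seq_along(body_means)),
                   bin_edges_bp = seq(-2000, 30000, 200), bin_bp = 200L,
                   assay = "polii", condition = "wt", timepoint_min = 10,
                   normalized = TRUE, library_size = 1e6),
              class = "coverage_matrix")
  }
  cls <- classify_by_occupancy(mk(c(0, 1, 10)), thresholds = c(0.5, 5))
  expect_equal(as.character(cls$group), c("No", "Low", "High"))
  expect_warning(cls0 <- classify_by_occupancy(mk(c(0, 0, 0))),
                 "zero body signal")
  expect_true(all(cls0$group == "No"))
  # partition property under default tertile thresholds
  set.seed(8)
  cls2 <- classify_by_occupancy(mk(c(0, rexp(30))))
  expect_equal(sum(table(cls2$group)), 31)
  expect_false(anyNA(cls2$group))
})
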