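centers_30k <- seq(-2000, 30000, 200)[-1] - 100

test_that("spline peak matches the analytic argmax on clean profiles", {
  # triangular wave peaking at +12,000 bp
  tri <- pmax(0, 1 - abs(centers_30k - 12000) / 8000)
  f <- fit_wave(tri, centers_30k)
  expect_true(f$ok)
  expect_lt(abs(f$peak_pos_bp - 12000), 200)

  # all mass in the pause-site bin, exclusion disabled
  pulse <- as.numeric(centers_30k == 100) * 5
  f0 <- fit_wave(pulse, centers_30k, exclusion_zone_bp = 0)
  expect_lt(abs(f0$peak_pos_bp - 100), 200)

  # translation invariance of the argmax
  f2 <- fit_wave(tri + 0.5, centers_30k)
  expect_equal(f2$peak_pos_bp, f$peak_pos_bp)
})

test_that("flat profiles give a flagged no-peak result", {
  f <- fit_wave(rep(0, 160), centers_30k)
  expect_false(f$ok)
  expect_true(is.na(f$peak_pos_bp))
  fc <- fit_wave(rep(3, 160), centers_30k)  # constant: no wave either
  expect_false(fc$ok)
  expect_error(fit_wave(c(1, 2, 3), c(1, 2, 3)),
               class = "polwave_param_error")
  expect_error(fit_wave(rep(-1, 160), centers_30k),
               class = "polwave_param_error")
})

test_that("front detection finds the drop below 10% of peak", {
  rect <- ifelse(centers_30k > 0 & centers_30k < 20000, 1, 0)
  f <- fit_wave(rect, centers_30k, exclusion_zone_bp = 500)
  expect_true(f$ok)
  expect_lt(abs(f$front_pos_bp - 20000), 600)  # spline edge roll-off
  # a profile that never drops: front is NA, peak still valid
  full <- rep(1, 160); full[1] <- 0.5  # non-constant, high everywhere
  ff <- fit_wave(full, centers_30k)
  expect_true(ff$ok)
  expect_true(is.na(ff$front_pos_bp))
})

stub_fit <- function(t, peak, front = peak) {
  structure(list(timepoint_min = t, peak_pos_bp = peak, front_pos_bp = front,
                 ok = TRUE), class = "wave_fit")
}

test_that("rate regression: two-point, degenerate and collinear cases", {
  est <- estimate_rate(list(stub_fit(0, 300), stub_fit(10, 20300)),
                       measure = "peak")
  expect_equal(est$rate_kb_per_min, 2.0)
  expect_equal(est$intercept_bp, 300)

  same <- estimate_rate(list(stub_fit(0, 5000), stub_fit(10, 5000)),
                        measure = "peak")
  expect_equal(same$rate_kb_per_min, 0)

  tri <- estimate_rate(list(stub_fit(0, 500), stub_fit(5, 10500),
                            stub_fit(10, 20500)), measure = "peak")
  expect_equal(tri$rate_kb_per_min, 2.0)
  expect_equal(tri$intercept_bp, 500)

  expect_error(estimate_rate(list(stub_fit(0, 300))),
               class = "polwave_estimation_error")
  expect_error(estimate_rate(list(stub_fit(0, 300), stub_fit(0, 400))),
               class = "polwave_estimation_error")
})

noiseless_matrix <- function(fronts_bp, t) {
  v <- t(vapply(fronts_bp, function(fr)
    ifelse(centers_30k > 0 & centers_30k < max(fr, 300), 1, 0),
    numeric(length(centers_30k))))
  structure(list(values = v, gene_ids = sprintf("g%d", seq_along(fronts_bp)),
                 bin_edges_bp = seq(-2000, 30000, 200), bin_bp = 200L,
                 assay = "nascent", condition = "wt", timepoint_min = t,
                 normalized = TRUE, library_size = 1e6),
            class = "coverage_matrix")
}

test_that("per-gene rates recover per-gene wave advances", {
  m0 <- noiseless_matrix(c(200, 200), 0)
  m10 <- noiseless_matrix(c(20200, 30000 + 200), 10)
  # gene 2's wave leaves the window at 10 min: excluded, counted
  pg <- per_gene_rates(list(m0, m10), c(0, 10))
  expect_equal(pg$n_excluded, 1L)
  expect_lt(abs(pg$per_gene_rates[1] - 2.0), 0.1)

  # two genes with clean 20- and 30-kb advances: rates {2, 3}, sd ~ 0.707
  m10b <- noiseless_matrix(c(20200, 29000), 10)
  pg2 <- per_gene_rates(list(m0, m10b), c(0, 10))
  expect_equal(pg2$n_genes, 2L)
  expect_lt(abs(pg2$per_gene_rates[1] - 2.0), 0.1)
  expect_lt(abs(pg2$per_gene_rates[2] - 2.9), 0.1)
  expect_equal(pg2$sd_across_genes,
               stats::sd(pg2$per_gene_rates), tolerance = 1e-12)
  # noiseless spread: sd below one bin width / 10 min
  m10c <- noiseless_matrix(c(20200, 20200), 10)
  pg3 <- per_gene_rates(list(m0, m10c), c(0, 10))
  expect_lt(pg3$sd_across_genes, 200 / 10 / 1000)

  expect_error(per_gene_rates(list(noiseless_matrix(0, 0)), 0),
               class = "polwave_estimation_error")
  expect_error(per_gene_rates(list(m0, noiseless_matrix(c(0, 0, 0), 10)),
                              c(0, 10)),
               class = "polwave_param_error")
})

test_that("peak positions advance with time on simulated metagenes", {
  co <- small_cohort()
  mats <- cohort_matrices(co, "wt", "nascent")
  fits <- lapply(names(mats), function(tl)
    fit_wave(metagene(mats[[tl]]),
             exclusion_zone_bp = if (tl == "0") 0 else 500,
             timepoint_min = as.numeric(tl)))
  fronts <- vapply(fits, `[[`, numeric(1), "front_pos_bp")
  expect_true(all(diff(fronts) > 0))
  # the 10-min metagene maximum lies beyond the 5-min maximum
  mg5 <- metagene(mats[["5"]]); mg10 <- metagene(mats[["10"]])
  expect_gt(fits[[3]]$front_pos_bp, fits[[2]]$front_pos_bp)
})

test_that("estimated rate is invariant under uniform depth scaling", {
  co <- small_cohort()
  mats <- cohort_matrices(co, "wt", "nascent")
  est1 <- estimate_rate(list(
    fit_wave(metagene(mats[["0"]]), exclusion_zone_bp = 0,
             timepoint_min = 0),
    fit_wave(metagene(mats[["10"]]), timepoint_min = 10)))
  scaled <- lapply(mats, function(m) { m$values <- m$values * 7; m })
  est7 <- estimate_rate(list(
    fit_wave(metagene(scaled[["0"]]), exclusion_zone_bp = 0,
             timepoint_min = 0),
    fit_wave(metagene(scaled[["10"]]), timepoint_min = 10)))
  expect_equal(est7$rate_kb_per_min, est1$rate_kb_per_min,
               tolerance = 1e-9)
})
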