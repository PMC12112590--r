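test_that("parameter invariants are enforced", {
  expect_error(sim_params(speed_kb_per_min = NaN), class = "polwave_param_error")
  expect_error(sim_params(termination_hazard_per_kb = -1),
               class = "polwave_param_error")
  expect_error(sim_params(timepoints_min = c(10, 5)),
               class = "polwave_param_error")
  expect_error(sim_params(timepoints_min = c(0, 5),
                          label_windows = list(c(0, 0), c(5, 4))),
               class = "polwave_param_error")
  p <- sim_params(release_rate_per_min = "instantaneous")
  expect_true(is.infinite(p$release_rate_per_min))
})

test_that("deterministic limits: hazard 0 and speed 0", {
  # hazard = 0, instantaneous release: every polymerase at pause + v t,
  # capped at the gene end
  p <- sim_params(speed_kb_per_min = 2.5, termination_hazard_per_kb = 0,
                  timepoints_min = c(0, 10), seed = 5)
  traj <- simulate_polymerases(p, gene_length_bp = 100000, n_pol = 50)
  pos <- polwave:::pol_positions(traj, 10)
  expect_true(all(pos == 25050))
  short <- simulate_polymerases(p, gene_length_bp = 20000, n_pol = 50)
  pos_s <- polwave:::pol_positions(short, 10)
  expect_true(all(is.na(pos_s)))         # ran off the 20-kb gene end
  expect_true(all(short$end_pos_bp == 20000))

  p0 <- sim_params(speed_kb_per_min = 0, termination_hazard_per_kb = 0,
                   timepoints_min = c(0, 5, 10), seed = 5)
  t0 <- simulate_polymerases(p0, 50000, 20)
  for (t in c(0, 5, 10))
    expect_true(all(polwave:::pol_positions(t0, t) == 50))
})

test_that("survival to distance follows exp(-hazard * d)", {
  p <- sim_params(speed_kb_per_min = 2, termination_hazard_per_kb = 0.05,
                  timepoints_min = c(0, 10), seed = 42)
  traj <- simulate_polymerases(p, gene_length_bp = 1e6, n_pol = 10000)
  for (d_kb in c(5, 10, 20)) {
    expected <- exp(-0.05 * d_kb)
    observed <- mean(traj$term_dist_bp > d_kb * 1000)
    se <- sqrt(expected * (1 - expected) / 10000)
    expect_lt(abs(observed - expected), 3 * se)
  }
})

test_that("nascent rendering matches the analytic synthesis model", {
  p <- sim_params(speed_kb_per_min = 2, termination_hazard_per_kb = 0,
                  timepoints_min = c(0, 10), read_depth_per_kb = 50,
                  seed = 9)
  traj <- simulate_polymerases(p, gene_length_bp = 50000, n_pol = 100)
  nt <- render_nascent_track(traj, p, 10, bin_bp = 200)
  # uniform expected signal from the pause site to the front at v t
  mid <- nt$edges[-length(nt$edges)] >= 200 & nt$edges[-1] <= 20000
  expect_true(all(abs(nt$expected[mid] - 50 * 0.2) < 1e-9))
  beyond <- nt$edges[-length(nt$edges)] >= 20200
  expect_true(all(nt$expected[beyond] == 0))
  # the first bin holds the pause-to-bin-edge fraction
  expect_equal(nt$expected[1], 50 * 0.2 * (200 - 50) / 200)

  # wave front of the noiseless track equals pause + v t within one bin
  front_bin <- max(which(nt$expected > 0))
  expect_lte(abs(nt$edges[front_bin + 1] - (50 + 20000)), 200)

  # linearity in depth; zero depth kills the track
  p2 <- sim_params(speed_kb_per_min = 2, termination_hazard_per_kb = 0,
                   timepoints_min = c(0, 10), read_depth_per_kb = 100,
                   seed = 9)
  nt2 <- render_nascent_track(traj, p2, 10, bin_bp = 200)
  expect_equal(nt2$expected, 2 * nt$expected)
  p0 <- sim_params(speed_kb_per_min = 2, termination_hazard_per_kb = 0,
                   timepoints_min = c(0, 10), read_depth_per_kb = 0,
                   seed = 9)
  nt0 <- render_nascent_track(traj, p0, 10, bin_bp = 200)
  expect_true(all(nt0$counts == 0))
  expect_error(render_nascent_track(traj, p, 10, bin_bp = 0),
               class = "polwave_param_error")
  expect_error(render_nascent_track(traj, p, 7),
               class = "polwave_param_error")
})

test_that("polii rendering: arrest concentration and conservation", {
  p <- sim_params(speed_kb_per_min = 2, termination_hazard_per_kb = 0,
                  release_rate_per_min = 0.5,
                  timepoints_min = c(0, 5, 10), seed = 13)
  traj <- simulate_polymerases(p, gene_length_bp = 100000, n_pol = 500)
  pt0 <- render_polii_track(traj, p, 0, bin_bp = 200)
  expect_equal(sum(pt0$expected > 0), 1L)   # all at the pause-site bin
  expect_gt(pt0$expected[1], 0)
  # hazard = 0, no runoff (front 20 kb << 100 kb): engaged count conserved
  tot <- sapply(c(0, 5, 10), function(t)
    sum(render_polii_track(traj, p, t, bin_bp = 200)$expected))
  expect_equal(tot[1], tot[2])
  expect_equal(tot[1], tot[3])
})

test_that("hazard drains gene-body occupancy between 5 and 10 min", {
  p <- sim_params(speed_kb_per_min = 2, termination_hazard_per_kb = 0.08,
                  timepoints_min = c(0, 5, 10), seed = 21)
  traj <- simulate_polymerases(p, gene_length_bp = 200000, n_pol = 5000)
  occ <- function(t) sum(render_polii_track(traj, p, t, 200)$expected)
  expect_lt(occ(10), occ(5))
})

test_that("terminated-RNA retention flag changes the nascent track", {
  mk <- function(keep) {
    p <- sim_params(speed_kb_per_min = 2, termination_hazard_per_kb = 0.2,
                    timepoints_min = c(0, 10), keep_terminated_rna = keep,
                    seed = 33)
    traj <- simulate_polymerases(p, gene_length_bp = 100000, n_pol = 2000)
    sum(render_nascent_track(traj, p, 10, 200)$expected)
  }
  expect_gt(mk(TRUE), mk(FALSE))
})

test_that("cohort generation: constraints, truth and byte determinism", {
  co <- small_cohort()
  len <- GenomicRanges::width(co$annotation)
  expect_true(all(len >= 30000 & len <= 300000))
  expect_true(all(co$truth$n_terminated <= co$truth$n_polymerases_released))
  # non-overlapping placement
  expect_true(GenomicRanges::isDisjoint(co$annotation))

  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(co, d1); write_cohort(co, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))

  # truth table round-trips losslessly through its TSV form
  tr <- read.table(file.path(d1, "truth.tsv"), header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  expect_equal(tr, co$truth, ignore_attr = TRUE)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("KO-like parameters yield less labeled signal than WT at 10 min", {
  co <- small_cohort()
  sig <- cohort_signals(co)
  expect_lt(sig$ko$nascent[["10"]]$total, sig$wt$nascent[["10"]]$total)
})

test_that("layout guard raises a layout error", {
  p <- sim_params(seed = 2)
  expect_error(simulate_cohort(p, n_genes = 5, max_chrom_size_bp = 40000,
                               seed = 2),
               class = "polwave_layout_error")
  expect_error(simulate_cohort(p, n_genes = 0, seed = 2),
               class = "polwave_param_error")
})
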