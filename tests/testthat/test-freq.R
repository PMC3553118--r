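freq_pm <- function() data.frame(probe_id = sprintf("p%02d", 1:8),
                                 chrom = rep(1L, 8),
                                 pos = seq(100, 800, by = 100))

test_that("probe states follow the strict threshold rule", {
  seg <- data.frame(sample_id = "A", chrom = 1L,
                    start_bp = c(50, 401), end_bp = c(400, 900),
                    span_bp = c(351, 500), n_probes = c(4L, 4L),
                    mean_log2 = c(0.25, -0.05))
  st <- call_states(seg, freq_pm(), gain_threshold = 0.1, loss_threshold = -0.1)
  expect_equal(st, c(rep("gain", 4), rep("neutral", 4)))

  # a mean exactly at the threshold is neutral
  seg$mean_log2 <- c(0.1, -0.1)
  st <- call_states(seg, freq_pm())
  expect_equal(unique(st), "neutral")

  # all-zero means are neutral everywhere
  seg$mean_log2 <- c(0, 0)
  expect_equal(unique(call_states(seg, freq_pm())), "neutral")
})

test_that("frequencies count samples correctly and stay in [0, 1]", {
  pm <- freq_pm()
  seg <- rbind(
    data.frame(sample_id = "A", chrom = 1L, start_bp = 50, end_bp = 400,
               span_bp = 351, n_probes = 4L, mean_log2 = 0.8),
    data.frame(sample_id = "A", chrom = 1L, start_bp = 401, end_bp = 900,
               span_bp = 500, n_probes = 4L, mean_log2 = 0),
    data.frame(sample_id = "B", chrom = 1L, start_bp = 50, end_bp = 400,
               span_bp = 351, n_probes = 4L, mean_log2 = 0),
    data.frame(sample_id = "B", chrom = 1L, start_bp = 401, end_bp = 900,
               span_bp = 500, n_probes = 4L, mean_log2 = 0.8))
  fr <- frequency_track(seg, pm)
  # disjoint gains: every probe gained in exactly one of two samples
  expect_equal(fr$gain_frequency, rep(0.5, 8))
  expect_equal(fr$loss_frequency, rep(0, 8))
  expect_true(all(fr$gain_frequency + fr$loss_frequency <= 1))
  # order of samples irrelevant
  fr2 <- frequency_track(seg[c(3, 4, 1, 2), ], pm)
  expect_equal(fr2$gain_frequency, fr$gain_frequency)
})

test_that("raising the gain threshold never increases gain frequencies", {
  set.seed(12)
  p <- sim_params(n_samples = 6, n_probes = 800, seed = 12)
  co <- simulate_cohort(p)
  seg <- segment_profiles(co$cn, pipeline_config())
  f1 <- frequency_track(seg, co$cn$probe_map, gain_threshold = 0.1)
  f2 <- frequency_track(seg, co$cn$probe_map, gain_threshold = 0.3)
  expect_true(all(f2$gain_frequency <= f1$gain_frequency + 1e-12))
})

test_that("noise-free cohort frequencies equal truth-derived frequencies", {
  p <- sim_params(n_samples = 8, n_probes = 1500, noise_sd = 0,
                  length_range = c(2e7, 1e8), seed = 13)
  co <- simulate_cohort(p)
  cfg <- pipeline_config(gamma = 1e-6, min_probes = 1,
                         center = FALSE, normalize = FALSE)
  seg <- segment_profiles(co$cn, cfg)
  fr <- frequency_track(seg, co$cn$probe_map, 0.1, -0.1)
  # truth: per-probe gain/loss from the clean probe values themselves
  expected_gain <- rowMeans(co$cn$values > 0.1)
  expected_loss <- rowMeans(co$cn$values < -0.1)
  expect_equal(fr$gain_frequency, expected_gain, tolerance = 1e-12)
  expect_equal(fr$loss_frequency, expected_loss, tolerance = 1e-12)
})

test_that("grid averages reproduce a flat genome and identical cohorts", {
  seg <- data.frame(sample_id = "A", chrom = c(1L, 2L),
                    start_bp = c(1, 1), end_bp = c(5e6, 3e6),
                    span_bp = c(5e6, 3e6), n_probes = c(10L, 10L),
                    mean_log2 = c(0.2, 0.2))
  g <- grid_average(seg, grid_spacing_bp = 1e6)
  expect_true(all(g$mean_log2 == 0.2))
  expect_equal(sum(g$chrom == 1L), 5L)  # loci at 1, 1e6+1, ..., 4e6+1
  expect_true(all(diff(g$pos[g$chrom == 1L]) == 1e6))

  # two cohorts with identical segmentations give identical tracks
  p <- sim_params(n_samples = 5, n_probes = 700, seed = 14)
  co <- simulate_cohort(p)
  seg2 <- segment_profiles(co$cn, pipeline_config())
  ga <- grid_average(seg2, 1e6)
  gb <- grid_average(seg2, 1e6)
  expect_identical(ga, gb)
})

test_that("independently noised replicate cohorts give concordant grid tracks", {
  # same true segment profiles, two independent noise draws: the paired
  # per-locus averages should be strongly correlated
  p0 <- sim_params(n_samples = 15, n_probes = 4000, noise_sd = 0, seed = 15)
  set.seed(15); pm <- make_probe_map(p0)
  set.seed(101); a0 <- simulate_profiles(p0, pm)
  set.seed(201); b_vals <- a0$values + rnorm(length(a0$values), 0, 0.15)
  set.seed(202); c_vals <- a0$values + rnorm(length(a0$values), 0, 0.15)
  cfg <- pipeline_config()
  mk <- function(v) structure(list(probe_map = pm, values = v), class = "cn_profiles")
  g1 <- grid_average(segment_profiles(mk(b_vals), cfg), 1e6)
  g2 <- grid_average(segment_profiles(mk(c_vals), cfg), 1e6)
  ok <- !is.na(g1$mean_log2) & !is.na(g2$mean_log2)
  expect_gt(cor(g1$mean_log2[ok], g2$mean_log2[ok]), 0.9)
})
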