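test_that("constant and step series are segmented in closed form", {
  fit <- pcf(rep(0.3, 10), gamma = 5)
  expect_length(fit$start, 1L)
  expect_equal(fit$mean, 0.3)
  expect_equal(fit$cost, 0)

  y <- c(rep(0, 6), rep(1, 6))
  # one-segment cost = SSE around 0.5 = 3.0; two-segment cost = gamma
  lo <- pcf(y, gamma = 0.5, min_probes = 3)
  expect_equal(lo$start, c(1L, 7L))
  expect_equal(lo$mean, c(0, 1))
  expect_equal(lo$cost, 0.5)
  hi <- pcf(y, gamma = 10, min_probes = 3)
  expect_length(hi$start, 1L)
  expect_equal(hi$mean, 0.5)
  expect_equal(hi$cost, 3.0)
})

test_that("series shorter than min_probes become a single segment", {
  fit <- pcf(c(0.1, 0.9), gamma = 1, min_probes = 3)
  expect_length(fit$start, 1L)
  expect_equal(fit$mean, 0.5)
})

test_that("non-finite input is rejected", {
  expect_error(pcf(c(0, NA, 1)), "non-finite")
  expect_error(pcf(numeric(0)), "empty")
})

test_that("dynamic program matches exhaustive enumeration on short series", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(5:14, 1)
    m <- if (n <= 10) sample(1:3, 1) else sample(2:3, 1)
    y <- round(rnorm(n, sd = sample(c(0.2, 1), 1)), 3)
    gamma <- runif(1, 0.05, 3)
    fit <- pcf(y, gamma = gamma, min_probes = m)
    expect_equal(fit$cost, brute_force_pcf_cost(y, gamma, m), tolerance = 1e-9)
  }
})

test_that("fitted means are within-segment arithmetic means", {
  set.seed(2)
  y <- rnorm(200) + rep(c(0, 1.5, -1), c(70, 60, 70))
  fit <- pcf(y, gamma = 8)
  for (k in seq_along(fit$start))
    expect_equal(fit$mean[k], mean(y[fit$start[k]:fit$end[k]]), tolerance = 1e-12)
  # residuals orthogonal to segment indicators
  r <- residuals(fit)
  for (k in seq_along(fit$start))
    expect_lt(abs(sum(r[fit$start[k]:fit$end[k]])), 1e-9)
})

test_that("segment count is non-increasing in gamma", {
  set.seed(3)
  for (rep in 1:5) {
    y <- rnorm(120) + rep(sample(c(-1, 0, 0.7, 2), 4), c(30, 30, 30, 30))
    counts <- vapply(c(0.1, 0.5, 1, 2, 5, 10, 40, 200),
                     function(g) length(pcf(y, gamma = g)$start), 0L)
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("no returned segment can be split with SSE gain above gamma", {
  set.seed(4)
  y <- rnorm(150) + rep(c(0, 1), c(80, 70))
  gamma <- 6; m <- 3
  fit <- pcf(y, gamma = gamma, min_probes = m)
  sse <- function(v) sum((v - mean(v))^2)
  for (k in seq_along(fit$start)) {
    seg <- y[fit$start[k]:fit$end[k]]
    n <- length(seg)
    if (n < 2 * m) next
    for (cut in m:(n - m)) {
      gain <- sse(seg) - sse(seg[1:cut]) - sse(seg[(cut + 1):n])
      expect_lte(gain, gamma + 1e-9)
    }
  }
})

test_that("cost ties break toward fewer segments", {
  # perfectly constant series: any split has identical SSE (0) but more
  # penalty; with gamma ~ 0 the DP must still return one segment
  fit <- pcf(rep(1, 12), gamma = 1e-12, min_probes = 3)
  expect_length(fit$start, 1L)
})

test_that("profiles are segmented per chromosome with missing probes dropped", {
  pm <- data.frame(probe_id = sprintf("p%02d", 1:20),
                   chrom = rep(c(1L, 2L), each = 10),
                   pos = rep(seq(1e6, 10e6, by = 1e6), 2))
  vals <- matrix(c(rep(0, 5), rep(2, 5), rep(0.5, 10)), ncol = 1,
                 dimnames = list(NULL, "S1"))
  vals[3, 1] <- NA  # dropped before fitting
  cn <- structure(list(probe_map = pm, values = vals), class = "cn_profiles")
  cfg <- pipeline_config(gamma = 0.5, center = FALSE, normalize = FALSE)
  seg <- segment_profiles(cn, cfg)
  expect_setequal(unique(seg$chrom), c(1L, 2L))
  c1 <- seg[seg$chrom == 1L, ]
  expect_equal(nrow(c1), 2L)
  expect_equal(c1$mean_log2, c(0, 2))
  expect_equal(sum(c1$n_probes), 9L)  # one missing probe dropped
  # chromosome tiling: gap-free, spans sum to covered range
  expect_equal(c1$start_bp[2], c1$end_bp[1] + 1)
  expect_equal(sum(c1$span_bp), max(c1$end_bp) - min(c1$start_bp) + 1)
})

test_that("a chromosome with only missing values is omitted with a warning", {
  pm <- data.frame(probe_id = sprintf("p%02d", 1:10),
                   chrom = rep(c(1L, 2L), each = 5),
                   pos = rep(seq(1e6, 5e6, by = 1e6), 2))
  vals <- matrix(c(rep(0.2, 5), rep(NA_real_, 5)), ncol = 1,
                 dimnames = list(NULL, "S1"))
  cn <- structure(list(probe_map = pm, values = vals), class = "cn_profiles")
  expect_warning(seg <- segment_profiles(cn, pipeline_config(center = FALSE)),
                 "no non-missing probes")
  expect_equal(unique(seg$chrom), 1L)
})

test_that("noise-free simulated profiles are segmented at the true breakpoints", {
  p <- sim_params(n_samples = 3, n_probes = 3000, noise_sd = 0,
                  aberrations_per_sample_mean = 6,
                  length_range = c(2e7, 1e8), seed = 5)
  co <- simulate_cohort(p)
  cfg <- pipeline_config(gamma = 1e-6, min_probes = 1,
                         center = FALSE, normalize = FALSE)
  seg <- segment_profiles(co$cn, cfg)
  tt <- tai_table(seg)
  expect_equal(tt$tai[order(tt$sample_id)],
               co$truth$samples$true_tai[order(co$truth$samples$sample_id)],
               tolerance = 1e-9)
})
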