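test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kaplan_meier(c(1, 2, 3, 4, 5, 6), c(1, 1, 0, 1, 0, 1))
  s_at <- function(t) km$surv[max(which(km$time <= t))]
  expect_equal(s_at(1), 5 / 6)
  expect_equal(s_at(2), 5 / 6 * 4 / 5)
  expect_equal(s_at(4), 5 / 6 * 4 / 5 * 2 / 3)  # = 4/9 = 0.4444
})

test_that("Kaplan-Meier limits: no censoring and all censored", {
  t <- c(2, 5, 7, 9)
  km <- kaplan_meier(t, rep(1, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))  # empirical survival
  km0 <- kaplan_meier(t, rep(0, 4))
  expect_true(all(km0$surv == 1))
  expect_true(is.na(km0$median))
})

test_that("log-rank matches the direct O/E/V computation and its symmetries", {
  set.seed(21)
  time <- c(rexp(20, 0.1), rexp(20, 0.25))
  event <- rbinom(40, 1, 0.85)
  group <- rep(c("a", "b"), each = 20)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chisq, logrank_by_hand(time, event, group == "a"),
               tolerance = 1e-9)
  # label swap changes nothing
  lr2 <- logrank_test(time, event, ifelse(group == "a", "b", "a"))
  expect_equal(lr2$chisq, lr$chisq, tolerance = 1e-12)

  # identical groups: duplicated data gives chi-square 0, p 1
  lr0 <- logrank_test(rep(time, 2), rep(event, 2), rep(c("a", "b"), each = 40))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  expect_error(logrank_test(time, rep(0, 40), group), "no events")
})

test_that("Cox fit matches a grid search of the partial likelihood", {
  time <- c(4, 7, 10); event <- c(1, 1, 1); x <- c(1.2, -0.3, 0.5)
  fit <- cox_fit(time, event, data.frame(x = x))
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, cox_logpl, 0, time = time, event = event, x = x)
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 1e-3)
})

test_that("Cox fit is invariant to monotone time transformation", {
  set.seed(22)
  time <- rexp(60, 0.1) + runif(60, 0, 1e-4)  # untied
  event <- rbinom(60, 1, 0.8)
  x <- rnorm(60)
  b1 <- cox_fit(time, event, data.frame(x = x))$beta
  b2 <- cox_fit(time^2, event, data.frame(x = x))$beta
  expect_equal(b1, b2, tolerance = 1e-8)
})

test_that("Cox null and effect recovery at large n", {
  set.seed(23)
  n <- 2000
  x <- rnorm(n)
  t0 <- rexp(n, 0.05)                # independent of x
  fit0 <- cox_fit(t0, rep(1, n), data.frame(x = x))
  expect_lt(abs(fit0$beta), 0.1)

  g <- rbinom(n, 1, 0.5)             # true HR = 2
  t1 <- rexp(n, 0.05 * 2^g)
  fit1 <- cox_fit(t1, rep(1, n), data.frame(g = g))
  expect_gte(fit1$hr, 1.8)
  expect_lte(fit1$hr, 2.2)
  expect_true(fit1$ci_lower < fit1$hr & fit1$hr < fit1$ci_upper)
})

test_that("Cox fit rejects degenerate inputs", {
  expect_error(cox_fit(c(1, 2, 3), c(1, 0, 0), data.frame(x = 1:3)), "2 events")
  expect_error(cox_fit(c(1, 2, 3), c(1, 1, 1), data.frame(x = rep(1, 3))), "constant")
  expect_error(cox_fit(c(1, 2, 3), c(1, 1, 1), data.frame(x = c(1, NA, 2))), "non-finite")
})

test_that("KM median CI covers the KM median at roughly nominal rate", {
  set.seed(24)
  hits <- 0L; reps <- 60L
  for (r in seq_len(reps)) {
    lat <- rexp(80, log(2) / 30)       # true median survival = 30
    cens <- rexp(80, 0.01)
    km <- kaplan_meier(pmin(lat, cens), as.integer(lat <= cens))
    if (!is.na(km$median_ci[1]) && !is.na(km$median_ci[2]) &&
        km$median_ci[1] <= 30 && 30 <= km$median_ci[2])
      hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("the survival summary has the expected shape and direction", {
  p <- sim_params(n_samples = 120, n_probes = 100, beta_tai = -0.6, seed = 25)
  co <- simulate_cohort(p)
  tt <- data.frame(sample_id = co$truth$samples$sample_id,
                   tai = co$truth$samples$true_tai,
                   group = median_split(co$truth$samples$true_tai),
                   z = co$truth$samples$z)
  t2 <- build_table2(co$clinical, tt)
  expect_named(t2, c("pfs", "os"))
  for (ep in names(t2)) {
    expect_named(t2[[ep]], c("logrank", "cox_univariate", "cox_multivariate",
                             "n", "n_events"))
    expect_equal(nrow(t2[[ep]]$cox_multivariate), 4L)  # z + age + stage + grade
  }
  # protective simulated effect: HR per SD below 1 for OS
  expect_lt(t2$os$cox_univariate$hr[1], 1)
  # deterministic given input
  t2b <- build_table2(co$clinical, tt)
  expect_equal(t2b$os$cox_univariate$beta, t2$os$cox_univariate$beta)

  # indicator coding is also accepted
  t2c <- build_table2(co$clinical, tt, ordinal_covariates = FALSE)
  expect_gte(nrow(t2c$os$cox_multivariate), 4L)
})
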