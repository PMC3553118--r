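# Independent brute-force oracles used to validate the fast implementations.

# All compositions of n into parts >= m (ordered), as a list of integer vectors.
compositions_min <- function(n, m) {
  if (n < m) return(list())
  out <- list(n)
  if (n >= 2 * m) {
    for (first in m:(n - m)) {
      for (rest in compositions_min(n - first, m)) out <- c(out, list(c(first, rest)))
    }
  }
  out
}

# Exhaustive minimum of the penalized segmentation objective.
brute_force_pcf_cost <- function(y, gamma, min_probes) {
  n <- length(y)
  if (n < min_probes) {
    return(sum((y - mean(y))^2))
  }
  best <- Inf
  for (parts in compositions_min(n, min_probes)) {
    ends <- cumsum(parts)
    starts <- c(1L, head(ends, -1L) + 1L)
    sse <- sum(vapply(seq_along(parts), function(k) {
      v <- y[starts[k]:ends[k]]; sum((v - mean(v))^2)
    }, 0))
    best <- min(best, sse + gamma * (length(parts) - 1L))
  }
  best
}

# Two-sided Fisher exact p by full enumeration over the hypergeometric
# support, via log-factorial arithmetic.
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p_obs <- logp[support == a]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# Exact two-sided permutation p for the Mann-Whitney U (deviation of the
# rank sum from its null mean), enumerating all group assignments.
mw_exact_perm_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  null_mean <- n1 * (N + 1) / 2
  dev_obs <- abs(sum(r[seq_len(n1)]) - null_mean)
  cmb <- utils::combn(N, n1)
  devs <- abs(colSums(matrix(r[cmb], nrow = n1)) - null_mean)
  mean(devs >= dev_obs - 1e-9)
}

# Direct observed-minus-expected log-rank chi-square from the O/E/V table.
logrank_by_hand <- function(time, event, in_group1) {
  chisq_num <- 0; ev <- 0
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    nt <- sum(at_risk); n1t <- sum(at_risk & in_group1)
    dt <- sum(time == t & event == 1)
    d1t <- sum(time == t & event == 1 & in_group1)
    O <- O + d1t
    E <- E + dt * n1t / nt
    if (nt > 1) V <- V + dt * (n1t / nt) * (1 - n1t / nt) * (nt - dt) / (nt - 1)
  }
  (O - E)^2 / V
}

# Cox log partial likelihood for a single covariate without tied event
# times (Breslow = Efron in that case); used for grid-search checks.
cox_logpl <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Tiny deterministic segmentation fixture: two samples, two chromosomes.
tiny_segmentation <- function() {
  structure(data.frame(
    sample_id = c("A", "A", "A", "B", "B"),
    chrom = c(1L, 1L, 2L, 1L, 2L),
    start_bp = c(1, 101, 1, 1, 1),
    end_bp = c(100, 400, 200, 400, 200),
    span_bp = c(100, 300, 200, 400, 200),
    n_probes = c(3L, 5L, 4L, 8L, 4L),
    mean_log2 = c(0.4, -0.2, 0, 0.1, -0.5),
    stringsAsFactors = FALSE),
    class = c("cn_segmentation", "data.frame"))
}

# Minimal clinical table generator for interface tests.
tiny_clinical <- function(n = 6, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             age = round(runif(n, 40, 75), 1),
             stage = sample(c(3L, 4L), n, TRUE),
             grade = sample(1:3, n, TRUE),
             chemo_response = sample(c("sensitive", "resistant"), n, TRUE),
             pfs_months = round(rexp(n, 1 / 15), 1) + 0.1,
             pfs_event = rbinom(n, 1, 0.8),
             os_months = round(rexp(n, 1 / 30), 1) + 0.1,
             os_event = rbinom(n, 1, 0.8),
             stringsAsFactors = FALSE)
}
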