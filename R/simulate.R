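# Approximate human chromosome lengths (1-22, X) in bp; hg-like proportions
# totalling ~3.1 Gb. The exact build is irrelevant to every statistic the
# package computes -- only relative lengths matter.
default_chrom_lengths <- function() {
  1e6 * c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
          115, 107, 102, 90, 81, 78, 59, 63, 48, 51, 155)
}

#' Parameters of the synthetic-cohort generator
#'
#' Defines the data-generating model used throughout testing: per sample, a
#' Poisson number of non-overlapping aberrant genomic intervals with
#' log-uniform lengths and discrete clean log2 levels; the observed level of
#' an aberration is attenuated by the sample's tumour-cell fraction as
#' `log2(tf * 2^level + (1 - tf))` (a linear mixture of tumour and normal
#' DNA, then logged); probe values add Gaussian noise. Clinical outcomes are
#' linked to the true TAI: overall survival is exponential with log-hazard
#' `beta_tai` per SD of true TAI, with independent exponential censoring,
#' and chemotherapy response is Bernoulli with a logistic link on the same
#' z-score.
#'
#' Defaults emulate a serous ovarian carcinoma array cohort: 20,000 probes
#' over chromosomes 1-23, a mean of 15 aberrations per sample spanning
#' 2-120 Mb, gain/loss levels of about one copy (log2 ratios +-0.58, +-1)
#' plus rare homozygous deletions (-3.3), tumour fractions 20-90%,
#' probe noise SD 0.15, baseline hazard log(2)/32 per month (median
#' survival 32 months in the untransformed group), a protective TAI effect
#' (`beta_tai = -0.5` per SD), and light independent censoring.
#'
#' @param n_samples number of samples (required).
#' @param n_probes total probes across the genome (>= 23; default 20000).
#' @param chromosome_lengths 23 chromosome lengths, bp.
#' @param aberrations_per_sample_mean Poisson mean number of aberrant
#'   intervals per sample.
#' @param length_range bp range of aberration lengths (log-uniform).
#' @param amplitude_levels,amplitude_probs discrete clean log2 levels of
#'   aberrations and their probabilities.
#' @param tumour_fraction_range uniform range of tumour-cell fraction.
#' @param noise_sd probe-level Gaussian noise SD.
#' @param beta_tai log-hazard per SD of true TAI (negative = protective).
#' @param baseline_hazard exponential event rate per month at z = 0.
#' @param censor_rate exponential censoring rate per month (0 = none).
#' @param chemo_logit_slope slope of the logistic link for chemotherapy
#'   sensitivity on the TAI z-score.
#' @param seed integer seed.
#' @returns A validated list of class `"sim_params"`.
#' @export
sim_params <- function(n_samples, n_probes = 20000L,
                       chromosome_lengths = default_chrom_lengths(),
                       aberrations_per_sample_mean = 15,
                       length_range = c(2e6, 1.2e8),
                       amplitude_levels = c(0.58, -0.58, 1, -1, -3.3),
                       amplitude_probs = c(0.3, 0.3, 0.175, 0.175, 0.05),
                       tumour_fraction_range = c(0.2, 0.9),
                       noise_sd = 0.15, beta_tai = -0.5,
                       baseline_hazard = log(2) / 32, censor_rate = 0.007,
                       chemo_logit_slope = 0.5, seed = 1L) {
  p <- list(n_samples = as.integer(n_samples), n_probes = as.integer(n_probes),
            chromosome_lengths = as.numeric(chromosome_lengths),
            aberrations_per_sample_mean = aberrations_per_sample_mean,
            length_range = as.numeric(length_range),
            amplitude_levels = as.numeric(amplitude_levels),
            amplitude_probs = as.numeric(amplitude_probs),
            tumour_fraction_range = as.numeric(tumour_fraction_range),
            noise_sd = noise_sd, beta_tai = beta_tai,
            baseline_hazard = baseline_hazard, censor_rate = censor_rate,
            chemo_logit_slope = chemo_logit_slope, seed = as.integer(seed))
  stopifnot(p$n_samples >= 1, p$n_probes >= 23,
            length(p$chromosome_lengths) == 23, all(p$chromosome_lengths > 0),
            p$aberrations_per_sample_mean >= 0,
            length(p$length_range) == 2, p$length_range[1] > 0,
            p$length_range[1] <= p$length_range[2],
            length(p$amplitude_levels) == length(p$amplitude_probs),
            all(p$amplitude_probs >= 0), sum(p$amplitude_probs) > 0,
            length(p$tumour_fraction_range) == 2,
            p$tumour_fraction_range[1] > 0, p$tumour_fraction_range[2] <= 1,
            p$tumour_fraction_range[1] <= p$tumour_fraction_range[2],
            p$noise_sd >= 0, p$baseline_hazard > 0, p$censor_rate >= 0)
  class(p) <- "sim_params"
  p
}

#' Generate a random probe map
#'
#' Probes are allocated to chromosomes proportionally to chromosome length
#' (largest-remainder rounding, at least one probe per chromosome) and
#' placed uniformly at random; positions are sorted and made strictly
#' increasing by +1 bp shifts at ties.
#'
#' @param params a [sim_params()] object.
#' @returns A probe-map data.frame (`probe_id`, `chrom`, `pos`).
#' @export
make_probe_map <- function(params) {
  L <- params$chromosome_lengths
  n <- params$n_probes
  frac <- n * L / sum(L)
  cnt <- pmax(1L, floor(frac))
  short <- n - sum(cnt)
  if (short > 0) {
    extra <- order(frac - floor(frac), decreasing = TRUE)
    cnt[extra[seq_len(short)]] <- cnt[extra[seq_len(short)]] + 1L
  } else if (short < 0) {
    # min-1 floors overshot: trim from the largest allocations
    take <- order(cnt, decreasing = TRUE)
    i <- 1L
    while (short < 0) {
      if (cnt[take[i]] > 1L) { cnt[take[i]] <- cnt[take[i]] - 1L; short <- short + 1L }
      i <- if (i == 23L) 1L else i + 1L
    }
  }
  rows <- lapply(1:23, function(cc) {
    p <- sort(floor(stats::runif(cnt[cc]) * L[cc]) + 1)
    if (cnt[cc] > 1L) for (i in 2:cnt[cc]) if (p[i] <= p[i - 1L]) p[i] <- p[i - 1L] + 1
    data.frame(chrom = cc, pos = p)
  })
  pm <- do.call(rbind, rows)
  data.frame(probe_id = sprintf("P%06d", seq_len(nrow(pm))),
             chrom = pm$chrom, pos = pm$pos, stringsAsFactors = FALSE)
}

# Dilution of a clean log2 level by tumour-cell fraction tf: a linear
# mixture of tumour DNA (relative copy number 2^level) with normal diploid
# DNA, measured on the log2 scale.
dilute_level <- function(level, tf) log2(tf * 2^level + (1 - tf))

# Draw K non-overlapping aberrant intervals; NULL on placement failure.
place_intervals <- function(K, params, max_tries = 50L) {
  if (K == 0L)
    return(data.frame(chrom = integer(0), start = numeric(0), end = numeric(0)))
  L <- params$chromosome_lengths
  lo <- log(params$length_range[1]); hi <- log(params$length_range[2])
  chrom <- integer(K); start <- numeric(K); end <- numeric(K)
  for (k in seq_len(K)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cc <- sample.int(23L, 1L, prob = L)
      len <- min(exp(stats::runif(1, lo, hi)), L[cc])
      s <- floor(stats::runif(1, 1, max(1, L[cc] - len))) + 1
      e <- min(s + len - 1, L[cc])
      prev <- which(chrom[seq_len(k - 1L)] == cc)
      if (!any(s <= end[prev] & e >= start[prev])) {
        chrom[k] <- cc; start[k] <- s; end[k] <- e; ok <- TRUE; break
      }
    }
    if (!ok) return(NULL)
  }
  data.frame(chrom = chrom, start = start, end = end)
}

# Exact TAI of a clean (noise-free) probe profile: run-length encode each
# chromosome into constant segments, convert to bp spans with the shared
# boundary convention, and apply the TAI formula.
true_tai_from_clean <- function(clean, pm) {
  total_span <- 0; total_w <- 0
  for (cc in unique(pm$chrom)) {
    idx <- which(pm$chrom == cc)
    r <- rle(clean[idx])
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    bp <- probe_ranges_to_bp(pm$pos[idx], starts, ends)
    total_span <- total_span + sum(bp$span_bp)
    total_w <- total_w + sum(bp$span_bp * abs(r$values))
  }
  total_w / total_span
}

#' Simulate a synthetic copy-number cohort with ground truth and outcomes
#'
#' Draws a probe map, per-sample aberration profiles (with purity dilution
#' and probe noise) and linked clinical outcomes from the generative model
#' of [sim_params()]. All randomness derives from `params$seed`, so results
#' are fully reproducible.
#'
#' @param params a [sim_params()] object.
#' @returns A list of class `"sim_cohort"`:
#'   \describe{
#'     \item{cn}{`cn_profiles` object (probe map + noisy log2 matrix).}
#'     \item{truth}{list with `samples` (data.frame: `sample_id`,
#'       `tumour_fraction`, `true_tai`, `z`, `linear_predictor`),
#'       `segments` (true aberrant intervals with clean and diluted
#'       levels), and `beta_tai`.}
#'     \item{clinical}{clinical data.frame (see [read_clinical()]).}
#'   }
#' @export
simulate_cohort <- function(params) {
  set.seed(params$seed)
  pm <- make_probe_map(params)
  prof <- simulate_profiles(params, pm)
  clin <- simulate_clinical(params, prof$truth)
  structure(list(cn = structure(list(probe_map = pm, values = prof$values),
                                class = "cn_profiles"),
                 truth = prof$truth, clinical = clin),
            class = "sim_cohort")
}

#' Simulate noisy copy-number profiles over a probe map
#'
#' Uses the current RNG state; call via [simulate_cohort()] for seeded
#' end-to-end generation.
#'
#' @param params a [sim_params()] object.
#' @param pm probe-map data.frame from [make_probe_map()].
#' @returns List with `values` (probes x samples matrix) and `truth` (as in
#'   [simulate_cohort()], without clinical fields).
#' @export
simulate_profiles <- function(params, pm) {
  n <- nrow(pm)
  ns <- params$n_samples
  by_chrom <- split(seq_len(n), pm$chrom)
  vals <- matrix(0, n, ns)
  ids <- sprintf("SIM%03d", seq_len(ns))
  colnames(vals) <- ids
  tf <- numeric(ns); true_tai <- numeric(ns)
  seg_list <- vector("list", ns)

  for (s in seq_len(ns)) {
    iv <- NULL
    for (attempt in 1:100) {
      K <- stats::rpois(1, params$aberrations_per_sample_mean)
      iv <- place_intervals(K, params)
      if (!is.null(iv)) break
      warning(sprintf("sample %s: interval placement failed; regenerating", ids[s]))
    }
    if (is.null(iv)) stop("interval placement failed repeatedly; lower the aberration rate or lengths")
    tf[s] <- stats::runif(1, params$tumour_fraction_range[1],
                          params$tumour_fraction_range[2])
    lev <- if (nrow(iv)) sample(params$amplitude_levels, nrow(iv), replace = TRUE,
                                prob = params$amplitude_probs) else numeric(0)
    dil <- dilute_level(lev, tf[s])
    clean <- numeric(n)
    if (nrow(iv)) for (k in seq_len(nrow(iv))) {
      idx <- by_chrom[[as.character(iv$chrom[k])]]
      hit <- idx[pm$pos[idx] >= iv$start[k] & pm$pos[idx] <= iv$end[k]]
      clean[hit] <- dil[k]
    }
    vals[, s] <- clean + if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd) else 0
    true_tai[s] <- true_tai_from_clean(clean, pm)
    seg_list[[s]] <- if (nrow(iv))
      data.frame(sample_id = ids[s], iv, level = lev, diluted_level = dil,
                 stringsAsFactors = FALSE)
    else NULL
  }
  z <- if (ns >= 2L && stats::sd(true_tai) > 0) tai_zscore(true_tai) else rep(0, ns)
  truth <- list(samples = data.frame(sample_id = ids, tumour_fraction = tf,
                                     true_tai = true_tai, z = z,
                                     linear_predictor = params$beta_tai * z,
                                     stringsAsFactors = FALSE),
                segments = do.call(rbind, seg_list),
                beta_tai = params$beta_tai)
  list(values = vals, truth = truth)
}

#' Simulate clinical outcomes linked to true TAI
#'
#' Overall survival is exponential with rate
#' `baseline_hazard * exp(beta_tai * z)` (z = cohort z-score of true TAI),
#' censored by an independent exponential time at `censor_rate`.
#' Progression-free survival is the latent survival time scaled by
#' Uniform(0.3, 1) with the same censoring time. Chemotherapy sensitivity
#' is Bernoulli(plogis(`chemo_logit_slope` * z)). Age is Normal(58, 11)
#' truncated to [23, 81]; stage is III/IV (0.8/0.2); grade is 1/2/3
#' (0.05/0.3/0.65). Uses the current RNG state; call via
#' [simulate_cohort()] for seeded generation.
#'
#' @param params a [sim_params()] object.
#' @param truth truth list from [simulate_profiles()].
#' @returns A clinical data.frame (columns of [read_clinical()]).
#' @export
simulate_clinical <- function(params, truth) {
  z <- truth$samples$z
  n <- length(z)
  rate <- params$baseline_hazard * exp(params$beta_tai * z)
  os_latent <- stats::rexp(n, rate)
  cens <- if (params$censor_rate > 0) stats::rexp(n, params$censor_rate) else rep(Inf, n)
  pfs_latent <- os_latent * stats::runif(n, 0.3, 1)
  age <- stats::qnorm(stats::runif(n, stats::pnorm(23, 58, 11),
                                   stats::pnorm(81, 58, 11)), 58, 11)
  data.frame(sample_id = truth$samples$sample_id,
             age = round(age, 1),
             stage = sample(c(3L, 4L), n, replace = TRUE, prob = c(0.8, 0.2)),
             grade = sample(1:3, n, replace = TRUE, prob = c(0.05, 0.3, 0.65)),
             chemo_response = ifelse(
               stats::runif(n) < stats::plogis(params$chemo_logit_slope * z),
               "sensitive", "resistant"),
             pfs_months = pmin(pfs_latent, cens),
             pfs_event = as.integer(pfs_latent <= cens),
             os_months = pmin(os_latent, cens),
             os_event = as.integer(os_latent <= cens),
             stringsAsFactors = FALSE)
}
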