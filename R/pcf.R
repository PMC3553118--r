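#' Penalized least-squares piecewise-constant fit (PCF) of an ordered series
#'
#' Fits a piecewise-constant signal to one ordered series of log2 copy-number
#' ratios by exact dynamic programming. The fit minimises
#' \deqn{\sum_{segments} \sum_{i \in seg} (y_i - \bar y_{seg})^2 +
#'       \gamma \,(\mathrm{segments} - 1)}
#' over all segmentations in which every segment contains at least
#' `min_probes` probes. The penalty \eqn{\gamma} per additional breakpoint
#' controls the bias-variance trade-off: larger values give fewer, longer
#' segments. The optimum is exact (no heuristic pruning), computed in
#' O(n^2) by a dynamic program over the last breakpoint; ties in cost are
#' broken toward fewer segments, then toward the earlier breakpoint, so the
#' result is deterministic.
#'
#' If the series is shorter than `min_probes` the whole series is returned
#' as a single segment rather than discarded.
#'
#' @param y numeric vector, ordered (e.g. along one chromosome); must be
#'   finite — drop missing values before calling.
#' @param gamma positive penalty per breakpoint, on the scale of squared
#'   residuals. Default 40 is intended for series pre-divided by their noise
#'   level (see [segment_profiles()], which scales the penalty by a robust
#'   noise estimate instead of rescaling the data).
#' @param min_probes minimum probes per segment (default 3).
#' @returns An object of class `"pcf"`: a list with `start`, `end`
#'   (1-based probe index ranges), `mean` (arithmetic segment means),
#'   `n_probes` per segment, `cost` (penalized objective at the optimum),
#'   `gamma`, `min_probes`, and the input `y`.
#' @seealso [segment_profiles()] for per-chromosome application to whole
#'   profiles, [total_aberration_index()] for the downstream burden score.
#' @examples
#' y <- c(rep(0, 6), rep(1, 6)) + rnorm(12, sd = 0.05)
#' fit <- pcf(y, gamma = 0.5)
#' coef(fit)
#' @export
pcf <- function(y, gamma = 40, min_probes = 3) {
  y <- as.numeric(y)
  if (length(y) == 0L) stop("empty series")
  if (!all(is.finite(y))) stop("series contains non-finite values; drop missing values before segmentation")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("gamma must be a single positive number")
  min_probes <- as.integer(min_probes)
  if (is.na(min_probes) || min_probes < 1L) stop("min_probes must be >= 1")

  n <- length(y)
  if (n < min_probes) {
    starts <- 1L
  } else {
    starts <- .pcf_dp(y, gamma, min_probes)
  }
  ends <- c(starts[-1L] - 1L, n)
  means <- vapply(seq_along(starts), function(k) mean(y[starts[k]:ends[k]]), 0)
  sse <- sum(vapply(seq_along(starts),
                    function(k) sum((y[starts[k]:ends[k]] - means[k])^2), 0))
  structure(list(start = as.integer(starts), end = as.integer(ends),
                 mean = means, n_probes = ends - starts + 1L,
                 cost = sse + gamma * (length(starts) - 1L),
                 gamma = gamma, min_probes = min_probes, y = y),
            class = "pcf")
}

#' @export
print.pcf <- function(x, ...) {
  cat(sprintf("Piecewise-constant fit: %d probes, %d segment%s (gamma = %g, min %d probes/segment)\n",
              length(x$y), length(x$start), if (length(x$start) == 1L) "" else "s",
              x$gamma, x$min_probes))
  cat(sprintf("Penalized cost: %.6g\n", x$cost))
  print(data.frame(start = x$start, end = x$end,
                   n_probes = x$n_probes, mean = signif(x$mean, 6)))
  invisible(x)
}

#' @export
coef.pcf <- function(object, ...) object$mean

#' @export
fitted.pcf <- function(object, ...)
  rep(object$mean, object$n_probes)

#' @export
residuals.pcf <- function(object, ...) object$y - fitted(object)

#' @export
plot.pcf <- function(x, ...) {
  graphics::plot(x$y, pch = 16, cex = 0.4, col = "grey40",
                 xlab = "probe index", ylab = "log2 ratio", ...)
  graphics::segments(x$start, x$mean, x$end, x$mean, col = "red", lwd = 2)
  invisible(x)
}

# Robust per-sample noise scale: median absolute first difference of
# consecutive probes within a chromosome, scaled to a Gaussian SD.
# (|y_{i+1}-y_i| for iid N(mu, s^2) has median s*sqrt(2)*qnorm(3/4).)
estimate_noise_sd <- function(values, chrom) {
  d <- unlist(lapply(split(values, chrom), function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1L) abs(diff(v)) else numeric(0)
  }), use.names = FALSE)
  if (length(d) == 0L) return(NA_real_)
  stats::median(d) / (sqrt(2) * stats::qnorm(0.75))
}

# Convert 1-based probe-index segment ranges to bp segments. A segment
# nominally runs from its first to its last probe position; adjacent
# segments are extended to meet at the midpoint between flanking probes so
# chromosome coverage is gap-free and the total span does not depend on
# exactly where between two probes a breakpoint falls.
probe_ranges_to_bp <- function(pos, starts, ends) {
  k <- length(starts)
  start_bp <- numeric(k); end_bp <- numeric(k)
  start_bp[1L] <- pos[starts[1L]]
  end_bp[k] <- pos[ends[k]]
  if (k > 1L) {
    for (j in seq_len(k - 1L)) {
      b <- floor((pos[ends[j]] + pos[starts[j + 1L]]) / 2)
      end_bp[j] <- b
      start_bp[j + 1L] <- b + 1
    }
  }
  list(start_bp = start_bp, end_bp = end_bp,
       span_bp = end_bp - start_bp + 1)
}

#' Segment every sample of a probe-level copy-number table
#'
#' Applies [pcf()] independently to each chromosome of each sample and
#' converts probe-index segments to genomic (bp) segments. Missing probe
#' values are dropped per sample and chromosome before fitting (the fit
#' needs a gap-free ordered series); a chromosome with no non-missing
#' probes is omitted with a warning. Segment boundaries are extended to the
#' midpoint between flanking probes, so each chromosome's segments tile the
#' covered range without gaps.
#'
#' Two preprocessing choices are governed by the config: per-sample median
#' centering (`center`, default on) makes the fit measure deviation from
#' the diploid baseline, and noise normalisation (`normalize`, default on)
#' scales the penalty by the sample's squared robust noise estimate
#' (median absolute consecutive-probe difference / (sqrt(2) Phi^-1(3/4))),
#' which lets one default `gamma` serve platforms of different noise
#' levels. Scaling the penalty by s^2 is exactly equivalent to dividing
#' the series by s before fitting, but keeps segment means on the original
#' log2 scale.
#'
#' @param cn a `cn_profiles` object from [read_probe_table()] or
#'   [simulate_cohort()], or a list with elements `probe_map`
#'   (data.frame: `probe_id`, `chrom`, `pos`) and `values` (numeric matrix,
#'   probes x samples, with sample ids as column names).
#' @param config a [pipeline_config()] (gamma, min_probes, normalize,
#'   center are used).
#' @returns An object of class `"cn_segmentation"`: a data.frame with
#'   columns `sample_id`, `chrom`, `start_bp`, `end_bp`, `span_bp`,
#'   `n_probes`, `mean_log2`, plus attributes `gamma_used`,
#'   `min_probes_used`, `normalize`, `center`.
#' @export
segment_profiles <- function(cn, config = pipeline_config()) {
  stopifnot(is.list(cn), !is.null(cn$probe_map), !is.null(cn$values))
  pm <- cn$probe_map
  vals <- as.matrix(cn$values)
  if (nrow(vals) != nrow(pm)) stop("values not aligned to probe map")
  samples <- colnames(vals)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(vals)))

  out <- vector("list", ncol(vals))
  for (s in seq_len(ncol(vals))) {
    y <- vals[, s]
    if (isTRUE(config$center)) {
      med <- stats::median(y, na.rm = TRUE)
      if (is.finite(med)) y <- y - med
    }
    gamma_eff <- config$gamma
    if (isTRUE(config$normalize)) {
      s_hat <- estimate_noise_sd(y, pm$chrom)
      if (is.finite(s_hat) && s_hat > 0) gamma_eff <- config$gamma * s_hat^2
    }
    rows <- lapply(sort(unique(pm$chrom)), function(cc) {
      idx <- which(pm$chrom == cc & !is.na(y))
      if (length(idx) == 0L) {
        warning(sprintf("sample %s: chromosome %d has no non-missing probes; omitted",
                        samples[s], cc))
        return(NULL)
      }
      fit <- pcf(y[idx], gamma = gamma_eff, min_probes = config$min_probes)
      bp <- probe_ranges_to_bp(pm$pos[idx], fit$start, fit$end)
      data.frame(sample_id = samples[s], chrom = cc,
                 start_bp = bp$start_bp, end_bp = bp$end_bp,
                 span_bp = bp$span_bp, n_probes = fit$n_probes,
                 mean_log2 = fit$mean)
    })
    out[[s]] <- do.call(rbind, rows)
  }
  seg <- do.call(rbind, out)
  if (is.null(seg)) seg <- data.frame(sample_id = character(0), chrom = integer(0),
                                      start_bp = numeric(0), end_bp = numeric(0),
                                      span_bp = numeric(0), n_probes = integer(0),
                                      mean_log2 = numeric(0))
  rownames(seg) <- NULL
  structure(seg, gamma_used = config$gamma, min_probes_used = config$min_probes,
            normalize = isTRUE(config$normalize), center = isTRUE(config$center),
            class = c("cn_segmentation", "data.frame"))
}

#' @export
print.cn_segmentation <- function(x, ...) {
  ns <- length(unique(x$sample_id))
  cat(sprintf("Copy-number segmentation: %d samples, %d segments (gamma = %g, min_probes = %d)\n",
              ns, nrow(x), attr(x, "gamma_used"), attr(x, "min_probes_used")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' @export
summary.cn_segmentation <- function(object, ...) {
  per <- tapply(seq_len(nrow(object)), object$sample_id, length)
  cat(sprintf("%d samples; segments per sample: median %g (range %d-%d)\n",
              length(per), stats::median(per), min(per), max(per)))
  invisible(data.frame(sample_id = names(per), n_segments = as.integer(per)))
}
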