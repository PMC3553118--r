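#' Total Aberration Index of one segmented profile
#'
#' The TAI is the length-weighted average absolute segment mean:
#' \deqn{\mathrm{TAI} = \frac{\sum_i L_i\,|\bar y_i|}{\sum_i L_i}}
#' where \eqn{L_i} is the genomic span (bp) of segment \eqn{i} and
#' \eqn{\bar y_i} its mean log2 ratio, summed over all segments of all
#' chromosomes (X included as chromosome 23). It measures the absolute
#' deviation from the normal (diploid) copy-number state averaged over the
#' genomic locations the platform covers, so it grows with both the
#' abundance and the genomic size of aberrations. The denominator is the
#' total covered span, making samples on the same platform comparable;
#' absolute values are not comparable across platforms with different
#' coverage.
#'
#' @param seg segments of a single sample: a data.frame with `span_bp` and
#'   `mean_log2` columns (rows for one `sample_id` of a
#'   `cn_segmentation`).
#' @returns The TAI, a non-negative scalar bounded by the largest
#'   `|mean_log2|`.
#' @export
total_aberration_index <- function(seg) {
  seg <- as.data.frame(seg)
  if (nrow(seg) == 0L) stop("empty segmentation")
  if (length(unique(seg$sample_id)) > 1L)
    stop("segments from more than one sample; use tai_table() for cohorts")
  tot <- sum(seg$span_bp)
  if (tot <= 0) stop("total segment span is zero")
  sum(seg$span_bp * abs(seg$mean_log2)) / tot
}

#' Per-sample TAI with cohort median split and z-scores
#'
#' Computes [total_aberration_index()] for every sample of a cohort
#' segmentation, then attaches the cohort median-split group label
#' ([median_split()]) and the cohort z-score ([tai_zscore()]), so the
#' score can be used both dichotomised (low/high) and continuous (per SD)
#' downstream.
#'
#' @param seg a `cn_segmentation` covering one or more samples.
#' @returns A data.frame of class `"tai_table"`: `sample_id`, `tai`,
#'   `group` (`"low"`/`"high"`), `z`.
#' @export
tai_table <- function(seg) {
  seg <- as.data.frame(seg)
  ids <- unique(seg$sample_id)
  tai <- vapply(ids, function(id)
    total_aberration_index(seg[seg$sample_id == id, , drop = FALSE]), 0)
  tab <- data.frame(sample_id = ids, tai = unname(tai),
                    stringsAsFactors = FALSE)
  tab$group <- if (nrow(tab) >= 2L) median_split(tab$tai) else NA_character_
  tab$z <- if (nrow(tab) >= 2L && stats::sd(tab$tai) > 0)
    tai_zscore(tab$tai) else NA_real_
  class(tab) <- c("tai_table", "data.frame")
  tab
}

#' @export
print.tai_table <- function(x, ...) {
  cat(sprintf("TAI table: %d samples, median TAI %.4g (%d low / %d high)\n",
              nrow(x), stats::median(x$tai),
              sum(x$group == "low"), sum(x$group == "high")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Median split of a cohort score
#'
#' Labels each sample `"high"` iff its score is strictly above the cohort
#' median (the midpoint of the two central order statistics for even n);
#' samples exactly at the median go to `"low"`. With even n and distinct
#' values the split is exactly 50/50. Ties at the median are flagged with
#' a warning attribute; identical values throughout give all-low with a
#' warning.
#'
#' @param x numeric vector of scores (length >= 2).
#' @returns Character vector of `"low"`/`"high"` labels.
#' @export
median_split <- function(x) {
  if (length(x) < 2L) stop("median split needs at least 2 samples")
  med <- stats::median(x)
  if (all(x == x[1L])) warning("all scores identical; every sample labelled low")
  else if (any(x == med)) message("score(s) exactly at the median assigned to the low group")
  ifelse(x > med, "high", "low")
}

#' Cohort z-scores of a score vector
#'
#' Standardises with the cohort mean and the n-1 standard deviation, so a
#' Cox coefficient on the result is a log-hazard per SD.
#'
#' @param x numeric vector (length >= 2, non-zero variance).
#' @returns Numeric vector with mean 0 and SD 1.
#' @export
tai_zscore <- function(x) {
  if (length(x) < 2L) stop("z-scores need at least 2 samples")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance; z-scores undefined")
  (x - mean(x)) / s
}
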