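# Map probe positions to the covering segment of one sample (one
# chromosome); NA where no segment covers the probe.
covering_segment <- function(pos, seg_start, seg_end) {
  i <- findInterval(pos, seg_start)
  i[i == 0L] <- NA_integer_
  bad <- !is.na(i) & pos > seg_end[pmax(i, 1L)]
  i[bad] <- NA_integer_
  i
}

#' Call per-probe copy-number states from a segmentation
#'
#' A probe is `gain` if its covering segment's mean log2 ratio is strictly
#' above `gain_threshold`, `loss` if strictly below `loss_threshold`, else
#' `neutral`. A probe with no covering segment is `NA`.
#'
#' @param seg segments of one sample (`cn_segmentation` rows).
#' @param pm probe-map data.frame.
#' @param gain_threshold,loss_threshold log2 cutoffs
#'   (`loss_threshold < 0 < gain_threshold`).
#' @returns Character vector of states aligned to `pm` rows.
#' @export
call_states <- function(seg, pm, gain_threshold = 0.1, loss_threshold = -0.1) {
  stopifnot(loss_threshold < 0, gain_threshold > 0)
  seg <- as.data.frame(seg)
  out <- rep(NA_character_, nrow(pm))
  for (cc in unique(seg$chrom)) {
    s <- seg[seg$chrom == cc, , drop = FALSE]
    s <- s[order(s$start_bp), , drop = FALSE]
    idx <- which(pm$chrom == cc)
    j <- covering_segment(pm$pos[idx], s$start_bp, s$end_bp)
    m <- s$mean_log2[j]
    st <- ifelse(is.na(m), NA_character_,
                 ifelse(m > gain_threshold, "gain",
                        ifelse(m < loss_threshold, "loss", "neutral")))
    out[idx] <- st
  }
  out
}

#' Cohort gain/loss frequency track
#'
#' For every probe, the fraction of samples whose covering segment is
#' called gained and the fraction called lost (see [call_states()]).
#' Samples without a covering segment at a probe are excluded from that
#' probe's denominator.
#'
#' @param seg a `cn_segmentation` covering the cohort.
#' @param pm probe-map data.frame.
#' @param gain_threshold,loss_threshold log2 cutoffs.
#' @returns Data.frame aligned to `pm`: `probe_id`, `chrom`, `pos`,
#'   `gain_frequency`, `loss_frequency`, `n_samples`.
#' @export
frequency_track <- function(seg, pm, gain_threshold = 0.1, loss_threshold = -0.1) {
  ids <- unique(seg$sample_id)
  stopifnot(length(ids) >= 1L)
  gains <- losses <- covered <- numeric(nrow(pm))
  for (id in ids) {
    st <- call_states(seg[seg$sample_id == id, , drop = FALSE], pm,
                      gain_threshold, loss_threshold)
    cov <- !is.na(st)
    covered <- covered + cov
    gains <- gains + (cov & st == "gain")
    losses <- losses + (cov & st == "loss")
  }
  data.frame(probe_id = pm$probe_id, chrom = pm$chrom, pos = pm$pos,
             gain_frequency = ifelse(covered > 0, gains / covered, NA_real_),
             loss_frequency = ifelse(covered > 0, losses / covered, NA_real_),
             n_samples = as.integer(covered))
}

#' Cohort mean segmented log2 ratio on a fixed genomic grid
#'
#' Defines loci spaced `grid_spacing_bp` apart within each chromosome,
#' anchored at the chromosome's first covered bp across the cohort, and
#' reports at each locus the mean (over samples) of the covering segment's
#' mean log2 ratio. Samples with no covering segment at a locus are
#' excluded there. Tracks on a common grid from two cohorts can be
#' compared locus by locus.
#'
#' @param seg a `cn_segmentation`.
#' @param grid_spacing_bp locus spacing in bp (default 1 Mb).
#' @returns Data.frame: `chrom`, `pos`, `mean_log2`, `n_samples`.
#' @export
grid_average <- function(seg, grid_spacing_bp = 1e6) {
  seg <- as.data.frame(seg)
  ids <- unique(seg$sample_id)
  rows <- lapply(sort(unique(seg$chrom)), function(cc) {
    s <- seg[seg$chrom == cc, , drop = FALSE]
    loci <- seq(min(s$start_bp), max(s$end_bp), by = grid_spacing_bp)
    tot <- cnt <- numeric(length(loci))
    for (id in ids) {
      si <- s[s$sample_id == id, , drop = FALSE]
      si <- si[order(si$start_bp), , drop = FALSE]
      if (nrow(si) == 0L) next
      j <- covering_segment(loci, si$start_bp, si$end_bp)
      ok <- !is.na(j)
      tot[ok] <- tot[ok] + si$mean_log2[j[ok]]
      cnt[ok] <- cnt[ok] + 1
    }
    data.frame(chrom = cc, pos = loci,
               mean_log2 = ifelse(cnt > 0, tot / cnt, NA_real_),
               n_samples = as.integer(cnt))
  })
  do.call(rbind, rows)
}
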