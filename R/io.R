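#' Read a probe-level copy-number table
#'
#' Reads a tab-separated table with header columns `probe_id`, `chrom`,
#' `pos`, followed by one log2-ratio column per sample. Chromosome tokens
#' `"1"`..`"22"` and `"X"` (mapped to 23) are accepted; rows with any other
#' chromosome token are dropped with a message reporting the count. Rows
#' are sorted to the canonical (chromosome, position) order; a warning is
#' issued if the input was not already sorted. Positions are kept 1-based
#' as read.
#'
#' @param path path to the TSV file.
#' @returns An object of class `"cn_profiles"`: a list with `probe_map`
#'   (data.frame `probe_id`, `chrom`, `pos`, sorted, unique probe ids,
#'   strictly increasing positions within chromosome) and `values`
#'   (numeric matrix, probes x samples).
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty probe table: ", path)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(df)[1:3]))
    stop("probe table must start with columns probe_id, chrom, pos")
  chrom <- parse_chrom(as.character(df$chrom))
  bad <- is.na(chrom)
  if (any(bad)) {
    message(sprintf("dropped %d row(s) with unparseable chromosome", sum(bad)))
    df <- df[!bad, , drop = FALSE]
    chrom <- chrom[!bad]
  }
  if (nrow(df) == 0L) stop("no rows with a recognised chromosome in ", path)
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in ", path)
  pos <- as.integer(df$pos)
  if (any(is.na(pos) | pos < 1)) stop("positions must be integers >= 1")

  ord <- order(chrom, pos)
  if (any(ord != seq_along(ord))) warning("probe table not in canonical order; sorted")
  sample_cols <- setdiff(names(df), need)
  vals <- as.matrix(df[ord, sample_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  pm <- data.frame(probe_id = as.character(df$probe_id)[ord],
                   chrom = chrom[ord], pos = pos[ord],
                   stringsAsFactors = FALSE)
  for (cc in unique(pm$chrom)) {
    p <- pm$pos[pm$chrom == cc]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing within chromosome ", cc)
  }
  rownames(vals) <- pm$probe_id
  structure(list(probe_map = pm, values = vals), class = "cn_profiles")
}

parse_chrom <- function(x) {
  x <- sub("^chr", "", trimws(x))
  out <- suppressWarnings(as.integer(x))
  out[x %in% c("X", "x")] <- 23L
  out[!is.na(out) & (out < 1L | out > 23L)] <- NA_integer_
  out
}

#' @export
print.cn_profiles <- function(x, ...) {
  cat(sprintf("Copy-number profiles: %d probes x %d samples, chromosomes %s\n",
              nrow(x$values), ncol(x$values),
              paste(range(x$probe_map$chrom), collapse = "-")))
  invisible(x)
}

#' Write a probe-level copy-number table
#'
#' Inverse of [read_probe_table()]; chromosome 23 is written as `X`.
#'
#' @param cn a `cn_profiles` object.
#' @param path output TSV path.
#' @export
write_probe_table <- function(cn, path) {
  chrom <- ifelse(cn$probe_map$chrom == 23L, "X", as.character(cn$probe_map$chrom))
  df <- data.frame(probe_id = cn$probe_map$probe_id, chrom = chrom,
                   pos = cn$probe_map$pos, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(cn$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Reads a CSV with columns `sample_id`, `age`, `stage` (2/3/4), `grade`
#' (1/2/3 or blank for missing), `chemo_response`
#' (`sensitive`/`resistant`), `pfs_months`, `pfs_event`, `os_months`,
#' `os_event`. Values are validated; a blank grade is preserved as `NA`.
#'
#' @param path path to the CSV file.
#' @returns A data.frame of class `"clinical_table"`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "stage", "grade", "chemo_response",
            "pfs_months", "pfs_event", "os_months", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!row$stage %in% c(2, 3, 4))
      stop(sprintf("row %d (%s): unknown stage code %s", i, row$sample_id, row$stage))
    if (!is.na(row$grade) && !row$grade %in% c(1, 2, 3))
      stop(sprintf("row %d (%s): unknown grade code %s", i, row$sample_id, row$grade))
    if (is.na(row$pfs_months) || row$pfs_months < 0 ||
        is.na(row$os_months) || row$os_months < 0)
      stop(sprintf("row %d (%s): survival times must be non-negative", i, row$sample_id))
    if (!row$pfs_event %in% c(0, 1) || !row$os_event %in% c(0, 1))
      stop(sprintf("row %d (%s): event indicators must be 0/1", i, row$sample_id))
    if (!row$chemo_response %in% c("sensitive", "resistant", NA))
      stop(sprintf("row %d (%s): chemo_response must be sensitive/resistant", i, row$sample_id))
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical table
#'
#' @param clinical a clinical data.frame as returned by [read_clinical()]
#'   or [simulate_cohort()].
#' @param path output CSV path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(as.data.frame(clinical), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write segments as a BED-like table
#'
#' Writes segments in 0-based half-open coordinates (`start = start_bp - 1`,
#' `end = end_bp`): columns `chrom`, `start`, `end`, `sample_id`,
#' `n_probes`, `mean_log2`. Means are written at full precision (17
#' significant digits) so a read-back reproduces them bit-identically.
#' Segments are written sorted by (sample, chromosome, start); overlapping
#' segments within a sample and chromosome are an error.
#'
#' @param seg a `cn_segmentation` data.frame.
#' @param path output TSV path.
#' @export
write_segments <- function(seg, path) {
  seg <- as.data.frame(seg)
  ord <- order(seg$sample_id, seg$chrom, seg$start_bp)
  seg <- seg[ord, , drop = FALSE]
  for (key in split(seq_len(nrow(seg)), list(seg$sample_id, seg$chrom), drop = TRUE)) {
    if (length(key) > 1L) {
      s <- seg[key, ]
      if (any(s$start_bp[-1L] <= s$end_bp[-nrow(s)]))
        stop("overlapping segments within sample ", s$sample_id[1L],
             " chromosome ", s$chrom[1L])
    }
  }
  out <- data.frame(chrom = seg$chrom, start = format_bp(seg$start_bp - 1),
                    end = format_bp(seg$end_bp), sample_id = seg$sample_id,
                    n_probes = seg$n_probes,
                    mean_log2 = sprintf("%.17g", seg$mean_log2))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_bp <- function(x) sprintf("%.0f", x)

#' Read a BED-like segment table written by [write_segments()]
#'
#' @param path segment TSV path.
#' @returns A `cn_segmentation` data.frame (1-based inclusive internal
#'   coordinates).
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "sample_id", "n_probes", "mean_log2")
  if (!all(need %in% names(df))) stop("segment table missing columns")
  seg <- data.frame(sample_id = as.character(df$sample_id),
                    chrom = as.integer(df$chrom),
                    start_bp = df$start + 1, end_bp = df$end,
                    span_bp = df$end - df$start,
                    n_probes = as.integer(df$n_probes),
                    mean_log2 = as.numeric(df$mean_log2),
                    stringsAsFactors = FALSE)
  structure(seg, class = c("cn_segmentation", "data.frame"))
}

#' Write a TAI table
#'
#' @param tai a `tai_table` data.frame (see [tai_table()]).
#' @param path output TSV path.
#' @export
write_tai <- function(tai, path) {
  out <- as.data.frame(tai)
  out$tai <- sprintf("%.17g", out$tai)
  out$z <- sprintf("%.17g", out$z)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
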