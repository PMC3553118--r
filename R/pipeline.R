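#' Run the full analysis pipeline
#'
#' Reads a probe-level copy-number table and a clinical table, segments
#' every sample ([segment_profiles()]), computes TAI with the cohort
#' median split and z-scores ([tai_table()]), builds the gain/loss
#' frequency track and the fixed-grid average track, and — on the samples
#' present in both tables — the clinicopathological summary with its test
#' battery ([build_table1()]) and the survival summary
#' ([build_table2()]). All artifacts are written as TSV under `out_dir`,
#' together with a YAML run manifest recording the configuration and
#' library versions. Given the same inputs, config and seed the output is
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param probe_table path to the probe-level TSV ([read_probe_table()]).
#' @param clinical path to the clinical CSV ([read_clinical()]), or NULL to
#'   skip the clinical stages.
#' @param out_dir output directory (created if needed).
#' @returns Invisibly, a list with the in-memory results: `segments`,
#'   `tai`, `freq`, `grid`, `table1`, `table2`, `paths`.
#' @export
run_pipeline <- function(config, probe_table, clinical = NULL, out_dir = ".") {
  set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cn <- read_probe_table(probe_table)
  clin <- if (!is.null(clinical)) read_clinical(clinical) else NULL

  seg <- segment_profiles(cn, config)
  tai <- tai_table(seg)
  freq <- frequency_track(seg, cn$probe_map,
                          config$gain_threshold, config$loss_threshold)
  grid <- grid_average(seg, config$grid_spacing_bp)

  paths <- list(segments = file.path(out_dir, "segments.tsv"),
                tai = file.path(out_dir, "tai.tsv"),
                freq = file.path(out_dir, "frequency_track.tsv"),
                grid = file.path(out_dir, "grid_track.tsv"),
                manifest = file.path(out_dir, "manifest.yaml"))
  write_segments(seg, paths$segments)
  write_tai(tai, paths$tai)
  utils::write.table(freq, paths$freq, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(grid, paths$grid, sep = "\t", quote = FALSE, row.names = FALSE)

  t1 <- t2 <- NULL
  if (!is.null(clin)) {
    common <- intersect(clin$sample_id, tai$sample_id)
    if (length(common) == 0L) stop("no overlapping sample ids between copy-number and clinical tables")
    if (length(common) < nrow(tai) || length(common) < nrow(clin))
      message(sprintf("clinical stages use the %d samples present in both tables", length(common)))
    t1 <- build_table1(clin, tai)
    t2 <- build_table2(clin, tai)
    paths$table1 <- file.path(out_dir, "table1_tests.tsv")
    paths$table2 <- file.path(out_dir, "table2_survival.tsv")
    utils::write.table(t1$tests, paths$table1, sep = "\t", quote = FALSE, row.names = FALSE)
    t2_flat <- do.call(rbind, lapply(names(t2), function(ep) {
      u <- t2[[ep]]$cox_univariate
      data.frame(endpoint = ep, logrank_p = t2[[ep]]$logrank$p,
                 hr_per_sd = u$hr[1], ci_lower = u$ci_lower[1],
                 ci_upper = u$ci_upper[1], cox_p = u$p[1],
                 n = t2[[ep]]$n, n_events = t2[[ep]]$n_events)
    }))
    utils::write.table(t2_flat, paths$table2, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(config = unclass(config),
                   inputs = list(probe_table = normalizePath(probe_table),
                                 clinical = if (is.null(clinical)) NULL else normalizePath(clinical)),
                   n_samples = ncol(cn$values), n_probes = nrow(cn$values),
                   versions = list(
                     R = paste(R.version$major, R.version$minor, sep = "."),
                     taiseg = as.character(utils::packageVersion("taiseg")),
                     survival = as.character(utils::packageVersion("survival"))))
  yaml::write_yaml(manifest, paths$manifest)

  invisible(list(segments = seg, tai = tai, freq = freq, grid = grid,
                 table1 = t1, table2 = t2, paths = paths))
}
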