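#' Pipeline configuration
#'
#' Collects and validates the tunable parameters of the analysis pipeline.
#'
#' @param gamma segmentation penalty per breakpoint (> 0); applied on the
#'   noise-normalised scale when `normalize = TRUE` (see
#'   [segment_profiles()]).
#' @param min_probes minimum probes per segment (default 3).
#' @param gain_threshold,loss_threshold log2 cutoffs for calling a probe
#'   gained/lost from its segment mean (strict inequalities);
#'   `loss_threshold < 0 < gain_threshold`.
#' @param grid_spacing_bp spacing of the fixed comparison grid, bp
#'   (default 1 Mb).
#' @param seed integer seed for any stochastic stage.
#' @param split_rule cohort dichotomisation rule; only `"above_median_high"`
#'   is defined: high group iff TAI strictly above the cohort median.
#' @param normalize scale the penalty by the squared per-sample robust
#'   noise estimate (default TRUE).
#' @param center per-sample median centering before segmentation
#'   (default TRUE).
#' @returns A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(gamma = 40, min_probes = 3,
                            gain_threshold = 0.1, loss_threshold = -0.1,
                            grid_spacing_bp = 1e6L, seed = 1L,
                            split_rule = "above_median_high",
                            normalize = TRUE, center = TRUE) {
  cfg <- list(gamma = as.numeric(gamma), min_probes = as.integer(min_probes),
              gain_threshold = as.numeric(gain_threshold),
              loss_threshold = as.numeric(loss_threshold),
              grid_spacing_bp = as.numeric(grid_spacing_bp),
              seed = as.integer(seed), split_rule = split_rule,
              normalize = isTRUE(normalize), center = isTRUE(center))
  if (!is.finite(cfg$gamma) || cfg$gamma <= 0) stop("gamma must be > 0")
  if (is.na(cfg$min_probes) || cfg$min_probes < 1L) stop("min_probes must be >= 1")
  if (!(cfg$loss_threshold < 0 && 0 < cfg$gain_threshold))
    stop("thresholds must satisfy loss_threshold < 0 < gain_threshold")
  if (!is.finite(cfg$grid_spacing_bp) || cfg$grid_spacing_bp < 1)
    stop("grid_spacing_bp must be >= 1")
  if (!identical(cfg$split_rule, "above_median_high"))
    stop("unknown split_rule: ", split_rule)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path path to a YAML file whose keys are [pipeline_config()]
#'   arguments.
#' @returns A `"pipeline_config"` object.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x)) x <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, x)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (k in names(x)) cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}
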