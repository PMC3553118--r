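#' Kaplan-Meier curve
#'
#' Product-limit estimate of the survival function, with the median
#' survival time and its 95% confidence interval on the log-log scale.
#' Censoring at a tied time is handled after the events at that time, as
#' usual for the product-limit estimator.
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @returns A list of class `"km_curve"`: `time`, `surv`, `n_risk`,
#'   `n_event` at the distinct observed times, plus `median` and
#'   `median_ci` (length-2).
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0), all(event %in% 0:1))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  s <- summary(fit)$table
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 median = unname(s["median"]),
                 median_ci = unname(c(s["0.95LCL"], s["0.95UCL"]))),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events; median %s (95%% CI %s-%s)\n",
              max(x$n_risk), sum(x$n_event), format(x$median),
              format(x$median_ci[1]), format(x$median_ci[2])))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(c(0, x$time), c(1, x$surv), type = "s", ylim = c(0, 1),
                 xlab = "time (months)", ylab = "survival", ...)
  invisible(x)
}

#' Log-rank test of two groups
#'
#' Observed-minus-expected statistic with hypergeometric variance summed
#' over event times; p from chi-square with 1 df.
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (1 = event, 0 = censored).
#' @param group two-level group labels.
#' @returns List: `chisq`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2L)
  if (sum(event) == 0) stop("no events; log-rank test undefined")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = unname(fit$chisq),
       p = stats::pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation with Efron handling of tied event times
#' (months-resolution follow-up ties heavily). Reports, per coefficient,
#' the log-hazard `beta`, hazard ratio, 95% Wald confidence interval and
#' Wald p-value. Enter TAI as its cohort z-score so its hazard ratio reads
#' per 1 SD.
#'
#' @param time follow-up times (> 0).
#' @param event event indicators; at least 2 events required.
#' @param covariates data.frame (or named list) of finite, non-constant
#'   numeric covariates.
#' @returns A data.frame of class `"cox_result"`: `term`, `beta`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`, with attribute `n_events`.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(length(time) == length(event), nrow(covariates) == length(time))
  if (sum(event) < 2) stop("need at least 2 events")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (!all(is.finite(v))) stop("covariate ", nm, " has non-finite values")
    if (stats::sd(v) == 0) stop("covariate ", nm, " is constant")
  }
  d <- cbind(data.frame(.time = time, .event = event), covariates)
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                  paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(form, data = d, ties = "efron",
                         control = survival::coxph.control(iter.max = 100))
  if (any(!is.finite(coef(fit))) || any(sqrt(diag(fit$var)) > 1e3))
    stop("monotone likelihood (separation); collapse groups or drop the covariate")
  if (fit$iter >= 100) stop("Cox fit did not converge in 100 iterations")
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  res <- data.frame(term = names(beta), beta = unname(beta),
                    hr = exp(unname(beta)),
                    ci_lower = exp(unname(beta - 1.96 * se)),
                    ci_upper = exp(unname(beta + 1.96 * se)),
                    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    row.names = NULL)
  structure(res, n_events = sum(event), class = c("cox_result", "data.frame"))
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (Efron ties), %d events\n",
              attr(x, "n_events")))
  df <- as.data.frame(x)
  df$hr <- sprintf("%.3f [%.3f, %.3f]", df$hr, df$ci_lower, df$ci_upper)
  print(df[, c("term", "beta", "hr", "p")], digits = 3)
  invisible(x)
}

#' Survival summary: log-rank by TAI group plus Cox models per endpoint
#'
#' For each endpoint (PFS, OS): the log-rank test across the TAI
#' median-split groups, the univariate Cox model with TAI per SD, and the
#' multivariate Cox model adding age, stage and grade. Stage and grade
#' enter as numeric ordinals by default, or as indicator contrasts with
#' `ordinal_covariates = FALSE`. Only samples present in both tables (and
#' with positive follow-up and complete covariates, for the multivariate
#' model) are used.
#'
#' @param clinical clinical data.frame ([read_clinical()] columns).
#' @param tai a `tai_table`.
#' @param ordinal_covariates code stage/grade as numeric ordinals
#'   (default TRUE) or indicators.
#' @returns A list of class `"table2"` keyed by endpoint, each with
#'   `logrank` (chisq, p), `cox_univariate` and `cox_multivariate`
#'   (`cox_result` objects), and `n`/`n_events`.
#' @export
build_table2 <- function(clinical, tai, ordinal_covariates = TRUE) {
  d <- merge(as.data.frame(clinical), as.data.frame(tai), by = "sample_id")
  if (nrow(d) == 0L) stop("no overlapping sample ids between clinical and TAI tables")
  out <- list()
  for (ep in c("pfs", "os")) {
    time <- d[[paste0(ep, "_months")]]
    event <- d[[paste0(ep, "_event")]]
    keep <- time > 0
    if (any(!keep)) warning(sum(!keep), " sample(s) with zero follow-up dropped for ", ep)
    dd <- d[keep, ]; tt <- time[keep]; ee <- event[keep]
    lr <- logrank_test(tt, ee, dd$group)
    uni <- cox_fit(tt, ee, data.frame(tai_per_sd = dd$z))
    cc <- !is.na(dd$grade)
    covs <- if (ordinal_covariates)
      data.frame(tai_per_sd = dd$z[cc], age = dd$age[cc],
                 stage = as.numeric(dd$stage[cc]), grade = as.numeric(dd$grade[cc]))
    else {
      mm <- stats::model.matrix(~ factor(stage) + factor(grade), dd[cc, ])[, -1, drop = FALSE]
      colnames(mm) <- gsub("[()]", "", colnames(mm))
      cbind(data.frame(tai_per_sd = dd$z[cc], age = dd$age[cc]), as.data.frame(mm))
    }
    multi <- cox_fit(tt[cc], ee[cc], covs)
    out[[ep]] <- list(logrank = lr, cox_univariate = uni,
                      cox_multivariate = multi,
                      n = sum(keep), n_events = sum(ee))
  }
  structure(out, class = "table2")
}

#' @export
print.table2 <- function(x, ...) {
  for (ep in names(x)) {
    e <- x[[ep]]
    u <- e$cox_univariate
    cat(sprintf("%s: n = %d, events = %d | log-rank p = %.4g | HR/SD = %.3f [%.3f, %.3f], p = %.4g\n",
                toupper(ep), e$n, e$n_events, e$logrank$p,
                u$hr[1], u$ci_lower[1], u$ci_upper[1], u$p[1]))
  }
  invisible(x)
}
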