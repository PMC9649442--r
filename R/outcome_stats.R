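#' Fisher enrichment of a binary feature in a binary group
#'
#' Two-sided Fisher's exact test on the 2x2 table of feature presence by
#' group membership, with the conditional-MLE odds ratio. FDR across a
#' feature set is the caller's responsibility (see [bh_fdr()]).
#'
#' @param feature,group Aligned binary vectors; both must be non-constant.
#' @return list with `odds_ratio`, `p`, `table`, or NA values with a
#'   `reason` when a vector is constant.
#' @export
fisher_enrichment <- function(feature, group) {
  if (length(feature) != length(group))
    abort2("length mismatch", "cllstrat_validation_error")
  if (length(unique(feature)) < 2L || length(unique(group)) < 2L)
    return(list(odds_ratio = NA_real_, p = NA_real_, table = NULL,
                reason = "constant vector"))
  tab <- table(factor(feature, levels = c(1, 0)),
               factor(group, levels = c(1, 0)))
  ft <- fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab,
       reason = NA_character_)
}

#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator with Greenwood standard errors via
#' [survival::survfit()]. The reported median is the first time at which the
#' survival function drops to 0.5 or below (NA when it never does).
#'
#' @param records data.frame with columns `time` (> 0) and `event`
#'   (1 observed, 0 censored).
#' @return list with `time`, `surv`, `std_err` step vectors, `median`,
#'   and the underlying `survfit` object.
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0L)
    abort2("records must be non-empty", "cllstrat_validation_error")
  if (any(records$time <= 0))
    abort2("times must be positive", "cllstrat_validation_error")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  s <- summary(fit, censored = TRUE)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1L]]
         else NA_real_
  list(time = fit$time, surv = fit$surv, std_err = fit$std.err,
       median = med, fit = fit)
}

#' Log-rank test across groups
#'
#' Standard log-rank statistic via [survival::survdiff()]. With more than
#' two groups and `mode = "extreme_pair"` the test compares only the two
#' extreme curves (best vs worst median survival; a group whose survival
#' never reaches 0.5 counts as the best).
#'
#' @param records data.frame with `time`, `event` and a `group` column.
#' @param mode `"all"` (default) or `"extreme_pair"`.
#' @return list with `chi2`, `df`, `p`, `groups_compared`.
#' @export
logrank_test <- function(records, mode = c("all", "extreme_pair")) {
  mode <- match.arg(mode)
  groups <- unique(records$group)
  if (length(groups) < 2L)
    abort2("need at least two groups", "cllstrat_validation_error")
  if (mode == "extreme_pair" && length(groups) > 2L) {
    meds <- vapply(groups, function(g) {
      km <- km_estimate(records[records$group == g, , drop = FALSE])
      if (is.na(km$median)) Inf else km$median
    }, 0)
    pick <- c(groups[which.min(meds)], groups[which.max(meds)])
    records <- records[records$group %in% pick, , drop = FALSE]
    groups <- pick
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       groups_compared = as.character(groups))
}

#' Univariate Cox proportional-hazards association
#'
#' Partial-likelihood fit with Efron tie handling via
#' [survival::coxph()]; Wald p-value, hazard ratio and 95% CI. Monotone
#' likelihood (e.g. zero events in one arm) is detected via an infinite or
#' extreme coefficient standard error and flagged with NA results.
#'
#' @param feature Binary (or numeric) covariate vector, non-constant among
#'   the supplied records.
#' @param records data.frame with `time` and `event` aligned to `feature`.
#' @return list with `hazard_ratio`, `ci95` (low, high), `p`, `beta`,
#'   `flagged`, `reason`.
#' @export
cox_univariate <- function(feature, records) {
  if (length(unique(feature)) < 2L)
    return(list(hazard_ratio = NA_real_, ci95 = c(NA_real_, NA_real_),
                p = NA_real_, beta = NA_real_, flagged = TRUE,
                reason = "constant feature"))
  df <- data.frame(time = records$time, event = records$event, x = feature)
  fit <- tryCatch(
    suppressWarnings(survival::coxph(survival::Surv(time, event) ~ x,
                                     data = df, ties = "efron")),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(hazard_ratio = NA_real_, ci95 = c(NA_real_, NA_real_),
                p = NA_real_, beta = NA_real_, flagged = TRUE,
                reason = "fit failed"))
  beta <- unname(coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se) || se > 50 || abs(beta) > 15)
    return(list(hazard_ratio = NA_real_, ci95 = c(NA_real_, NA_real_),
                p = NA_real_, beta = beta, flagged = TRUE,
                reason = "monotone likelihood"))
  z <- beta / se
  list(hazard_ratio = exp(beta),
       ci95 = exp(beta + c(-1, 1) * qnorm(0.975) * se),
       p = 2 * pnorm(-abs(z)), beta = beta, flagged = FALSE,
       reason = NA_character_)
}

#' Feature-by-feature Cox screen with FDR
#'
#' Runs [cox_univariate()] for every column of a binary feature matrix
#' against one endpoint and applies BH-FDR across the tested features
#' (one FDR family per analysis table).
#'
#' @param matrix Patients x features binary matrix.
#' @param records Survival data.frame (`patient`, `time`, `event`) whose
#'   patients appear in the matrix rownames.
#' @return data.frame with `feature`, `hazard_ratio`, `ci_low`, `ci_high`,
#'   `p`, `fdr`, `flagged`.
#' @export
cox_screen <- function(matrix, records) {
  idx <- match(records$patient, rownames(matrix))
  if (anyNA(idx))
    abort2("survival records reference unknown patients",
           "cllstrat_validation_error")
  M <- matrix[idx, , drop = FALSE]
  res <- lapply(colnames(M), function(f) {
    r <- cox_univariate(M[, f], records)
    data.frame(feature = f, hazard_ratio = r$hazard_ratio,
               ci_low = r$ci95[1L], ci_high = r$ci95[2L], p = r$p,
               flagged = r$flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$fdr[ok] <- bh_fdr(out$p[ok])
  out
}

#' @importFrom stats coef
NULL
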