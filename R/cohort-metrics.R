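#' Area under the ROC curve
#'
#' Computed by the Mann-Whitney identity (ties counted half), which
#' equals trapezoidal integration of the empirical ROC over all
#' thresholds and is invariant under strictly monotone transforms of the
#' score.
#'
#' @param score Numeric marker values.
#' @param truth Logical (or 0/1) class labels; both classes required.
#' @return AUC in [0,1].
#' @export
roc_auc <- function(score, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes required for ROC")
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity at a cutoff
#'
#' Positivity convention: `score >= cutoff` is test-positive.
#'
#' @inheritParams roc_auc
#' @param cutoff Threshold.
#' @return List: `sensitivity`, `specificity`.
#' @export
sens_spec_at <- function(score, truth, cutoff) {
  truth <- as.logical(truth)
  pos <- score >= cutoff
  list(sensitivity = sum(pos & truth) / sum(truth),
       specificity = sum(!pos & !truth) / sum(!truth))
}

#' Optimal biomarker cutoff by Youden's J
#'
#' Evaluates J = sensitivity + specificity - 1 at every distinct observed
#' score (plus a cutoff above the maximum, the all-negative rule) under
#' the `score >= cutoff` positivity convention, and returns the
#' maximiser. Ties are broken toward the lowest cutoff (favouring
#' sensitivity) unless `tie = "specificity"`.
#'
#' @inheritParams roc_auc
#' @param tie `"sensitivity"` (default; lowest maximising cutoff) or
#'   `"specificity"` (highest).
#' @return List of class `roc_result`: `auc`, `optimal_cutoff`,
#'   `sensitivity`, `specificity`, `J`.
#' @export
youden_cutoff <- function(score, truth, tie = c("sensitivity",
                                                "specificity")) {
  tie <- match.arg(tie)
  truth <- as.logical(truth)
  if (sum(truth) == 0 || sum(!truth) == 0)
    stop("both classes required for Youden's statistic")
  cuts <- sort(unique(score))
  cuts <- c(cuts, max(score) + 1)  # all-negative rule as a baseline
  J <- vapply(cuts, function(ct) {
    ss <- sens_spec_at(score, truth, ct)
    ss$sensitivity + ss$specificity - 1
  }, numeric(1))
  best <- if (tie == "sensitivity") which.max(J) else
    max(which(J == max(J)))
  ss <- sens_spec_at(score, truth, cuts[best])
  out <- list(auc = roc_auc(score, truth), optimal_cutoff = cuts[best],
              sensitivity = ss$sensitivity, specificity = ss$specificity,
              J = J[best])
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("ROC: AUC %.3f; optimal cutoff %.4g ",
                     "(sens %.1f%%, spec %.1f%%, J = %.3f)\n"),
              x$auc, x$optimal_cutoff, 100 * x$sensitivity,
              100 * x$specificity, x$J))
  invisible(x)
}

#' Kaplan-Meier medians and the log-rank test
#'
#' Product-limit medians per group (smallest time at which the survival
#' curve drops to 0.5 or below) and the one-degree-of-freedom log-rank
#' statistic, via the survival package. With no censoring the KM curve
#' reduces to the empirical survival function.
#'
#' @param times Follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Group labels (two or more groups for the test).
#' @return List: `medians` (named per group; `NA` when the curve never
#'   reaches 0.5), `chisq`, `p`, `degenerate` (`TRUE` when no events are
#'   observed, in which case the test is skipped and medians are
#'   undefined).
#' @export
km_median_and_logrank <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("at least two non-empty groups required")
  if (sum(events) == 0) {
    return(list(medians = stats::setNames(rep(NA_real_, nlevels(groups)),
                                          levels(groups)),
                chisq = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) {  # single stratum edge
    med <- stats::setNames(tab["median"], levels(groups))
  } else {
    med <- tab[, "median"]
    names(med) <- sub("^groups=", "", rownames(tab))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  p <- stats::pchisq(sd$chisq, df = nlevels(groups) - 1,
                     lower.tail = FALSE)
  list(medians = med, chisq = unname(sd$chisq), p = p, degenerate = FALSE)
}
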