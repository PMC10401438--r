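## Survival and generic statistics used throughout the pipeline. The
## survival package provides the estimators (product-limit, log-rank score
## test, Cox partial likelihood with Efron ties); these wrappers fix the
## conventions (two-sided p-values, Wald CIs, explicit degenerate-input
## handling) and return plain data structures.

#' Kaplan-Meier product-limit estimate
#'
#' @param times nonnegative follow-up times.
#' @param events 0/1 event indicators (1 = death observed).
#' @return data frame with one row per event time: `time`, `n_risk`,
#'   `n_event`, `surv` (the product-limit survival probability just after
#'   `time`). With no events the frame has zero rows (S is identically 1).
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$surv  # 2/3, 1/3, 0
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  if (any(times < 0)) stop("negative times", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep],
             n_risk = fit$n.risk[keep],
             n_event = fit$n.event[keep],
             surv = fit$surv[keep])
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank statistic on 1 degree of freedom with the
#' chi-square upper-tail p-value. Defined even when one group has no events.
#'
#' @param times,events as in [km_estimate()].
#' @param groups per-sample labels with exactly two levels.
#' @return list with `chi_square` and `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  f <- .two_group_factor(groups, length(times), "groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ f)
  chi <- unname(sd$chisq)
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood maximization with the Efron approximation for tied
#' event times; Wald confidence intervals and p-values per term. Constant
#' or duplicated covariate columns are rejected up front; non-convergence
#' is reported through the `converged` flag rather than an error.
#'
#' @param design data frame of per-sample covariates (numeric or factor).
#' @param times,events as in [km_estimate()].
#' @return list of class `cox_fit`: `terms`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `converged`, and the underlying `fit`.
#' @export
cox_ph <- function(design, times, events) {
  design <- as.data.frame(design)
  if (nrow(design) != length(times)) {
    stop("'design' rows must match the number of samples", call. = FALSE)
  }
  num <- design[vapply(design, is.numeric, logical(1))]
  const <- names(design)[vapply(design, function(v)
    length(unique(v)) == 1L, logical(1))]
  if (length(const)) stop("constant covariate(s): ",
                          paste(const, collapse = ", "), call. = FALSE)
  if (ncol(num) >= 2L) {
    cm <- stats::cor(num)
    dup <- which(abs(cm) > 1 - 1e-12 & upper.tri(cm), arr.ind = TRUE)
    if (nrow(dup)) {
      stop("collinear covariates: ",
           paste(colnames(num)[dup[1L, 1L]], "and",
                 colnames(num)[dup[1L, 2L]]), call. = FALSE)
    }
  }
  if (sum(events) < ncol(design)) {
    stop("fewer events than model terms", call. = FALSE)
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ .,
                    data = design, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w),
                ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)
  structure(list(
    terms = rownames(sm$coefficients),
    hr = unname(sm$conf.int[, "exp(coef)"]),
    ci_low = unname(sm$conf.int[, "lower .95"]),
    ci_high = unname(sm$conf.int[, "upper .95"]),
    p = unname(sm$coefficients[, "Pr(>|z|)"]),
    converged = converged,
    fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  tab <- data.frame(term = x$terms, HR = round(x$hr, 3),
                    `95% CI` = sprintf("%.3f-%.3f", x$ci_low, x$ci_high),
                    p = signif(x$p, 3), check.names = FALSE)
  print(tab, row.names = FALSE)
  if (!x$converged) cat("warning: fit did not converge\n")
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties; the p-value is exact when the smaller sample has at
#' most 8 observations and there are no ties, and otherwise uses the normal
#' approximation with continuity correction.
#'
#' @param x,y nonempty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`;
#'   directions refer to `x` relative to `y`.
#' @return list with `statistic` (the Mann-Whitney U of `x`) and `p_value`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "less")$p_value  # 1/6
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample",
                                               call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1). Tables
#' with a zero row or column margin are rejected.
#'
#' @param contingency count matrix, at least 2 x 2.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(contingency) {
  contingency <- as.matrix(contingency)
  if (nrow(contingency) < 2L || ncol(contingency) < 2L) {
    stop("table must be at least 2 x 2", call. = FALSE)
  }
  if (any(contingency < 0)) stop("negative counts", call. = FALSE)
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Area under the ROC curve by the rank statistic
#'
#' `AUC = P(score_pos > score_neg) + 0.5 P(tie)`, computed from midranks
#' (the Mann-Whitney identity).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical or 0/1 per-sample labels (TRUE/1 = positive);
#'   both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- as.logical(labels)
  if (anyNA(pos)) stop("labels must be logical or 0/1", call. = FALSE)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present",
                                       call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
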