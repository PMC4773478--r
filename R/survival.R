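#' Validate a survival table
#'
#' @param tbl Data.frame with columns `time` (> 0), `event` (0/1), and
#'   optionally `expr`, `group`, `patient_id`.
#' @return The table with class `survival_table`.
#' @export
survival_table <- function(tbl) {
  stopifnot(is.data.frame(tbl), all(c("time", "event") %in% names(tbl)))
  if (any(tbl$time <= 0)) stop("times must be positive")
  if (!all(tbl$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (!inherits(tbl, "survival_table")) {
    class(tbl) <- c("survival_table", class(tbl))
  }
  tbl
}

#' Stratify patients by focal-gene expression fold change vs the median
#'
#' Fold change is each patient's expression over the cohort median;
#' `HIGH` when strictly above `high_fc`, `LOW` when strictly below
#' `low_fc`, `MID` otherwise (boundaries fall in `MID`).
#'
#' @param tbl A survival table with an `expr` column.
#' @param high_fc,low_fc Fold-change cutoffs (`high_fc > low_fc > 0`;
#'   defaults 2 and 0.5).
#' @return Factor of labels `HIGH`/`MID`/`LOW` in patient order.
#' @export
stratify_by_expression <- function(tbl, high_fc = 2, low_fc = 0.5) {
  stopifnot("expr" %in% names(tbl), nrow(tbl) >= 1)
  if (!(high_fc > low_fc && low_fc > 0)) {
    stop("need high_fc > low_fc > 0")
  }
  med <- stats::median(tbl$expr)
  if (med == 0) stop("median expression is zero; fold change undefined")
  fc <- tbl$expr / med
  factor(ifelse(fc > high_fc, "HIGH", ifelse(fc < low_fc, "LOW", "MID")),
         levels = c("HIGH", "MID", "LOW"))
}

#' Kaplan-Meier product-limit estimator
#'
#' Thin wrapper around [survival::survfit()] returning the step function as
#' a tidy table; censored times reduce the risk set without a step. With no
#' censoring the estimator equals the empirical survival function.
#'
#' @param tbl A survival table.
#' @param group Optional vector of group labels (one per patient).
#' @return Data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `survival`, sorted by time within group.
#' @export
km_estimator <- function(tbl, group = NULL) {
  tbl <- survival_table(as.data.frame(tbl))
  if (sum(tbl$event) == 0) {
    warning("no events: survival curve is flat at 1")
  }
  if (is.null(group)) group <- rep("all", nrow(tbl))
  group <- as.character(group)
  out <- do.call(rbind, lapply(unique(group), function(g) {
    sub <- tbl[group == g, , drop = FALSE]
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
    data.frame(group = g, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, survival = fit$surv,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Log-rank (Mantel-Cox / Mantel-Haenszel) test
#'
#' Standard log-rank comparison of survival across two or more groups via
#' [survival::survdiff()]: at each event time, observed events per group
#' are compared with their expectation under the hypergeometric margins;
#' the statistic is chi-squared with `k - 1` degrees of freedom.
#'
#' @param tbl A survival table.
#' @param group Vector of group labels (one per patient; >= 2 groups).
#' @return List with `chi2`, `df`, `p`, `observed`, `expected`.
#' @export
logrank_test <- function(tbl, group) {
  tbl <- survival_table(as.data.frame(tbl))
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (any(table(group) == 0)) stop("group with zero patients")
  if (sum(tbl$event) == 0) stop("need at least one event")
  d <- data.frame(time = tbl$time, event = tbl$event, group = group)
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(fit$n) - 1
  list(chi2 = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df = df, lower.tail = FALSE),
       observed = fit$obs, expected = fit$exp)
}
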