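# Survival statistics: Kaplan-Meier, logrank, Cox proportional hazards
# (via the survival package, Efron tie handling), BH false-discovery-rate
# adjustment, and the normality-gated choice of group-comparison test.
# Overall survival is measured in months; censoring at last follow-up.

#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative survival/censoring times (months).
#' @param events Logical or 0/1 event indicator (TRUE = death observed).
#' @return Object of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`
#'   step-function tables plus `median` (first time with survival <= 0.5;
#'   `NA` when never reached).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input", call. = FALSE)
  if (any(times < 0)) stop("negative survival times", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1]]
         else NA_real_
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n = length(times),
                 events = sum(as.integer(events)), median = med),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, median = %s\n",
              x$n, x$events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km A `km_curve`.
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(ti) {
    idx <- which(km$time <= ti)
    if (length(idx) == 0L) 1 else km$surv[max(idx)]
  }, numeric(1))
}

#' Plot a Kaplan-Meier curve
#'
#' @param x A `km_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(c(0, x$time), c(1, x$surv), type = "s",
                 xlab = "time (months)", ylab = "survival probability",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' Logrank test across groups
#'
#' Standard (score) logrank chi-square with k - 1 degrees of freedom via
#' [survival::survdiff()].
#'
#' @param groups Group labels (>= 2 non-empty groups).
#' @param times,events As in [km_estimate()].
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(groups, times, events) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) {
    stop("at least two non-empty groups are required", call. = FALSE)
  }
  groups <- droplevels(groups)
  sd <- survival::survdiff(
    survival::Surv(times, as.integer(events)) ~ groups)
  df <- nlevels(groups) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = pchisq(unname(sd$chisq), df, lower.tail = FALSE))
}

#' Fit a Cox proportional hazards model
#'
#' Partial-likelihood maximization with Efron tie handling. Reports per
#' covariate the hazard ratio with 95\% confidence interval, and the three
#' whole-model tests (likelihood ratio, score/logrank, Wald). Fits that do
#' not converge or show separation (infinite coefficients) are flagged and
#' report no hazard ratios.
#'
#' @param records Data frame of patient records.
#' @param covariates Character vector of covariate column names.
#' @param time_col,event_col Names of the time and event columns
#'   (defaults `"os_time"`, `"os_event"`).
#' @param strata Optional column name to stratify the baseline hazard on.
#' @param subset Optional logical vector selecting records.
#' @return Object of class `survival_fit`.
#' @export
coxph_fit <- function(records, covariates, time_col = "os_time",
                      event_col = "os_event", strata = NULL, subset = NULL) {
  if (!is.null(subset)) records <- records[subset, , drop = FALSE]
  if (sum(records[[event_col]]) < 1) stop("no events in data", call. = FALSE)
  for (v in covariates) {
    if (length(unique(records[[v]][!is.na(records[[v]])])) < 2L) {
      stop("covariate '", v, "' is constant", call. = FALSE)
    }
  }
  rhs <- paste(c(covariates,
                 if (!is.null(strata)) sprintf("strata(%s)", strata)),
               collapse = " + ")
  fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s",
                                   time_col, event_col, rhs))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|out of iterations",
                conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  if (any(!is.finite(stats::coef(fit)))) converged <- FALSE
  s <- summary(fit)
  coefs <- if (converged) {
    data.frame(term = rownames(s$coefficients),
               log_hr = s$coefficients[, "coef"],
               hr = s$conf.int[, "exp(coef)"],
               hr_lower = s$conf.int[, "lower .95"],
               hr_upper = s$conf.int[, "upper .95"],
               se = s$coefficients[, "se(coef)"],
               p = s$coefficients[, "Pr(>|z|)"],
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(term = character(), log_hr = numeric(), hr = numeric(),
               hr_lower = numeric(), hr_upper = numeric(), se = numeric(),
               p = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(
    coefficients = coefs,
    tests = c(likelihood_ratio = unname(s$logtest["pvalue"]),
              score_logrank = unname(s$sctest["pvalue"]),
              wald = unname(s$waldtest["pvalue"])),
    statistics = c(likelihood_ratio = unname(s$logtest["test"]),
                   score_logrank = unname(s$sctest["test"]),
                   wald = unname(s$waldtest["test"])),
    n = s$n, events = unname(s$nevent), converged = converged,
    formula = deparse(fml)),
    class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> n = %d, events = %d%s\n", x$n, x$events,
              if (!x$converged) " [NOT CONVERGED - no hazard ratios]" else ""))
  if (x$converged && nrow(x$coefficients)) {
    df <- x$coefficients
    df$hr <- sprintf("%.3f [%.3f, %.3f]", df$hr, df$hr_lower, df$hr_upper)
    print(df[, c("term", "hr", "p")], row.names = FALSE)
    cat(sprintf("LR p = %.4g, score-logrank p = %.4g, Wald p = %.4g\n",
                x$tests["likelihood_ratio"], x$tests["score_logrank"],
                x$tests["wald"]))
  }
  invisible(x)
}

#' @export
coef.survival_fit <- function(object, ...) {
  setNames(object$coefficients$log_hr, object$coefficients$term)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values (same order as input).
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Normality-gated choice of group-comparison test
#'
#' Runs the Shapiro-Wilk test on the pooled values; with p >= `alpha` the
#' parametric branch is chosen (t-test for two groups, ANOVA for more),
#' otherwise the rank-based branch (Wilcoxon rank-sum / Kruskal-Wallis).
#'
#' @param values Numeric vector (>= 3 values).
#' @param n_groups Number of groups the variable will be compared across.
#' @param alpha Shapiro-Wilk significance gate (default 0.05).
#' @return Test identifier: one of `"t_test"`, `"wilcoxon"`, `"anova"`,
#'   `"kruskal_wallis"`.
#' @export
normality_gate <- function(values, n_groups = 2L, alpha = 0.05) {
  if (length(values) < 3L) {
    stop("at least 3 values are required for the Shapiro-Wilk gate",
         call. = FALSE)
  }
  normal <- shapiro.test(values)$p.value >= alpha
  if (n_groups <= 2L) {
    if (normal) "t_test" else "wilcoxon"
  } else {
    if (normal) "anova" else "kruskal_wallis"
  }
}

#' Run the gated group comparison
#'
#' Applies [normality_gate()] and runs the selected test.
#'
#' @param values Numeric vector.
#' @param groups Group labels (same length).
#' @param alpha Shapiro-Wilk gate (default 0.05).
#' @return List with `test` (identifier) and `p_value`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  test <- normality_gate(values, nlevels(droplevels(groups)), alpha)
  p <- switch(test,
    t_test = stats::t.test(values ~ groups)$p.value,
    wilcoxon = stats::wilcox.test(values ~ groups)$p.value,
    anova = summary(stats::aov(values ~ groups))[[1]][["Pr(>F)"]][1],
    kruskal_wallis = stats::kruskal.test(values, groups)$p.value)
  list(test = test, p_value = p)
}
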