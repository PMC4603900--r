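#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and returns the step function at the event
#' times only, together with the at-risk counts and the Greenwood variance of
#' the survival estimate. With no events the curve is identically 1.
#'
#' @param times positive observation times
#' @param events 0/1 event indicators of the same length
#' @return object of class `km_curve` with `event_times`, `survival`,
#'   `at_risk`, `variance` and `n`
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop_ctx("empty input")
  if (length(times) != length(events)) stop_ctx("length mismatch")
  if (anyNA(times) || anyNA(events)) stop_ctx("missing values in input")
  if (any(times < 0)) stop_ctx("negative time")
  if (!is_binary(events)) stop_ctx("events must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "none")
  keep <- sf$n.event > 0
  structure(list(
    event_times = sf$time[keep],
    survival = sf$surv[keep],
    at_risk = sf$n.risk[keep],
    # survfit std.err is the SE of log S; Greenwood variance of S is S^2 var(log S)
    variance = (sf$surv[keep] * sf$std.err[keep])^2,
    n = length(times)
  ), class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' The estimate is a right-continuous step function; the last value is
#' carried forward beyond the last event time, and the value before the
#' first event is 1.
#'
#' @param curve a [km_estimate()] result
#' @param t nonnegative time (vectorized)
#' @return survival probability at `t`
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), all(t >= 0))
  vapply(t, function(tt) {
    i <- sum(curve$event_times <= tt)
    if (i == 0L) 1 else curve$survival[i]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ",", length(x$event_times),
      "event times\n")
  if (length(x$event_times)) {
    cat(sprintf("  last: S(%g) = %.3f\n",
                max(x$event_times), x$survival[length(x$survival)]))
  }
  invisible(x)
}

#' Log-rank test for equality of survival distributions
#'
#' Observed-minus-expected chi-square with hypergeometric variance summed
#' over distinct event times, on `k - 1` degrees of freedom for `k` groups.
#' Wraps [survival::survdiff()].
#'
#' @param times,events as in [km_estimate()]
#' @param group group labels; every level must be nonempty
#' @return object of class `logrank_result` with `statistic`, `df`,
#'   `p_value`, and per-group observed/expected counts
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (any(table(group) == 0L)) stop_ctx("empty group level")
  if (nlevels(group) < 2L) stop_ctx("need at least two groups")
  if (length(times) != length(events) || length(times) != length(group)) {
    stop_ctx("length mismatch")
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1L
  structure(list(
    statistic = unname(sd$chisq),
    df = df,
    p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
    observed = sd$obs, expected = sd$exp
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank chi-square = %.3f on %d df, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards fit with Wald inference
#'
#' Maximizes the partial likelihood over the supplied design matrix, with
#' the Efron approximation for tied event times by default (Breslow
#' available for cross-checks). Returns coefficients, standard errors,
#' hazard ratios with log-scale 95 percent Wald confidence intervals, and
#' two-sided Wald p-values. Constant (non-identifiable) columns are
#' rejected; diverging coefficients (complete separation) are flagged via
#' `converged = FALSE`.
#'
#' @param times,events as in [km_estimate()]
#' @param design numeric matrix (or vector, treated as one column) of
#'   covariates; no missing values
#' @param labels optional coefficient names (default: design column names)
#' @param ties `"efron"` (default) or `"breslow"`
#' @return object of class `cox_fit`
#' @export
cox_fit <- function(times, events, design, labels = NULL,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop_ctx("missing values in design matrix")
  if (nrow(X) != length(times)) stop_ctx("design rows must match times")
  if (sum(events) < 1) stop_ctx("need at least one event")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop_ctx("non-identifiable: constant covariate column(s) ",
             paste(which(sds == 0), collapse = ", "))
  }
  if (is.null(labels)) {
    labels <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  }
  colnames(X) <- labels
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ X, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) {
        diverged <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- qnorm(0.975)
  converged <- !diverged && !anyNA(beta) && all(abs(beta) < 15)
  structure(list(
    coefficients = stats::setNames(beta, labels),
    standard_errors = stats::setNames(unname(se), labels),
    hr = stats::setNames(exp(beta), labels),
    ci95 = structure(
      cbind(lower = exp(beta - z * se), upper = exp(beta + z * se)),
      dimnames = list(labels, c("lower", "upper"))),
    wald_p = stats::setNames(
      2 * stats::pnorm(-abs(beta / se)), labels),
    loglik = unname(fit$loglik[2L]),
    loglik_null = unname(fit$loglik[1L]),
    n = fit$n, n_events = fit$nevent,
    ties = ties,
    converged = converged
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d%s\n", x$ties, x$n,
              x$n_events, if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(
    coef = x$coefficients,
    se = x$standard_errors,
    HR = x$hr,
    lower95 = x$ci95[, "lower"],
    upper95 = x$ci95[, "upper"],
    p = x$wald_p)
  print(round(tab, 4))
  invisible(x)
}
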