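#' Kaplan-Meier survival curve
#'
#' Product-limit estimator of the survival function; `S(0) = 1` and the
#' curve is non-increasing with right-continuous steps at event times.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicators (1 = death, 0 = censored).
#' @return A `km_curve`: data.frame-like list with `time`, `n_risk`,
#'   `n_event`, `surv`. Evaluate it at arbitrary times with
#'   [km_survival()].
#' @examples
#' km <- km_curve(c(1, 1.5, 2), c(1, 0, 1))
#' km_survival(km, c(0, 1, 2))
#' @export
km_curve <- function(time, event) {
  if (length(time) < 1L) stop("at least one record is required")
  if (length(event) != length(time)) stop("time/event length mismatch")
  if (any(time <= 0)) stop("times must be > 0")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = sf$time, n_risk = sf$n.risk,
                 n_event = sf$n.event, surv = sf$surv),
            class = "km_curve")
}

#' @rdname km_curve
#' @param km A `km_curve`.
#' @param t Times at which to evaluate the estimated survival.
#' @export
km_survival <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  f <- stats::stepfun(km$time, c(1, km$surv), right = FALSE)
  f(t)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-squared statistic with
#' hypergeometric variance at each distinct event time, 1 degree of
#' freedom.
#'
#' @param time,event Survival data.
#' @param group Two-level grouping vector.
#' @return List with `chisq`, `p_value`, `n` (group sizes), and the
#'   observed/expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    stop("exactly two non-empty groups are required")
  }
  if (sum(event) < 1L) {
    stop("log-rank statistic undefined without any events")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- sd$chisq
  list(chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       n = as.vector(table(droplevels(group))),
       observed = sd$obs, expected = sd$exp)
}

#' Minimum-p log-rank cutpoint for a continuous indicator
#'
#' Scans every admissible dichotomization of `values` (midpoints between
#' consecutive sorted distinct values whose low/high groups each contain
#' at least `ceiling(minprop * n)` subjects), computes the log-rank
#' p-value for each split, and returns the cutpoint with the smallest
#' p-value (ties broken toward the smaller cutpoint). Records with
#' missing `values` are dropped listwise.
#'
#' The minimum over many correlated tests is anticonservative as a
#' p-value; an optional maximally-selected-statistic correction
#' (improved-Bonferroni approximation for the supremum of a standardized
#' Brownian bridge over the admissible quantile range) is reported when
#' `corrected = TRUE`, but the uncorrected minimum p remains the primary
#' output.
#'
#' @param time,event Survival data.
#' @param values Continuous indicator, aligned with `time`.
#' @param minprop Minimum group proportion (default 0.1).
#' @param corrected Also report the corrected p-value.
#' @return A `cutpoint_result`: `cutpoint`, `chisq`, `p_value`,
#'   optionally `p_corrected`, group sizes `n_low` / `n_high`, `minprop`,
#'   and the scanned `candidates` table.
#' @export
optimal_cutpoint <- function(time, event, values, minprop = 0.1,
                             corrected = FALSE) {
  keep <- !is.na(values) & !is.na(time) & !is.na(event)
  time <- time[keep]; event <- event[keep]; values <- values[keep]
  n <- length(values)
  v <- sort(unique(values))
  if (length(v) < 2L) stop("at least two distinct values are required")
  min_n <- ceiling(minprop * n)
  cand <- (v[-length(v)] + v[-1L]) / 2
  n_low <- vapply(cand, function(ct) sum(values <= ct), 0L)
  ok <- n_low >= min_n & (n - n_low) >= min_n
  cand <- cand[ok]
  if (!length(cand)) stop("no admissible cutpoint under minprop")
  res <- lapply(cand, function(ct) {
    tryCatch({
      lr <- logrank_test(time, event, values > ct)
      c(chisq = lr$chisq, p = lr$p_value)
    }, error = function(e) c(chisq = NA_real_, p = NA_real_))
  })
  res <- do.call(rbind, res)
  if (all(is.na(res[, "p"]))) {
    stop("log-rank statistic undefined for every admissible cutpoint")
  }
  best <- which.min(res[, "p"])   # first minimum = smallest cutpoint
  out <- list(cutpoint = cand[best], chisq = unname(res[best, "chisq"]),
              p_value = unname(res[best, "p"]),
              n_low = sum(values <= cand[best]),
              n_high = sum(values > cand[best]),
              minprop = minprop, n = n,
              candidates = data.frame(cutpoint = cand,
                                      chisq = res[, "chisq"],
                                      p = res[, "p"]))
  if (corrected) {
    out$p_corrected <- maxstat_p(sqrt(out$chisq), minprop, 1 - minprop)
  }
  structure(out, class = "cutpoint_result")
}

# Improved-Bonferroni approximation for the supremum of |B(t)| /
# sqrt(t (1 - t)) over t in [eps1, eps2] exceeding b.
maxstat_p <- function(b, eps1, eps2) {
  if (b <= 0) return(1)
  p <- stats::dnorm(b) * (b - 1 / b) *
    log(eps2 * (1 - eps1) / (eps1 * (1 - eps2))) +
    4 * stats::dnorm(b) / b
  min(1, max(p, 2 * stats::pnorm(-b)))
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "min-p cutpoint %.4g (chisq %.3f, p %.4g; %d low / %d high, minprop %.2f)\n",
    x$cutpoint, x$chisq, x$p_value, x$n_low, x$n_high, x$minprop))
  if (!is.null(x$p_corrected)) {
    cat(sprintf("  corrected p (maximally selected statistic): %.4g\n",
                x$p_corrected))
  }
  invisible(x)
}

#' Cox proportional-hazards regression
#'
#' Fits a Cox model by partial-likelihood maximization with Efron's tie
#' correction and reports per-covariate hazard ratios with Wald
#' confidence intervals. Convergence problems and monotone-likelihood
#' separation (runaway coefficients) are flagged rather than silently
#' reported.
#'
#' @param data data.frame containing the time, event, and covariate
#'   columns.
#' @param covariates Character vector of covariate column names.
#' @param time,event Column names (defaults `"time"`, `"event"`).
#' @param conf_level Confidence level for the Wald intervals.
#' @return A `cox_result`: `table` (term, beta, se, hr, ci_low, ci_high,
#'   p), `loglik`, `converged`, `separation`, and any warnings captured.
#' @examples
#' d <- simulate_survival(runif(80), survival_sim_config(beta = -2, seed = 4))
#' d$z <- runif(80)
#' cox_fit(d, "z")
#' @export
cox_fit <- function(data, covariates, time = "time", event = "event",
                    conf_level = 0.95) {
  if (!all(covariates %in% names(data))) {
    stop("missing covariate columns: ",
         paste(setdiff(covariates, names(data)), collapse = ", "))
  }
  keep <- stats::complete.cases(data[, c(time, event, covariates)])
  data <- data[keep, , drop = FALSE]
  if (sum(data[[event]]) < 1L) stop("at least one event is required")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")))
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(
    term = names(beta), beta = unname(beta), se = unname(se),
    hr = exp(unname(beta)),
    ci_low = exp(unname(beta) - z * unname(se)),
    ci_high = exp(unname(beta) + z * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))))
  separation <- any(!is.finite(se)) || any(abs(beta) > 15) ||
    any(grepl("infinite", warns, ignore.case = TRUE))
  converged <- !any(grepl("did not converge|Ran out of iterations",
                          warns, ignore.case = TRUE)) && !separation
  structure(list(table = tab, loglik = fit$loglik[length(fit$loglik)],
                 n = fit$n, n_events = fit$nevent,
                 converged = converged, separation = separation,
                 warnings = warns),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox model (Efron ties): %d subjects, %d events\n",
              x$n, x$n_events))
  print(x$table, row.names = FALSE, digits = 4)
  if (!x$converged) cat("WARNING: fit did not converge cleanly\n")
  if (x$separation) cat("WARNING: monotone-likelihood separation suspected\n")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the t
#' approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p_value`.
#' @examples
#' spearman_cor(1:4, c(1, 3, 2, 4))$rho  # 0.8
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: rank correlation undefined")
  }
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}
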