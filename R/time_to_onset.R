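# Time-to-onset analysis: onset intervals, Weibull shape-parameter (WSP)
# failure profiles, and Kaplan-Meier cumulative incidence.

#' Compute time-to-onset records for a cohort
#'
#' The onset interval is the calendar-day difference between the adverse
#' event date and the therapy start date. Reports are excluded when either
#' date is missing, invalid or imprecise (month/year precision), or when the
#' therapy start postdates the event; same-day onsets (0 days) are kept. One
#' record is emitted per report. Exclusion counts by reason are attached as
#' the `"exclusions"` attribute.
#'
#' @param cohort A deduplicated `faers_reports` tibble.
#' @return Tibble with columns `caseid`, `days`; attribute `exclusions`.
#' @export
compute_tto <- function(cohort) {
  ev <- parse_date(cohort$event_date)
  st <- parse_date(cohort$therapy_start)
  imprecise <- ev$precision != "day" | st$precision != "day"
  days <- ev$ordinal_day - st$ordinal_day
  negative <- !imprecise & days < 0
  keep <- !imprecise & !negative
  out <- tibble::tibble(caseid = cohort$caseid[keep],
                        days = as.integer(days[keep]))
  attr(out, "exclusions") <- c(
    imprecise_or_missing_date = sum(imprecise),
    start_after_event = sum(negative)
  )
  out
}

#' Median and quartiles of onset times
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), so half-day values can occur.
#'
#' @param records Tibble from [compute_tto()] (or any object with a numeric
#'   `days` column).
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
tto_summary <- function(records) {
  days <- records$days
  if (length(days) == 0L) abort_faersmine("no valid time-to-onset records", "no_valid_tto")
  q <- unname(quantile(days, c(0.5, 0.25, 0.75), type = 7))
  c(median = q[1], q1 = q[2], q3 = q[3])
}

# negative log-likelihood of a 2-parameter Weibull in log-parameters
# theta = (log shape, log scale), with analytic gradient
weibull_nll <- function(theta, x) {
  beta <- exp(theta[1]); alpha <- exp(theta[2])
  z <- x / alpha
  -(length(x) * (log(beta) - beta * log(alpha)) +
      (beta - 1) * sum(log(x)) - sum(z^beta))
}

weibull_nll_grad <- function(theta, x) {
  beta <- exp(theta[1]); alpha <- exp(theta[2])
  n <- length(x)
  z <- x / alpha
  zb <- z^beta
  logz <- log(z)
  # d nll / d log beta, d nll / d log alpha
  c(-beta * (n / beta + sum(logz) - sum(zb * logz)),
    -beta * (sum(zb) - n))
}

#' Maximum-likelihood Weibull fit with shape-parameter failure profile
#'
#' Fits the 2-parameter Weibull distribution to onset times by maximum
#' likelihood (quasi-Newton on the log-parameters with analytic gradient) and
#' classifies the hazard profile from the shape parameter beta: a 95% CI
#' entirely below 1 indicates early failure (risk decreasing over time), a CI
#' containing 1 random failure (constant risk), and a CI entirely above 1
#' wear-out failure (risk increasing). The CI for beta is the Wald interval
#' on the log scale from the observed information matrix.
#'
#' Zero-day onsets lie outside the Weibull support and are shifted to 0.5
#' days rather than discarded, preserving same-day events; the shift is
#' configurable via `zero_day_value`.
#'
#' @param records Tibble from [compute_tto()], or a numeric vector of onset
#'   times in days.
#' @param min_n Minimum sample size (default 10).
#' @param conf_level Confidence level for the shape CI.
#' @param zero_day_value Replacement for zero-day onsets before fitting.
#' @return A `weibull_fit` list: `shape_beta`, `scale_alpha`, `beta_ci`
#'   (low/high), `scale_ci`, `profile`, `n`, `loglik`.
#' @export
weibull_mle <- function(records, min_n = 10, conf_level = 0.95,
                        zero_day_value = 0.5) {
  x <- if (is.numeric(records)) as.double(records) else as.double(records$days)
  x <- x[!is.na(x)]
  if (length(x) < min_n) {
    abort_faersmine(sprintf("need at least %d onset times, got %d", min_n,
                            length(x)), "insufficient_sample")
  }
  if (any(x < 0)) abort_faersmine("negative onset times", "negative_tto")
  x[x == 0] <- zero_day_value
  if (length(unique(x)) == 1L) {
    abort_faersmine("all onset times identical; Weibull fit is degenerate",
                    "degenerate_sample")
  }
  # moment-style start: shape from the log-sample spread, scale from its mean
  lx <- log(x)
  beta0 <- max(1.2 / stats::sd(lx), 1e-3)
  theta0 <- c(log(beta0), mean(lx) + 0.5772 / beta0)
  fit <- optim(theta0, weibull_nll, gr = weibull_nll_grad, x = x,
               method = "BFGS", hessian = FALSE,
               control = list(maxit = 500, reltol = 1e-12))
  # Newton polish on the score: quasi-Newton stops on function change, the
  # convergence contract here is on the score itself (1e-8 per observation)
  par <- fit$par
  tol <- 1e-8 * max(1, length(x))
  trace <- numeric()
  for (it in 1:25) {
    grad <- weibull_nll_grad(par, x)
    trace[it] <- max(abs(grad))
    if (trace[it] <= tol) break
    hess <- stats::optimHess(par, weibull_nll, weibull_nll_grad, x = x)
    step <- tryCatch(solve(hess, grad), error = function(e) grad * 0)
    par <- par - step
  }
  grad <- weibull_nll_grad(par, x)
  if (fit$convergence != 0 || max(abs(grad)) > tol) {
    abort_faersmine(paste0("Weibull MLE did not converge (code ",
                           fit$convergence, "); max |score| per iteration: ",
                           paste(format(trace, digits = 3), collapse = ", ")),
                    "weibull_nonconvergence")
  }
  fit$par <- par
  fit$value <- weibull_nll(par, x)
  vcov_log <- solve(stats::optimHess(par, weibull_nll, weibull_nll_grad, x = x))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  se_logbeta <- sqrt(vcov_log[1, 1])
  se_logalpha <- sqrt(vcov_log[2, 2])
  beta <- exp(fit$par[1]); alpha <- exp(fit$par[2])
  beta_ci <- c(low = beta * exp(-zq * se_logbeta),
               high = beta * exp(zq * se_logbeta))
  structure(list(
    shape_beta = beta, scale_alpha = alpha,
    beta_ci = beta_ci,
    scale_ci = c(low = alpha * exp(-zq * se_logalpha),
                 high = alpha * exp(zq * se_logalpha)),
    profile = classify_profile(beta_ci),
    n = length(x), loglik = -fit$value
  ), class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("<weibull_fit> n = %d\n", x$n))
  cat(sprintf("  shape beta = %.3f (95%% CI %.3f-%.3f)\n",
              x$shape_beta, x$beta_ci[["low"]], x$beta_ci[["high"]]))
  cat(sprintf("  scale alpha = %.1f days\n", x$scale_alpha))
  cat(sprintf("  profile: %s\n", x$profile))
  invisible(x)
}

#' Classify the Weibull failure profile from the shape CI
#'
#' @param beta_ci Numeric length-2 vector (low, high) of the 95% CI of the
#'   Weibull shape parameter.
#' @return `"early_failure"` (CI entirely below 1), `"random_failure"` (CI
#'   contains 1) or `"wear_out_failure"` (CI entirely above 1).
#' @export
#' @examples
#' classify_profile(c(0.75, 0.87))
#' classify_profile(c(1.21, 1.76))
classify_profile <- function(beta_ci) {
  lo <- beta_ci[[1]]; hi <- beta_ci[[2]]
  stopifnot(is.finite(lo), is.finite(hi), lo <= hi)
  if (hi < 1) "early_failure" else if (lo > 1) "wear_out_failure" else "random_failure"
}

#' Kaplan-Meier cumulative incidence of onset times
#'
#' Spontaneous reports are events by construction, so no censoring is
#' present and the KM cumulative incidence coincides with the empirical CDF;
#' the KM machinery is retained for API generality.
#'
#' @param records Tibble from [compute_tto()] or numeric vector of days.
#' @return A `km_curve` list: `times` (increasing), `cum_incidence`
#'   (non-decreasing, in \[0, 1\]), `n`.
#' @export
km_curve <- function(records) {
  days <- if (is.numeric(records)) records else records$days
  days <- as.double(days[!is.na(days)])
  stopifnot(length(days) >= 1)
  sf <- survival::survfit(survival::Surv(days, rep(1, length(days))) ~ 1)
  structure(list(times = sf$time, cum_incidence = 1 - sf$surv,
                 n = length(days)), class = "km_curve")
}

#' Cumulative incidence at a time point
#'
#' Step-function lookup on a [km_curve()]: 0 before the first event time.
#'
#' @param curve A `km_curve`.
#' @param t Numeric vector of times (days).
#' @return Numeric vector of cumulative incidences in \[0, 1\].
#' @export
km_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(ti) {
    i <- findInterval(ti, curve$times)
    if (i == 0L) 0 else curve$cum_incidence[i]
  }, double(1))
}

#' Overlay Kaplan-Meier cumulative incidence curves
#'
#' @param curves Named list of `km_curve` objects (one per drug).
#' @return A ggplot step plot of cumulative incidence against days.
#' @export
plot_km <- function(curves) {
  df <- dplyr::bind_rows(purrr::imap(curves, function(cv, nm) {
    tibble::tibble(drug = nm,
                   time = c(0, cv$times),
                   cum_incidence = c(0, cv$cum_incidence))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$cum_incidence,
                                   colour = .data$drug)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Days since therapy start",
                  y = "Cumulative incidence of adverse events",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
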