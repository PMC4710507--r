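# Survival analysis: Kaplan-Meier curves, median survival, log-rank tests,
# and the efficacy-curve bi-exponential fit.

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over event times `t_i` with
#' `d_i` events among `n_i` at risk; ties follow the standard convention
#' (events precede censorings at the same time).  Computed via
#' [survival::survfit()].
#'
#' @param times Survival times (months), `>= 0`.
#' @param events Logical (or 0/1) event indicators; `FALSE` = censored.
#' @return A `km_curve`: data frame fields `time`, `surv`, `n_risk`,
#'   `n_event`, `n_censor`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) stop("times and events lengths differ", call. = FALSE)
  if (any(times < 0)) stop("negative survival times", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  med <- median_survival(x)
  cat(sprintf("km_curve: %d subjects, %d events, median %s months\n",
              x$n, sum(x$n_event),
              if (is.na(med)) sprintf("> %.2f (not reached)", max(x$time)) else format(round(med, 2))))
  invisible(x)
}

#' Median survival from a Kaplan-Meier curve
#'
#' The smallest event time at which the survival probability drops to 0.5
#' or below; `NA` if the curve never reaches 0.5 (median beyond follow-up).
#'
#' @param curve A `km_curve` (see [km_estimate()]).
#' @return Months, or `NA` if undefined.
#' @export
median_survival <- function(curve) {
  i <- which(curve$surv <= 0.5 & curve$n_event > 0)
  if (!length(i)) NA_real_ else curve$time[min(i)]
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic over the pooled event times, with the
#' p-value from a chi-square distribution on 1 degree of freedom (via
#' [survival::survdiff()]); `method = "permutation"` instead estimates the
#' p-value by permuting group labels.
#'
#' @param times_a,times_b Survival times (months) in each group.
#' @param events_a,events_b Event indicators (`FALSE` = censored).
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations (default 10000).
#' @return List with `chi2` and `p`.
#' @export
logrank <- function(times_a, events_a, times_b, events_b,
                    method = c("chisq", "permutation"), n_perm = 10000) {
  method <- match.arg(method)
  times <- c(times_a, times_b)
  events <- as.integer(c(events_a, events_b))
  group <- rep(1:2, c(length(times_a), length(times_b)))
  chi2 <- logrank_chi2(times, events, group)
  if (method == "chisq") {
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    perm <- replicate(n_perm, logrank_chi2(times, events, sample(group)))
    p <- (1 + sum(perm >= chi2)) / (n_perm + 1)
  }
  list(chi2 = chi2, p = p)
}

logrank_chi2 <- function(times, events, group) {
  if (sum(events) == 0) return(0)   # no events anywhere: no information
  fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  unname(fit$chisq)
}

#' Fit a bi-exponential efficacy curve
#'
#' Nonlinear least squares for `f(x) = a e^{bx} + c e^{dx}`, used for the
#' relationship between agent efficacy (percent) and median overall
#' survival (months).  Initialised from a log-linear fit of the data plus a
#' small second component; on failure, retries from 5 seeded multi-start
#' perturbations.  Set `c_zero = TRUE` to fit a single exponential
#' (`c` fixed at 0).
#'
#' @param x Efficacy values (percent).
#' @param y Median overall survival (months); at least 5 points.
#' @param c_zero Fix `c = 0` (single-exponential fit).
#' @return List with `a`, `b`, `c`, `d`, `r_squared`, and the `fitted`
#'   values.
#' @export
fit_biexponential <- function(x, y, c_zero = FALSE) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 5) stop("need at least 5 points", call. = FALSE)
  df <- data.frame(x = x, y = y)
  lf <- stats::lm(log(pmax(y, 1e-8)) ~ x)
  a0 <- exp(coef(lf)[[1]]); b0 <- coef(lf)[[2]]
  fit1 <- function(start) {
    if (c_zero)
      minpack.lm::nlsLM(y ~ a * exp(b * x), data = df,
                        start = start[c("a", "b")],
                        control = nls.control(maxiter = 500))
    else
      minpack.lm::nlsLM(y ~ a * exp(b * x) + cc * exp(d * x), data = df,
                        start = start,
                        control = nls.control(maxiter = 500))
  }
  starts <- c(list(list(a = a0, b = b0, cc = max(a0 * 0.01, 1e-4), d = b0 * 4)),
              lapply(1:5, function(i) with_seed(i, list(
                a = a0 * runif(1, 0.5, 2), b = b0 * runif(1, 0.5, 2),
                cc = a0 * runif(1, 1e-4, 0.2), d = b0 * runif(1, 2, 8)))))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(fit1(st), error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("bi-exponential fit did not converge", call. = FALSE)
  cf <- coef(fit)
  fitted <- predict(fit)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(a = unname(cf["a"]), b = unname(cf["b"]),
       c = if (c_zero) 0 else unname(cf["cc"]),
       d = if (c_zero) NA_real_ else unname(cf["d"]),
       r_squared = r2, fitted = fitted)
}

#' @importFrom stats predict lm
NULL
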