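# Non-parametric comparator: Kaplan-Meier product-limit estimate with
# Greenwood's variance, and normal-approximation difference bands that plug
# into the same test machinery as the parametric bands.

#' Kaplan-Meier estimate with Greenwood variance
#'
#' Product-limit estimate \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}
#' with Greenwood's variance
#' \eqn{\widehat{Var}(t) = \hat S(t)^2 \sum_{t_i \le t} d_i / (n_i (n_i - d_i))}.
#' At tied times, events precede censorings (the standard convention: both
#' are counted with the risk set of all subjects with observed time
#' `>= t_i`).
#'
#' @inheritParams censored_loglik
#' @return A `km_fit`: data.frame with one row per distinct observed time
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `surv`, `var`).
#' @export
km_with_greenwood <- function(time, event) {
  s <- .check_sample(time, event)
  ut <- sort(unique(s$time))
  n_risk <- vapply(ut, function(u) sum(s$time >= u), numeric(1))
  n_event <- vapply(ut, function(u) sum(s$time == u & s$event == 1), numeric(1))
  n_censor <- vapply(ut, function(u) sum(s$time == u & s$event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw_inc <- ifelse(n_event > 0,
                   n_event / (n_risk * pmax(n_risk - n_event, 0)), 0)
  gw_inc[n_event > 0 & n_risk == n_event] <- Inf   # S drops to 0
  v <- surv^2 * cumsum(gw_inc)
  v[surv == 0] <- 0   # conventional: variance of a degenerate estimate
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv, var = v)
  class(out) <- c("km_fit", "data.frame")
  out
}

# step-function evaluation at arbitrary times (right-continuous;
# S = 1 and var = 0 before the first observed time)
.km_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  list(
    surv = ifelse(idx == 0, 1, km$surv[pmax(idx, 1)]),
    var = ifelse(idx == 0, 0, km$var[pmax(idx, 1)]),
    beyond = t > max(km$time)
  )
}

#' Non-parametric difference bands from two Kaplan-Meier curves
#'
#' Estimates `S1(t) - S2(t)` by the difference of the product-limit curves,
#' with variance the sum of the two Greenwood variances and normal
#' pointwise bands of the same one-sided form as the parametric ones, so
#' the result feeds [pointwise_test()] / [interval_test()] unchanged.
#'
#' @param time1,event1 Reference-arm sample.
#' @param time2,event2 Test-arm sample.
#' @param grid Evaluation times.
#' @param alpha One-sided level of each band.
#' @return An `nph_band` with `method = "nonparametric"`; grid points beyond
#'   the last observed time of either arm are flagged in `$unreliable`.
#' @export
np_diff_bands <- function(time1, event1, time2, event2, grid, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 0.5) {
    stop("alpha must lie in (0, 0.5]", call. = FALSE)
  }
  if (is.unsorted(grid)) stop("grid must be ordered", call. = FALSE)
  km1 <- km_with_greenwood(time1, event1)
  km2 <- km_with_greenwood(time2, event2)
  a1 <- .km_at(km1, grid)
  a2 <- .km_at(km2, grid)
  .new_band(grid, a1$surv - a2$surv, a1$var + a2$var, alpha,
            contrast = "surv_diff", method = "nonparametric",
            unreliable = a1$beyond | a2$beyond)
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier estimate,", sum(x$n_event), "events /",
      sum(x$n_event) + sum(x$n_censor), "observations\n")
  NextMethod()
}
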