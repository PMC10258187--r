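# Parametric survival families in the (shape, scale)-style parameterizations
# used throughout the package:
#   weibull      theta = (shape k, scale lambda),  S(t) = exp(-(t/lambda)^k)
#   exponential  theta = (rate)
#   log_logistic theta = (scale a, shape b),       S(t) = 1 / (1 + (t/a)^b)
#   log_normal   theta = (meanlog, sdlog)
#   gaussian     theta = (mean, sd)        -- support on all reals
#   logistic     theta = (location, scale) -- support on all reals
#   uniform      theta = (upper c), U[0, c] -- censoring-model use only
# All internal computations work with logS and logf to avoid underflow in the
# tails; S, f, h, H are derived from these.

.nph_families <- list(
  weibull = list(
    npar = 2L, par_names = c("shape", "scale"), support = "pos",
    positive = c(TRUE, TRUE),
    logS = function(t, th) stats::pweibull(t, th[1L], th[2L],
                                           lower.tail = FALSE, log.p = TRUE),
    logf = function(t, th) stats::dweibull(t, th[1L], th[2L], log = TRUE),
    q = function(p, th) stats::qweibull(p, th[1L], th[2L]),
    r = function(n, th) stats::rweibull(n, th[1L], th[2L]),
    start = function(t) {
      m <- mean(log(t))
      s <- stats::sd(log(t))
      if (!is.finite(s) || s <= 0) s <- 1
      c(1.2 / s, exp(m + 0.5772 * s))
    }
  ),
  exponential = list(
    npar = 1L, par_names = "rate", support = "pos", positive = TRUE,
    logS = function(t, th) -th[1L] * t,
    logf = function(t, th) log(th[1L]) - th[1L] * t,
    q = function(p, th) stats::qexp(p, th[1L]),
    r = function(n, th) stats::rexp(n, th[1L]),
    start = function(t) 1 / mean(t)
  ),
  log_logistic = list(
    npar = 2L, par_names = c("scale", "shape"), support = "pos",
    positive = c(TRUE, TRUE),
    # T = a * exp(Z / b), Z standard logistic
    logS = function(t, th) stats::plogis(th[2L] * log(t / th[1L]),
                                         lower.tail = FALSE, log.p = TRUE),
    logf = function(t, th) stats::dlogis(th[2L] * log(t / th[1L]), log = TRUE) +
      log(th[2L]) - log(t),
    q = function(p, th) th[1L] * exp(stats::qlogis(p) / th[2L]),
    r = function(n, th) th[1L] * exp(stats::rlogis(n) / th[2L]),
    start = function(t) {
      s <- stats::sd(log(t))
      if (!is.finite(s) || s <= 0) s <- 1
      c(exp(mean(log(t))), pi / (sqrt(3) * s))
    }
  ),
  log_normal = list(
    npar = 2L, par_names = c("meanlog", "sdlog"), support = "pos",
    positive = c(FALSE, TRUE),
    logS = function(t, th) stats::plnorm(t, th[1L], th[2L],
                                         lower.tail = FALSE, log.p = TRUE),
    logf = function(t, th) stats::dlnorm(t, th[1L], th[2L], log = TRUE),
    q = function(p, th) stats::qlnorm(p, th[1L], th[2L]),
    r = function(n, th) stats::rlnorm(n, th[1L], th[2L]),
    start = function(t) {
      s <- stats::sd(log(t))
      c(mean(log(t)), if (is.finite(s) && s > 0) s else 1)
    }
  ),
  gaussian = list(
    npar = 2L, par_names = c("mean", "sd"), support = "real",
    positive = c(FALSE, TRUE),
    logS = function(t, th) stats::pnorm(t, th[1L], th[2L],
                                        lower.tail = FALSE, log.p = TRUE),
    logf = function(t, th) stats::dnorm(t, th[1L], th[2L], log = TRUE),
    q = function(p, th) stats::qnorm(p, th[1L], th[2L]),
    r = function(n, th) stats::rnorm(n, th[1L], th[2L]),
    start = function(t) {
      s <- stats::sd(t)
      c(mean(t), if (is.finite(s) && s > 0) s else 1)
    }
  ),
  logistic = list(
    npar = 2L, par_names = c("location", "scale"), support = "real",
    positive = c(FALSE, TRUE),
    logS = function(t, th) stats::plogis(t, th[1L], th[2L],
                                         lower.tail = FALSE, log.p = TRUE),
    logf = function(t, th) stats::dlogis(t, th[1L], th[2L], log = TRUE),
    q = function(p, th) stats::qlogis(p, th[1L], th[2L]),
    r = function(n, th) stats::rlogis(n, th[1L], th[2L]),
    start = function(t) {
      s <- stats::sd(t)
      c(mean(t), if (is.finite(s) && s > 0) s * sqrt(3) / pi else 1)
    }
  ),
  uniform = list(
    npar = 1L, par_names = "upper", support = "pos", positive = TRUE,
    logS = function(t, th) ifelse(t >= th[1L], -Inf, log1p(-pmin(t, th[1L]) / th[1L])),
    logf = function(t, th) ifelse(t > th[1L], -Inf, -log(th[1L])),
    q = function(p, th) p * th[1L],
    r = function(n, th) stats::runif(n, 0, th[1L]),
    start = function(t) max(t) * 1.5
  )
)

#' Available parametric survival families
#'
#' The six candidate event-time families plus a uniform family intended for
#' censoring models only. Parameter conventions: `weibull` = (shape, scale)
#' with \eqn{S(t)=\exp\{-(t/scale)^{shape}\}}; `exponential` = (rate);
#' `log_logistic` = (scale, shape) with \eqn{S(t)=1/(1+(t/scale)^{shape})};
#' `log_normal` = (meanlog, sdlog); `gaussian` = (mean, sd); `logistic` =
#' (location, scale). The Gaussian and logistic families have support on the
#' whole real line; all others require `t >= 0`.
#'
#' @return Character vector of family names.
#' @export
surv_families <- function() names(.nph_families)

.get_family <- function(family) {
  if (!is.character(family) || length(family) != 1L ||
      is.na(match(family, names(.nph_families)))) {
    stop("unknown family '", paste(family, collapse = ","),
         "'; see surv_families()", call. = FALSE)
  }
  .nph_families[[family]]
}

.check_theta <- function(fam, theta, family) {
  theta <- as.numeric(theta)
  if (length(theta) != fam$npar) {
    stop("family '", family, "' needs ", fam$npar, " parameter(s), got ",
         length(theta), call. = FALSE)
  }
  if (any(!is.finite(theta))) {
    stop("non-finite parameter for family '", family, "'", call. = FALSE)
  }
  bad <- fam$positive & theta <= 0
  if (any(bad)) {
    stop("parameter '", fam$par_names[which(bad)[1L]], "' of family '",
         family, "' must be positive", call. = FALSE)
  }
  theta
}

.check_times <- function(fam, t, family) {
  if (any(!is.finite(t))) stop("non-finite time value", call. = FALSE)
  if (fam$support == "pos" && any(t < 0)) {
    stop("negative times are not in the support of family '", family, "'",
         call. = FALSE)
  }
  t
}

#' Evaluate a parametric survival family at given times
#'
#' Returns the survival function S, density f, hazard h = f/S and cumulative
#' hazard H = -log S at each time.
#'
#' @param family Family name, see [surv_families()].
#' @param theta Numeric parameter vector in the family's convention.
#' @param t Vector of evaluation times (non-negative except for the
#'   Gaussian and logistic families).
#' @return A data.frame with columns `t`, `S`, `f`, `h`, `H`.
#' @examples
#' evaluate_family("weibull", c(1.5, 4.9), c(1.6, 2.3, 3.8, 4))
#' @export
evaluate_family <- function(family, theta, t) {
  fam <- .get_family(family)
  theta <- .check_theta(fam, theta, family)
  t <- .check_times(fam, t, family)
  lS <- fam$logS(t, theta)
  lf <- fam$logf(t, theta)
  data.frame(t = t, S = exp(lS), f = exp(lf),
             h = exp(lf - lS), H = -lS)
}

#' @rdname evaluate_family
#' @param log If `TRUE` return the value on the log scale.
#' @export
surv_prob <- function(family, t, theta, log = FALSE) {
  fam <- .get_family(family)
  theta <- .check_theta(fam, theta, family)
  lS <- fam$logS(.check_times(fam, t, family), theta)
  if (log) lS else exp(lS)
}

#' @rdname evaluate_family
#' @export
surv_dens <- function(family, t, theta, log = FALSE) {
  fam <- .get_family(family)
  theta <- .check_theta(fam, theta, family)
  lf <- fam$logf(.check_times(fam, t, family), theta)
  if (log) lf else exp(lf)
}

#' @rdname evaluate_family
#' @export
surv_haz <- function(family, t, theta, log = FALSE) {
  fam <- .get_family(family)
  theta <- .check_theta(fam, theta, family)
  t <- .check_times(fam, t, family)
  lh <- fam$logf(t, theta) - fam$logS(t, theta)
  if (log) lh else exp(lh)
}

#' @rdname evaluate_family
#' @export
surv_cumhaz <- function(family, t, theta) {
  -surv_prob(family, t, theta, log = TRUE)
}

#' Quantile function of a parametric survival family
#'
#' Inverse of the event-time CDF: returns the time `q` with
#' \eqn{F(q) = p}, i.e. \eqn{S(q) = 1 - p}.
#'
#' @inheritParams evaluate_family
#' @param p Probabilities in `[0, 1)`.
#' @return Vector of times.
#' @examples
#' surv_quantile("weibull", 0.5, c(1.5, 3.4)) # median, 3.4 * log(2)^(1/1.5)
#' @export
surv_quantile <- function(family, p, theta) {
  fam <- .get_family(family)
  theta <- .check_theta(fam, theta, family)
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("p must lie in [0, 1)", call. = FALSE)
  }
  fam$q(p, theta)
}

#' Draw random event times from a parametric survival family
#'
#' Uses R's global RNG stream; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @inheritParams evaluate_family
#' @param n Number of draws.
#' @return Vector of `n` times.
#' @export
surv_sample <- function(family, n, theta) {
  fam <- .get_family(family)
  theta <- .check_theta(fam, theta, family)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1",
                                                       call. = FALSE)
  fam$r(n, theta)
}
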