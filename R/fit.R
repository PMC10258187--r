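# Censored-data maximum likelihood. The observed-data likelihood for one arm
# factorizes into an event-model part
#     prod_j f(t_j)^d_j * S(t_j)^(1-d_j)
# and a censoring-model part
#     prod_j (1 - G(t_j))^d_j * g(t_j)^(1-d_j),
# which is the event-model part of the sample with the event indicators
# flipped. Both are maximized here; the observed information (negative
# Hessian of the log-likelihood at the MLE) is returned in the family's
# natural parameterization, so its inverse already carries the 1/n scaling
# needed by the delta method.

.check_sample <- function(time, event) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(event)) {
    stop("time and event must have equal length", call. = FALSE)
  }
  if (length(time) == 0L) stop("empty sample", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("all observation times must be finite and positive", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("event indicators must be coded 0 (censored) / 1 (event)",
         call. = FALSE)
  }
  list(time = time, event = event)
}

#' Censored-data log-likelihood
#'
#' Log-likelihood of right-censored observations under a parametric event
#' model: events contribute `log f(t)`, censored observations `log S(t)`.
#'
#' @param time Positive observation times.
#' @param event Event indicators, 1 = event, 0 = censored.
#' @inheritParams evaluate_family
#' @return The log-likelihood; `-Inf` if any observation has zero density or
#'   survival under `theta`.
#' @export
censored_loglik <- function(time, event, family, theta) {
  s <- .check_sample(time, event)
  fam <- .get_family(family)
  theta <- .check_theta(fam, theta, family)
  lf <- fam$logf(s$time, theta)
  lS <- fam$logS(s$time, theta)
  ll <- sum(ifelse(s$event == 1, lf, lS))
  if (!is.finite(ll)) -Inf else ll
}

# negative log-likelihood on the optimizer's transformed scale
.make_nll <- function(fam, time, event) {
  pos <- fam$positive
  function(par) {
    th <- par
    th[pos] <- exp(par[pos])
    lf <- fam$logf(time, th)
    lS <- fam$logS(time, th)
    nll <- -sum(ifelse(event == 1, lf, lS))
    if (!is.finite(nll)) 1e10 else nll
  }
}

.obs_info <- function(fam, family, time, event, theta) {
  f <- function(th) {
    lf <- fam$logf(time, th)
    lS <- fam$logS(time, th)
    sum(ifelse(event == 1, lf, lS))
  }
  info <- -pracma::hessian(f, theta)
  (info + t(info)) / 2
}

.new_fit <- function(family, theta, loglik, info, n, n_event, role,
                     converged = TRUE) {
  fam <- .get_family(family)
  names(theta) <- fam$par_names
  dimnames(info) <- list(fam$par_names, fam$par_names)
  structure(list(
    family = family, theta = theta, loglik = loglik, info = info,
    n = n, n_event = n_event, npar = fam$npar,
    aic = -2 * loglik + 2 * fam$npar, role = role, converged = converged
  ), class = "nph_fit")
}

# profile MLE for the Weibull: given shape k the scale MLE is closed form,
# lambda = (sum t^k / d)^(1/k), leaving a smooth 1-d problem in log k
.fit_weibull <- function(time, event) {
  d <- sum(event)
  prof <- function(lk) {
    k <- exp(lk)
    lam <- (sum(time^k) / d)^(1 / k)
    sum(event * stats::dweibull(time, k, lam, log = TRUE) +
          (1 - event) * stats::pweibull(time, k, lam, lower.tail = FALSE,
                                        log.p = TRUE))
  }
  o <- stats::optimize(prof, c(-4, 4), maximum = TRUE, tol = 1e-10)
  k <- exp(o$maximum)
  c(k, (sum(time^k) / d)^(1 / k))
}

.fit_uniform_cens <- function(time, event) {
  # "events" of the model being fitted contribute its survival 1 - t/c,
  # "censorings" its density 1/c; the MLE exceeds max(time)
  tm <- max(time)
  obj <- function(lc) {
    c0 <- tm + exp(lc)
    sum(event * log1p(-time / c0)) - sum(1 - event) * log(c0)
  }
  o <- stats::optimize(obj, c(log(tm) - 20, log(tm) + 12), maximum = TRUE,
                       tol = 1e-10)
  tm + exp(o$maximum)
}

#' Fit a parametric event-time model to right-censored data
#'
#' Maximum likelihood under right censoring. The exponential rate has a
#' closed-form MLE; the Weibull is maximized by profiling out the scale; the
#' remaining families are optimized by BFGS on log-transformed positive
#' parameters with up to 5 jittered restarts. The observed information is
#' the numerically differentiated negative Hessian at the optimum, in the
#' natural parameterization.
#'
#' @inheritParams censored_loglik
#' @param family Event-time family, see [surv_families()].
#' @return An object of class `nph_fit` with elements `family`, `theta`,
#'   `loglik`, `info` (observed information), `n`, `n_event`, `aic`.
#' @examples
#' set.seed(1)
#' y <- rweibull(200, 1.5, 3.4)
#' cns <- rexp(200, 0.1)
#' fit_event_model(pmin(y, cns), as.numeric(y <= cns), "weibull")
#' @export
fit_event_model <- function(time, event, family = "weibull") {
  s <- .check_sample(time, event)
  fam <- .get_family(family)
  if (sum(s$event) < 1) {
    stop("event-model fitting requires at least one event", call. = FALSE)
  }
  time <- s$time
  event <- s$event

  if (family == "exponential") {
    rate <- sum(event) / sum(time)
    theta <- rate
    info <- matrix(sum(event) / rate^2, 1, 1)
    ll <- censored_loglik(time, event, family, theta)
    return(.new_fit(family, theta, ll, info, length(time), sum(event),
                    "event"))
  }
  if (family == "weibull") {
    theta <- .fit_weibull(time, event)
  } else if (family == "uniform") {
    theta <- .fit_uniform_cens(time, 1 - event)
  } else {
    nll <- .make_nll(fam, time, event)
    start <- fam$start(time[event == 1])
    par0 <- start
    par0[fam$positive] <- log(par0[fam$positive])
    best <- NULL
    for (try in 0:5) {
      p0 <- if (try == 0) par0 else par0 + stats::rnorm(length(par0), 0, 0.3)
      o <- tryCatch(stats::optim(p0, nll, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
      if (!is.null(o) && o$value < 1e9 &&
          (is.null(best) || o$value < best$value)) best <- o
      if (!is.null(best) && try >= 1) break
    }
    if (is.null(best)) {
      stop("maximum-likelihood fit did not converge for family '", family,
           "' after restarts", call. = FALSE)
    }
    theta <- best$par
    theta[fam$positive] <- exp(theta[fam$positive])
  }
  ll <- censored_loglik(time, event, family, theta)
  if (!is.finite(ll)) {
    stop("degenerate fit for family '", family, "'", call. = FALSE)
  }
  info <- .obs_info(fam, family, time, event, theta)
  .new_fit(family, theta, ll, info, length(time), sum(event), "event")
}

#' Fit a parametric model for the censoring distribution
#'
#' Maximizes the censoring factor of the full likelihood, which equals the
#' event-model likelihood of the sample with event indicators flipped:
#' censored observations contribute the censoring density `g`, events the
#' censoring survival `1 - G`. The `uniform` family (censoring uniform on
#' `[0, upper]`) is supported here in addition to the event families.
#'
#' @inheritParams fit_event_model
#' @return An `nph_fit` with `role = "censoring"`; `n_event` counts the
#'   censored observations.
#' @export
fit_censoring_model <- function(time, event, family = "exponential") {
  s <- .check_sample(time, event)
  if (sum(1 - s$event) < 1) {
    stop("censoring-model fitting requires at least one censored observation",
         call. = FALSE)
  }
  f <- fit_event_model(s$time, 1 - s$event, family)
  f$role <- "censoring"
  f
}

#' AIC-based model selection across candidate families
#'
#' Fits each candidate family to the same censored sample and ranks by AIC
#' (`-2 loglik + 2 npar`), ascending, ties broken by fewer parameters.
#' Families that fail to fit are kept in the table with the error message.
#'
#' @inheritParams fit_event_model
#' @param families Character vector of candidate families (at least two
#'   unless you really want a one-row table).
#' @return A data.frame with columns `family`, `npar`, `loglik`, `aic`,
#'   `error`, sorted by AIC; the fitted objects are in `attr(, "fits")`.
#' @export
model_selection_aic <- function(time, event,
                                families = c("weibull", "exponential",
                                             "gaussian", "logistic",
                                             "log_normal", "log_logistic")) {
  fits <- lapply(families, function(f) {
    tryCatch(fit_event_model(time, event, f), error = function(e) e)
  })
  names(fits) <- families
  tab <- data.frame(
    family = families,
    npar = vapply(families, function(f) .get_family(f)$npar, integer(1)),
    loglik = vapply(fits, function(x)
      if (inherits(x, "nph_fit")) x$loglik else NA_real_, numeric(1)),
    aic = vapply(fits, function(x)
      if (inherits(x, "nph_fit")) x$aic else NA_real_, numeric(1)),
    error = vapply(fits, function(x)
      if (inherits(x, "nph_fit")) "" else conditionMessage(x), character(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(is.na(tab$aic), tab$aic, tab$npar)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' @export
print.nph_fit <- function(x, ...) {
  cat("Parametric", x$role, "model:", x$family, "\n")
  cat("  n =", x$n, " events =", x$n_event, "\n")
  cat("  theta =", paste(sprintf("%s=%.4g", names(x$theta), x$theta),
                         collapse = ", "), "\n")
  cat("  loglik =", format(x$loglik, digits = 6),
      " AIC =", format(x$aic, digits = 6), "\n")
  invisible(x)
}

#' @export
vcov.nph_fit <- function(object, ...) {
  info <- object$info
  rc <- tryCatch(rcond(info), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-12) {
    stop("observed information is numerically singular (rcond = ",
         format(rc, digits = 3), ")", call. = FALSE)
  }
  solve(info)
}

#' @export
logLik.nph_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, class = "logLik")
}

#' @export
AIC.nph_fit <- function(object, ..., k = 2) {
  -2 * object$loglik + k * object$npar
}
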