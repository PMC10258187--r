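# Pointwise confidence bands for the two contrasts
#     Delta(t) = S1(t, theta1) - S2(t, theta2)
#     r(t)     = log{ h1(t, theta1) / h2(t, theta2) }
# The asymptotic variance is the delta-method form
#     sigma^2(t) = g1' I1^{-1} g1 + g2' I2^{-1} g2,
# with g_l the gradient of S_l(t, .) (or log h_l(t, .)) at the MLE and I_l
# the full-sample observed information, whose inverse already carries the
# 1/n_l scaling. The parametric bootstrap instead simulates from the fitted
# event and censoring models, refits, and takes the empirical variance of
# the contrast across replicates.

.contrasts <- c("surv_diff", "log_hr")

# gradient of S(t, theta) wrt theta: matrix npar x length(t);
# analytic for weibull/exponential, central differences otherwise
.grad_surv <- function(family, theta, t, numeric = FALSE) {
  if (!numeric && family == "weibull") {
    k <- theta[1L]; lam <- theta[2L]
    u <- (t / lam)^k
    s <- exp(-u)
    gk <- ifelse(t > 0, -s * u * log(t / lam), 0)
    return(rbind(gk, s * u * k / lam, deparse.level = 0))
  }
  if (!numeric && family == "exponential") {
    return(rbind(-t * exp(-theta[1L] * t), deparse.level = 0))
  }
  .grad_numeric(function(th) surv_prob(family, t, th), theta)
}

# gradient of log h(t, theta) wrt theta
.grad_loghaz <- function(family, theta, t, numeric = FALSE) {
  if (!numeric && family == "weibull") {
    k <- theta[1L]; lam <- theta[2L]
    return(rbind(1 / k - log(lam) + log(t),
                 rep(-k / lam, length(t)), deparse.level = 0))
  }
  if (!numeric && family == "exponential") {
    return(rbind(rep(1 / theta[1L], length(t)), deparse.level = 0))
  }
  .grad_numeric(function(th) surv_haz(family, t, th, log = TRUE), theta)
}

.grad_numeric <- function(f, theta) {
  h <- 1e-6 * pmax(1, abs(theta))
  g <- vapply(seq_along(theta), function(i) {
    e <- replace(numeric(length(theta)), i, h[i])
    (f(theta + e) - f(theta - e)) / (2 * h[i])
  }, numeric(length(f(theta))))
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  t(g)
}

.check_fit <- function(x, arg) {
  if (!inherits(x, "nph_fit")) {
    stop("'", arg, "' must be an nph_fit object", call. = FALSE)
  }
  x
}

#' Contrast between two fitted survival models
#'
#' Evaluates either the survival-curve difference `S1(t) - S2(t)` or the
#' log hazard ratio `log(h1(t) / h2(t))` at the fitted parameters.
#'
#' @param fit1,fit2 `nph_fit` event models for the reference (1) and test
#'   (2) arm.
#' @param t Evaluation times.
#' @param contrast `"surv_diff"` or `"log_hr"`.
#' @return Numeric vector of contrast values.
#' @export
contrast_at <- function(fit1, fit2, t, contrast = c("surv_diff", "log_hr")) {
  contrast <- match.arg(contrast)
  .check_fit(fit1, "fit1"); .check_fit(fit2, "fit2")
  if (contrast == "surv_diff") {
    surv_prob(fit1$family, t, fit1$theta) - surv_prob(fit2$family, t, fit2$theta)
  } else {
    r <- surv_haz(fit1$family, t, fit1$theta, log = TRUE) -
      surv_haz(fit2$family, t, fit2$theta, log = TRUE)
    if (any(!is.finite(r))) {
      stop("log hazard ratio is not finite at some evaluation times ",
           "(zero hazard or survival)", call. = FALSE)
    }
    r
  }
}

#' Delta-method variance of a contrast
#'
#' Asymptotic variance of the estimated contrast obtained by propagating the
#' inverse observed information of each arm through the gradient of
#' `S(t, theta)` (or `log h(t, theta)`). Gradients are analytic for the
#' Weibull and exponential families and central finite differences
#' otherwise.
#'
#' @inheritParams contrast_at
#' @return Vector of variances (one per time), non-negative.
#' @export
delta_variance <- function(fit1, fit2, t, contrast = c("surv_diff", "log_hr")) {
  contrast <- match.arg(contrast)
  .check_fit(fit1, "fit1"); .check_fit(fit2, "fit2")
  v1 <- vcov(fit1)
  v2 <- vcov(fit2)
  gfun <- if (contrast == "surv_diff") .grad_surv else .grad_loghaz
  g1 <- gfun(fit1$family, fit1$theta, t)
  g2 <- gfun(fit2$family, fit2$theta, t)
  out <- colSums(g1 * (v1 %*% g1)) + colSums(g2 * (v2 %*% g2))
  unname(pmax(out, 0))
}

.new_band <- function(grid, estimate, variance, alpha, contrast, method,
                      n_boot = NA_integer_, unreliable = NULL) {
  z <- stats::qnorm(1 - alpha)
  sd <- sqrt(variance)
  out <- data.frame(t = grid, estimate = estimate, variance = variance,
                    lower = estimate - z * sd, upper = estimate + z * sd)
  structure(list(band = out, alpha = alpha, contrast = contrast,
                 method = method, n_boot = n_boot,
                 unreliable = unreliable %||% rep(FALSE, length(grid))),
            class = "nph_band")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pointwise confidence bands for a survival contrast
#'
#' One-sided `(1 - alpha)` lower and upper pointwise bands
#' `estimate -/+ z_{1-alpha} * sigma_hat` on a user-supplied time grid,
#' with the variance from the delta method (`method = "asymptotic"`) or the
#' parametric bootstrap (`method = "bootstrap"`). Displayed jointly the two
#' one-sided bands form a two-sided `(1 - 2 alpha)` interval; this is the
#' construct the intersection-union tests consume.
#'
#' @inheritParams contrast_at
#' @param grid Ordered evaluation times.
#' @param alpha One-sided level in `(0, 0.5]` of each band.
#' @param method `"asymptotic"` or `"bootstrap"`.
#' @param censor_fit1,censor_fit2 Fitted censoring models (required for the
#'   bootstrap; see [fit_censoring_model()]).
#' @param n_boot Bootstrap replicates.
#' @param t_max Administrative censoring cap applied when regenerating
#'   bootstrap data; `Inf` when the original design had none.
#' @param seed Seed for the bootstrap (required there, ignored otherwise).
#' @return An `nph_band` object: data.frame `$band` with columns
#'   `t, estimate, variance, lower, upper` plus metadata.
#' @export
pointwise_bands <- function(fit1, fit2, grid,
                            contrast = c("surv_diff", "log_hr"),
                            alpha = 0.05,
                            method = c("asymptotic", "bootstrap"),
                            censor_fit1 = NULL, censor_fit2 = NULL,
                            n_boot = 500L, t_max = Inf, seed = NULL) {
  contrast <- match.arg(contrast)
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 0.5) {
    stop("alpha must lie in (0, 0.5]", call. = FALSE)
  }
  if (is.unsorted(grid)) stop("grid must be ordered", call. = FALSE)
  est <- contrast_at(fit1, fit2, grid, contrast)
  v <- if (method == "asymptotic") {
    delta_variance(fit1, fit2, grid, contrast)
  } else {
    bootstrap_variance(fit1, fit2, censor_fit1, censor_fit2, grid,
                       contrast = contrast, n_boot = n_boot, t_max = t_max,
                       seed = seed)
  }
  .new_band(grid, est, v, alpha, contrast, method,
            n_boot = if (method == "bootstrap") n_boot else NA_integer_)
}

#' Parametric-bootstrap variance of a contrast
#'
#' Implements the parametric bootstrap: per replicate, event times are drawn
#' from the fitted event models and censoring times from the fitted
#' censoring models, observations are capped at `t_max`, the event models
#' are refitted and the contrast re-evaluated on the grid; the empirical
#' variance (denominator `n_boot - 1`) across replicates is returned per
#' grid point. Replicates that fail to refit (e.g. no events) are redrawn;
#' more than 10% failures abort.
#'
#' @inheritParams pointwise_bands
#' @return Vector of variances, one per grid point.
#' @export
bootstrap_variance <- function(fit1, fit2, censor_fit1, censor_fit2, grid,
                               contrast = c("surv_diff", "log_hr"),
                               n_boot = 500L, t_max = Inf, seed = NULL) {
  contrast <- match.arg(contrast)
  .check_fit(fit1, "fit1"); .check_fit(fit2, "fit2")
  .check_fit(censor_fit1, "censor_fit1"); .check_fit(censor_fit2, "censor_fit2")
  if (is.null(seed)) {
    stop("bootstrap_variance requires an explicit seed for reproducibility",
         call. = FALSE)
  }
  if (!is.numeric(n_boot) || n_boot < 2) stop("n_boot must be >= 2",
                                              call. = FALSE)
  set.seed(seed)
  fits <- list(fit1, fit2)
  cfits <- list(censor_fit1, censor_fit2)
  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(grid))
  fail <- 0L
  max_fail <- ceiling(0.1 * n_boot)
  k <- 1L
  while (k <= n_boot) {
    one <- tryCatch({
      refit <- lapply(1:2, function(l) {
        y <- surv_sample(fits[[l]]$family, fits[[l]]$n, fits[[l]]$theta)
        cns <- surv_sample(cfits[[l]]$family, fits[[l]]$n, cfits[[l]]$theta)
        tobs <- pmin(y, cns, t_max)
        ev <- as.numeric(y <= pmin(cns, t_max))
        if (sum(ev) < 1) stop("no events in bootstrap replicate")
        fit_event_model(tobs, ev, fits[[l]]$family)
      })
      val <- contrast_at(refit[[1L]], refit[[2L]], grid, contrast)
      if (any(!is.finite(val))) stop("non-finite contrast in replicate")
      val
    }, error = function(e) NULL)
    if (is.null(one)) {
      fail <- fail + 1L
      if (fail > max_fail) {
        stop("more than 10% of bootstrap replicates failed to refit",
             call. = FALSE)
      }
    } else {
      reps[k, ] <- one
      k <- k + 1L
    }
  }
  apply(reps, 2L, stats::var)
}

#' @export
print.nph_band <- function(x, ...) {
  cat(sprintf("Pointwise %s bands for %s (alpha = %g one-sided%s)\n",
              x$method, x$contrast, x$alpha,
              if (!is.na(x$n_boot)) paste0(", n_boot = ", x$n_boot) else ""))
  print(utils::head(x$band, 10))
  if (nrow(x$band) > 10) cat("  ...", nrow(x$band), "grid points\n")
  invisible(x)
}

#' @export
as.data.frame.nph_band <- function(x, ...) x$band
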