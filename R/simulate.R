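# Scenario generator and Monte-Carlo harness. The built-in presets encode
# the operating-characteristic study designs: two Weibull scenarios (PH:
# proportional hazards; NPH: crossing curves) with exponential random
# censoring plus administrative censoring at t_max = 9 months, calibrated
# to ~25% censoring, and a log-logistic scenario with uniform censoring
# (~20%) and t_max = 12 used to study misspecification (the analysis model
# stays Weibull there by design).

.presets <- function() list(
  `ph-type1` = list(
    arms = list(
      list(event_family = "weibull", event_theta = c(1.5, 3.4),
           censor_family = "exponential", censor_theta = 0.1),
      list(event_family = "weibull", event_theta = c(1.5, 4.9),
           censor_family = "exponential", censor_theta = 0.09)),
    t_max = 9, grid = seq(1.5, 6, length.out = 23), fit_family = "weibull"),
  `ph-power` = list(
    arms = list(
      list(event_family = "weibull", event_theta = c(1.5, 3.4),
           censor_family = "exponential", censor_theta = 0.1),
      list(event_family = "weibull", event_theta = c(1.5, 3.7),
           censor_family = "exponential", censor_theta = 0.05)),
    t_max = 9, grid = seq(1.5, 6, length.out = 23), fit_family = "weibull"),
  `nph-type1` = list(
    arms = list(
      list(event_family = "weibull", event_theta = c(1.5, 3.4),
           censor_family = "exponential", censor_theta = 0.1),
      list(event_family = "weibull", event_theta = c(2, 2.5),
           censor_family = "exponential", censor_theta = 0.14)),
    t_max = 9, grid = seq(1.5, 4, length.out = 14), fit_family = "weibull"),
  `nph-power` = list(
    arms = list(
      list(event_family = "weibull", event_theta = c(1.5, 3.4),
           censor_family = "exponential", censor_theta = 0.1),
      list(event_family = "weibull", event_theta = c(2, 3.4),
           censor_family = "exponential", censor_theta = 0.1)),
    t_max = 9, grid = seq(1.5, 4, length.out = 14), fit_family = "weibull"),
  `ll-misspec` = list(
    arms = list(
      list(event_family = "log_logistic", event_theta = c(2.6, 1.5),
           censor_family = "uniform", censor_theta = NA),
      list(event_family = "log_logistic", event_theta = c(3.9, 2.1),
           censor_family = "uniform", censor_theta = NA)),
    t_max = 12, grid = seq(1, 5, length.out = 21), fit_family = "weibull")
)

# expected censored fraction P(Y > min(C, t_max)) for uniform C on [0, c]
.unif_cens_frac <- function(c0, family, theta, t_max) {
  up <- min(c0, t_max)
  intS <- stats::integrate(function(u) surv_prob(family, u, theta),
                           0, up, rel.tol = 1e-9)$value
  (intS + if (c0 > t_max) (c0 - t_max) * surv_prob(family, t_max, theta)
   else 0) / c0
}

#' Build a two-arm simulation scenario
#'
#' Returns a scenario configuration: per arm an event model and a censoring
#' model, an administrative cutoff `t_max`, a default evaluation grid and
#' the analysis family used when fitting simulated trials. Presets:
#' `"ph-type1"`, `"ph-power"` (proportional-hazards Weibull pair),
#' `"nph-type1"`, `"nph-power"` (crossing Weibull curves), and
#' `"ll-misspec"` (log-logistic truth, uniform censoring calibrated
#' numerically to ~20%, analyzed with a deliberately misspecified Weibull).
#' Any field can be overridden for custom designs.
#'
#' @param preset Preset name, or `NULL` to build a fully custom scenario
#'   from the remaining arguments.
#' @param n1,n2 Arm sample sizes.
#' @param arms Optional list of two arm specifications (`event_family`,
#'   `event_theta`, `censor_family`, `censor_theta`), overriding the preset.
#' @param t_max,grid,fit_family Optional overrides.
#' @param censor_fit_family Family used to model censoring when the
#'   bootstrap needs it (default exponential; set `"uniform"` to study
#'   censoring-model misspecification).
#' @return An object of class `nph_scenario`.
#' @export
scenario_config <- function(preset = c("ph-type1", "ph-power", "nph-type1",
                                       "nph-power", "ll-misspec"),
                            n1 = 100L, n2 = 100L, arms = NULL, t_max = NULL,
                            grid = NULL, fit_family = NULL,
                            censor_fit_family = "exponential") {
  if (is.null(preset) && is.null(arms)) {
    stop("either a preset or explicit arms must be given", call. = FALSE)
  }
  base <- if (!is.null(preset)) {
    preset <- match.arg(preset)
    .presets()[[preset]]
  } else list(arms = NULL, t_max = NULL, grid = NULL, fit_family = "weibull")
  cfg <- list(
    name = preset %||% "custom",
    n = c(n1, n2),
    arms = arms %||% base$arms,
    t_max = t_max %||% base$t_max,
    grid = grid %||% base$grid,
    fit_family = fit_family %||% base$fit_family,
    censor_fit_family = censor_fit_family
  )
  if (length(cfg$arms) != 2L) stop("exactly two arms required", call. = FALSE)
  if (!is.numeric(cfg$t_max) || cfg$t_max <= 0) {
    stop("t_max must be positive", call. = FALSE)
  }
  # calibrate uniform censoring bounds to ~20% censoring where unset
  for (l in 1:2) {
    a <- cfg$arms[[l]]
    if (identical(a$censor_family, "uniform") && any(is.na(a$censor_theta))) {
      f <- function(c0) .unif_cens_frac(c0, a$event_family, a$event_theta,
                                        cfg$t_max) - 0.2
      cfg$arms[[l]]$censor_theta <-
        stats::uniroot(f, c(0.05, 500), tol = 1e-8)$root
    }
    .check_theta(.get_family(cfg$arms[[l]]$event_family),
                 cfg$arms[[l]]$event_theta, cfg$arms[[l]]$event_family)
    .check_theta(.get_family(cfg$arms[[l]]$censor_family),
                 cfg$arms[[l]]$censor_theta, cfg$arms[[l]]$censor_family)
  }
  structure(cfg, class = "nph_scenario")
}

#' True contrast of a scenario
#'
#' Evaluates the scenario's true `S1 - S2` or log hazard ratio at `t`,
#' from the generating models (not from any fit).
#'
#' @param config An `nph_scenario`.
#' @param t Evaluation times.
#' @inheritParams contrast_at
#' @export
true_contrast <- function(config, t, contrast = c("surv_diff", "log_hr")) {
  contrast <- match.arg(contrast)
  a <- config$arms
  if (contrast == "surv_diff") {
    surv_prob(a[[1L]]$event_family, t, a[[1L]]$event_theta) -
      surv_prob(a[[2L]]$event_family, t, a[[2L]]$event_theta)
  } else {
    surv_haz(a[[1L]]$event_family, t, a[[1L]]$event_theta, log = TRUE) -
      surv_haz(a[[2L]]$event_family, t, a[[2L]]$event_theta, log = TRUE)
  }
}

#' Generate one two-arm trial from a scenario
#'
#' Per subject a latent event time `Y` is drawn from the arm's event model
#' and a censoring time `C` from its censoring model; the observation is
#' `min(Y, C, t_max)` with event indicator `1` iff `Y <= min(C, t_max)`.
#'
#' @param config An `nph_scenario`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A data.frame with columns `time`, `event`, `group` (1/2).
#' @export
generate_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "nph_scenario"))
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(1:2, function(l) {
    a <- config$arms[[l]]
    n <- config$n[l]
    y <- surv_sample(a$event_family, n, a$event_theta)
    cns <- surv_sample(a$censor_family, n, a$censor_theta)
    data.frame(time = pmin(y, cns, config$t_max),
               event = as.numeric(y <= pmin(cns, config$t_max)),
               group = l)
  })
  rbind(out[[1L]], out[[2L]])
}

.trial_seed <- function(master, i) {
  (as.double(master) * 48271 + i * 9973) %% 2147483629 + 1
}

#' Monte-Carlo operating characteristics of the equivalence machinery
#'
#' Runs `n_sim` independent trials of a scenario; per trial the two arms
#' are fitted with the scenario's analysis family, bands are built and the
#' requested decision rule applied. `metric = "rejection"` returns the
#' rejection fraction of the pointwise test at `t0` (type-I error when the
#' scenario sits on the null margin, power under the alternative);
#' `metric = "coverage"` instead records pointwise containment of the true
#' contrast in two-sided `(1 - alpha)` bands across the scenario grid.
#' Trials are seeded individually from the master seed, so results do not
#' depend on execution order.
#'
#' @param config An `nph_scenario`.
#' @param t0 Test time (rejection metric).
#' @param margin Positive margin (rejection metric).
#' @param alpha Nominal level (one-sided band level for tests; two-sided
#'   interval level for coverage).
#' @param type `"equivalence"` or `"noninferiority"`.
#' @param contrast `"surv_diff"` or `"log_hr"`.
#' @param method `"asymptotic"`, `"bootstrap"` or `"nonparametric"`.
#' @param metric `"rejection"` or `"coverage"`.
#' @param n_sim Number of simulated trials.
#' @param n_boot Bootstrap replicates per trial (bootstrap method only).
#' @param seed Master seed (required).
#' @return An `nph_simsummary` with the estimate(s), Monte-Carlo standard
#'   error and failure count. Per-trial fit failures above 5% abort.
#' @export
estimate_operating_characteristics <- function(config, t0 = NULL,
                                               margin = NULL, alpha = 0.05,
                                               type = "equivalence",
                                               contrast = "surv_diff",
                                               method = c("asymptotic",
                                                          "bootstrap",
                                                          "nonparametric"),
                                               metric = c("rejection",
                                                          "coverage"),
                                               n_sim = 1000L, n_boot = 500L,
                                               seed = NULL) {
  stopifnot(inherits(config, "nph_scenario"))
  method <- match.arg(method)
  metric <- match.arg(metric)
  if (is.null(seed)) stop("a master seed is required", call. = FALSE)
  if (metric == "rejection" && (is.null(t0) || is.null(margin))) {
    stop("rejection metric needs t0 and margin", call. = FALSE)
  }
  if (method == "nonparametric" && contrast != "surv_diff") {
    stop("the non-parametric comparator only supports surv_diff",
         call. = FALSE)
  }
  grid <- if (metric == "rejection") t0 else config$grid
  band_alpha <- if (metric == "rejection") alpha else alpha / 2
  truth <- if (metric == "coverage") true_contrast(config, grid, contrast)

  res <- matrix(NA_real_, nrow = n_sim, ncol = length(grid))
  n_fail <- 0L
  for (i in seq_len(n_sim)) {
    set.seed(.trial_seed(seed, i))
    one <- tryCatch({
      d <- generate_trial(config)
      d1 <- d[d$group == 1L, ]; d2 <- d[d$group == 2L, ]
      band <- if (method == "nonparametric") {
        np_diff_bands(d1$time, d1$event, d2$time, d2$event, grid, band_alpha)
      } else {
        f1 <- fit_event_model(d1$time, d1$event, config$fit_family)
        f2 <- fit_event_model(d2$time, d2$event, config$fit_family)
        if (method == "bootstrap") {
          c1 <- fit_censoring_model(d1$time, d1$event, config$censor_fit_family)
          c2 <- fit_censoring_model(d2$time, d2$event, config$censor_fit_family)
          pointwise_bands(f1, f2, grid, contrast, band_alpha, "bootstrap",
                          c1, c2, n_boot = n_boot, t_max = config$t_max,
                          seed = .trial_seed(seed, i) + 1)
        } else {
          pointwise_bands(f1, f2, grid, contrast, band_alpha, "asymptotic")
        }
      }
      if (metric == "rejection") {
        as.numeric(pointwise_test(band, t0, margin, type)$reject)
      } else {
        as.numeric(band$band$lower <= truth & truth <= band$band$upper)
      }
    }, error = function(e) NULL)
    if (is.null(one)) n_fail <- n_fail + 1L else res[i, ] <- one
  }
  if (n_fail > 0.05 * n_sim) {
    stop("more than 5% of simulated trials failed (", n_fail, "/", n_sim, ")",
         call. = FALSE)
  }
  est <- colMeans(res, na.rm = TRUE)
  n_eff <- n_sim - n_fail
  structure(list(
    metric = metric, estimate = if (metric == "rejection") est[1L] else est,
    grid = grid, mc_se = sqrt(pmax(est * (1 - est), 0) / n_eff),
    n_sim = n_sim, n_fail = n_fail, method = method, type = type,
    contrast = contrast, t0 = t0, margin = margin, alpha = alpha,
    scenario = config$name
  ), class = "nph_simsummary")
}

#' @export
print.nph_simsummary <- function(x, ...) {
  cat(sprintf("Simulated %s (%s, %s test, %s): scenario '%s', n_sim = %d",
              x$metric, x$method, x$type, x$contrast, x$scenario, x$n_sim))
  if (x$n_fail > 0) cat(sprintf(" (%d failed trials)", x$n_fail))
  cat("\n")
  if (x$metric == "rejection") {
    cat(sprintf("  t0 = %g, margin = %g, alpha = %g: rate = %.3f (MC SE %.4f)\n",
                x$t0, x$margin, x$alpha, x$estimate, x$mc_se))
  } else {
    print(data.frame(t = x$grid, coverage = round(x$estimate, 3)))
  }
  invisible(x)
}

#' Power/type-I-error table over a grid of cells
#'
#' Convenience wrapper looping [estimate_operating_characteristics()] over
#' time points and margins, shaped like the study tables: one row per
#' `t0`, one column per margin, equivalence rate with the non-inferiority
#' rate in brackets.
#'
#' @inheritParams estimate_operating_characteristics
#' @param t0s Vector of test times.
#' @param margins Vector of margins.
#' @return A data.frame of formatted cells; the raw rates are in
#'   `attr(, "rates")`.
#' @export
oc_table <- function(config, t0s, margins, alpha = 0.05,
                     method = "asymptotic", n_sim = 1000L, n_boot = 500L,
                     seed = NULL) {
  rates <- array(NA_real_, c(length(t0s), length(margins), 2L),
                 dimnames = list(t0s, margins, c("equivalence",
                                                 "noninferiority")))
  for (i in seq_along(t0s)) for (j in seq_along(margins)) {
    for (ty in c("equivalence", "noninferiority")) {
      r <- estimate_operating_characteristics(
        config, t0 = t0s[i], margin = margins[j], alpha = alpha, type = ty,
        method = method, n_sim = n_sim, n_boot = n_boot,
        seed = seed + i * 131 + j * 17)
      rates[i, j, ty] <- r$estimate
    }
  }
  out <- data.frame(t0 = t0s)
  for (j in seq_along(margins)) {
    out[[paste0("delta_", margins[j])]] <-
      sprintf("%.3f (%.3f)", rates[, j, "equivalence"],
              rates[, j, "noninferiority"])
  }
  attr(out, "rates") <- rates
  out
}
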