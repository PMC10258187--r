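test_that("censored log-likelihood matches closed forms", {
  # exponential, times {1,2,3}, events {1,1,0}: 2 log(rate) - 6 rate
  for (lam in c(0.2, 0.5, 1.3)) {
    expect_equal(censored_loglik(c(1, 2, 3), c(1, 1, 0), "exponential", lam),
                 2 * log(lam) - 6 * lam)
  }
  set.seed(1)
  tt <- rweibull(20, 1.4, 3)
  th <- c(1.4, 3)
  expect_equal(censored_loglik(tt, rep(1, 20), "weibull", th),
               sum(dweibull(tt, 1.4, 3, log = TRUE)))
  expect_equal(censored_loglik(tt, rep(0, 20), "weibull", th),
               sum(pweibull(tt, 1.4, 3, lower.tail = FALSE, log.p = TRUE)))
})

test_that("exponential MLE matches the closed form exactly", {
  set.seed(2)
  s <- sim_arm(300, rate = 0.15)
  f <- fit_event_model(s$time, s$event, "exponential")
  expect_equal(unname(f$theta), sum(s$event) / sum(s$time), tolerance = 1e-10)
  expect_equal(f$aic, -2 * f$loglik + 2)
  g <- fit_censoring_model(s$time, s$event, "exponential")
  expect_equal(unname(g$theta), sum(1 - s$event) / sum(s$time),
               tolerance = 1e-10)
})

test_that("censoring fit equals event fit on flipped indicators, and the
           full likelihood decomposes", {
  set.seed(3)
  s <- sim_arm(150)
  cf <- fit_censoring_model(s$time, s$event, "weibull")
  ef <- fit_event_model(s$time, 1 - s$event, "weibull")
  expect_equal(cf$theta, ef$theta, tolerance = 1e-7)
  expect_identical(cf$role, "censoring")
  # log of the full two-factor likelihood = event part + flipped part
  th <- c(1.5, 3.4); ps <- 0.1
  full <- censored_loglik(s$time, s$event, "weibull", th) +
    censored_loglik(s$time, 1 - s$event, "exponential", ps)
  byhand <- sum(s$event * (dweibull(s$time, th[1], th[2], log = TRUE) +
                             pexp(s$time, ps, lower.tail = FALSE, log.p = TRUE)) +
                  (1 - s$event) * (pweibull(s$time, th[1], th[2],
                                            lower.tail = FALSE, log.p = TRUE) +
                                     dexp(s$time, ps, log = TRUE)))
  expect_equal(full, byhand)
})

test_that("Weibull MLE recovers the truth and agrees with survreg", {
  skip_if_not_installed("survival")
  set.seed(4)
  s <- sim_arm(5000)
  f <- fit_event_model(s$time, s$event, "weibull")
  expect_lt(abs(f$theta[["shape"]] - 1.5) / 1.5, 0.05)
  expect_lt(abs(f$theta[["scale"]] - 3.4) / 3.4, 0.05)
  sr <- survival::survreg(survival::Surv(s$time, s$event) ~ 1,
                          dist = "weibull")
  expect_equal(unname(f$theta[["shape"]]), 1 / sr$scale, tolerance = 1e-5)
  expect_equal(unname(log(f$theta[["scale"]])), unname(coef(sr)[1]),
               tolerance = 1e-5)
  expect_equal(f$loglik, sr$loglik[1], tolerance = 1e-7)
})

test_that("location-scale families agree with survreg under censoring", {
  skip_if_not_installed("survival")
  set.seed(5)
  s <- sim_arm(400, theta = c(1.3, 5), rate = 0.08)
  for (pair in list(c("log_normal", "lognormal"),
                    c("log_logistic", "loglogistic"),
                    c("gaussian", "gaussian"),
                    c("logistic", "logistic"))) {
    f <- fit_event_model(s$time, s$event, pair[1])
    sr <- survival::survreg(survival::Surv(s$time, s$event) ~ 1,
                            dist = pair[2])
    expect_equal(f$loglik, sr$loglik[1], tolerance = 1e-6, info = pair[1])
  }
})

test_that("observed information is symmetric, PSD, and calibrated", {
  set.seed(6)
  s <- sim_arm(400)
  f <- fit_event_model(s$time, s$event, "weibull")
  expect_equal(f$info, t(f$info))
  expect_true(all(eigen(f$info, symmetric = TRUE)$values > 0))
  # studentized estimates are approximately standard normal: coverage of
  # +-1.96 over repeated sampling
  nrep <- 500
  cover <- matrix(NA, nrep, 2)
  for (i in 1:nrep) {
    set.seed(100 + i)
    si <- sim_arm(200)
    fi <- fit_event_model(si$time, si$event, "weibull")
    se <- sqrt(diag(vcov(fi)))
    cover[i, ] <- abs(fi$theta - c(1.5, 3.4)) / se <= qnorm(0.975)
  }
  cov <- colMeans(cover)
  expect_true(all(cov >= 0.92 & cov <= 0.98))
})

test_that("AIC model selection ranks sensibly and keeps failures visible", {
  set.seed(7)
  tt <- rexp(2000, 0.3)
  tab <- model_selection_aic(tt, rep(1, 2000))
  expect_true(tab$family[1] %in% c("exponential", "weibull"))
  expect_true(!is.unsorted(tab$aic[tab$error == ""]))
  one <- model_selection_aic(tt, rep(1, 2000), families = "weibull")
  expect_identical(nrow(one), 1L)
  expect_s3_class(attr(tab, "fits")[["weibull"]], "nph_fit")
})

test_that("degenerate samples are refused with clear errors", {
  expect_error(fit_event_model(c(1, 2), c(0, 0)), "at least one event")
  expect_error(fit_censoring_model(c(1, 2), c(1, 1)), "censored")
  expect_error(fit_event_model(c(1, -2), c(1, 1)), "positive")
  expect_error(fit_event_model(c(1, 2), c(1, 2)), "0.*1|coded")
})
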