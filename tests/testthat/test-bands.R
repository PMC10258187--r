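test_that("contrasts at known parameters behave as the theory says", {
  f1 <- fit_at("weibull", c(1.5, 3.4))
  f2 <- fit_at("weibull", c(2, 3.4))
  tt <- seq(0.2, 5, by = 0.3)
  # identical parameters: both contrasts vanish everywhere
  expect_equal(contrast_at(f1, f1, tt), rep(0, length(tt)))
  expect_equal(contrast_at(f1, f1, tt, "log_hr"), rep(0, length(tt)))
  # crossing-curves pair: |S1 - S2|(0.6) = 0.04 to two decimals
  expect_equal(round(abs(contrast_at(f1, f2, 0.6)), 2), 0.04)
  # equal shapes: the log hazard ratio is constant k * log(l2/l1)
  f3 <- fit_at("weibull", c(1.5, 4.9))
  r <- contrast_at(f1, f3, tt, "log_hr")
  expect_equal(r, rep(1.5 * log(4.9 / 3.4), length(tt)), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  for (case in list(list("weibull", c(1.5, 3.4)),
                    list("exponential", 0.21))) {
    fam <- case[[1]]; th <- case[[2]]
    tt <- c(0.4, 1.6, 3.8, 7)
    expect_equal(nphequiv:::.grad_surv(fam, th, tt),
                 nphequiv:::.grad_surv(fam, th, tt, numeric = TRUE),
                 tolerance = 1e-6, info = fam)
    expect_equal(nphequiv:::.grad_loghaz(fam, th, tt),
                 nphequiv:::.grad_loghaz(fam, th, tt, numeric = TRUE),
                 tolerance = 1e-6, info = fam)
  }
})

test_that("delta-method variance: boundary, information scaling", {
  set.seed(11)
  s1 <- sim_arm(200); s2 <- sim_arm(200, theta = c(1.5, 3.7), rate = 0.05)
  f1 <- fit_event_model(s1$time, s1$event)
  f2 <- fit_event_model(s2$time, s2$event)
  # at t = 0 the survival gradient vanishes for positive-support families
  expect_equal(delta_variance(f1, f2, 0), 0)
  v <- delta_variance(f1, f2, c(1, 2, 4))
  expect_true(all(v > 0))
  # duplicating every observation doubles the information, halving sigma^2
  g1 <- fit_event_model(rep(s1$time, 2), rep(s1$event, 2))
  g2 <- fit_event_model(rep(s2$time, 2), rep(s2$event, 2))
  expect_equal(delta_variance(g1, g2, c(1, 2, 4)), v / 2, tolerance = 1e-3)
})

test_that("bands are centred, ordered in alpha, and arm-symmetric", {
  set.seed(12)
  s1 <- sim_arm(150); s2 <- sim_arm(150, theta = c(2, 3.4))
  f1 <- fit_event_model(s1$time, s1$event)
  f2 <- fit_event_model(s2$time, s2$event)
  grid <- seq(0.5, 5, by = 0.5)
  b05 <- pointwise_bands(f1, f2, grid, alpha = 0.05)
  expect_true(all(b05$band$lower <= b05$band$estimate &
                    b05$band$estimate <= b05$band$upper))
  expect_equal(b05$band$upper - b05$band$lower,
               2 * qnorm(0.95) * sqrt(b05$band$variance))
  # smaller alpha -> strictly wider bands at every grid point
  b01 <- pointwise_bands(f1, f2, grid, alpha = 0.01)
  expect_true(all(b01$band$lower < b05$band$lower))
  expect_true(all(b01$band$upper > b05$band$upper))
  # alpha = 0.5: bands collapse onto the estimate
  b50 <- pointwise_bands(f1, f2, grid, alpha = 0.5)
  expect_equal(b50$band$lower, b50$band$estimate)
  # swapping the arms negates and reflects the bands
  bsw <- pointwise_bands(f2, f1, grid, alpha = 0.05)
  expect_equal(bsw$band$estimate, -b05$band$estimate)
  expect_equal(bsw$band$lower, -b05$band$upper)
  expect_equal(bsw$band$upper, -b05$band$lower)
  expect_error(pointwise_bands(f1, f2, grid, alpha = 0.7), "alpha")
})

test_that("parametric bootstrap is reproducible and tracks the delta method", {
  set.seed(13)
  s1 <- sim_arm(300); s2 <- sim_arm(300, theta = c(1.5, 3.7), rate = 0.05)
  f1 <- fit_event_model(s1$time, s1$event)
  f2 <- fit_event_model(s2$time, s2$event)
  c1 <- fit_censoring_model(s1$time, s1$event, "exponential")
  c2 <- fit_censoring_model(s2$time, s2$event, "exponential")
  grid <- c(1, 2.3, 4)
  v1 <- bootstrap_variance(f1, f2, c1, c2, grid, n_boot = 120, t_max = 9,
                           seed = 99)
  v2 <- bootstrap_variance(f1, f2, c1, c2, grid, n_boot = 120, t_max = 9,
                           seed = 99)
  expect_identical(v1, v2)
  expect_error(bootstrap_variance(f1, f2, c1, c2, grid, n_boot = 120),
               "seed")
  vb <- bootstrap_variance(f1, f2, c1, c2, grid, n_boot = 400, t_max = 9,
                           seed = 7)
  vd <- delta_variance(f1, f2, grid)
  expect_true(all(abs(vb / vd - 1) < 0.3))
  bb <- pointwise_bands(f1, f2, grid, method = "bootstrap",
                        censor_fit1 = c1, censor_fit2 = c2, n_boot = 120,
                        t_max = 9, seed = 5)
  expect_identical(bb$method, "bootstrap")
  expect_true(all(bb$band$variance > 0))
})
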