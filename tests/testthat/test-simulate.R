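test_that("scenario presets encode the study designs", {
  cfg <- scenario_config("ph-type1", 50, 50)
  expect_equal(cfg$arms[[1]]$event_theta, c(1.5, 3.4))
  expect_equal(cfg$arms[[2]]$event_theta, c(1.5, 4.9))
  expect_equal(cfg$t_max, 9)
  expect_length(cfg$grid, 23)
  expect_equal(range(cfg$grid), c(1.5, 6))
  expect_length(scenario_config("nph-power")$grid, 14)
  # PH pair: constant log hazard ratio k*log(l2/l1), about 0.55
  # (the reference arm has the shorter survival, hence the larger hazard)
  r <- true_contrast(cfg, c(1, 2, 5), "log_hr")
  expect_equal(r, rep(1.5 * log(4.9 / 3.4), 3), tolerance = 1e-12)
})

test_that("log-logistic misspecification preset calibrates ~20% censoring", {
  cfg <- scenario_config("ll-misspec", 20000, 20000)
  expect_identical(cfg$arms[[1]]$censor_family, "uniform")
  expect_identical(cfg$fit_family, "weibull")
  d <- generate_trial(cfg, seed = 41)
  for (l in 1:2) {
    expect_equal(mean(1 - d$event[d$group == l]), 0.2, tolerance = 0.1)
  }
})

test_that("generated trials respect the observation scheme", {
  cfg <- scenario_config("ph-type1", 400, 300)
  d <- generate_trial(cfg, seed = 42)
  expect_identical(nrow(d), 700L)
  expect_identical(sum(d$group == 1), 400L)
  expect_true(all(d$time > 0 & d$time <= 9))
  expect_true(all(d$event %in% 0:1))
  # reproducible under a fixed seed
  expect_identical(d, generate_trial(cfg, seed = 42))
  # censored fraction near the calibrated 25% in the reference arm
  big <- generate_trial(scenario_config("ph-type1", 20000, 10), seed = 43)
  expect_equal(mean(1 - big$event[big$group == 1]), 0.25, tolerance = 0.06)
})

test_that("the Monte-Carlo harness is deterministic and order-independent", {
  cfg <- scenario_config("ph-power", 30, 30)
  a <- estimate_operating_characteristics(cfg, t0 = 0.7, margin = 0.15,
                                          n_sim = 40, seed = 8)
  b <- estimate_operating_characteristics(cfg, t0 = 0.7, margin = 0.15,
                                          n_sim = 40, seed = 8)
  expect_identical(a$estimate, b$estimate)
  expect_error(estimate_operating_characteristics(cfg, t0 = 0.7,
                                                  margin = 0.15, n_sim = 10),
               "seed")
  expect_equal(a$mc_se, sqrt(a$estimate * (1 - a$estimate) / 40))
})

test_that("power approaches one when the margin dwarfs the true difference", {
  cfg <- scenario_config("ph-power", 150, 150)
  r <- estimate_operating_characteristics(cfg, t0 = 1.6, margin = 0.45,
                                          n_sim = 60, seed = 9)
  expect_gte(r$estimate, 0.97)
  rnp <- estimate_operating_characteristics(cfg, t0 = 1.6, margin = 0.45,
                                            method = "nonparametric",
                                            n_sim = 60, seed = 9)
  expect_gte(rnp$estimate, 0.97)
})

test_that("coverage metric checks containment of the true contrast", {
  cfg <- scenario_config("ph-type1", 150, 150)
  r <- estimate_operating_characteristics(cfg, metric = "coverage",
                                          n_sim = 80, seed = 10)
  expect_length(r$estimate, 23)
  expect_true(all(r$estimate >= 0.8 & r$estimate <= 1))
})

test_that("the parametric test dominates the non-parametric comparator
           at small samples under proportional hazards", {
  cfg <- scenario_config("ph-power", 50, 50)
  nsim <- 400
  pp <- estimate_operating_characteristics(cfg, t0 = 0.7, margin = 0.15,
                                           n_sim = nsim, seed = 12)
  np <- estimate_operating_characteristics(cfg, t0 = 0.7, margin = 0.15,
                                           method = "nonparametric",
                                           n_sim = nsim, seed = 12)
  se <- sqrt(0.25 / nsim)
  expect_gte(pp$estimate, np$estimate - 2 * se)
  pp2 <- estimate_operating_characteristics(cfg, t0 = 1.2, margin = 0.2,
                                            n_sim = nsim, seed = 13)
  np2 <- estimate_operating_characteristics(cfg, t0 = 1.2, margin = 0.2,
                                            method = "nonparametric",
                                            n_sim = nsim, seed = 13)
  expect_gte(pp2$estimate, np2$estimate - 2 * se)
})

test_that("oc_table lays out equivalence with non-inferiority in brackets", {
  cfg <- scenario_config("ph-power", 30, 30)
  tab <- oc_table(cfg, t0s = c(0.7, 1.2), margins = c(0.15, 0.2),
                  n_sim = 25, seed = 3)
  expect_identical(dim(tab), c(2L, 3L))
  expect_match(tab$delta_0.15[1], "^0\\.\\d{3} \\(0\\.\\d{3}\\)$")
  expect_identical(dim(attr(tab, "rates")), c(2L, 2L, 2L))
})
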