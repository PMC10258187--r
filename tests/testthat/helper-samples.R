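# shared fixture builders: everything is generated in code at test time

# one censored arm: Weibull events, exponential censoring, optional cap
sim_arm <- function(n, theta = c(1.5, 3.4), rate = 0.1, t_max = 9,
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- rweibull(n, theta[1], theta[2])
  cns <- rexp(n, rate)
  list(time = pmin(y, cns, t_max), event = as.numeric(y <= pmin(cns, t_max)))
}

# an nph_fit at exactly the given parameters (identity information),
# for tests that exercise contrasts/tests at known theta
fit_at <- function(family, theta, n = 100) {
  npar <- length(theta)
  nphequiv:::.new_fit(family, theta, loglik = 0,
                      info = diag(npar) * n, n = n, n_event = n, role = "event")
}

# a band object with fully specified bounds
band_of <- function(t, est, var, alpha = 0.05, contrast = "surv_diff") {
  nphequiv:::.new_band(t, est, var, alpha, contrast, "asymptotic")
}
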