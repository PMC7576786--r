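test_that("biomass projection reproduces hand-computed recursions", {
  p <- spm_parameters(r = 0.2, K = 1000, q_pre = 1e-3, psi = 1)
  proj <- project_biomass(p, c(50, 50, 0), n_years = 3)
  # B3 = 950 + 0.2 * 950 * (1 - 0.95) - 50
  expect_equal(proj$biomass, c(1000, 950, 909.5))
  expect_false(proj$floor_hit)

  # MSY equilibrium and carrying-capacity fixed point, exactly
  set.seed(21)
  for (i in 1:100) {
    r <- stats::runif(1, 0.05, 0.8)
    K <- stats::runif(1, 500, 20000)
    eq <- project_biomass(spm_parameters(r, K, 1e-3, psi = 0.5),
                          rep(r * K / 4, 12))
    expect_identical(eq$biomass, rep(K / 2, 12))
    idle <- project_biomass(spm_parameters(r, K, 1e-3, psi = 1), rep(0, 12))
    expect_identical(idle$biomass, rep(K, 12))
  }
})

test_that("projection agrees with an independently coded recursion", {
  set.seed(22)
  for (i in 1:1000) {
    r <- stats::runif(1, 0.05, 0.9)
    K <- stats::runif(1, 100, 50000)
    psi <- stats::runif(1, 0.2, 1)
    n <- sample(5:40, 1)
    catch <- stats::runif(n, 0, 0.3 * K)
    proj <- project_biomass(spm_parameters(r, K, 1e-3, psi = psi), catch)
    b <- numeric(n)
    b[1] <- psi * K
    hit <- FALSE
    for (t in seq_len(n - 1)) {
      nxt <- b[t] + (r * b[t] * (1 - b[t] / K) - catch[t])
      if (nxt < 1e-6 * K) { nxt <- 1e-6 * K; hit <- TRUE }
      b[t + 1] <- nxt
    }
    expect_identical(proj$biomass, b)
    expect_identical(proj$floor_hit, hit)
  }
})

test_that("expected CPUE applies regimes and efficiency trends", {
  p <- spm_parameters(r = 0.3, K = 1000, q_pre = 0.001, q_post = 0.001)
  yrs <- 2001:2004
  expect_equal(expected_cpue(p, rep(1000, 4), yrs), rep(1, 4))
  # 1%/yr trend on constant biomass: geometric growth
  tr <- expected_cpue(p, rep(1000, 4), yrs, efficiency_trend_pct = 1)
  expect_equal(tr[-1] / tr[-4], rep(1.01, 3))
  # regime at year 3 of 4 with q doubling
  p2 <- spm_parameters(r = 0.3, K = 1000, q_pre = 1, q_post = 2)
  reg <- expected_cpue(p2, rep(1000, 4), yrs, regime_year = 2003)
  expect_equal(reg, 1000 * c(1, 1, 2, 2))
})

test_that("log-likelihood follows the lognormal observation model", {
  cfg <- spm_sim_config(sigma_obs = 0, n_years = 20, seed = 4)
  sim <- simulate_spm_series(cfg)
  p_exact <- spm_parameters(cfg$r_true, cfg$K_true, cfg$q_pre,
                            sigma_obs = 0.1, psi = 1)
  ll1 <- spm_log_likelihood(p_exact, sim$series)
  # at an exact fit, doubling sigma costs sum(log 2) plus nothing else
  p_double <- p_exact
  p_double$sigma_obs <- 0.2
  ll2 <- spm_log_likelihood(p_double, sim$series)
  expect_equal(ll1 - ll2, 20 * log(2), tolerance = 1e-9)
  # shrinking sigma at an exact fit increases the likelihood
  p_small <- p_exact
  p_small$sigma_obs <- 0.01
  expect_gt(spm_log_likelihood(p_small, sim$series), ll1)
  # floor-hit trajectories carry zero weight
  p_floor <- spm_parameters(0.05, 500, cfg$q_pre, sigma_obs = 0.1, psi = 0.3)
  expect_identical(spm_log_likelihood(p_floor, sim$series), -Inf)
  # gap years contribute nothing
  gappy <- sim$series
  gappy$cpue[5] <- NA
  p_gap <- p_exact
  expect_equal(spm_log_likelihood(p_gap, gappy),
               ll1 - stats::dlnorm(sim$series$cpue[5],
                                   log(sim$series$cpue[5]), 0.1, log = TRUE))
})

test_that("likelihood location is invariant to joint rescaling of cpue and q", {
  cfg <- spm_sim_config(sigma_obs = 0.05, n_years = 30, seed = 5)
  sim <- simulate_spm_series(cfg)
  p <- spm_parameters(0.25, 6000, 3e-4, sigma_obs = 0.08, psi = 0.9)
  ll <- spm_log_likelihood(p, sim$series)
  scaled <- sim$series
  scaled$cpue <- scaled$cpue * 1000
  p_scaled <- p
  p_scaled$q_pre <- p$q_pre * 1000
  p_scaled$q_post <- p$q_post * 1000
  ll_scaled <- spm_log_likelihood(p_scaled, scaled)
  # densities shift by the jacobian of the unit change, identically in (r, K)
  expect_equal(ll_scaled, ll - 30 * log(1000), tolerance = 1e-9)
})

test_that("prior-predictive simulation yields positive finite CPUE", {
  set.seed(23)
  priors <- spm_priors()
  n_ok <- 0
  n_draws <- 200
  for (i in seq_len(n_draws)) {
    r <- stats::rlnorm(1, priors$r_meanlog, priors$r_sdlog)
    K <- stats::rlnorm(1, log(5 * 500), priors$K_sdlog)
    psi <- stats::runif(1, priors$psi_min, priors$psi_max)
    proj <- project_biomass(list(r = r, K = K, psi = psi), rep(0, 20))
    cpue <- 2e-4 * proj$biomass
    if (all(is.finite(cpue)) && all(cpue > 0)) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n_draws, 0.99)
})

test_that("cpue_series validates its contract", {
  expect_error(cpue_series("s", c(2000, 2002), c(1, 1), c(1, 1)),
               "consecutive")
  expect_error(cpue_series("s", 2000:2002, c(1, NA, 1), c(1, 1, 1)),
               "complete")
  expect_error(cpue_series("s", 2000:2002, c(1, 1, 1), c(1, -2, 1)),
               "positive")
  expect_error(cpue_series("s", 2000:2002, c(1, 1, 1), rep(NA_real_, 3)),
               "gaps")
  expect_error(cpue_series("s", 2000:2002, c(1, 1, 1), c(1, 1, 1),
                           regime_year = 1999), "inside")
  expect_warning(
    fit_spm(cpue_series("s", 2000:2004, rep(100, 5),
                        c(1, 0.9, NA, NA, 0.8) ),
            control = spm_mcmc_control(chains = 1, iter = 50, warmup = 50,
                                       min_ess = 1, rhat_max = Inf)),
    "recommended"
  )
})

test_that("posterior MSY per draw equals rK/4 and summaries are quantiles", {
  fake <- list(draws = tibble::tibble(
    r = c(0.2, 0.4), K = c(1000, 2000),
    msy = c(0.2 * 1000 / 4, 0.4 * 2000 / 4),
    depletion = c(0.4, 0.6)
  ))
  expect_identical(fake$draws$msy, fake$draws$r * fake$draws$K / 4)
  expect_equal(unname(depletion_summary(fake)["median"]), 50)
  single <- list(draws = tibble::tibble(depletion = 0.5))
  expect_equal(unname(depletion_summary(single)), c(50, 50, 50))
})

test_that("fitted posterior audits: MSY identity, depletion, R-squared", {
  cfg <- spm_sim_config(r_true = 0.3, K_true = 5000, sigma_obs = 0.05,
                        seed = 1)
  sim <- simulate_spm_series(cfg)
  fit <- fit_spm(sim$series, seed = 1)
  expect_identical(fit$draws$msy, fit$draws$r * fit$draws$K / 4)
  expect_true(all(fit$diagnostics$rhat < 1.05))
  expect_true(all(fit$diagnostics$ess >= 400))
  dep <- depletion_summary(fit)
  expect_lt(dep["lower"], dep["median"])
  expect_lt(dep["median"], dep["upper"])
  # low-noise recovery runs sit in the regime of good CPUE fits
  expect_gt(fit_r_squared(fit), 0.8)
  expect_error(fit_r_squared(fit, cpue_series("s", 2000:2003, rep(1, 4),
                                              c(1, 1, NA, NA))),
               "fewer than 3")
  # efficiency-trend sensitivity: ignoring a simulated 1%/yr trend biases r
  cfg_tr <- spm_sim_config(r_true = 0.3, K_true = 5000, sigma_obs = 0.05,
                           seed = 6)
  sim_tr <- simulate_spm_series(cfg_tr)
  trend <- (1.01)^(seq_along(sim_tr$series$years) - 1)
  sim_tr$series$cpue <- sim_tr$series$cpue * trend
  fit_on <- fit_spm(sim_tr$series, efficiency_trend_pct = 1, seed = 6)
  expect_lt(abs(stats::median(fit_on$draws$r) - 0.3), 0.09)
  fit_off <- fit_spm(sim_tr$series, efficiency_trend_pct = 0, seed = 6)
  # with the trend unmodelled, apparent CPUE declines too slowly: r is
  # estimated too optimistic (upward) relative to the trend-aware fit
  expect_gt(stats::median(fit_off$draws$r), stats::median(fit_on$draws$r))
})
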