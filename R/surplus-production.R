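# Bayesian Schaefer surplus-production model fitted to catch + CPUE
# series. Biomass dynamics are logistic with annual catch removal; CPUE is
# lognormal around catchability x biomass, with an optional catchability
# regime change at a configured year (a management restructure changes
# fishing efficiency) and an optional smooth efficiency trend. Estimation
# is observation-error-only: the biomass trajectory is a deterministic
# function of (r, K, psi) and the catch history, and all noise is in the
# CPUE observations. Sampling is adaptive random-walk Metropolis on
# log-transformed parameters.

#' Construct a catch + CPUE series for one stock
#'
#' @param stock_id stock identifier.
#' @param years consecutive calendar years (strictly increasing by 1).
#' @param catch annual catch (tonnes), complete (no gaps).
#' @param cpue standardized CPUE index, positive; `NA` marks gap years.
#' @param regime_year calendar year at which catchability changes (years
#'   strictly before use the pre-regime catchability; the regime year
#'   itself uses the post value), or `NA` for a single catchability.
#' @return Object of class `cpue_series`.
#' @export
cpue_series <- function(stock_id, years, catch, cpue, regime_year = NA) {
  years <- as.integer(years)
  if (length(years) < 2 || any(diff(years) != 1L)) {
    stop("years must be consecutive calendar years")
  }
  if (length(catch) != length(years) || length(cpue) != length(years)) {
    stop("catch and cpue must have one entry per year")
  }
  if (any(is.na(catch)) || any(catch < 0)) {
    stop("catch must be complete and non-negative")
  }
  if (any(cpue[!is.na(cpue)] <= 0)) stop("cpue must be positive where present")
  if (all(is.na(cpue))) stop("cpue is all gaps: nothing to fit")
  if (!is.na(regime_year)) {
    regime_year <- as.integer(regime_year)
    if (regime_year <= years[1] || regime_year > years[length(years)]) {
      stop("regime_year must fall strictly inside the simulated span")
    }
  }
  structure(
    list(
      stock_id = as.character(stock_id), years = years,
      catch = as.numeric(catch), cpue = as.numeric(cpue),
      regime_year = regime_year
    ),
    class = "cpue_series"
  )
}

#' Schaefer parameter set
#'
#' @param r intrinsic growth rate (per year).
#' @param K carrying capacity (tonnes).
#' @param q_pre,q_post catchability before/at-and-after the regime year
#'   (index units per tonne); equal when there is no regime change.
#' @param sigma_obs lognormal observation standard deviation on CPUE.
#' @param psi initial depletion B1/K; values slightly above 1 describe a
#'   stock starting above its deterministic carrying capacity.
#' @return Named list of parameters.
#' @export
spm_parameters <- function(r, K, q_pre, q_post = q_pre, sigma_obs = 0.1,
                           psi = 1) {
  stopifnot(r > 0, K > 0, q_pre > 0, q_post > 0, sigma_obs >= 0,
            psi > 0, psi <= 1.5)
  list(r = r, K = K, q_pre = q_pre, q_post = q_post,
       sigma_obs = sigma_obs, psi = psi)
}

#' Project biomass under the Schaefer recursion
#'
#' `B1 = psi * K`; `B[t+1] = B[t] + r * B[t] * (1 - B[t]/K) - C[t]`,
#' floored at `1e-6 * K`. Hitting the floor flags the parameter/catch
#' combination as implausible rather than raising an error; the likelihood
#' assigns such trajectories zero weight.
#'
#' @param params from [spm_parameters()] (only `r`, `K`, `psi` are used).
#' @param catch annual catch vector.
#' @param n_years trajectory length; defaults to `length(catch)`.
#' @return List with `biomass` (length `n_years`) and logical `floor_hit`.
#' @export
project_biomass <- function(params, catch, n_years = length(catch)) {
  if (length(catch) < n_years) stop("catch must cover n_years entries")
  r <- params$r; K <- params$K; psi <- params$psi
  floor_b <- 1e-6 * K
  b <- numeric(n_years)
  b[1] <- psi * K
  hit <- FALSE
  if (n_years > 1) {
    for (t in seq_len(n_years - 1)) {
      bt <- b[t]
      # net change grouped first so exact growth/catch balance cancels
      nxt <- bt + (r * bt * (1 - bt / K) - catch[t])
      if (nxt < floor_b) {
        nxt <- floor_b
        hit <- TRUE
      }
      b[t + 1] <- nxt
    }
  }
  list(biomass = b, floor_hit = hit)
}

#' Expected CPUE given biomass and catchability regimes
#'
#' `E[CPUE_t] = q(t) * B_t`, with `q(t) = q_pre` for years strictly before
#' the regime year and `q_post` from the regime year on, multiplied by
#' `(1 + efficiency_trend_pct/100)^(t - t1)` when the fishing-efficiency
#' trend is enabled. The trend applies to both regimes from the first data
#' year, modelling fleet-wide technological drift.
#'
#' @param params from [spm_parameters()].
#' @param biomass biomass vector.
#' @param years calendar years matching `biomass`.
#' @param regime_year regime-change year or `NA`.
#' @param efficiency_trend_pct percent-per-year efficiency increase
#'   (default 0).
#' @return Numeric vector of expected CPUE.
#' @export
expected_cpue <- function(params, biomass, years, regime_year = NA,
                          efficiency_trend_pct = 0) {
  if (length(biomass) != length(years)) {
    stop("biomass and years must have equal length")
  }
  q <- if (is.na(regime_year)) {
    rep(params$q_pre, length(years))
  } else {
    ifelse(years < regime_year, params$q_pre, params$q_post)
  }
  trend <- (1 + efficiency_trend_pct / 100)^(years - years[1])
  q * biomass * trend
}

#' Log-likelihood of a CPUE series under the Schaefer model
#'
#' Sum over observed (non-gap) years of the lognormal density of CPUE
#' centred (median) at `q(t) * B_t` with log-scale standard deviation
#' `sigma_obs`. Trajectories that hit the biomass floor get `-Inf`.
#'
#' @param params from [spm_parameters()].
#' @param series a [cpue_series()].
#' @param efficiency_trend_pct percent-per-year efficiency trend.
#' @return Scalar log-likelihood.
#' @export
spm_log_likelihood <- function(params, series, efficiency_trend_pct = 0) {
  proj <- project_biomass(params, series$catch)
  if (proj$floor_hit) return(-Inf)
  mu <- expected_cpue(params, proj$biomass, series$years,
                      series$regime_year, efficiency_trend_pct)
  obs <- !is.na(series$cpue)
  sum(stats::dlnorm(series$cpue[obs], meanlog = log(mu[obs]),
                    sdlog = params$sigma_obs, log = TRUE))
}

#' Prior settings for the surplus-production model
#'
#' Weakly-informative defaults suited to multi-decade reef-fishery series:
#' lognormal on r centred at 0.3/yr, lognormal on K centred at five times
#' the maximum observed catch (set at fit time), flat (improper) priors on
#' log catchability, half-normal on the observation sd and uniform initial
#' depletion on \[0.2, 1.1\]. The upper bound sits above 1 so that a stock
#' unfished at the start of the series does not pin the initial-depletion
#' posterior against a boundary, which would bias derived depletion
#' downward.
#'
#' @param r_meanlog,r_sdlog lognormal prior on r.
#' @param K_mult multiplier of max catch giving the K prior median.
#' @param K_sdlog lognormal sd of the K prior.
#' @param sigma_scale half-normal scale for sigma_obs.
#' @param psi_min,psi_max bounds of the uniform initial-depletion prior.
#' @return List of prior hyperparameters.
#' @export
spm_priors <- function(r_meanlog = log(0.3), r_sdlog = 0.5, K_mult = 5,
                       K_sdlog = 1, sigma_scale = 0.3,
                       psi_min = 0.2, psi_max = 1.1) {
  stopifnot(r_sdlog > 0, K_mult > 0, K_sdlog > 0, sigma_scale > 0,
            psi_min > 0, psi_max <= 1.5, psi_min < psi_max)
  list(r_meanlog = r_meanlog, r_sdlog = r_sdlog, K_mult = K_mult,
       K_sdlog = K_sdlog, sigma_scale = sigma_scale,
       psi_min = psi_min, psi_max = psi_max)
}

#' MCMC settings for the surplus-production sampler
#'
#' @param chains number of chains.
#' @param iter retained draws per chain.
#' @param warmup adaptation draws per chain (discarded).
#' @param target_accept target acceptance rate of the adaptive random walk
#'   (0.2-0.4 is the usual band for full-dimensional proposals).
#' @param rhat_max convergence gate: largest tolerated split R-hat.
#' @param min_ess convergence gate: smallest tolerated total effective
#'   sample size per parameter.
#' @param max_doublings on a failed gate, how many times to double the run
#'   length and retry before raising a diagnostics-bearing error.
#' @return List of sampler settings.
#' @export
spm_mcmc_control <- function(chains = 4, iter = 3000, warmup = 3000,
                             target_accept = 0.25, rhat_max = 1.05,
                             min_ess = 400, max_doublings = 2) {
  list(chains = chains, iter = iter, warmup = warmup,
       target_accept = target_accept, rhat_max = rhat_max,
       min_ess = min_ess, max_doublings = max_doublings)
}

# log-posterior over the transformed parameter vector
# theta = (log r, log K, log q_pre[, log q_post], log sigma, z) where
# psi = psi_min + (psi_max - psi_min) * plogis(z)
.spm_log_post <- function(theta, series, priors, two_q,
                          efficiency_trend_pct) {
  r <- exp(theta[1]); K <- exp(theta[2]); q_pre <- exp(theta[3])
  i <- 4L
  q_post <- if (two_q) exp(theta[i]) else q_pre
  if (two_q) i <- i + 1L
  sigma <- exp(theta[i])
  z <- theta[i + 1L]
  psi <- priors$psi_min + (priors$psi_max - priors$psi_min) * stats::plogis(z)
  if (!is.finite(r) || !is.finite(K) || !is.finite(sigma) || sigma <= 0) {
    return(-Inf)
  }
  params <- list(r = r, K = K, q_pre = q_pre, q_post = q_post,
                 sigma_obs = sigma, psi = psi)
  ll <- spm_log_likelihood(params, series, efficiency_trend_pct)
  if (!is.finite(ll)) return(-Inf)
  lp <- stats::dnorm(theta[1], priors$r_meanlog, priors$r_sdlog, log = TRUE) +
    stats::dnorm(theta[2], priors$K_meanlog, priors$K_sdlog, log = TRUE) +
    # flat prior on log q (improper, scale-free)
    stats::dnorm(sigma, 0, priors$sigma_scale, log = TRUE) + log(2) +
    log(sigma) +                       # jacobian of log sigma
    stats::dlogis(z, log = TRUE)       # uniform psi through the logistic map
  ll + lp
}

.spm_run_chain <- function(theta0, lp_fun, n_warmup, n_iter, target_accept) {
  d <- length(theta0)
  theta <- theta0
  lp_cur <- lp_fun(theta)
  if (!is.finite(lp_cur)) stop("invalid chain start: zero posterior density")
  log_scale <- log(0.3)
  cov_chol <- diag(0.1, d)
  total <- n_warmup + n_iter
  hist_mat <- matrix(NA_real_, total, d)
  keep <- matrix(NA_real_, n_iter, d)
  n_acc <- 0L
  for (it in seq_len(total)) {
    prop <- theta + exp(log_scale) * drop(stats::rnorm(d) %*% cov_chol)
    lp_prop <- lp_fun(prop)
    acc_prob <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp_cur)) else 0
    if (stats::runif(1) < acc_prob) {
      theta <- prop
      lp_cur <- lp_prop
      n_acc <- n_acc + 1L
    }
    hist_mat[it, ] <- theta
    if (it <= n_warmup) {
      # Robbins-Monro scale tuning toward the target acceptance rate
      log_scale <- log_scale + it^(-0.6) * (acc_prob - target_accept)
      if (it >= 300 && it %% 100 == 0) {
        win <- hist_mat[max(1, it - 1500):it, , drop = FALSE]
        cv <- stats::cov(win) + diag(1e-8, d)
        ch <- tryCatch(chol(cv), error = function(e) NULL)
        if (!is.null(ch)) cov_chol <- ch
      }
    } else {
      keep[it - n_warmup, ] <- theta
    }
  }
  list(draws = keep, acceptance = n_acc / total)
}

#' Fit the Bayesian surplus-production model
#'
#' Samples the joint posterior of `(r, K, q_pre, q_post, sigma_obs, psi)`
#' by adaptive random-walk Metropolis on log-transformed parameters, four
#' chains from dispersed starts. When the series carries no regime year a
#' single catchability is estimated (`q_post` mirrors `q_pre` in the
#' draws). Convergence is gated on split R-hat and effective sample size;
#' a failed gate doubles the run length and retries before raising an
#' error carrying the diagnostics. Per-draw MSY (`r*K/4`) and final-year
#' depletion (`B_T/K`) are attached to the draws.
#'
#' @param series a [cpue_series()]; at least 10 observed CPUE years are
#'   recommended (a warning is issued below that).
#' @param priors from [spm_priors()].
#' @param control from [spm_mcmc_control()].
#' @param efficiency_trend_pct percent-per-year fishing-efficiency trend
#'   assumed when fitting (0 disables it).
#' @param seed integer seed.
#' @return Object of class `spm_posterior`: `draws` (tibble with `r`, `K`,
#'   `q_pre`, `q_post`, `sigma_obs`, `psi`, `msy`, `depletion`),
#'   `diagnostics`, `acceptance`, the `series`, and the settings used.
#' @export
fit_spm <- function(series, priors = spm_priors(),
                    control = spm_mcmc_control(),
                    efficiency_trend_pct = 0, seed = 1) {
  stopifnot(inherits(series, "cpue_series"))
  n_obs <- sum(!is.na(series$cpue))
  if (n_obs == 0) stop("all CPUE values are gaps: nothing to fit")
  if (n_obs < 10) {
    warning("only ", n_obs, " observed CPUE years; at least 10 recommended")
  }
  two_q <- !is.na(series$regime_year)
  priors$K_meanlog <- log(priors$K_mult * max(series$catch))

  par_names <- c("log_r", "log_K", "log_q_pre",
                 if (two_q) "log_q_post", "log_sigma", "z_psi")
  d <- length(par_names)
  lp_fun <- function(theta) {
    .spm_log_post(theta, series, priors, two_q, efficiency_trend_pct)
  }

  set.seed(seed)
  iter <- control$iter
  warmup <- control$warmup
  attempt <- 0
  repeat {
    draws_arr <- array(NA_real_, dim = c(iter, control$chains, d),
                       dimnames = list(NULL, NULL, par_names))
    acc <- numeric(control$chains)
    for (ch in seq_len(control$chains)) {
      # dispersed starts; resample (drifting K upward) until the start has
      # positive posterior density, since low-K starts can hit the biomass
      # floor under the observed catch history
      theta0 <- NULL
      for (try in seq_len(200)) {
        K0 <- exp(priors$K_meanlog + stats::rnorm(1, 0, 0.4) +
                    0.02 * (try - 1))
        r0 <- exp(priors$r_meanlog + stats::rnorm(1, 0, 0.3))
        q0 <- stats::median(series$cpue, na.rm = TRUE) / (0.6 * K0)
        cand <- c(log(r0), log(K0), log(q0),
                  if (two_q) log(q0) + stats::rnorm(1, 0, 0.2),
                  log(0.15) + stats::rnorm(1, 0, 0.3),
                  stats::rnorm(1, 1, 0.5))
        if (is.finite(lp_fun(cand))) {
          theta0 <- cand
          break
        }
      }
      if (is.null(theta0)) {
        stop("could not find a valid chain start: the catch history may be ",
             "inconsistent with any biomass trajectory under the priors")
      }
      res <- .spm_run_chain(theta0, lp_fun, warmup, iter,
                            control$target_accept)
      draws_arr[, ch, ] <- res$draws
      acc[ch] <- res$acceptance
    }
    diagnostics <- mcmc_diagnostics(draws_arr, par_names)
    converged <- all(diagnostics$rhat < control$rhat_max) &&
      all(diagnostics$ess >= control$min_ess)
    if (converged || attempt >= control$max_doublings) break
    attempt <- attempt + 1
    iter <- iter * 2L
    warmup <- warmup * 2L
  }
  if (!converged) {
    msg <- paste0(
      "surplus-production sampler did not converge after ", attempt + 1,
      " attempt(s): max R-hat = ", signif(max(diagnostics$rhat), 4),
      ", min ESS = ", signif(min(diagnostics$ess), 4)
    )
    cond <- simpleError(msg)
    cond$diagnostics <- diagnostics
    stop(cond)
  }

  flat <- apply(draws_arr, 3, as.vector)
  draws <- tibble::tibble(
    r = exp(flat[, "log_r"]),
    K = exp(flat[, "log_K"]),
    q_pre = exp(flat[, "log_q_pre"]),
    q_post = if (two_q) exp(flat[, "log_q_post"]) else exp(flat[, "log_q_pre"]),
    sigma_obs = exp(flat[, "log_sigma"]),
    psi = priors$psi_min +
      (priors$psi_max - priors$psi_min) * stats::plogis(flat[, "z_psi"])
  )
  draws$msy <- draws$r * draws$K / 4
  n_yr <- length(series$years)
  draws$depletion <- vapply(seq_len(nrow(draws)), function(i) {
    proj <- project_biomass(draws[i, ], series$catch)
    proj$biomass[n_yr] / draws$K[i]
  }, numeric(1))

  out <- list(
    draws = draws, diagnostics = diagnostics, acceptance = acc,
    series = series, priors = priors, control = control,
    efficiency_trend_pct = efficiency_trend_pct,
    iterations_used = iter, two_q = two_q
  )
  class(out) <- "spm_posterior"
  out
}

#' @export
print.spm_posterior <- function(x, ...) {
  med <- vapply(x$draws[c("r", "K", "msy", "depletion")], stats::median,
                numeric(1))
  cat("Schaefer surplus-production posterior for stock '",
      x$series$stock_id, "'\n", sep = "")
  cat(sprintf("  %d draws; median r = %.3f, K = %.0f t, MSY = %.0f t, final depletion = %.0f%%\n",
              nrow(x$draws), med["r"], med["K"], med["msy"],
              100 * med["depletion"]))
  cat(sprintf("  max R-hat = %.3f, min ESS = %.0f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

#' Summarise final-year depletion
#'
#' Posterior quantiles (2.5, 50, 97.5 percent) of final-year biomass as a
#' percentage of carrying capacity.
#'
#' @param posterior an `spm_posterior` (or any object whose `draws` carry a
#'   `depletion` column).
#' @return Named numeric vector `lower`, `median`, `upper` (percent of
#'   unfished biomass).
#' @export
depletion_summary <- function(posterior) {
  dep <- posterior$draws$depletion
  if (is.null(dep) || length(dep) == 0) stop("posterior has no depletion draws")
  q <- stats::quantile(dep, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  stats::setNames(100 * q, c("lower", "median", "upper"))
}

#' Goodness of fit on the CPUE scale
#'
#' Squared Pearson correlation between observed log CPUE and the
#' posterior-median predicted log CPUE over observed years.
#'
#' @param posterior an `spm_posterior`.
#' @param series the fitted [cpue_series()]; defaults to the one stored in
#'   the posterior.
#' @param max_draws cap on draws used to form the posterior-median
#'   prediction.
#' @return R-squared in \[0, 1\].
#' @export
fit_r_squared <- function(posterior, series = posterior$series,
                          max_draws = 1000) {
  obs <- !is.na(series$cpue)
  if (sum(obs) < 3) stop("fewer than 3 observed CPUE years: R-squared undefined")
  draws <- posterior$draws
  idx <- unique(round(seq(1, nrow(draws), length.out = min(max_draws, nrow(draws)))))
  pred_log <- vapply(idx, function(i) {
    p <- draws[i, ]
    proj <- project_biomass(p, series$catch)
    log(expected_cpue(p, proj$biomass, series$years, series$regime_year,
                      posterior$efficiency_trend_pct))
  }, numeric(length(series$years)))
  med_pred <- apply(pred_log, 1, stats::median)
  if (stats::sd(med_pred[obs]) == 0) return(0)
  stats::cor(log(series$cpue[obs]), med_pred[obs])^2
}
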