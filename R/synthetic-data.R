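# Synthetic-data generators: emulate the four pipeline inputs (habitat
# evidence, catch tables, region reef areas, CPUE series) with known ground
# truth, so every downstream stage is testable without any data download.
# One master seed per generator call; all sub-streams derive from it.

#' Configuration for the habitat/catch generators
#'
#' Defaults mirror the study system the package targets: 57 commercially
#' reported species/groups, 9 reporting regions, a 10-year analysis decade,
#' and a positive effect of regional reef area on the share of catch from
#' live-coral-dependent (category 3) taxa.
#'
#' @param n_species number of species.
#' @param n_regions number of reporting regions.
#' @param n_years number of calendar years of catch records.
#' @param category_probs length-4 probabilities of the four dependence
#'   categories across species (must sum to 1).
#' @param reef_effect_slope percentage points of category-3 catch share per
#'   percentage point of regional reef area.
#' @param catch_noise_cv lognormal coefficient of variation applied to each
#'   taxon x region x year catch cell (0 disables noise).
#' @param start_year first calendar year of the records.
#' @param seed master seed for the generator call.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 57, n_regions = 9, n_years = 10,
                       category_probs = c(0.50, 0.25, 0.15, 0.10),
                       reef_effect_slope = 2.1, catch_noise_cv = 0.1,
                       start_year = 2008, seed = 1) {
  if (length(category_probs) != 4 || any(category_probs < 0) ||
      abs(sum(category_probs) - 1) > 1e-9) {
    stop("category_probs must be 4 non-negative probabilities summing to 1")
  }
  if (n_species < 1 || n_regions < 1) stop("counts must be >= 1")
  if (n_years < 2) stop("n_years must be >= 2")
  if (catch_noise_cv < 0) stop("catch_noise_cv must be >= 0")
  structure(
    list(
      n_species = as.integer(n_species), n_regions = as.integer(n_regions),
      n_years = as.integer(n_years), category_probs = category_probs,
      reef_effect_slope = reef_effect_slope,
      catch_noise_cv = catch_noise_cv,
      start_year = as.integer(start_year), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Deterministic category assignment: largest-remainder apportionment of
# n_species over category_probs, then a seeded shuffle. Guarantees every
# category with appreciable probability is represented, which the
# share-targeting catch construction requires.
.assign_true_categories <- function(config) {
  n <- config$n_species
  quota <- n * config$category_probs
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  cats <- rep(1:4, times = counts)
  set.seed(config$seed)
  sample(cats, n)
}

.species_ids <- function(n) sprintf("sp_%03d", seq_len(n))
.region_ids <- function(n) sprintf("region_%02d", seq_len(n))
.gear_types <- c("pot", "otter_trawl", "net", "line", "dive", "beam_trawl")

#' Generate a habitat-evidence database with known categories
#'
#' For each species, emits evidence rows whose flag pattern encodes the
#' species' ground-truth dependence category (plus extra lower-evidence
#' rows, as real literature reviews hold many observations per species).
#' The flag hierarchy (obligate implies dependent implies associated) holds
#' by construction, so the classifier recovers the truth exactly.
#'
#' @param config a [sim_config()].
#' @return List with `evidence` (habitat-evidence tibble) and `truth`
#'   (tibble `species_id`, `category`) — the ground-truth sidecar, never
#'   merged into the inputs.
#' @export
generate_habitat_database <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cats <- .assign_true_categories(config)
  ids <- .species_ids(config$n_species)
  set.seed(config$seed + 1L)
  non_coral <- setdiff(.evidence_substrates, c("coral_reef", "none"))

  one_row <- function(sp, level) {
    habitat_evidence(
      species_id = sp,
      life_stage = sample(.evidence_life_stages, 1),
      method = sample(.evidence_methods, 1),
      habitat_kind = "substrate",
      substrate = if (level >= 2) "coral_reef" else sample(non_coral, 1),
      coral_assoc = level >= 2,
      live_coral_dependent = level >= 3,
      live_coral_obligate = level >= 4,
      source_ref = "synthetic"
    )
  }

  rows <- lapply(seq_along(ids), function(i) {
    n_extra <- sample(0:2, 1)
    # the defining row at the species' true level, plus weaker extras
    levels <- c(cats[i], if (n_extra > 0) sample(seq_len(cats[i]), n_extra,
                                                 replace = TRUE))
    dplyr::bind_rows(lapply(levels, one_row, sp = ids[i]))
  })
  list(
    evidence = dplyr::bind_rows(rows),
    truth = tibble::tibble(species_id = ids, category = as.integer(cats))
  )
}

#' Generate catch and region tables with an embedded reef-area effect
#'
#' Builds one region table (percent coral-reef area) and one catch table
#' whose expected category-3 share in region i is
#' `baseline + reef_effect_slope * reef_pct_i` (clipped to \[0, 100\]),
#' where the baseline is the configured category-3 probability in percent.
#' The remaining share is split across categories 1, 2 and 4 in proportion
#' to their configured probabilities. Within a category, quantity is split
#' equally across that category's species, then lognormal multiplicative
#' noise with the configured CV is applied per taxon x region x year cell.
#'
#' @param config a [sim_config()].
#' @param region_reef_pct percent reef area per region, in \[0, 100\].
#' @param annual_total expected total catch per region per year (tonnes).
#' @return List with `catch` (catch-record tibble), `regions` (tibble
#'   `region`, `reef_pct`) and `truth` (expected percent share per region x
#'   category before noise).
#' @export
generate_catch_tables <- function(config, region_reef_pct,
                                  annual_total = 1000) {
  stopifnot(inherits(config, "sim_config"))
  if (length(region_reef_pct) != config$n_regions) {
    stop("region_reef_pct must have one entry per region")
  }
  if (any(region_reef_pct < 0 | region_reef_pct > 100)) {
    stop("reef percentages must be in [0, 100]")
  }
  cats <- .assign_true_categories(config)
  ids <- .species_ids(config$n_species)
  regions <- .region_ids(config$n_regions)
  years <- config$start_year + seq_len(config$n_years) - 1L

  set.seed(config$seed + 2L)
  gear_of <- stats::setNames(
    sample(.gear_types, config$n_species, replace = TRUE), ids
  )

  p <- config$category_probs
  baseline3 <- 100 * p[3]
  other <- c(1, 2, 4)
  other_w <- p[other]
  other_w <- if (sum(other_w) > 0) other_w / sum(other_w) else c(1, 0, 0)

  share_mat <- matrix(0, nrow = config$n_regions, ncol = 4)
  for (i in seq_len(config$n_regions)) {
    s3 <- min(100, max(0, baseline3 + config$reef_effect_slope *
                         region_reef_pct[i]))
    share_mat[i, 3] <- s3
    share_mat[i, other] <- (100 - s3) * other_w
  }

  n_per_cat <- tabulate(cats, nbins = 4)
  sdlog <- if (config$catch_noise_cv > 0) {
    sqrt(log(1 + config$catch_noise_cv^2))
  } else {
    0
  }

  cells <- tidyr::expand_grid(
    taxon_label = ids, region = regions, year = years
  )
  cells$category <- cats[match(cells$taxon_label, ids)]
  cells$gear <- unname(gear_of[cells$taxon_label])
  ri <- match(cells$region, regions)
  base <- annual_total * share_mat[cbind(ri, cells$category)] / 100 /
    n_per_cat[cells$category]
  noise <- if (sdlog > 0) {
    exp(stats::rnorm(nrow(cells), -sdlog^2 / 2, sdlog))
  } else {
    1
  }
  cells$quantity <- base * noise
  cells$sector <- "commercial"
  cells$basis <- "weight_tonnes"
  catch <- cells[, c("taxon_label", "region", "sector", "gear", "year",
                     "quantity", "basis")]

  truth <- tibble::tibble(
    region = rep(regions, each = 4),
    category = rep(1:4, times = config$n_regions),
    expected_percent = as.vector(t(share_mat))
  )
  list(
    catch = tibble::as_tibble(catch),
    regions = tibble::tibble(region = regions,
                             reef_pct = as.numeric(region_reef_pct)),
    truth = truth
  )
}

#' Configuration for the surplus-production simulator
#'
#' Holds the true parameter values of one simulated stock. Defaults match
#' a moderately productive reef meso-predator observed over four decades.
#'
#' @param r_true intrinsic growth rate (per year).
#' @param K_true carrying capacity (tonnes).
#' @param q_pre,q_post catchability before/from the regime year.
#' @param sigma_obs lognormal sd of CPUE observation error.
#' @param regime_year catchability change year, or `NA` for none.
#' @param harvest_pattern `"up_down"` (effort rises then falls; the
#'   default, because one-way histories leave r and K weakly identified),
#'   `"one_way"` or `"constant_fraction"`.
#' @param n_years series length.
#' @param start_year first calendar year; the default places the final
#'   year at 2018.
#' @param process_error_sd optional lognormal process error on the biomass
#'   update (0 by default: the fitted model is observation-error-only, and
#'   this flag exists to probe robustness).
#' @param b0_frac starting biomass as a fraction of K (default 1: the
#'   stock is unfished at the start of the series).
#' @param seed master seed.
#' @return Validated list of class `spm_sim_config`.
#' @export
spm_sim_config <- function(r_true = 0.3, K_true = 5000,
                           q_pre = 2e-4, q_post = 2e-4, sigma_obs = 0.05,
                           regime_year = NA, harvest_pattern = "up_down",
                           n_years = 40, start_year = 2018 - n_years + 1,
                           process_error_sd = 0, b0_frac = 1, seed = 1) {
  stopifnot(r_true > 0, K_true > 0, q_pre > 0, q_post > 0, sigma_obs >= 0,
            n_years >= 2, process_error_sd >= 0, b0_frac > 0, b0_frac <= 1)
  harvest_pattern <- match.arg(harvest_pattern,
                               c("up_down", "one_way", "constant_fraction"))
  years <- start_year + seq_len(n_years) - 1L
  if (!is.na(regime_year) &&
      (regime_year <= years[1] || regime_year > years[n_years])) {
    stop("regime_year must fall strictly inside the simulated span")
  }
  structure(
    list(
      r_true = r_true, K_true = K_true, q_pre = q_pre, q_post = q_post,
      sigma_obs = sigma_obs, regime_year = regime_year,
      harvest_pattern = harvest_pattern, n_years = as.integer(n_years),
      start_year = as.integer(start_year),
      process_error_sd = process_error_sd, b0_frac = b0_frac,
      seed = as.integer(seed)
    ),
    class = "spm_sim_config"
  )
}

# harvest rate (fraction of biomass removed) per year for each pattern
.harvest_rates <- function(pattern, r, n_years) {
  switch(
    pattern,
    up_down = {
      peak <- ceiling(0.6 * n_years)
      up <- seq(0.05 * r, 0.75 * r, length.out = peak)
      down <- seq(0.75 * r, 0.25 * r, length.out = n_years - peak + 1)[-1]
      c(up, down)
    },
    one_way = seq(0.05 * r, 0.75 * r, length.out = n_years),
    constant_fraction = rep(r / 4, n_years)
  )
}

#' Simulate a catch + CPUE series from the Schaefer model
#'
#' Runs the logistic biomass recursion forward from `B1 = K` under the
#' configured harvest pattern (catch each year is the harvest rate times
#' current biomass), then observes
#' `CPUE_t = q(t) * B_t * exp(eps_t)`, `eps_t ~ Normal(0, sigma_obs^2)`,
#' with `q(t) = q_pre` before the regime year and `q_post` from it on.
#' Configurations whose harvest drives biomass below `1e-3 * K` are
#' rejected with an error naming the offending year, keeping simulated data
#' inside the fitted model's support.
#'
#' @param config a [spm_sim_config()].
#' @param stock_id label for the simulated stock.
#' @param catch_override optional explicit catch vector (tonnes per year)
#'   replacing the harvest pattern.
#' @return List with `series` (a [cpue_series()]) and `biomass` (the latent
#'   trajectory, for oracle tests).
#' @export
simulate_spm_series <- function(config, stock_id = "sim_stock",
                                catch_override = NULL) {
  stopifnot(inherits(config, "spm_sim_config"))
  n <- config$n_years
  years <- config$start_year + seq_len(n) - 1L
  r <- config$r_true; K <- config$K_true
  set.seed(config$seed)

  u <- if (is.null(catch_override)) {
    .harvest_rates(config$harvest_pattern, r, n)
  } else {
    if (length(catch_override) != n) stop("catch_override must cover n_years")
    NULL
  }
  proc_eps <- if (config$process_error_sd > 0) {
    stats::rnorm(n, 0, config$process_error_sd)
  } else {
    rep(0, n)
  }

  b <- numeric(n)
  catch <- numeric(n)
  b[1] <- config$b0_frac * K
  for (t in seq_len(n)) {
    catch[t] <- if (is.null(u)) catch_override[t] else u[t] * b[t]
    if (t < n) {
      nxt <- (b[t] + (r * b[t] * (1 - b[t] / K) - catch[t])) * exp(proc_eps[t])
      if (nxt < 1e-3 * K) {
        stop("harvest drives biomass below the floor in year ", years[t + 1])
      }
      b[t + 1] <- nxt
    }
  }

  q_t <- if (is.na(config$regime_year)) {
    rep(config$q_pre, n)
  } else {
    ifelse(years < config$regime_year, config$q_pre, config$q_post)
  }
  obs_eps <- if (config$sigma_obs > 0) {
    stats::rnorm(n, 0, config$sigma_obs)
  } else {
    rep(0, n)
  }
  cpue <- q_t * b * exp(obs_eps)

  list(
    series = cpue_series(stock_id, years, catch, cpue,
                         regime_year = config$regime_year),
    biomass = b
  )
}
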