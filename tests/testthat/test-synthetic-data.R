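test_that("degenerate category probabilities force the stated flag patterns", {
  cfg1 <- sim_config(n_species = 12, category_probs = c(1, 0, 0, 0), seed = 3)
  hab1 <- generate_habitat_database(cfg1)
  expect_false(any(hab1$evidence$coral_assoc))
  expect_false(any(hab1$evidence$live_coral_dependent))

  cfg4 <- sim_config(n_species = 12, category_probs = c(0, 0, 0, 1), seed = 3)
  hab4 <- generate_habitat_database(cfg4)
  obligate_sp <- unique(hab4$evidence$species_id[hab4$evidence$live_coral_obligate])
  expect_setequal(obligate_sp, hab4$truth$species_id)
})

test_that("generated evidence is internally consistent and classifiable", {
  cfg <- sim_config(seed = 7)
  hab <- generate_habitat_database(cfg)
  expect_silent(validate_evidence(hab$evidence))
  # every species has at least one row
  expect_setequal(unique(hab$evidence$species_id), hab$truth$species_id)
  # downstream classification recovers the ground truth for 100% of species
  rec <- build_catalog(hab$evidence)$catalog
  truth <- stats::setNames(hab$truth$category, hab$truth$species_id)
  expect_identical(
    unname(truth[rec$group_label]), rec$category
  )
})

test_that("invalid generator configurations are refused", {
  expect_error(sim_config(category_probs = c(0.5, 0.5, 0.5, 0)), "summing to 1")
  expect_error(sim_config(n_years = 1), "n_years")
  expect_error(sim_config(catch_noise_cv = -0.1), "catch_noise_cv")
  cfg <- sim_config(n_regions = 3)
  expect_error(generate_catch_tables(cfg, c(-5, 0, 10)), "\\[0, 100\\]")
  expect_error(generate_catch_tables(cfg, c(0, 10)), "one entry per region")
})

test_that("catch tables embed the configured reef-area effect", {
  # zero slope: shares differ across regions only by noise (none at cv=0)
  cfg0 <- sim_config(n_regions = 4, reef_effect_slope = 0,
                     catch_noise_cv = 0, seed = 5)
  t0 <- generate_catch_tables(cfg0, c(0, 10, 20, 30))
  s3 <- t0$truth$expected_percent[t0$truth$category == 3]
  expect_equal(max(s3) - min(s3), 0)

  # slope 2, cv 0, reef 0 vs 10: category-3 share differs by 20 points
  cfg2 <- sim_config(n_regions = 2, reef_effect_slope = 2.0,
                     catch_noise_cv = 0, seed = 5)
  t2 <- generate_catch_tables(cfg2, c(0, 10))
  s3 <- t2$truth$expected_percent[t2$truth$category == 3]
  expect_equal(diff(s3), 20)

  # realized shares at cv=0 equal the expected shares exactly
  catalog <- build_catalog(generate_habitat_database(cfg2)$evidence)$catalog
  prof <- aggregate_profile(t2$catch, catalog, "region",
                            c(cfg2$start_year, cfg2$start_year + cfg2$n_years - 1))
  m <- merge(prof, t2$truth, by.x = c("key", "category"),
             by.y = c("region", "category"))
  expect_equal(m$percent, m$expected_percent, tolerance = 1e-12)
})

test_that("downstream regression recovers the generator slope across replicates", {
  reef <- seq(0, 32, length.out = 9)
  covered <- vapply(1:50, function(s) {
    cfg <- sim_config(reef_effect_slope = 2.0, catch_noise_cv = 0.1,
                      seed = 100 + s)
    tabs <- generate_catch_tables(cfg, reef)
    catalog <- build_catalog(generate_habitat_database(cfg)$evidence)$catalog
    prof <- aggregate_profile(tabs$catch, catalog, "region", c(2008, 2017))
    reg <- regress_reef_area(prof, tabs$regions, categories = 3, seed = s)
    reg$ci_lower <= 2.0 && reg$ci_upper >= 2.0
  }, logical(1))
  expect_gte(sum(covered), 45)
})

test_that("forward simulation matches the analytic recursion and honours floors", {
  # sigma 0, single q, constant catch rK/4 from B = K/2: CPUE constant at qK/2
  cfg <- spm_sim_config(r_true = 0.4, K_true = 2000, q_pre = 1e-3,
                        q_post = 1e-3, sigma_obs = 0, b0_frac = 0.5,
                        n_years = 15, seed = 2)
  sim <- simulate_spm_series(cfg, catch_override = rep(0.4 * 2000 / 4, 15))
  expect_equal(sim$series$cpue, rep(1e-3 * 1000, 15))
  expect_equal(sim$biomass, rep(1000, 15))

  # zero catch from B = K: carrying capacity is a fixed point
  cfg0 <- spm_sim_config(r_true = 0.3, K_true = 5000, sigma_obs = 0,
                         n_years = 10, seed = 2)
  sim0 <- simulate_spm_series(cfg0, catch_override = rep(0, 10))
  expect_equal(sim0$biomass, rep(5000, 10))

  # configurations that crash the stock are rejected, naming the year
  cfg_bad <- spm_sim_config(r_true = 0.1, K_true = 1000, sigma_obs = 0,
                            n_years = 6, start_year = 2000, seed = 2)
  expect_error(simulate_spm_series(cfg_bad, catch_override = rep(600, 6)),
               "year 200[0-9]")

  # independently coded recursion agrees exactly under each harvest pattern
  set.seed(77)
  for (pattern in c("up_down", "one_way", "constant_fraction")) {
    r <- stats::runif(1, 0.1, 0.6); K <- stats::runif(1, 1000, 9000)
    cfg <- spm_sim_config(r_true = r, K_true = K, sigma_obs = 0,
                          harvest_pattern = pattern, n_years = 25, seed = 9)
    sim <- simulate_spm_series(cfg)
    b <- numeric(25); b[1] <- K
    for (t in 1:24) {
      b[t + 1] <- b[t] + (r * b[t] * (1 - b[t] / K) - sim$series$catch[t])
    }
    expect_identical(sim$biomass, b)
    expect_identical(sim$series$cpue, cfg$q_pre * b)
  }
})

test_that("generators are bit-reproducible for a fixed seed", {
  cfg <- sim_config(seed = 42)
  h1 <- generate_habitat_database(cfg)
  h2 <- generate_habitat_database(cfg)
  expect_identical(h1, h2)
  reef <- seq(0, 40, length.out = cfg$n_regions)
  c1 <- generate_catch_tables(cfg, reef)
  c2 <- generate_catch_tables(cfg, reef)
  expect_identical(c1, c2)
  s1 <- simulate_spm_series(spm_sim_config(seed = 42))
  s2 <- simulate_spm_series(spm_sim_config(seed = 42))
  expect_identical(s1, s2)
})
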