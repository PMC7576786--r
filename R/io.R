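# CSV schemas and pipeline plumbing. Each reader validates the header
# against its schema exactly (missing and unknown columns are both errors,
# named in the message) and reads with explicit column types; writers are
# plain RFC-4180 CSV so read(write(x)) round-trips.

.schemas <- list(
  habitat_evidence = list(
    cols = readr::cols(
      species_id = readr::col_character(),
      life_stage = readr::col_character(),
      method = readr::col_character(),
      habitat_kind = readr::col_character(),
      substrate = readr::col_character(),
      coral_assoc = readr::col_logical(),
      live_coral_dependent = readr::col_logical(),
      live_coral_obligate = readr::col_logical(),
      source_ref = readr::col_character()
    )
  ),
  group_map = list(
    cols = readr::cols(
      group_label = readr::col_character(),
      species_id = readr::col_character(),
      resolution = readr::col_character()
    )
  ),
  catch = list(
    cols = readr::cols(
      taxon_label = readr::col_character(),
      region = readr::col_character(),
      sector = readr::col_character(),
      gear = readr::col_character(),
      year = readr::col_integer(),
      quantity = readr::col_double(),
      basis = readr::col_character()
    )
  ),
  region = list(
    cols = readr::cols(
      region = readr::col_character(),
      reef_pct = readr::col_double()
    )
  ),
  cpue = list(
    cols = readr::cols(
      stock_id = readr::col_character(),
      year = readr::col_integer(),
      catch_t = readr::col_double(),
      cpue = readr::col_double()
    )
  )
)

.read_schema <- function(path, schema_name) {
  spec <- .schemas[[schema_name]]
  expected <- names(spec$cols$cols)
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(expected, header)
  extra <- setdiff(header, expected)
  if (length(missing) > 0 || length(extra) > 0) {
    stop(
      "schema mismatch for ", schema_name, " file '", path, "'",
      if (length(missing) > 0) paste0("; missing column(s): ",
                                      paste(missing, collapse = ", ")),
      if (length(extra) > 0) paste0("; unknown column(s): ",
                                    paste(extra, collapse = ", "))
    )
  }
  out <- readr::read_csv(path, col_types = spec$cols, show_col_types = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop(
      "malformed row(s) in '", path, "' at line(s): ",
      paste(unique(probs$row), collapse = ", ")
    )
  }
  out[, expected]
}

#' Read / write the pipeline's CSV tables
#'
#' Five input schemas tie the pipeline together: habitat evidence
#' (`species_id`, `life_stage`, `method`, `habitat_kind`, `substrate`,
#' `coral_assoc`, `live_coral_dependent`, `live_coral_obligate`,
#' `source_ref`), group map (`group_label`, `species_id`, `resolution`),
#' catch records (`taxon_label`, `region`, `sector`, `gear`, `year`,
#' `quantity`, `basis`), region reef areas (`region`, `reef_pct`) and CPUE
#' series (`stock_id`, `year`, `catch_t`, `cpue`). Headers must match the
#' schema exactly; mismatches raise an error naming the missing or unknown
#' columns, and malformed rows are reported with their line numbers.
#'
#' @param path file path.
#' @return The validated tibble (readers); the input, invisibly (writers).
#' @name reef_csv
NULL

#' @rdname reef_csv
#' @export
read_habitat_csv <- function(path) {
  validate_evidence(.read_schema(path, "habitat_evidence"))
}

#' @rdname reef_csv
#' @export
read_group_map_csv <- function(path) .read_schema(path, "group_map")

#' @rdname reef_csv
#' @export
read_catch_csv <- function(path) .read_schema(path, "catch")

#' @rdname reef_csv
#' @export
read_region_csv <- function(path) .read_schema(path, "region")

#' @rdname reef_csv
#' @export
read_cpue_csv <- function(path) .read_schema(path, "cpue")

#' @rdname reef_csv
#' @param x table to write.
#' @export
write_reef_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' Convert a long CPUE table to per-stock series objects
#'
#' @param cpue_table tibble from [read_cpue_csv()].
#' @param regime_year catchability change year applied to every stock, or
#'   `NA`.
#' @return Named list of [cpue_series()] objects, one per `stock_id`.
#' @export
cpue_table_to_series <- function(cpue_table, regime_year = NA) {
  split(cpue_table, cpue_table$stock_id) |>
    lapply(function(d) {
      d <- d[order(d$year), ]
      cpue_series(d$stock_id[1], d$year, d$catch_t, d$cpue, regime_year)
    })
}

#' Flatten a fitted cpue_series to the CPUE CSV schema
#'
#' @param series a [cpue_series()].
#' @return Tibble in the CPUE CSV schema.
#' @export
series_to_cpue_table <- function(series) {
  tibble::tibble(
    stock_id = series$stock_id, year = series$years,
    catch_t = series$catch, cpue = series$cpue
  )
}

#' Run the full synthetic-data pipeline end to end
#'
#' Generates the four input tables, classifies species, profiles catch
#' composition by region, regresses category shares on reef area, fits the
#' surplus-production model to a simulated stock and derives its risk
#' curve, writing every artifact as CSV into `out_dir`. A `run_info.csv`
#' sidecar records the package version and seed so reruns are
#' attributable. Inputs are never mutated.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()] for the habitat/catch generators.
#' @param spm_config a [spm_sim_config()] for the simulated stock.
#' @param region_reef_pct percent reef area per region; defaults to an
#'   even spread over 0-40%.
#' @param risk_window inclusive year window for recent catch; defaults to
#'   the simulated stock's last three years.
#' @param mcmc_control from [spm_mcmc_control()].
#' @return Invisible list of the in-memory results (profiles, regression
#'   summary, posterior, risk curve, file paths).
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         spm_config = spm_sim_config(),
                         region_reef_pct = NULL,
                         risk_window = NULL,
                         mcmc_control = spm_mcmc_control()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(region_reef_pct)) {
    region_reef_pct <- seq(0, 40, length.out = config$n_regions)
  }

  hab <- generate_habitat_database(config)
  tabs <- generate_catch_tables(config, region_reef_pct)
  sim <- simulate_spm_series(spm_config)

  write_reef_csv(hab$evidence, file.path(out_dir, "habitat_evidence.csv"))
  write_reef_csv(tabs$catch, file.path(out_dir, "catch.csv"))
  write_reef_csv(tabs$regions, file.path(out_dir, "regions.csv"))
  write_reef_csv(series_to_cpue_table(sim$series),
                 file.path(out_dir, "cpue.csv"))
  write_reef_csv(hab$truth, file.path(out_dir, "ground_truth_categories.csv"))

  catalog <- build_catalog(hab$evidence)
  write_reef_csv(catalog$catalog, file.path(out_dir, "catalog.csv"))
  write_reef_csv(catalog$rejects, file.path(out_dir, "catalog_rejects.csv"))

  year_range <- c(config$start_year, config$start_year + config$n_years - 1L)
  profiles <- aggregate_profile(tabs$catch, catalog$catalog,
                                group_by = "region", year_range = year_range)
  write_reef_csv(profiles, file.path(out_dir, "profiles_by_region.csv"))

  regression <- regress_reef_area(profiles, tabs$regions,
                                  seed = config$seed)
  write_reef_csv(regression[, setdiff(names(regression), "fit")],
                 file.path(out_dir, "reef_regression_summary.csv"))

  posterior <- fit_spm(sim$series, control = mcmc_control,
                       seed = spm_config$seed)
  write_reef_csv(posterior$draws, file.path(out_dir, "spm_draws.csv"))
  write_reef_csv(posterior$diagnostics,
                 file.path(out_dir, "spm_diagnostics.csv"))

  if (is.null(risk_window)) {
    last <- sim$series$years[length(sim$series$years)]
    risk_window <- c(last - 2L, last)
  }
  rc <- risk_curve(posterior, recent_catch(sim$series, risk_window))
  write_reef_csv(rc, file.path(out_dir, "risk_curve.csv"))

  write_reef_csv(
    tibble::tibble(
      package_version = as.character(utils::packageVersion("reefdep")),
      seed = config$seed, spm_seed = spm_config$seed
    ),
    file.path(out_dir, "run_info.csv")
  )

  invisible(list(
    catalog = catalog, profiles = profiles, regression = regression,
    posterior = posterior, risk_curve = rc, out_dir = out_dir
  ))
}
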