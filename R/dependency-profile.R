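# Catch-composition profiling: per-category shares of catch by gear,
# region or sector, on a weight (tonnes) or count (individuals) basis.

#' Mean annual catch per taxon over an analysis window
#'
#' Sums reported quantity per taxon within the window and divides by the
#' number of calendar years in the window. A taxon absent from a year's
#' records contributed zero catch that year (logbook semantics), so the
#' divisor is always the full window length — a taxon reported once with
#' 10 t over a 10-year window averages 1 t/yr.
#'
#' @param catch catch-record table with columns `taxon_label`, `year`,
#'   `quantity` (see [read_catch_csv()] for the full schema).
#' @param year_range inclusive integer interval `c(first, last)`.
#' @return Named numeric vector: mean annual quantity per taxon.
#' @export
mean_annual_catch <- function(catch, year_range) {
  year_range <- as.integer(year_range)
  if (length(year_range) != 2 || year_range[2] < year_range[1]) {
    stop("year_range must be an inclusive interval c(first, last)")
  }
  n_years <- year_range[2] - year_range[1] + 1L
  inside <- catch[catch$year >= year_range[1] & catch$year <= year_range[2], ]
  if (nrow(inside) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  sums <- tapply(inside$quantity, inside$taxon_label, sum)
  out <- as.numeric(sums) / n_years
  stats::setNames(out, names(sums))[sort(names(sums))]
}

#' Profile catch composition by coral-dependence category
#'
#' Aggregates catch records to mean annual quantity per grouping key (gear,
#' region or sector) and coral-dependence category over an analysis window,
#' and converts to percent shares. Taxa absent from the catalog accumulate
#' in `excluded_quantity` and are omitted from the shares; the category-4
#' column is always carried, even when empty, so "no catch in the obligate
#' category" is an explicit zero rather than a missing row. Quantities on a
#' weight basis (commercial, charter logbooks) and a count basis
#' (recreational, aquarium surveys) are never mixed in one aggregation.
#'
#' @param catch catch-record table (columns `taxon_label`, `region`,
#'   `sector`, `gear`, `year`, `quantity`, `basis`).
#' @param catalog tibble with `group_label` and `category` columns, as from
#'   [build_catalog()]`$catalog`.
#' @param group_by one of `"gear"`, `"region"`, `"sector"`.
#' @param year_range inclusive integer interval `c(first, last)`.
#' @return Tidy tibble: one row per key x category with columns `key`,
#'   `category` (1..4), `percent`, `total_quantity`, `excluded_quantity`,
#'   `basis`. `percent` is `NA` (flagged, not silently zero) for keys whose
#'   entire catch was excluded. Shares sum to 100 per key otherwise.
#' @export
aggregate_profile <- function(catch, catalog,
                              group_by = c("gear", "region", "sector"),
                              year_range) {
  group_by <- match.arg(group_by)
  basis <- unique(catch$basis)
  if (length(basis) > 1) {
    stop(
      "mixed quantity bases in one aggregation (",
      paste(basis, collapse = ", "),
      "): weight- and count-based records must be profiled separately"
    )
  }
  year_range <- as.integer(year_range)
  n_years <- year_range[2] - year_range[1] + 1L

  inside <- catch[catch$year >= year_range[1] & catch$year <= year_range[2], ]
  inside$key <- inside[[group_by]]

  cat_map <- stats::setNames(catalog$category, catalog$group_label)
  inside$category <- unname(cat_map[inside$taxon_label])

  # mean annual quantity: window sum / window length (zero-fill semantics)
  keyed <- dplyr::group_by(inside, .data$key)
  per_key <- dplyr::summarise(
    keyed,
    total_quantity = sum(.data$quantity) / n_years,
    excluded_quantity = sum(.data$quantity[is.na(.data$category)]) / n_years,
    .groups = "drop"
  )

  classified <- inside[!is.na(inside$category), ]
  per_cat <- dplyr::summarise(
    dplyr::group_by(classified, .data$key, .data$category),
    quantity = sum(.data$quantity) / n_years,
    .groups = "drop"
  )

  grid <- tidyr::expand_grid(
    key = unique(inside$key),
    category = 1:4
  )
  out <- dplyr::left_join(grid, per_cat, by = c("key", "category"))
  out$quantity[is.na(out$quantity)] <- 0
  out <- dplyr::left_join(out, per_key, by = "key")

  classified_total <- out$total_quantity - out$excluded_quantity
  out$percent <- ifelse(
    classified_total > 0, 100 * out$quantity / classified_total, NA_real_
  )
  out$quantity <- NULL
  out$basis <- if (nrow(catch) > 0) basis else NA_character_
  dplyr::arrange(
    out[, c("key", "category", "percent", "total_quantity",
            "excluded_quantity", "basis")],
    .data$key, .data$category
  )
}
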