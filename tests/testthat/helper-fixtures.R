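# Shared fixtures: evidence rows transcribing the worked classification
# examples, and small helpers for random tables.

barramundi_evidence <- function() {
  # estuarine soft-sediment and vegetated habitats, no coral flags
  habitat_evidence(
    species_id = "Lates_calcarifer",
    life_stage = c("adult", "juvenile"),
    method = "catch_survey",
    substrate = c("unvegetated_soft", "seagrass"),
    coral_assoc = FALSE
  )
}

curryfish_evidence <- function() {
  # associates with reef habitat, no evidence of live-coral dependence
  habitat_evidence(
    species_id = "Stichopus_hermanni",
    method = "direct_observation",
    substrate = "coral_reef",
    coral_assoc = TRUE,
    live_coral_dependent = FALSE
  )
}

coral_trout_evidence <- function() {
  # higher recruitment to live coral habitat (juvenile experiment evidence)
  habitat_evidence(
    species_id = "Plectropomus_maculatus",
    life_stage = "juvenile",
    method = "experiment",
    substrate = "coral_reef",
    coral_assoc = TRUE,
    live_coral_dependent = TRUE,
    live_coral_obligate = FALSE
  )
}

# random catch table over a handful of taxa/regions/years
random_catch_table <- function(n_taxa, n_regions, years, classified_frac = 0.8) {
  taxa <- sprintf("tax_%02d", seq_len(n_taxa))
  grid <- expand.grid(
    taxon_label = taxa,
    region = sprintf("reg_%02d", seq_len(n_regions)),
    year = years,
    stringsAsFactors = FALSE
  )
  grid$sector <- "commercial"
  grid$gear <- sample(c("line", "net", "pot"), nrow(grid), replace = TRUE)
  grid$quantity <- stats::rlnorm(nrow(grid), log(10), 1)
  grid$basis <- "weight_tonnes"
  catalog <- tibble::tibble(
    group_label = taxa,
    category = sample(1:4, n_taxa, replace = TRUE)
  )
  keep <- sample(n_taxa, max(1, round(classified_frac * n_taxa)))
  list(catch = tibble::as_tibble(grid), catalog = catalog[keep, ])
}
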