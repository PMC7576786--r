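# Coral-dependence classification: the 4-level ordinal scheme and the rules
# for assigning categories to species and to aggregated catch groups.

#' Coral-dependence category labels
#'
#' The four ordinal sensitivity-to-coral-loss categories used throughout the
#' package: 1 = not known to be associated with coral reefs (live or dead);
#' 2 = associated with coral reefs but not known to depend on live coral
#' cover; 3 = known dependence on live coral cover; 4 = obligate dependence
#' on live coral cover. Higher values mean greater sensitivity to coral loss.
#'
#' @return Named integer vector of length 4.
#' @export
dependence_categories <- function() {
  c(
    "not_reef_associated"   = 1L,
    "reef_associated"       = 2L,
    "live_coral_dependent"  = 3L,
    "live_coral_obligate"   = 4L
  )
}

# controlled vocabularies for evidence rows
.evidence_life_stages <- c("egg", "larva", "juvenile", "adult", "unspecified")
.evidence_methods <- c(
  "direct_observation", "catch_survey", "e_tag", "video_survey",
  "diet_analysis", "experiment"
)
.evidence_substrates <- c(
  "coral_reef", "rocky_reef", "seagrass", "mangrove", "macroalgae",
  "unvegetated_soft", "none"
)

#' Construct a table of habitat-evidence rows
#'
#' One row records one observation linking a species (at some life stage,
#' by some method) to a habitat, with three structured coral-dependence
#' flags. The flags form a hierarchy: obligate live-coral dependence implies
#' live-coral dependence, which implies coral association; and any record on
#' coral-reef substrate is, by definition, coral-associated.
#'
#' @param species_id character, species identifiers.
#' @param life_stage one of `"egg"`, `"larva"`, `"juvenile"`, `"adult"`,
#'   `"unspecified"`.
#' @param method observation method: `"direct_observation"`,
#'   `"catch_survey"`, `"e_tag"`, `"video_survey"`, `"diet_analysis"` or
#'   `"experiment"`.
#' @param habitat_kind `"substrate"` or `"physico_chemical"`.
#' @param substrate one of `"coral_reef"`, `"rocky_reef"`, `"seagrass"`,
#'   `"mangrove"`, `"macroalgae"`, `"unvegetated_soft"`, `"none"`.
#' @param coral_assoc,live_coral_dependent,live_coral_obligate logical
#'   evidence flags; must respect the hierarchy described above.
#' @param source_ref free-text provenance for the observation.
#' @return A tibble with one row per observation.
#' @export
habitat_evidence <- function(species_id,
                             life_stage = "unspecified",
                             method = "catch_survey",
                             habitat_kind = "substrate",
                             substrate = "none",
                             coral_assoc = FALSE,
                             live_coral_dependent = FALSE,
                             live_coral_obligate = FALSE,
                             source_ref = "") {
  ev <- tibble::tibble(
    species_id = as.character(species_id),
    life_stage = as.character(life_stage),
    method = as.character(method),
    habitat_kind = as.character(habitat_kind),
    substrate = as.character(substrate),
    coral_assoc = as.logical(coral_assoc),
    live_coral_dependent = as.logical(live_coral_dependent),
    live_coral_obligate = as.logical(live_coral_obligate),
    source_ref = as.character(source_ref)
  )
  validate_evidence(ev)
}

#' Validate a habitat-evidence table
#'
#' Checks vocabulary membership and the evidence-flag hierarchy
#' (obligate implies dependent implies associated; coral-reef substrate
#' implies associated).
#'
#' @param evidence a tibble as produced by [habitat_evidence()].
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_evidence <- function(evidence) {
  required <- c(
    "species_id", "life_stage", "method", "habitat_kind", "substrate",
    "coral_assoc", "live_coral_dependent", "live_coral_obligate"
  )
  missing <- setdiff(required, names(evidence))
  if (length(missing) > 0) {
    stop("evidence table is missing columns: ", paste(missing, collapse = ", "))
  }
  bad_stage <- setdiff(unique(evidence$life_stage), .evidence_life_stages)
  if (length(bad_stage) > 0) {
    stop("unknown life_stage value(s): ", paste(bad_stage, collapse = ", "))
  }
  bad_method <- setdiff(unique(evidence$method), .evidence_methods)
  if (length(bad_method) > 0) {
    stop("unknown method value(s): ", paste(bad_method, collapse = ", "))
  }
  bad_sub <- setdiff(unique(evidence$substrate), .evidence_substrates)
  if (length(bad_sub) > 0) {
    stop("unknown substrate value(s): ", paste(bad_sub, collapse = ", "))
  }
  if (any(evidence$live_coral_obligate & !evidence$live_coral_dependent)) {
    stop("flag hierarchy violated: live_coral_obligate requires live_coral_dependent")
  }
  if (any(evidence$live_coral_dependent & !evidence$coral_assoc)) {
    stop("flag hierarchy violated: live_coral_dependent requires coral_assoc")
  }
  if (any(evidence$substrate == "coral_reef" & !evidence$coral_assoc)) {
    stop("flag hierarchy violated: substrate 'coral_reef' requires coral_assoc")
  }
  evidence
}

#' Classify one species from its habitat evidence
#'
#' Applies the ordinal rule: category 4 if any evidence row records obligate
#' dependence on live coral; otherwise 3 if any row records dependence on
#' live coral cover; otherwise 2 if any row records association with coral
#' reefs; otherwise 1. A species is placed in category 3 only when specific
#' evidence points to live-coral dependence; reef association alone yields
#' category 2. Adding evidence can never lower a category (the rule is a
#' maximum over rows), which mirrors the conservative treatment of
#' conflicting studies.
#'
#' @param evidence all habitat-evidence rows for a single species.
#' @return Integer category in 1..4.
#' @export
classify_species <- function(evidence) {
  if (is.null(evidence) || nrow(evidence) == 0) {
    stop("cannot classify a species with no evidence rows")
  }
  validate_evidence(evidence)
  if (length(unique(evidence$species_id)) > 1) {
    stop("classify_species() expects evidence for exactly one species")
  }
  if (any(evidence$live_coral_obligate)) return(4L)
  if (any(evidence$live_coral_dependent)) return(3L)
  if (any(evidence$coral_assoc)) return(2L)
  1L
}

#' Classify a catch group from its members' categories
#'
#' Catch statistics are often reported at genus or family level, or for
#' arbitrary market groups. A group is conservatively assigned the highest
#' category of any member species, so a family containing one obligate
#' coral feeder is category 4 even if most members are not.
#'
#' @param member_categories integer vector (multiset) of member categories.
#' @return Integer category in 1..4.
#' @export
classify_group <- function(member_categories) {
  if (length(member_categories) == 0) {
    stop("cannot classify a group with no member categories")
  }
  member_categories <- as.integer(member_categories)
  if (any(is.na(member_categories)) ||
      any(member_categories < 1L | member_categories > 4L)) {
    stop("member categories must be integers in 1..4")
  }
  max(member_categories)
}

#' Build the category catalog for all catch-reporting labels
#'
#' Resolves every group label appearing in catch data to a dependence
#' category: explicit overrides first (used, e.g., for aquarium taxa
#' classified from external global assessments, and for fixed assignments
#' such as harvested coral pieces = category 4); otherwise members are
#' classified from evidence and the group takes the maximum. Labels that
#' cannot be resolved — arbitrary groups flagged unclassifiable (such as a
#' bare "fish" category too broad to be useful), or members lacking any
#' evidence — are listed in a rejects table, never silently defaulted.
#'
#' @param evidence habitat-evidence table covering the member species.
#' @param group_map tibble with columns `group_label`, `species_id`,
#'   `resolution` (one of `"species"`, `"genus"`, `"family"`,
#'   `"arbitrary"`); one row per group member. `species_id` may be `NA` for
#'   arbitrary unclassifiable groups. If `NULL`, every species in
#'   `evidence` forms its own species-level group.
#' @param overrides named list or named integer vector mapping
#'   `group_label` to a fixed category.
#' @return A list with `catalog` (tibble: `group_label`, `category`) and
#'   `rejects` (tibble: `group_label`, `reason`).
#' @export
build_catalog <- function(evidence, group_map = NULL, overrides = NULL) {
  if (!is.null(evidence) && nrow(evidence) > 0) validate_evidence(evidence)
  if (is.null(group_map)) {
    sp <- unique(evidence$species_id)
    group_map <- tibble::tibble(
      group_label = sp, species_id = sp, resolution = "species"
    )
  }
  ov <- if (is.null(overrides)) integer(0) else unlist(overrides)
  if (length(ov) > 0 && (any(ov < 1 | ov > 4))) {
    stop("override categories must be in 1..4")
  }

  species_cat <- if (!is.null(evidence) && nrow(evidence) > 0) {
    split(evidence, evidence$species_id) |>
      vapply(classify_species, integer(1))
  } else {
    integer(0)
  }

  labels <- union(unique(group_map$group_label), names(ov))
  cat_rows <- list()
  rej_rows <- list()
  for (lab in labels) {
    if (lab %in% names(ov)) {
      cat_rows[[lab]] <- as.integer(ov[[lab]])
      next
    }
    members <- group_map[group_map$group_label == lab, ]
    member_ids <- members$species_id[!is.na(members$species_id)]
    if (length(member_ids) == 0) {
      rej_rows[[lab]] <- "unclassifiable: no resolvable member species"
      next
    }
    known <- member_ids[member_ids %in% names(species_cat)]
    unknown <- setdiff(member_ids, known)
    if (length(unknown) > 0) {
      rej_rows[[lab]] <- paste0(
        "members without evidence or override: ",
        paste(sort(unknown), collapse = ", ")
      )
      next
    }
    cat_rows[[lab]] <- classify_group(species_cat[known])
  }

  catalog <- tibble::tibble(
    group_label = names(cat_rows),
    category = as.integer(unlist(cat_rows, use.names = FALSE))
  )
  rejects <- tibble::tibble(
    group_label = names(rej_rows),
    reason = as.character(unlist(rej_rows, use.names = FALSE))
  )
  if (nrow(catalog) == 0) {
    catalog <- tibble::tibble(group_label = character(0), category = integer(0))
  }
  if (nrow(rejects) == 0) {
    rejects <- tibble::tibble(group_label = character(0), reason = character(0))
  }
  list(catalog = catalog, rejects = rejects)
}

#' Rank taxa by catch and take the smallest set covering a share threshold
#'
#' Orders taxa from highest to lowest catch and returns the shortest prefix
#' whose cumulative share of total catch reaches the threshold — the rule
#' used to decide which taxa need habitat-association review (typically the
#' taxa making up 95% of catch by weight for each gear type). Ties in
#' weight are broken lexicographically by taxon label. A prefix reaching
#' exactly the threshold qualifies.
#'
#' @param catch_by_taxon named numeric vector of non-negative catch weights.
#' @param threshold_pct coverage threshold in (0, 100].
#' @return Character vector of taxon labels, in descending catch order.
#' @export
coverage_rank <- function(catch_by_taxon, threshold_pct = 95) {
  if (is.null(names(catch_by_taxon)) || any(!nzchar(names(catch_by_taxon)))) {
    stop("catch_by_taxon must be a named vector")
  }
  if (any(catch_by_taxon < 0)) stop("catch weights must be non-negative")
  total <- sum(catch_by_taxon)
  if (total <= 0) stop("all-zero catch: coverage ranking is undefined")
  if (threshold_pct <= 0 || threshold_pct > 100) {
    stop("threshold_pct must be in (0, 100]")
  }
  ord <- order(-catch_by_taxon, names(catch_by_taxon))
  w <- catch_by_taxon[ord]
  cum_share <- cumsum(w) / total * 100
  # tolerance guards exact-threshold prefixes against FP rounding
  k <- which(cum_share >= threshold_pct - 1e-9)[1]
  names(w)[seq_len(k)]
}
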