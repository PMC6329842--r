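# Normalization and tallying of the ALC-use record database: one row per
# study x species x anthropic-land-cover record, reduced to a species-level
# presence matrix with resolved activities, and counted every way the
# downstream comparisons need.

#' The five anthropic land-cover categories
#'
#' Human settlements (any urban environment: cities, towns, villages), open
#' areas (annual crops and cattle pastures), tree plantations (including
#' agroforestry systems), connectors (isolated trees and linear elements
#' such as live fences, hedgerows and corridors), and secondary forests
#' (regenerating forest after removal of native vegetation).
#'
#' @return character vector of the five canonical category codes.
#' @export
alc_types <- function() {
  c("human_settlements", "open_areas", "tree_plantations", "connectors",
    "secondary_forests")
}

#' @rdname alc_types
#' @export
realms <- function() {
  c("mainland_africa", "madagascar", "asia", "neotropics")
}

# keyword -> category synonym patterns, matched on lower-cased labels
#' @noRd
alc_synonyms <- function() {
  list(
    open_areas = c("open area", "crop", "pasture", "grazing", "cattle",
                   "agricultur", "cultivat"),
    tree_plantations = c("plantation", "agroforest", "orchard", "shade coffee",
                         "cacao", "eucalypt"),
    human_settlements = c("human settlement", "settlement", "city", "town",
                          "village", "urban", "garden"),
    connectors = c("connector", "live fence", "life fence", "fence", "hedgerow",
                   "fencerow", "isolated tree", "scattered tree", "remnant tree",
                   "corridor", "stepping stone", "linear"),
    secondary_forests = c("secondary", "second growth", "regenerating", "regrowth")
  )
}

#' Map raw land-cover labels to the five ALC categories
#'
#' Matches a controlled keyword list (e.g. "cattle pasture" -> `open_areas`,
#' "live fence" -> `connectors`, "second growth" -> `secondary_forests`);
#' canonical category codes pass through unchanged. Labels that match no
#' keyword are returned as `"unclassified"` with a warning - they are never
#' silently dropped, so callers can report them.
#'
#' @param labels character vector of raw land-cover descriptions.
#' @return character vector of category codes (or `"unclassified"`).
#' @examples
#' normalize_alc_type(c("cattle pasture", "live fence", "mangrove"))
#' @export
normalize_alc_type <- function(labels) {
  if (!length(labels) || any(!nzchar(trimws(labels)))) {
    stop("labels must be nonempty strings", call. = FALSE)
  }
  low <- tolower(trimws(labels))
  low <- gsub("_", " ", low)
  syn <- alc_synonyms()
  canonical <- gsub("_", " ", alc_types())
  out <- vapply(low, function(x) {
    hit <- alc_types()[match(x, canonical)]
    if (!is.na(hit)) return(hit)
    for (cat in names(syn)) {
      if (any(vapply(syn[[cat]], grepl, TRUE, x = x, fixed = TRUE))) return(cat)
    }
    "unclassified"
  }, "", USE.NAMES = FALSE)
  if (any(out == "unclassified")) {
    warning("unclassified land-cover labels: ",
            paste(unique(labels[out == "unclassified"]), collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Resolve a set of reported activities to record activity labels
#'
#' A record reporting all three of traveling, resting and foraging - or
#' resting and foraging together, since both imply travel to reach the
#' site - is labelled `all`. Single activities keep their own label. Other
#' pairs (e.g. traveling + resting) are kept as the two separate labels,
#' and an empty report becomes `unreported`.
#'
#' @param acts character vector: the activities reported by one record (a
#'   subset of `traveling`, `resting`, `foraging`, or `all`; empty / NA for
#'   unreported).
#' @return character vector of one or more resolved labels.
#' @examples
#' normalize_activity(c("resting", "foraging")) # "all"
#' normalize_activity("traveling")
#' normalize_activity(character(0)) # "unreported"
#' @export
normalize_activity <- function(acts) {
  acts <- acts[!is.na(acts)]
  acts <- tolower(trimws(acts))
  acts <- acts[nzchar(acts) & acts != "unreported"]
  if (!length(acts)) return("unreported")
  if ("all" %in% acts) return("all")
  known <- c("traveling", "resting", "foraging")
  bad <- setdiff(acts, known)
  if (length(bad)) {
    stop("unknown activity labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  acts <- unique(acts)
  if (all(c("resting", "foraging") %in% acts)) return("all")
  sort(acts)
}

# Split a packed activity cell ("resting; foraging", "traveling+resting", ...)
#' @noRd
split_activities <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  strsplit(x, "[;,+/|]")[[1]]
}

#' Normalize a raw ALC-use record table
#'
#' Applies land-cover and activity normalization to every row and (optionally)
#' standardizes species names through a synonym map. Rows whose land cover
#' cannot be classified into the five categories are moved to an
#' `unclassified` report rather than dropped.
#'
#' @param db data frame with at least `study_id`, `species`, `alc_type`,
#'   `activity` columns (plus `family`, `realm`, `country` when available).
#' @param name_map optional synonym map for [standardize_names()].
#' @return list with `records` (clean rows; `activity` holds resolved labels
#'   collapsed with `+`), `unclassified` (rejected rows with their raw
#'   label), and `name_report` (the standardization report, or NULL).
#' @export
normalize_records <- function(db, name_map = NULL) {
  required <- c("study_id", "species", "alc_type", "activity")
  missing <- setdiff(required, names(db))
  if (length(missing)) {
    stop("records table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  name_report <- NULL
  std <- standardize_names(db$species, name_map)
  name_report <- std$report
  db$species <- std$report$accepted
  dropped <- is.na(db$species)
  db <- db[!dropped, , drop = FALSE]
  alc <- suppressWarnings(normalize_alc_type(db$alc_type))
  unclassified <- db[alc == "unclassified", , drop = FALSE]
  db <- db[alc != "unclassified", , drop = FALSE]
  db$alc_type <- alc[alc != "unclassified"]
  db$activity <- vapply(db$activity, function(a) {
    paste(normalize_activity(split_activities(a)), collapse = "+")
  }, "", USE.NAMES = FALSE)
  rownames(db) <- NULL
  list(records = db, unclassified = unclassified, name_report = name_report)
}

#' Collapse records to a species x ALC presence matrix
#'
#' One row per species with at least one record; for each of the five land
#' covers a logical presence flag (true iff at least one record exists for
#' that species x cover) and a resolved activity label: the union of the
#' record-level activity sets passed through [normalize_activity()], so
#' e.g. separate foraging and resting records resolve to `all`.
#'
#' @param records a normalized record table (see [normalize_records()]).
#' @return data frame with columns `species`, `family`, `realm`, one logical
#'   `<alc>` column and one character `<alc>_activity` column per land cover.
#' @export
build_presence_matrix <- function(records) {
  if (!nrow(records)) stop("record table is empty", call. = FALSE)
  bad <- setdiff(unique(records$alc_type), alc_types())
  if (length(bad)) {
    stop("unnormalized land-cover labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  species <- sort(unique(records$species))
  first <- records[!duplicated(records$species), , drop = FALSE]
  rownames(first) <- first$species
  pm <- data.frame(
    species = species,
    family = if (!is.null(records$family)) first[species, "family"] else NA_character_,
    realm = if (!is.null(records$realm)) first[species, "realm"] else NA_character_,
    stringsAsFactors = FALSE
  )
  for (alc in alc_types()) {
    sub <- records[records$alc_type == alc, , drop = FALSE]
    pm[[alc]] <- species %in% sub$species
    acts <- vapply(species, function(sp) {
      a <- sub$activity[sub$species == sp]
      if (!length(a)) return(NA_character_)
      paste(normalize_activity(unlist(lapply(a, split_activities))),
            collapse = "+")
    }, "", USE.NAMES = FALSE)
    pm[[paste0(alc, "_activity")]] <- acts
  }
  rownames(pm) <- NULL
  pm
}

#' @noRd
has_foraging <- function(activity) {
  !is.na(activity) & grepl("foraging|all", activity)
}

#' Tally the ALC-use database
#'
#' Produces the counting tables behind the headline results: unique species,
#' genera (lexical first token of the binomial), families, countries, studies
#' and records overall; species per land-cover type; per-realm user counts
#' (with world counts when a world table is supplied, the input to the realm
#' chi-square test); record-level activity counts per land cover; and the
#' number of species foraging (label `foraging` or `all`) in at least one
#' land cover, overall and per cover.
#'
#' @param presence species presence matrix from [build_presence_matrix()].
#' @param records the normalized record table (for record-level counts).
#' @param world optional world trait table with `species` and `realm`
#'   columns, used for expected realm frequencies.
#' @return a list of data frames: `summary`, `species_per_alc`, `realm`,
#'   `activity_records`, `foraging_per_alc`.
#' @export
tally <- function(presence, records = NULL, world = NULL) {
  if (!nrow(presence)) stop("presence matrix is empty", call. = FALSE)
  genus <- vapply(strsplit(presence$species, "[ _]"), `[[`, "", 1L)
  act_cols <- paste0(alc_types(), "_activity")
  any_foraging <- Reduce(`|`, lapply(act_cols, function(cl) has_foraging(presence[[cl]])))
  summary <- data.frame(
    n_species = nrow(presence),
    n_genera = length(unique(genus)),
    n_families = length(unique(stats::na.omit(presence$family))),
    n_records = if (!is.null(records)) nrow(records) else NA_integer_,
    n_studies = if (!is.null(records)) length(unique(records$study_id)) else NA_integer_,
    n_countries = if (!is.null(records)) length(unique(stats::na.omit(records$country))) else NA_integer_,
    n_foraging_species = sum(any_foraging)
  )
  species_per_alc <- data.frame(
    alc_type = alc_types(),
    n_species = vapply(alc_types(), function(a) sum(presence[[a]]), 0L)
  )
  foraging_per_alc <- data.frame(
    alc_type = alc_types(),
    n_foraging_species = vapply(act_cols, function(cl) sum(has_foraging(presence[[cl]])), 0L)
  )
  realm_tab <- NULL
  if (!all(is.na(presence$realm))) {
    realm_tab <- data.frame(
      realm = realms(),
      n_users = vapply(realms(), function(r) sum(presence$realm == r, na.rm = TRUE), 0L)
    )
    if (!is.null(world) && !is.null(world$realm)) {
      realm_tab$n_world <- vapply(realms(), function(r) sum(world$realm == r, na.rm = TRUE), 0L)
      realm_tab$world_prop <- realm_tab$n_world / sum(realm_tab$n_world)
    }
  }
  activity_records <- NULL
  if (!is.null(records)) {
    labels <- c("traveling", "resting", "foraging", "all", "unreported")
    activity_records <- do.call(rbind, lapply(alc_types(), function(a) {
      acts <- unlist(lapply(records$activity[records$alc_type == a], split_activities))
      if (!length(acts)) acts <- character(0)
      data.frame(alc_type = a, activity = labels,
                 n_records = vapply(labels, function(l) sum(acts == l), 0L))
    }))
    rownames(activity_records) <- NULL
  }
  list(summary = summary, species_per_alc = species_per_alc,
       realm = realm_tab, activity_records = activity_records,
       foraging_per_alc = foraging_per_alc)
}
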