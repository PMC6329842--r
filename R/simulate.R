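# Synthetic-data generators: every downstream stage (tallies, chi-square
# trait tests, D statistic, clade influence) can be run against data with a
# known ground truth. Defaults emulate the study conditions of the real
# database: 504 world primate species, 147 ALC users, ~468 use records.

#' Simulate a Yule (pure-birth) phylogeny
#'
#' Wraps [ape::rphylo()] with birth rate 1 and death rate 0, producing a
#' rooted, bifurcating, ultrametric tree with strictly positive branch
#' lengths and unique tip labels.
#'
#' @param n number of tips (at least 3).
#' @param seed optional integer seed for reproducibility.
#' @param labels optional character vector of `n` unique tip labels; the
#'   default is `sp001 ... spNNN`.
#' @return an [ape::phylo] object.
#' @export
simulate_yule_tree <- function(n, seed = NULL, labels = NULL) {
  if (n < 3L) stop("n must be at least 3", call. = FALSE)
  if (is.null(labels)) {
    labels <- sprintf("sp%03d", seq_len(n))
  }
  if (length(labels) != n || anyDuplicated(labels)) {
    stop("labels must be ", n, " unique tip names", call. = FALSE)
  }
  gen <- function() ape::rphylo(n, birth = 1, death = 0)
  tree <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  tree$tip.label <- labels
  tree
}

#' Simulate a binary trait under the Brownian-motion threshold model
#'
#' A continuous liability evolves from root to tips by Brownian motion
#' (independent increments with variance equal to branch length; rate fixed
#' at 1, which rank thresholding makes immaterial). The `k` tips with the
#' largest liabilities take state 1, so prevalence is exact. A signal knob
#' `f` then degrades the phylogenetic structure: a fraction `f` of tips,
#' chosen uniformly, have their states randomly permuted among themselves,
#' which preserves the count of ones exactly. `f = 0` gives a pure
#' threshold-BM trait (expected D near 0); `f = 1` re-shuffles every state
#' and the trait is independent of the tree (expected D near 1).
#'
#' @param tree an [ape::phylo] tree with positive branch lengths.
#' @param k number of state-1 tips (1 to n-1).
#' @param f fraction of tips whose states are re-randomized, in \[0, 1\].
#' @param seed optional integer seed.
#' @return integer 0/1 vector named by tip label, with exactly `k` ones.
#' @export
simulate_bm_threshold_trait <- function(tree, k, f = 0, seed = NULL) {
  assert_phylo(tree, require_lengths = TRUE)
  n <- length(tree$tip.label)
  if (k < 1L || k > n - 1L) {
    stop("prevalence k must satisfy 1 <= k <= n - 1", call. = FALSE)
  }
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  gen <- function() {
    states <- threshold_top_k(bm_tip_values(tree, 1L), k)[, 1L]
    m <- round(f * n)
    if (m >= 2L) {
      pick <- sample.int(n, m)
      states[pick] <- states[sample(pick)]
    }
    states
  }
  states <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  stats::setNames(as.integer(states), tree$tip.label)
}

#' Default effect specification for the synthetic world-trait generator
#'
#' World category frequencies chosen to resemble the global primate fauna
#' (about 55% of species threatened, mostly decreasing populations, mostly
#' diurnal, arboreal, forest-specialist species) with all enrichment
#' multipliers at 1 (the null). Supply `multipliers` entries to plant
#' effects, e.g. `list(iucn_category = c(LC = 2))`.
#'
#' @param multipliers named list: trait name -> named numeric vector of
#'   per-category enrichment multipliers (categories omitted default to 1).
#' @return a list keyed by trait, each element holding `freqs` (world
#'   category frequencies summing to 1) and `multipliers`.
#' @export
default_effect_spec <- function(multipliers = list()) {
  freqs <- list(
    realm = c(mainland_africa = 0.23, madagascar = 0.21, asia = 0.22,
              neotropics = 0.34),
    iucn_category = c(CR = 0.09, EN = 0.24, VU = 0.22, NT = 0.09, LC = 0.30,
                      DD = 0.05, NE = 0.01),
    population_trend = c(increasing = 0.02, stable = 0.12, decreasing = 0.74,
                         unknown = 0.12),
    diel_activity = c(diurnal = 0.55, nocturnal = 0.40, cathemeral = 0.05),
    locomotion = c(arboreal = 0.70, terrestrial = 0.05, both = 0.25),
    body_mass_class = c(small = 0.45, medium = 0.35, large = 0.20),
    trophic_guild = c(frugivorous = 0.35, folivorous = 0.15,
                      `folivorous-frugivorous` = 0.15, omnivorous = 0.20,
                      insectivorous = 0.08, gummivorous = 0.07),
    forest_specialist = c(yes = 0.70, no = 0.30)
  )
  spec <- lapply(names(freqs), function(tr) {
    mult <- stats::setNames(rep(1, length(freqs[[tr]])), names(freqs[[tr]]))
    if (!is.null(multipliers[[tr]])) {
      extra <- multipliers[[tr]]
      bad <- setdiff(names(extra), names(mult))
      if (length(bad)) {
        stop("unknown categories in multipliers for ", tr, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      if (any(extra < 0)) stop("multipliers must be >= 0", call. = FALSE)
      mult[names(extra)] <- extra
    }
    list(freqs = freqs[[tr]], multipliers = mult)
  })
  stats::setNames(spec, names(freqs))
}

#' @noRd
user_frequencies <- function(trait_spec) {
  w <- trait_spec$freqs * trait_spec$multipliers
  if (sum(w) <= 0) stop("impossible frequency spec: all mass removed", call. = FALSE)
  w / sum(w)
}

#' Simulate a world primate trait table with a flagged ALC-user subset
#'
#' Generates `n_world` species with categorical traits drawn independently at
#' the world frequencies of `spec`, grouped into synthetic genera and
#' families. A user subset of `n_users` species is sampled from the world
#' species list and its trait categories are drawn afresh from the
#' enrichment-renormalized frequencies, so planted effect sizes are exact:
#' for a trait with world frequencies p and multipliers m, the users follow
#' `p * m / sum(p * m)`. The true generating frequencies of both groups are
#' attached for type-I-error and power checks.
#'
#' @param spec an effect specification from [default_effect_spec()].
#' @param n_world number of world species (default 504).
#' @param n_users number of ALC-user species (default 147).
#' @param seed optional integer seed.
#' @param n_families,n_genera number of synthetic families and genera.
#' @return a list with `world` and `users` data frames (columns `species`,
#'   `genus`, `family` plus one column per trait; `users` also carries the
#'   `realm` drawn for each user), and `world_freqs` / `user_freqs`, the true
#'   per-trait generating frequencies.
#' @export
simulate_world_traits <- function(spec = default_effect_spec(), n_world = 504,
                                  n_users = 147, seed = NULL,
                                  n_families = 15, n_genera = 82) {
  if (n_users > n_world) stop("n_users cannot exceed n_world", call. = FALSE)
  gen <- function() {
    genera <- sprintf("Genus%02d", seq_len(n_genera))
    genus_family <- stats::setNames(
      sprintf("Family%02d", sort(sample.int(n_families, n_genera, replace = TRUE))),
      genera)
    sp_genus <- sort(sample(genera, n_world, replace = TRUE))
    species <- stats::ave(sp_genus, sp_genus, FUN = function(g) {
      sprintf("%s sp%02d", g, seq_along(g))
    })
    world <- data.frame(
      species = species,
      genus = sp_genus,
      family = unname(genus_family[sp_genus]),
      stringsAsFactors = FALSE
    )
    for (tr in names(spec)) {
      p <- spec[[tr]]$freqs
      world[[tr]] <- sample(names(p), n_world, replace = TRUE, prob = p)
    }
    pick <- sample.int(n_world, n_users)
    users <- world[pick, c("species", "genus", "family")]
    rownames(users) <- NULL
    for (tr in names(spec)) {
      q <- user_frequencies(spec[[tr]])
      users[[tr]] <- sample(names(q), n_users, replace = TRUE, prob = q)
    }
    list(world = world, users = users)
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out$world_freqs <- lapply(spec, `[[`, "freqs")
  out$user_freqs <- lapply(spec, user_frequencies)
  out
}

#' @noRd
default_country_pool <- function() {
  list(
    mainland_africa = sprintf("AfricanCountry%02d", 1:17),
    madagascar = "Madagascar",
    asia = sprintf("AsianCountry%02d", 1:13),
    neotropics = sprintf("NeotropicalCountry%02d", 1:13)
  )
}

#' Simulate an ALC-use record database
#'
#' Builds a study x species x land-cover record table for a set of ALC-using
#' species. Every species receives at least one record; additional records
#' per species are Poisson so that the mean matches `mean_records` (the
#' default 468/147 reproduces the real database's records-per-species rate).
#' Land-cover types and record activities are drawn from configurable
#' distributions; realm and country are assigned once per species so all of
#' a species' records are geographically consistent.
#'
#' @param users character vector of species names, or a data frame with a
#'   `species` column (and optionally `family`, `realm`).
#' @param seed optional integer seed.
#' @param mean_records mean number of records per species (>= 1).
#' @param alc_probs named probabilities over the five land-cover types.
#' @param activity_probs named probabilities over record activity labels
#'   (`traveling`, `resting`, `foraging`, `all`, `unreported`).
#' @param records_per_study mean number of records contributed by one study.
#' @return a data frame with columns `study_id`, `species`, `family`,
#'   `realm`, `country`, `latitude`, `longitude`, `alc_type`, `activity`.
#' @export
simulate_records_db <- function(users, seed = NULL, mean_records = 468 / 147,
                                alc_probs = c(human_settlements = 0.12,
                                              open_areas = 0.20,
                                              tree_plantations = 0.22,
                                              connectors = 0.16,
                                              secondary_forests = 0.30),
                                activity_probs = c(traveling = 0.25,
                                                   resting = 0.10,
                                                   foraging = 0.30,
                                                   all = 0.20,
                                                   unreported = 0.15),
                                records_per_study = 1.8) {
  if (is.character(users)) {
    users <- data.frame(species = users, stringsAsFactors = FALSE)
  }
  if (!nrow(users)) stop("users must be nonempty", call. = FALSE)
  if (mean_records < 1) stop("mean_records must be >= 1", call. = FALSE)
  stopifnot(setequal(names(alc_probs), alc_types()))
  pool <- default_country_pool()
  lat_range <- list(mainland_africa = c(-25, 15), madagascar = c(-25, -12),
                    asia = c(-8, 30), neotropics = c(-25, 20))
  gen <- function() {
    n_sp <- nrow(users)
    fam <- if (!is.null(users$family)) users$family else
      paste0("Family_", substr(users$species, 1, 7))
    realm <- if (!is.null(users$realm)) users$realm else
      sample(names(pool), n_sp, replace = TRUE,
             prob = c(0.23, 0.21, 0.22, 0.34))
    country <- vapply(realm, function(r) sample(pool[[r]], 1L), "")
    n_rec <- 1L + stats::rpois(n_sp, mean_records - 1)
    i <- rep(seq_len(n_sp), n_rec)
    total <- length(i)
    n_studies <- max(1L, round(total / records_per_study))
    data.frame(
      study_id = sprintf("S%03d", sample.int(n_studies, total, replace = TRUE)),
      species = users$species[i],
      family = fam[i],
      realm = realm[i],
      country = country[i],
      latitude = round(stats::runif(total,
                                    vapply(realm[i], function(r) lat_range[[r]][1], 0),
                                    vapply(realm[i], function(r) lat_range[[r]][2], 0)), 3),
      longitude = round(stats::runif(total, -80, 140), 3),
      alc_type = sample(names(alc_probs), total, replace = TRUE, prob = alc_probs),
      activity = sample(names(activity_probs), total, replace = TRUE,
                        prob = activity_probs),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Plant a phylogenetically clustered block of non-users
#'
#' Forces all tips of one clade of size `m` to state 0 (non-use) and
#' redistributes the displaced state-1 assignments to random tips outside
#' the clade, preserving overall prevalence. Used to build ground truth for
#' the clade-removal influence analysis: the planted clade's uniform
#' non-use is exactly the situation where removing the clade should shift
#' the D estimate more than removing the same number of random species.
#'
#' @param tree an [ape::phylo] tree.
#' @param trait named 0/1 trait vector over the tips.
#' @param m clade size; `m = 0` returns the trait unchanged.
#' @param seed optional integer seed (controls clade choice among candidates
#'   and the redistribution of displaced ones).
#' @return a list with `trait` (modified vector), `clade_tips` (labels),
#'   and `node` (the clade's internal node id; `NA` when `m = 0`).
#' @export
plant_influential_clade <- function(tree, trait, m, seed = NULL) {
  assert_phylo(tree)
  trait <- align_trait(tree, trait)
  if (m == 0L) {
    return(list(trait = trait, clade_tips = character(0), node = NA_integer_))
  }
  n <- length(tree$tip.label)
  counts <- clade_tip_counts(tree)
  candidates <- which(counts == m)
  if (!length(candidates)) {
    stop("no clade of exactly ", m, " tips in this tree", call. = FALSE)
  }
  gen <- function() {
    node <- candidates[sample.int(length(candidates), 1L)] + n
    tips <- tree$tip.label[tips_under(tree, node)]
    displaced <- sum(trait[tips])
    new_trait <- trait
    new_trait[tips] <- 0L
    outside_zero <- names(new_trait)[new_trait == 0L & !(names(new_trait) %in% tips)]
    if (length(outside_zero) < displaced) {
      stop("cannot preserve prevalence: too few non-user tips outside the clade",
           call. = FALSE)
    }
    new_trait[sample(outside_zero, displaced)] <- 1L
    list(trait = new_trait, clade_tips = tips, node = node)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Number of descendant tips of each internal node (index 1 = root node n+1).
#' @noRd
clade_tip_counts <- function(tree) {
  idx <- tree_index(tree)
  n_tip <- idx$n_tip
  counts <- c(rep(1L, n_tip), rep(0L, max(idx$edge) - n_tip))
  for (i in seq_along(idx$parents)) {
    counts[idx$parents[i]] <- sum(counts[idx$children[[i]]])
  }
  counts[-seq_len(n_tip)]
}

# Tip ids (1..n) descending from internal node id `node`.
#' @noRd
tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    kids <- edge[edge[, 1L] %in% todo, 2L]
    tips <- c(tips, kids[kids <= n_tip])
    todo <- kids[kids > n_tip]
  }
  sort(tips)
}
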