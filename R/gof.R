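# Goodness-of-fit comparisons: do species recorded using anthropic land
# covers differ, trait by trait, from the expectation set by all the
# world's primates?

#' Classify body mass into small / medium / large
#'
#' Small < 2 kg, medium 2-10 kg (closed interval), large > 10 kg.
#'
#' @param mass_kg numeric body mass in kilograms (> 0; NA passes through).
#' @return character vector of classes.
#' @examples
#' classify_body_mass(c(1.5, 2, 10, 12)) # small medium medium large
#' @export
classify_body_mass <- function(mass_kg) {
  if (any(mass_kg <= 0, na.rm = TRUE)) {
    stop("body mass must be positive", call. = FALSE)
  }
  out <- rep(NA_character_, length(mass_kg))
  out[!is.na(mass_kg) & mass_kg < 2] <- "small"
  out[!is.na(mass_kg) & mass_kg >= 2 & mass_kg <= 10] <- "medium"
  out[!is.na(mass_kg) & mass_kg > 10] <- "large"
  out
}

#' Classify diet composition into one of six trophic guilds
#'
#' Frugivorous (> 60% fruit), folivorous (> 60% leaves),
#' folivorous-frugivorous (fruit and leaves jointly a majority, neither
#' above 60%, and within 15 percentage points of each other), omnivorous
#' (both plant and animal matter substantial), insectivorous (diet dominated
#' by arthropods), gummivorous (dominated by plant exudates).
#'
#' @param fruit,leaves,animal,exudate,other diet fractions in \[0, 1\]
#'   (vectors recycle; fractions for one species may sum to less than 1 when
#'   minor items are unrecorded, but never to more than 1 + `tol`).
#' @param tol tolerance on the sum-to-one check (default 0.01).
#' @return character vector of guild labels.
#' @examples
#' classify_trophic_guild(fruit = 0.7, leaves = 0.2, animal = 0.1)
#' classify_trophic_guild(fruit = 0.45, leaves = 0.45, animal = 0.1)
#' @export
classify_trophic_guild <- function(fruit = 0, leaves = 0, animal = 0,
                                   exudate = 0, other = 0, tol = 0.01) {
  d <- cbind(fruit = fruit, leaves = leaves, animal = animal,
             exudate = exudate, other = other)
  if (any(d < 0 | d > 1, na.rm = TRUE)) {
    stop("diet fractions must lie in [0, 1]", call. = FALSE)
  }
  sums <- rowSums(d)
  if (any(sums > 1 + tol, na.rm = TRUE)) {
    stop("diet fractions sum to more than 1", call. = FALSE)
  }
  apply(d, 1L, function(x) {
    if (anyNA(x)) return(NA_character_)
    fr <- x["fruit"]; le <- x["leaves"]; an <- x["animal"]; ex <- x["exudate"]
    plant <- fr + le + ex + x["other"]
    if (fr > 0.6) return("frugivorous")
    if (le > 0.6) return("folivorous")
    if (fr + le > 0.5 && abs(fr - le) <= 0.15 && fr > 0 && le > 0 &&
        an < 0.25 && ex < 0.25) {
      return("folivorous-frugivorous")
    }
    if (ex >= max(x)) return("gummivorous")
    if (an >= max(x)) {
      if (plant < 0.3) return("insectivorous") else return("omnivorous")
    }
    if (an >= 0.25 && plant >= 0.25) return("omnivorous")
    # residual mixed diets: dominated by whichever single item is largest
    switch(names(which.max(x)),
           fruit = "frugivorous", leaves = "folivorous",
           exudate = "gummivorous", animal = "insectivorous",
           "omnivorous")
  })
}

#' Pearson chi-square goodness-of-fit test
#'
#' Compares observed category counts against expected counts derived from
#' stated baseline proportions: \eqn{E_i = p_i \sum O_i},
#' \eqn{\chi^2 = \sum (O_i - E_i)^2 / E_i}, with df = (number of
#' categories - 1) and an upper-tail asymptotic p-value. No continuity
#' correction is applied. When any expected count falls below 5 the result
#' carries a `small_expected` flag, and a Monte-Carlo p-value (resampling
#' multinomial draws from the baseline) can be requested instead of the
#' asymptotic one.
#'
#' @param observed named (or ordered) integer vector of category counts.
#' @param expected_props baseline proportions, same categories, summing to 1.
#' @param monte_carlo if TRUE, replace the asymptotic p-value with a
#'   Monte-Carlo one (via [stats::chisq.test()] resampling).
#' @param mc_reps Monte-Carlo replicates (default 2000).
#' @return an object of class `alc_gof`: list with `observed`, `expected`,
#'   `chisq`, `df`, `p`, `small_expected`, `method`.
#' @examples
#' gof_chi_square(c(10, 20), c(0.5, 0.5)) # chisq 3.33, p ~ 0.068
#' @export
gof_chi_square <- function(observed, expected_props, monte_carlo = FALSE,
                           mc_reps = 2000) {
  if (length(observed) < 2L) stop("need at least 2 categories", call. = FALSE)
  if (length(observed) != length(expected_props)) {
    stop("observed and expected_props must align", call. = FALSE)
  }
  if (abs(sum(expected_props) - 1) > 1e-6) {
    stop("expected proportions must sum to 1", call. = FALSE)
  }
  if (sum(observed) < 1) stop("no observations", call. = FALSE)
  zero_p <- expected_props == 0
  if (any(zero_p & observed > 0)) {
    stop("category with expected proportion 0 but observed count > 0: ",
         paste(names(observed)[zero_p & observed > 0], collapse = ", "),
         call. = FALSE)
  }
  if (any(zero_p)) { # zero-mass, zero-count categories carry no information
    observed <- observed[!zero_p]
    expected_props <- expected_props[!zero_p]
  }
  n <- sum(observed)
  expected <- expected_props * n
  chisq <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  if (monte_carlo) {
    p <- suppressWarnings(
      stats::chisq.test(observed, p = expected_props,
                        simulate.p.value = TRUE, B = mc_reps)$p.value)
    method <- "monte_carlo"
  } else {
    p <- stats::pchisq(chisq, df, lower.tail = FALSE)
    method <- "asymptotic"
  }
  structure(list(observed = observed, expected = expected, chisq = chisq,
                 df = df, p = p, small_expected = any(expected < 5),
                 method = method),
            class = "alc_gof")
}

#' @export
print.alc_gof <- function(x, ...) {
  cat(sprintf("chi-square goodness of fit: X2 = %.4f, df = %d, p = %.4g%s\n",
              x$chisq, x$df, x$p,
              if (x$small_expected) "  [some expected counts < 5]" else ""))
  invisible(x)
}

#' @noRd
trait_exclusions <- function(trait, values) {
  drop <- is.na(values) | values == ""
  reason <- rep(NA_character_, length(values))
  reason[drop] <- "missing trait"
  if (trait == "iucn_category") {
    dd <- values %in% c("DD", "NE")
    drop <- drop | dd
    reason[dd] <- "DD/NE"
  }
  if (trait == "population_trend") {
    un <- values %in% "unknown"
    drop <- drop | un
    reason[un] <- "unknown trend"
  }
  list(drop = drop, reason = reason)
}

#' Compare ALC-user trait frequencies against the world baseline
#'
#' Runs the goodness-of-fit chi-square for one categorical trait, for the
#' overall user set and (when a presence matrix is supplied) separately for
#' the users of each of the five land covers. Exclusions are applied
#' identically to users and baseline before anything is counted: species
#' missing the trait are excluded; Data Deficient / Not Evaluated species
#' are excluded from threat-category tests; species with unknown trends are
#' excluded from population-trend tests. The baseline may be the world trait
#' table (proportions computed after the same exclusions) or, e.g. in
#' simulations where the truth is known, a named vector of population
#' proportions.
#'
#' @param users data frame of ALC-using species (needs `species` and the
#'   trait column).
#' @param world the world trait table, or a named numeric vector of
#'   baseline proportions for the trait's categories.
#' @param trait name of the trait column to compare.
#' @param presence optional presence matrix from [build_presence_matrix()];
#'   adds one test per land cover.
#' @param monte_carlo,mc_reps passed to [gof_chi_square()].
#' @param holm if TRUE, append Holm-adjusted p-values across the returned
#'   rows (off by default; the raw p-values are always reported).
#' @return data frame with one row per subset: `trait`, `subset`, `n`,
#'   `n_excluded`, `categories`, `observed`, `expected` (both collapsed as
#'   `label=value` strings), `chisq`, `df`, `p`, `small_expected`, and
#'   optionally `p_holm`.
#' @export
compare_users_vs_world <- function(users, world, trait, presence = NULL,
                                   monte_carlo = FALSE, mc_reps = 2000,
                                   holm = FALSE) {
  if (!trait %in% names(users)) {
    stop("trait '", trait, "' not found in the user table", call. = FALSE)
  }
  if (is.data.frame(world)) {
    if (!trait %in% names(world)) {
      stop("trait '", trait, "' not found in the world table", call. = FALSE)
    }
    excl_w <- trait_exclusions(trait, world[[trait]])
    w_vals <- world[[trait]][!excl_w$drop]
    if (!length(w_vals)) stop("world table empty after exclusions", call. = FALSE)
    props <- table(w_vals)
    props <- stats::setNames(as.numeric(props) / sum(props), names(props))
  } else {
    if (is.null(names(world)) || abs(sum(world) - 1) > 1e-6) {
      stop("baseline proportions must be named and sum to 1", call. = FALSE)
    }
    props <- world
  }
  subsets <- list(overall = users)
  if (!is.null(presence)) {
    for (alc in alc_types()) {
      sp <- presence$species[presence[[alc]]]
      subsets[[alc]] <- users[users$species %in% sp, , drop = FALSE]
    }
  }
  rows <- lapply(names(subsets), function(nm) {
    sub <- subsets[[nm]]
    excl <- trait_exclusions(trait, sub[[trait]])
    vals <- sub[[trait]][!excl$drop]
    if (!length(vals)) {
      stop("subset '", nm, "' empty after exclusions for trait '", trait, "'",
           call. = FALSE)
    }
    unknown <- setdiff(unique(vals), names(props))
    if (length(unknown)) {
      stop("user categories absent from the baseline: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    obs <- vapply(names(props), function(cat) sum(vals == cat), 0L)
    fit <- gof_chi_square(obs, props, monte_carlo = monte_carlo, mc_reps = mc_reps)
    data.frame(
      trait = trait, subset = nm, n = length(vals),
      n_excluded = sum(excl$drop),
      categories = paste(names(props), collapse = ";"),
      observed = paste(sprintf("%s=%d", names(props), obs), collapse = ";"),
      expected = paste(sprintf("%s=%.2f", names(props), fit$expected), collapse = ";"),
      chisq = fit$chisq, df = fit$df, p = fit$p,
      small_expected = fit$small_expected,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}
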