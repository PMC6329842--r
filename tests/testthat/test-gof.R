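test_that("body-mass classes follow the 2 and 10 kg cut points", {
  expect_equal(classify_body_mass(c(1.5, 2, 9.99, 10, 12)),
               c("small", "medium", "medium", "medium", "large"))
  expect_true(is.na(classify_body_mass(NA)))
  expect_error(classify_body_mass(0), "positive")
  expect_error(classify_body_mass(-3), "positive")
})

test_that("trophic guilds follow the diet-dominance rules", {
  expect_equal(classify_trophic_guild(fruit = 0.7, leaves = 0.2, animal = 0.1),
               "frugivorous")
  expect_equal(classify_trophic_guild(fruit = 0.2, leaves = 0.65, animal = 0.1),
               "folivorous")
  expect_equal(classify_trophic_guild(fruit = 0.45, leaves = 0.45, animal = 0.1),
               "folivorous-frugivorous")
  expect_equal(classify_trophic_guild(animal = 0.8, fruit = 0.1, other = 0.1),
               "insectivorous")
  expect_equal(classify_trophic_guild(animal = 0.4, fruit = 0.3, leaves = 0.3),
               "omnivorous")
  expect_equal(classify_trophic_guild(exudate = 0.6, animal = 0.2, fruit = 0.2),
               "gummivorous")
  expect_error(classify_trophic_guild(fruit = 0.8, leaves = 0.4), "sum")
  expect_error(classify_trophic_guild(fruit = -0.1), "\\[0, 1\\]")
})

test_that("chi-square matches the Pearson formula and flags small cells", {
  fit <- gof_chi_square(c(15, 15), c(0.5, 0.5))
  expect_equal(fit$chisq, 0)
  expect_equal(fit$p, 1)

  fit <- gof_chi_square(c(10, 20), c(0.5, 0.5))
  expect_equal(fit$chisq, 10 / 3, tolerance = 1e-10)
  expect_equal(fit$df, 1L)
  expect_equal(fit$p, 0.06788915, tolerance = 1e-6)
  expect_false(fit$small_expected)

  fit <- gof_chi_square(c(5, 0), c(0.5, 0.5))
  expect_equal(fit$chisq, 5)
  expect_true(fit$small_expected)

  expect_error(gof_chi_square(c(5), c(1)), "2 categories")
  expect_error(gof_chi_square(c(5, 5), c(0.7, 0.7)), "sum to 1")
  expect_error(gof_chi_square(c(5, 5, 1), c(0.5, 0.5, 0)), "expected proportion 0")
  # chi-square is invariant to category order
  o <- c(a = 4, b = 9, c = 17); p <- c(a = 0.2, b = 0.3, c = 0.5)
  i <- c(3, 1, 2)
  expect_equal(gof_chi_square(o, p)$chisq, gof_chi_square(o[i], p[i])$chisq)
  # Monte-Carlo option returns a valid p
  mc <- withr::with_seed(1, gof_chi_square(c(5, 0), c(0.5, 0.5),
                                           monte_carlo = TRUE, mc_reps = 999))
  expect_true(mc$p > 0 && mc$p <= 1)
  expect_equal(mc$method, "monte_carlo")
})

test_that("self-comparison of a population with itself gives chi-square 0", {
  world <- simulate_world_traits(n_world = 300, n_users = 30, seed = 21)$world
  res <- compare_users_vs_world(world, world, "diel_activity")
  expect_equal(res$chisq, 0, tolerance = 1e-10)
  expect_equal(res$p, 1)
})

test_that("exclusions are applied to users and baseline alike", {
  users <- data.frame(
    species = sprintf("u%d", 1:8),
    iucn_category = c("LC", "LC", "EN", "DD", "NE", "VU", "CR", NA),
    population_trend = c("stable", "unknown", rep("decreasing", 6)),
    stringsAsFactors = FALSE)
  world <- data.frame(
    species = sprintf("w%d", 1:40),
    iucn_category = rep(c("LC", "EN", "VU", "CR", "DD"), 8),
    population_trend = rep(c("stable", "decreasing", "unknown", "increasing"), 10),
    stringsAsFactors = FALSE)
  res <- compare_users_vs_world(users, world, "iucn_category")
  expect_equal(res$n, 5L) # DD, NE and NA users excluded
  expect_equal(res$n_excluded, 3L)
  expect_equal(res$n + res$n_excluded, nrow(users))
  expect_false(grepl("DD", res$categories)) # world baseline excludes DD too
  res2 <- compare_users_vs_world(users, world, "population_trend")
  expect_equal(res2$n, 7L)

  expect_error(compare_users_vs_world(users, world, "locomotion"), "locomotion")
})

test_that("per-ALC subsets and Holm adjustment are reported", {
  sim <- simulate_world_traits(n_world = 250, n_users = 60, seed = 22)
  db <- simulate_records_db(sim$users, seed = 23)
  pm <- build_presence_matrix(db)
  res <- compare_users_vs_world(sim$users, sim$world, "locomotion",
                                presence = pm, holm = TRUE)
  expect_equal(res$subset, c("overall", alc_types()))
  expect_true(all(res$p_holm >= res$p))
  expect_true(all(res$df == 2L))
})

test_that("baseline can be a vector of true population proportions", {
  users <- data.frame(species = c("a", "b", "c"),
                      forest_specialist = c("yes", "yes", "no"))
  res <- compare_users_vs_world(users, c(yes = 0.7, no = 0.3),
                                "forest_specialist")
  expect_equal(res$chisq, (2 - 2.1)^2 / 2.1 + (1 - 0.9)^2 / 0.9)
  expect_error(compare_users_vs_world(users, c(0.7, 0.3), "forest_specialist"),
               "named")
})

test_that("null p-values are uniform (KS) under the null effect spec", {
  # users drawn at the true world frequencies, tested against those truths
  spec <- default_effect_spec()
  p_true <- spec$locomotion$freqs
  pvals <- withr::with_seed(77, replicate(2000, {
    users <- data.frame(species = sprintf("u%d", 1:150),
                        locomotion = sample(names(p_true), 150, TRUE, p_true))
    compare_users_vs_world(users, p_true, "locomotion")$p
  }))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
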