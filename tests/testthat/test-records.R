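test_that("raw land-cover labels map onto the five categories", {
  expect_equal(normalize_alc_type("cattle pasture"), "open_areas")
  expect_equal(normalize_alc_type("live fence"), "connectors")
  expect_equal(normalize_alc_type("Second growth"), "secondary_forests")
  expect_equal(normalize_alc_type("village"), "human_settlements")
  expect_equal(normalize_alc_type("shade coffee"), "tree_plantations")
  expect_equal(normalize_alc_type("secondary_forests"), "secondary_forests")
  expect_warning(out <- normalize_alc_type("mangrove"), "mangrove")
  expect_equal(out, "unclassified")
  expect_error(normalize_alc_type(""), "nonempty")
})

test_that("activity sets resolve by the all-activities rule", {
  expect_equal(normalize_activity(c("resting", "foraging")), "all")
  expect_equal(normalize_activity(c("traveling", "resting", "foraging")), "all")
  expect_equal(normalize_activity("traveling"), "traveling")
  expect_equal(normalize_activity(c("traveling", "resting")),
               c("resting", "traveling")) # pair kept, never promoted to all
  expect_equal(normalize_activity(character(0)), "unreported")
  expect_equal(normalize_activity(NA_character_), "unreported")
  expect_equal(normalize_activity("all"), "all")
  expect_error(normalize_activity("sleeping"), "unknown activity")
})

test_that("presence matrix deduplicates and unions activities", {
  db <- toy_records()
  norm <- normalize_records(db)
  expect_equal(nrow(norm$records), nrow(db))
  pm <- build_presence_matrix(norm$records)
  expect_equal(nrow(pm), 4L) # 7 records, 4 species
  ap <- pm[pm$species == "Alouatta palliata", ]
  expect_true(ap$secondary_forests && ap$human_settlements)
  expect_false(ap$open_areas)
  # separate foraging and resting records union to "all"
  expect_equal(ap$secondary_forests_activity, "all")
  cc <- pm[pm$species == "Cebus capucinus", ]
  expect_equal(cc$connectors_activity, "all")
  ag <- pm[pm$species == "Ateles geoffroyi", ]
  expect_equal(ag$tree_plantations_activity, "unreported")
})

test_that("tallies count species, genera, records and foraging correctly", {
  norm <- normalize_records(toy_records())
  pm <- build_presence_matrix(norm$records)
  tl <- tally(pm, norm$records)
  expect_equal(tl$summary$n_species, 4L)
  expect_equal(tl$summary$n_genera, 3L) # Alouatta, Cebus, Ateles
  expect_equal(tl$summary$n_families, 2L)
  expect_equal(tl$summary$n_records, 7L)
  expect_equal(tl$summary$n_countries, 4L)
  # foragers: A. palliata (all in HS + foraging in SF), C. capucinus (all)
  expect_equal(tl$summary$n_foraging_species, 2L)
  spa <- setNames(tl$species_per_alc$n_species, tl$species_per_alc$alc_type)
  expect_equal(unname(spa["secondary_forests"]), 1L)
  expect_equal(unname(spa["connectors"]), 1L)
  # record-level activity counts (Fig. 2 analogue)
  ar <- tl$activity_records
  expect_equal(ar$n_records[ar$alc_type == "secondary_forests" &
                              ar$activity == "foraging"], 1L)
  expect_equal(sum(ar$n_records), 7L)
})

test_that("tallies are invariant to record order and duplication", {
  norm <- normalize_records(toy_records())
  pm1 <- build_presence_matrix(norm$records)
  shuffled <- norm$records[rev(seq_len(nrow(norm$records))), ]
  pm2 <- build_presence_matrix(shuffled)
  expect_equal(pm1, pm2)
  doubled <- rbind(norm$records, norm$records)
  pm3 <- build_presence_matrix(doubled)
  expect_equal(pm1[order(pm1$species), names(pm1)],
               pm3[order(pm3$species), names(pm1)])
  # species-per-ALC sums can exceed the species total; genera <= species
  tl <- tally(pm1, norm$records)
  expect_gte(sum(tl$species_per_alc$n_species), tl$summary$n_species)
  expect_lte(tl$summary$n_genera, tl$summary$n_species)
  expect_lte(tl$summary$n_families, tl$summary$n_genera)
})

test_that("unclassified covers are reported, never silently dropped", {
  db <- toy_records()
  db$alc_type[3] <- "mangrove"
  norm <- suppressWarnings(normalize_records(db))
  expect_equal(nrow(norm$unclassified), 1L)
  expect_equal(norm$unclassified$alc_type, "mangrove")
  expect_equal(nrow(norm$records) + nrow(norm$unclassified), nrow(db))
})

test_that("realm tallies carry world baseline counts", {
  norm <- normalize_records(toy_records())
  pm <- build_presence_matrix(norm$records)
  world <- data.frame(species = sprintf("w%d", 1:10),
                      realm = rep(realms(), c(4, 2, 2, 2)))
  tl <- tally(pm, norm$records, world)
  expect_equal(tl$realm$n_users[tl$realm$realm == "neotropics"], 4L)
  expect_equal(sum(tl$realm$n_world), 10L)
  expect_equal(sum(tl$realm$world_prop), 1)
})
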