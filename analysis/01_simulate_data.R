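#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system.
#
# Emulates the scale of the real analysis: 504 world primate species with
# categorical conservation and ecological traits, 147 of them recorded using
# anthropic land covers (~468 literature records), and a dated phylogeny of
# 352 species carrying the binary use/non-use trait. All later stages read
# the files written here.

suppressMessages(library(alcuse))
seed <- 20260927
dir.create("results/analysis/data", recursive = TRUE, showWarnings = FALSE)

sim <- simulate_world_traits(seed = seed)
db <- simulate_records_db(sim$users, seed = seed + 1)

# phylogeny over 352 of the 504 species (all users kept when possible)
tips <- withr::with_seed(seed + 2, {
  extra <- setdiff(sim$world$species, sim$users$species)
  sort(c(sim$users$species, sample(extra, 352 - nrow(sim$users))))
})
tree <- simulate_yule_tree(length(tips), seed = seed + 3, labels = tips)

write.csv(sim$world, "results/analysis/data/world_traits.csv", row.names = FALSE)
write.csv(sim$users, "results/analysis/data/alc_users.csv", row.names = FALSE)
write.csv(db, "results/analysis/data/alc_records.csv", row.names = FALSE)
write_newick(tree, "results/analysis/data/timetree.nwk")

cat(sprintf("world species: %d   ALC users: %d   records: %d   tree tips: %d\n",
            nrow(sim$world), nrow(sim$users), nrow(db), length(tree$tip.label)))
cat(sprintf("users on the tree: %d (prevalence %.2f)\n",
            sum(tips %in% sim$users$species),
            mean(tips %in% sim$users$species)))
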