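#!/usr/bin/env Rscript
# Stage 2: normalize the record database and count everything.
#
# Species- and record-level tallies: how many species use each land-cover
# type, in which realms, and for what activities; how many forage in at
# least one anthropic cover.

suppressMessages(library(alcuse))
dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)

raw <- read_table_auto("results/analysis/data/alc_records.csv")
world <- read_table_auto("results/analysis/data/world_traits.csv")
norm <- normalize_records(raw)
pm <- build_presence_matrix(norm$records)
tl <- tally(pm, norm$records, world)

for (nm in names(tl)) {
  if (!is.null(tl[[nm]])) {
    utils::write.table(tl[[nm]], sprintf("results/analysis/tally_%s.tsv", nm),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
}

s <- tl$summary
cat(sprintf("species using ALCs: %d (%d genera, %d families, %d countries)\n",
            s$n_species, s$n_genera, s$n_families, s$n_countries))
cat(sprintf("records: %d from %d studies\n", s$n_records, s$n_studies))
spa <- setNames(tl$species_per_alc$n_species, tl$species_per_alc$alc_type)
cat(sprintf("most-used cover: %s (%d species); least-used: %s (%d species)\n",
            names(which.max(spa)), max(spa), names(which.min(spa)), min(spa)))
cat(sprintf("species foraging in at least one ALC: %d\n", s$n_foraging_species))
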