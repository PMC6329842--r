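Package: alcuse
Title: Primate Use of Anthropic Land Covers: Tallies, Trait Tests and
    Phylogenetic Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a global analysis of primate use of anthropic land
    covers (ALCs): normalization and tallying of literature-derived ALC-use
    records, chi-square goodness-of-fit comparisons of ALC-user traits
    against the world-primate baseline, the D statistic for phylogenetic
    signal in binary traits with tip-shuffle and Brownian-threshold
    randomization nulls, and a clade-removal influence analysis with a
    size-matched random-removal null. Includes a synthetic-data module
    (Yule trees, threshold Brownian-motion binary traits with a tunable
    signal knob, trait tables and record databases with planted effect
    sizes) so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
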