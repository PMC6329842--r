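---
title: "Methods: primate use of anthropic land covers and its phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: primate use of anthropic land covers and its phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`alcuse` implements a global, record-based analysis of how nonhuman primates
use anthropic land covers (ALCs) — the human-created cover types that make up
the matrix around remnants of natural vegetation. The analysis has four
pillars: (1) normalization and tallying of a literature-derived record
database; (2) chi-square goodness-of-fit comparisons of the traits of
ALC-using species against the expectation set by all of the world's primates;
(3) a permutation-based D statistic for phylogenetic signal in the binary
use/non-use trait; and (4) a clade-removal influence analysis with a
size-matched randomization null. A synthetic-data module generates all three
input objects (record database, world trait table, dated phylogeny) with
known ground truth, so every stage is testable without external downloads.

## The record database and its normalization

The unit of observation is a record: one study reporting one species in one
ALC. Five cover categories are recognised — human settlements, open areas
(annual crops and cattle pastures), tree plantations (including
agroforestry), connectors (isolated trees and linear elements such as live
fences and hedgerows), and secondary forests. `normalize_alc_type()` maps
raw labels onto these through a keyword list; anything unmatched becomes an
explicit `unclassified` row in the normalization report — records are never
silently dropped, because the headline species counts depend on the
denominator.

Activities are resolved by an asymmetric rule: a record reporting all three
of traveling, resting and foraging — or resting *and* foraging, since both
imply travel to the site — is labelled `all`; single activities keep their
own label; the pair traveling + resting stays as two labels, because it does
not imply foraging; an empty report is `unreported`. At the species × cover
level the union of record activity sets is resolved by the same rule, so a
species with one foraging record and one resting record in secondary forest
counts as using it for all activities.

Species names are standardized before any counting: separators unified, a
user-supplied synonym map applied, and infraspecific names truncated to the
binomial unless that binomial is already present (then dropped, and listed
in the report). The synonym table of the original compilation is not
published, so the map is a file input; retained-tip counts therefore depend
on the map supplied.

Counting happens at two levels deliberately kept apart: species-level
presence (a species either uses a cover or not, however many records exist)
drives the per-cover species counts and the trait comparisons, while
record-level activity counts preserve the fact that studies, not species,
report activities. "Uses ALCs for foraging" is species-level: any record
with `foraging` or `all` in any cover. Genera are derived lexically from the
first token of the binomial, since a genus column cannot be assumed.

## Trait comparisons against the world baseline

For each categorical trait (IUCN threat category, population trend, diel
activity, locomotion, body-mass class, trophic guild, forest specialism) the
observed category counts among ALC users — overall and separately for the
users of each cover type — are compared with expected counts from the world
table by a Pearson goodness-of-fit chi-square with df = categories − 1 and
no continuity correction. Exclusions are applied identically on both sides
before anything is counted: species missing the trait; Data Deficient and
Not Evaluated species for threat-category tests; unknown trends for trend
tests. Using the same exclusions for the baseline is essential — otherwise
the two frequency vectors have different denominators and the test compares
artefacts.

Body mass is classed small (< 2 kg), medium (2–10 kg, both ends included),
large (> 10 kg). Trophic guilds follow diet dominance: frugivorous (> 60 %
fruit), folivorous (> 60 % leaves), folivorous–frugivorous when fruit and
leaves jointly exceed half the diet, neither passes 60 %, they are within 15
percentage points of each other and no other component is substantial
(≥ 25 %); gummivorous when exudates are the largest component; insectivorous
when animal matter dominates a diet with little plant material (< 30 %);
omnivorous when plant and animal fractions are both substantial. The 15-point
and 25 % thresholds operationalise "similar proportions" and "both in diet";
they are stated here because the verbal definitions underdetermine them.

Raw p-values are reported, as is conventional for these figure-level tests; a
Holm adjustment across the rows of one comparison table is available
(`holm = TRUE`) but off by default. When any expected count falls below 5 the
result carries a flag, and a Monte-Carlo p-value can be requested
(`monte_carlo = TRUE`); the default stays asymptotic to match standard
practice for these tests.

In simulations the baseline can be passed as a named vector of true
population proportions instead of a finite world table. This matters for
calibration checks: testing a 150-species subset against proportions
*estimated* from a 504-row table inflates the type-I error (the estimation
noise adds roughly n_users/n_world of spurious chi-square mass), while
subsampling users from the same finite table deflates it
hypergeometrically. Against the generator's recorded true frequencies the
test is calibrated; the test suite verifies a rejection rate in [0.04, 0.06]
at α = 0.05 over 2000 null subsets and uniformity of the null p-values.

## The D statistic

Phylogenetic signal in the binary use/non-use trait is measured by a
sum-of-changes statistic. Each internal node is assigned the unweighted
arithmetic mean of its children's values in a single leaf-to-root pass
(polytomies: mean over all children — handled natively, never randomly
resolved, so results are deterministic); Σd is the sum over all edges of the
absolute difference between parent and child values. A clumped trait
changes along few edges (small Σd); a scattered trait changes everywhere
(large Σd). The estimator uses topology only, so Σd is invariant to branch
length rescaling and to children order, and is symmetric under complementing
the trait.

Two null distributions bracket the observation. The shuffle null permutes
the observed states across tips (prevalence preserved exactly). The
Brownian-threshold null evolves a continuous liability by Brownian motion
along the branches (increment variance = branch length; the rate is fixed at
1 because rank thresholding makes the statistic rate-invariant) and assigns
state 1 to the k tips with the largest liabilities, k being the observed
prevalence. Rank thresholding rather than a fixed cut keeps prevalence
exact, matching the standard published formulation of this statistic. D then
rescales the observation between the two null means:

$$D = \frac{\Sigma d_{obs} - \overline{\Sigma d_b}}{\overline{\Sigma d_r} - \overline{\Sigma d_b}}$$

so D = 0 means "as clumped as Brownian inheritance of a liability" and D = 1
means "random with respect to the tree". Two one-sided randomization
p-values are reported with add-one correction, each oriented so that small
values are evidence *against* the respective set point: P(D = 0) counts
Brownian replicates at least as dispersed as the observation,
(1 + #{Σd_b ≥ Σd_obs})/(B + 1); P(D = 1) counts shuffle replicates at least
as clumped, (1 + #{Σd_r ≤ Σd_obs})/(B + 1). Neither can be exactly zero; the
default is B = 9999 permutations for headline estimates.

Two numerical choices deserve note. First, the nodal estimator weights
children equally rather than by branch length. Because the *same* estimator
is applied to the observation and to both nulls, the calibration of D is
preserved by construction: under threshold-BM data Σd_obs is itself a draw
from the Brownian null, so E[D] ≈ 0 for any internal estimator, and likewise
E[D] ≈ 1 under shuffled data. The exact weighting inside the originally
published function is not documented in the sources available here, so
equivalence is validated by those set points and by parameter recovery, not
claimed numerically. Second, the scaling denominator is guarded: when the
two null means differ by less than 10⁻¹⁰ × mean(Σd_r) — as on a pure star
tree, where every arrangement of k ones gives the identical Σd — the
function raises an explicit error instead of returning an unstable number.

The test suite verifies calibration by parameter recovery on 200-tip Yule
trees at prevalence 0.3 (B = 999, 20 replicates per condition): traits
generated under pure threshold-BM give mean D within [−0.25, 0.25], fully
shuffled traits within [0.75, 1.25], and mean D increases monotonically in
the generator's signal knob across five levels of 50 replicates each. These
sizes keep the default test run to minutes while leaving the Monte-Carlo
error well inside the asserted bands.

## Clade-removal influence

To ask which clades drive the signal estimate, every family with at least 10
species on the tree is removed in turn and D recomputed. The change
ΔD = D_without − D_full is compared against a null built by removing the
same number of *randomly chosen* species (uniformly, irrespective of family
membership) R times; the two-tailed add-one p-value counts null replicates
with |ΔD| at least as large as observed, ties counting as extreme
(conservative). Direction is still reported. Since the random-removal null
depends only on the number removed, null distributions are cached per
removal size within one scan — statistically identical to per-family nulls
and several-fold faster when family sizes repeat. Families whose removal
leaves a monomorphic trait (or fewer than 4 tips) are reported as
untestable, not as errors; random removals that do so are redrawn.

Defaults are R = 999 replicates with B = 999 inner permutations; the
packaged analysis scripts and the acceptance checks use R = 199, B = 199 for
the scan, sizes at which a planted fully-non-using clade of 30 tips on a
300-tip tree (prevalence 90/300, otherwise random trait) is flagged at
p ≤ 0.05 in the large majority of runs while the family-level false-flag
rate under fully random traits stays at the nominal 5 %. Results are
reproducible for a fixed seed and independent of family iteration order:
every family and every removal size gets its own RNG stream derived from the
seed and its name.

## The synthetic study system

The generator mirrors the real analysis' scale and structure without
claiming biological realism. `simulate_world_traits()` draws 504 species
with independent categorical traits at frequencies chosen to resemble the
global primate fauna (≈ 55 % threatened, ≈ 74 % with decreasing populations,
40 % nocturnal, 70 % arboreal, 70 % forest specialists, realms at roughly
their real share of species); 147 of them form the user subset, whose trait
categories are drawn from enrichment-renormalized frequencies
p·m / Σ(p·m) so planted effect sizes are exact and known.
`simulate_records_db()` gives every user at least one record, with
per-species record counts 1 + Poisson such that the mean matches the real
468/147 ≈ 3.2 records per species, covers and activities drawn from
configurable distributions, and one realm/country per species.
`simulate_yule_tree()` provides ultrametric pure-birth trees, and
`simulate_bm_threshold_trait()` plants a binary trait with tunable signal: a
threshold-BM trait whose states are then partially re-shuffled among a
uniformly chosen fraction f of tips. Shuffling *among the selected tips*
(rather than redrawing) keeps prevalence exact at every f, makes f = 1
coincide with the shuffle null, and spans expected D from ≈ 0 to ≈ 1
monotonically — which is why it was chosen over mixing BM rates.

What the generator does **not** emulate: correlation between ecological
traits (nocturnality and arboreality are independent here, unlike in real
primates), biogeographic structure of the phylogeny, uneven sampling effort
across realms, and any dependence of ALC use on the traits themselves unless
an enrichment is explicitly planted. Passing tests therefore demonstrate
that the machinery measures what it claims under known conditions, not that
the real data would yield any particular value. In particular, the headline
quantities of the original compilation (147 user species and the weak,
non-random signal of use) require the real supplementary database and the
published timetree as inputs; with those files the pipeline reproduces the
published workflow end to end, but they are external inputs, not shipped.

## Degenerate inputs and edge rules

Monomorphic traits are rejected wherever Σd is computed (the statistic is
undefined); star trees raise the degenerate-denominator error above; missing
branch lengths are an error for anything touching the Brownian null but fine
for pure tallies and for Σd itself; unmapped land covers and unknown
activity labels are surfaced, not guessed. Record tallies are invariant to
record order and duplication, which the suite property-tests.

## Reproducibility

Every stochastic function takes an explicit seed and restores the caller's
RNG state (`withr::with_seed`); the pipeline derives per-stage streams from
one configured seed, so a fixed configuration reproduces its output files
byte for byte. The numbered scripts under `analysis/` run the full synthetic
study (504 species, 352-tip tree, B = 9999 for the headline D, R = B = 199
for the influence scan) in a few minutes on one core.
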