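---
title: "Methods: lipidome signatures of mammalian maximal lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipidome signatures of mammalian maximal lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lifelipid` reimplements, end to end, an analysis linking mammalian maximal
lifespan (MLS) to tissue lipidome composition. This vignette is the
package's account of the underlying models and of the design decisions we
made where the procedure admitted more than one reasonable reading.

## The scientific question and the overall design

MLS is treated as a fixed species trait. Within each of three clades
(rodents, primates, bats) a species is called *long-living* when its MLS
strictly exceeds 0.9 × the highest MLS of the clade, which by construction
labels the clade maximum and any species close to it. The analysis then
asks three questions: (i) can a sparse classifier on lipid concentrations
identify the long-living species, and does the signal transfer across
clades; (ii) which lipid classes, sub-classes and pathways concentrate the
predictive lipids, and in which direction their concentrations shift;
(iii) do enzymes linked to the predictive lipids show stronger purifying
selection (lower dN/dS) on long-living lineages.

Because the original measurements are not deposited, the package ships a
synthetic-data generator whose defaults emulate the study's statistical
structure at desk scale, with complete ground truth. All pipeline stages
are exercised and tested against that generator.

## The synthetic cohort and lipidome

**Cohort.** 35 species — 16 rodents, 12 primates, 7 bats — each with 3
individuals sampled in 6 tissues (liver, skeletal muscle, kidney, heart,
brain cortex, cerebellum): 630 samples, a desk-scale surrogate of a
669-sample design. Clade MLS ranges are 4–31 years (rodents), 15–100
(primates) and 10–33 (bats). The MLS draw plants exactly one long-living
rodent, one primate and two bats (mirroring naked mole-rat, human and two
bat species): long-living species are drawn in the top 5% of the clade
range and all others below 85% of it, so the 0.9 × clade-max rule labels
them deterministically. Body mass is log-uniform per clade and BMR follows
an allometric power law `bmr = 0.018 · mass^0.75` (W, mass in g) with
log-normal noise (sd 0.15); body temperature is N(36.5, 1) °C; diet is
categorical; hibernation is Bernoulli per clade (0.25 rodents, 0.5 bats, 0
primates). MLS is drawn independently of all of these, emulating a cohort
chosen so that lifespan is uncoupled from the usual confounders.

**Lipidome.** Each tissue table holds 350 peaks by default. Log-scale
concentration of peak *p* in sample *i* is

> baseline(p, tissue) + species effect + planted shift + confounder term + noise

with a per-peak baseline N(11, 1) plus a tissue offset N(0, 0.5), a species
random effect N(0, 0.3²), and individual noise N(0, 0.4²). 25 *predictor
peaks* receive a shift of `±effect_size × √(0.3² + 0.4²)` in long-living
individuals, with the sign drawn once per peak and shared by all clades —
the property the cross-clade correlation stage relies on. The default
effect size is 2.0 (standardized mean difference), a strong planted signal
chosen so the benchmark classifiers operate in the high-accuracy regime the
analysis is about; cortex carries a 1.5× multiplier as the designated
high-signal tissue. 25 *confounded peaks* receive a linear term (slope 1.5
in standardized units) in one confounding factor, matching the linear
confounder tests. Intensities are exponentiated and multiplied by a
per-sample internal-standard level (log-normal, sd 0.25), so the
normalization stage's `log(intensity / IS)` round-trips the simulated
values; an IS peak is appended to each table. Detection is missing
completely at random at rate 0.15. Peak metadata (m/z in 100–1500 Da, RT in
0–20 min, ionization mode) is generated jointly with a synthetic compound
reference — 12 lipid classes, 2 sub-classes each, 12 pathways, Poisson(3)
double bonds, and per-class adduct lists (+H/−H primary; +NH4, +Na, +HCOO
rare) — such that annotated peaks sit within ~3 ppm of a real adduct ion
mass of their compound. Six peak pairs are split features of one compound
(near-identical m/z and RT, shared profile up to 0.05 sd noise) to exercise
the merge stage.

The generator emulates: the group structure (clades, species, tissues),
clade-shared planted signal, confounder structure, internal-standard
variation, annotation ambiguity, split peaks, and missingness. It does
**not** emulate: raw spectra or chromatographic peak shapes, isotope
envelopes, correlated lipid co-regulation networks, tissue-specific
predictor sets (the planted set is shared across tissues, so the
tissue-overlap statistic is strongly positive by design), non-random
missingness, or real lipid-database content. Passing tests therefore show
the machinery is correct and calibrated, not that real lipidomes behave
this way.

**Enzymes.** 908 enzymes are linked to Poisson(6) compounds each; a planted
10% draw ~70% of their links from predictor compounds. Enzymes whose links
are predictor-enriched (proportion ≥ 0.5) have their long-living-branch
dN/dS (Gamma(2, 10), mean 0.2) multiplied by `1 − enzyme_effect` (default
0.5); the short-living branch is never shifted. Flat term annotations
(30 terms, planted enzymes concentrated in a few) stand in for GO.

## Peak processing

Normalization divides by the sample's internal-standard intensity and takes
the natural log; samples lacking the IS are flagged and dropped. The IS
quality filter removes samples more than 2.5 sd from the tissue mean of the
IS, with mean and sd computed once on all samples (single pass — no
iterative re-estimation). The detection filter keeps a peak iff it was
detected in ≥ 50% of the individuals of at least one species in the
tissue. Annotation matches observed m/z against compound-plus-adduct ion
masses within 10 ppm (relative, so scale-free), restricted to the peak's
ionization mode and the adducts allowed for the compound's class, primary
adducts before rare ones; all in-tolerance matches are kept, so peaks may
be ambiguous, and each match contributes once to class-level statistics.
Merging connects peaks with Pearson r > 0.7 (computed on log values over
jointly detected samples; undefined below 3 shared samples), ΔRT < 0.05
min and a shared matched compound, then merges connected components —
a deterministic, order-independent closure of the stated pairwise rule —
averaging member log concentrations. Cross-dataset matching uses 10 ppm
and 0.1 s; the RT unit inconsistency (minutes for merging, seconds for
matching) is preserved as configurable defaults rather than silently
harmonized. Remaining missing values are imputed at half the smallest
detected value of the peak (log-scale minimum − log 2), a standard
left-censoring surrogate applied just before model fitting.

## Confounder filtering

Each peak is tested against seven factors: sex and hibernation (two-sided
pooled t-test), diet (one-way ANOVA), BMR, body temperature, body mass and
age (simple linear regression F). Species-level traits are tested on
species-mean log concentrations to avoid pseudoreplication; sex and age at
the sample level — the unit question is genuinely open, and species means
are the conservative choice. Multiple testing is controlled per factor
across peaks by Westfall–Young maxT: factor values are permuted across the
observation units 1000 times, each peak's corrected p is the add-one
fraction of permutations whose maximum statistic over peaks reaches its
observed statistic, step-down monotonicity is enforced, and ties are
counted with a small relative tolerance so permutations equivalent to the
observed labeling are never lost to floating-point noise. Peaks with
corrected p < 0.01 for any factor are removed. Under a global-null
simulation the realized per-factor removal fraction is essentially zero —
family-wise control is much stricter than per-test control, which is the
point of the maxT choice: it is the standard permutation scheme that
yields one corrected p per test. The age screen for time-series data fits
polynomials of degree 1–3, picks the degree by adjusted R², and F-tests
the chosen fit against the constant model at p < 0.01.

## Classification

Features are standardized per tissue (mean 0, sd 1 per peak) so the
penalty treats peaks comparably. The logistic elastic net minimizes the
mean negative Bernoulli log-likelihood plus
`λ[(1−α)/2 ||β||² + α ||β||₁]` with an unpenalized intercept (solved by
glmnet along a warm-started path). Cross-validation is 10 folds × 10
repeats, stratified by class at the individual level; the mixing parameter
α ∈ {0.1, 0.5, 0.9} is chosen by mean held-out AUC, computed as
Mann–Whitney concordance (ties count one half). The penalty λ is chosen
inside each training split by inner-CV **binomial deviance**, not AUC: with
a strong planted signal the held-out AUC is 1 along a wide stretch of the
λ path, so an AUC criterion degenerates to its tie-break and (under the
usual most-parsimonious convention) collapses the refit model to a handful
of peaks; deviance still discriminates along the path and keeps the
predictor set inclusive of the correlated signal peaks. Class imbalance is
left unweighted. Whether folds should be blocked by species is open;
individual-level stratification is the default, and the clade hold-out
protocol (which blocks by individual and by clade) covers the stronger
leakage concern. The refit on all samples at the selected α defines the
MLS predictors as the nonzero-coefficient peaks. SVM-RFE removes
`ceil(1%)` of the initial features per iteration by lowest |weight| (ties
by column index) down to 10, choosing the feature count by mean CV AUC;
the linear elastic net regresses clade-normalized lifespan (species MLS /
clade max, so clade maxima have response exactly 1) with the same penalty.

## Clade hold-out

For fractions 0.1–1.0 and 100 replicates each (the analysis drivers and
acceptance checks use 20–25 replicates to keep runs to minutes; the
protocol is unchanged), the sampled individuals of the test clade move
from training to test as whole individuals across tissues. Per-tissue
models are fitted at α = 0.5; tissues are then merged into brain
(cortex + cerebellum) and non-neural (liver + muscle + kidney) datasets:
per tissue, features are ordered by |coefficient| descending, then by the
long-vs-short training mean difference, zero-coefficient lowest-difference
features are dropped so all tissues reach the same width (the minimum
nonzero-coefficient count over tissues), and the reduced matrices are
concatenated row-wise with features aligned purely by rank — features are
tissue-specific, so rank alignment is the only coherent reading of
merging "according to the predefined order". AUC is computed on the
held-out clade individuals only. Replicates draw counter-derived seeds, so
any single replicate is reproducible in isolation. The random baseline
permutes the labels 100 times and reruns a full fit-and-evaluate per
permutation; the evaluator fits at a fixed weak penalty (λ = 0.05) because
a CV-selected penalty under destroyed labels collapses to the constant
model, which would pin every baseline AUC at exactly 0.5 and make the
baseline band degenerate.

## Predictor characterization

Per clade, a peak's *change* is the mean log concentration in long-living
species minus the mean in all others. Cross-clade concordance is the
Pearson correlation of change vectors over predictor peaks, with a
permutation null that shuffles peak identity of one vector (one-sided,
positive). Group enrichment is an upper-tail hypergeometric test within
the tissue's annotated universe, corrected empirically: 1000 draws of a
random predictor-sized peak set, each contributing its minimum group p;
a group's corrected p is the add-one fraction of draws at or below its
observed p. The concentration-shift statistic for a group is the median
across clades of the group's median change — a robust choice consistent
with median-based reporting — with a null built by resampling equal-sized
sets from all predictors and a two-sided p; direction is called at
p < 0.05. Double-bond association uses Spearman correlation (counts are
ordinal) between double bonds and per-peak median change, with quartile
(0.25, 0.75) reporting. Tissue overlap is hypergeometric on the
m/z-and-RT-matched peak universe of each tissue pair. Fatty-acid-style
focal comparisons place a peak's change in the percentile of the
complement distribution. Enrichment universes are per tissue (detected,
annotated peaks), the natural choice when detection differs by tissue.

## Enzyme evolution

Per enzyme, the predictor-link proportion is |links ∩ predictor
compounds| / |links|; enzymes at or above the (1−q) quantile are selected,
ties included, with q = 0.30 (0.25 heart, 0.35 non-neural). The dN/dS
comparison is a one-sided Wilcoxon rank-sum (selected < background,
background excluding the selection) per branch — a distribution-level
claim with no normality assumption; dN/dS values are rank-based, so the
test is invariant to common rescaling. One value per enzyme per branch is
assumed; computing dN/dS (alignments, codon models) is out of scope — the
table is consumed as data. The term network connects significantly
enriched terms (hypergeometric, p < 0.05) with edges weighted by shared
selected enzymes.

## Numerical choices and degenerate inputs

- Permutation and resampling p-values all use the add-one estimator, so
  the attainable minimum is `1/(n+1)`.
- Constant factors, constant double-bond counts, single-class folds and
  all-zero-coefficient tissues are detected and flagged or re-drawn rather
  than producing NaNs; constant responses return the fully shrunk model.
- Elastic-net fits run along a 30-point warm-started λ path to the target
  value with convergence threshold 1e-10; solutions satisfy the KKT
  subgradient conditions to ~1e-4 in the worst case on test fixtures.
- All randomness flows from one master seed through a splitmix-style
  integer derivation (`derive_seed`), keeping every stage and replicate
  independently reproducible and all seeds below 2³¹.

## Problem sizes

The shipped drivers and checks use the default benchmark — 630 samples,
350 peaks per tissue, 10 × 10 CV, 1000 permutations/draws, 10,000 null
lipids for the calibration run, 20–25 hold-out replicates per fraction —
sizes chosen so a full run completes in minutes on a single core while
keeping every statistic's Monte-Carlo error well inside the margins the
tests assert.

## Known limitations

- The planted predictor set is shared across tissues; per-tissue predictor
  fractions and tissue specificity therefore do not reproduce real
  heterogeneity.
- With the default strong effect size most tissues sit near AUC 1, so the
  benchmark does not probe the middling-signal regime; lower
  `effect_size` in `lipidome_config()` to study it.
- Confounder injection is linear on log concentration; nonlinear
  confounding would evade the linear tests by design.
- No phylogenetic correction anywhere: species are treated as exchangeable
  within clades, as in the original procedure.
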