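---
title: "Methods: radiation-responsive miRNA screening and panel discovery"
author: "radmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiation-responsive miRNA screening and panel discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmir)
```

## The problem

Circulating serum miRNAs shift within days of total-body irradiation, which
makes them candidate biodosimetry markers: a blood draw could report how much
radiation a subject absorbed, how long ago, and how likely the exposure is to
prove fatal. `radmir` implements a screening and panel-discovery pipeline for
a non-human primate cohort design: six dose groups from 6.0 to 8.5 Gy in
0.5 Gy steps, six animals per group (19 males, 17 females), serum sampled
before irradiation and on days 1, 2 and 6 afterwards, and survival to the end
of the observation window as the clinical endpoint (16 of 36 animals
survive; 10 of 18 at doses up to 7.0 Gy, 6 of 18 above). Because such cohorts
are small and expensive, every stage of the pipeline is also exercised
against a synthetic cohort generator with known planted structure, so that
recovery, specificity and calibration can be measured exactly.

## The synthetic cohort generator

`simulate_cohort()` draws one small-RNA-seq sample per animal per timepoint
(144 samples under the default design). Counts are negative binomial — the
standard overdispersed model for RNA-seq counts — with:

* per-feature baseline means drawn log-normally (sdlog 1) around a median of
  100 expected counts, emulating the skewed abundance distribution of
  detected serum miRNA;
* per-sample library sizes uniform in 0.8–1.2 million reads (the scale of a
  targeted small-RNA assay after processing), entering as a multiplicative
  depth factor;
* dispersion 0.2, a typical between-animal biological coefficient of
  variation for bulk expression data.

Planted effects act multiplicatively on the log2 scale of post-irradiation
means, so the per-animal log2 fold change is linear in dose or day by
construction — matching the linear screening model downstream. The default
planted truth contains five dose markers at 0.5 log2FC per Gy (dose effects
scale with Gy above the lowest group, so the 6.0 Gy group shows no shift),
five time markers at 0.3 log2FC per day, four sex markers at a 1.0 log2
shift, and a three-feature survival panel separating survivors from
decedents by 1.5 log2 units. These sizes were fixed once, chosen so that the
simulated per-dose-means regressions reproduce the strength of published
dose-responsive markers (slope F statistics in the single digits to tens);
they are conditions of the study, not tuning knobs.

Survival is assigned per animal by drawing exactly the design's survivor
count within each dose group, which reproduces the aggregate outcomes by
construction and keeps survival correlated with dose through the survivor
table. Companion FASTA files for two species are generated by
`simulate_mirna_fasta()`: mature sequences 20–24 nt over A/C/G/U, with
homologous pairs mutated at random non-repeating positions to a requested
percent identity (rounded to the nearest value achievable at the drawn
length, and reported).

What the generator does **not** emulate: sequencing reads and their
artifacts (adapters, quality, mapping ambiguity), hematology or clinical
covariates, per-animal baseline biology beyond the shared baseline sample,
and batch structure. Tests passing on this generator therefore demonstrate
the statistical machinery, not robustness to upstream assay artifacts.

## Normalization and fold change

Features detected (count > 0) in fewer than 40% of samples are removed;
the boundary is inclusive on the keep side (a feature non-zero in exactly
40% of samples stays). Filtering precedes normalization. TMM scaling
factors are computed by the canonical trimmed-mean-of-M-values procedure
(reference sample by upper-quartile proximity to the mean, trim fractions
0.30 on M and 0.05 on A, precision weights, factors rescaled to geometric
mean one), delegated to edgeR. CPM is counts over effective library size
(library size times TMM factor) per million. Expression change is the
per-animal log2 fold change of CPM against that animal's own
pre-irradiation sample, with a pseudocount of 1 in numerator and
denominator so zero-zero pairs map to exactly zero and all values are
finite. Animals lacking a baseline sample are excluded with a message.

## The four-way screen and its error structure

Each feature's fold change is screened across the 15 terms of the full
factorial in radiation dose (RD, 6 levels), time since irradiation (TSI, 3
post-irradiation levels), Sex, and survival outcome (RRiF). Two structural
choices matter:

**Split-plot error strata.** The three fold-change values of one animal
share that animal's single baseline sample, so they are positively
correlated: a naive fixed-effects ANOVA is anticonservative for
between-animal terms (empirically 0.15–0.33 rejection at the 0.05 level
under the null) and conservative for TSI terms. `fit_four_way_anova()`
therefore uses the classical split-plot analysis for repeated measures:
terms constant within an animal (RD, Sex, RRiF and their mutual
interactions) are tested on per-animal means against the animal-stratum
error, which absorbs the shared baseline noise; TSI-containing terms are
tested against the within-animal residual, in which the baseline cancels.
Under a zero-effect simulated cohort every term's rejection rate is within
0.05 ± 0.02.

**Type II sums of squares.** The design is unbalanced (unequal sex ratios
per group; survival partially confounded with dose), so each term is tested
against the model containing every term that does not include it —
order-invariant and the appropriate default for unbalanced factorials.
Fully aliased terms (design columns adding no rank, e.g. high-order
interactions with empty cells) are flagged inestimable rather than
reported. Effect size is classical eta squared, term SS over total SS, with
all SS expressed on the full sample layout so the decomposition is exact
for balanced designs. No multiple-testing correction is applied: the
screening convention is raw p < 0.05 per term, and the union of features
significant in at least one term forms the DE set.

**Power.** The study's original power computation mixed effect sizes with
sequencing-depth arguments in a way that cannot be reconstructed;
`estimate_power_by_simulation()` instead measures power directly: simulate
the cohort layout with a dose trend calibrated to a target eta squared,
run the actual screen, and report the rejection fraction. Power approaches
the test level as the effect vanishes and is monotone in effect size and
group size.

## Cross-species conservation

The conservation stage asks which screened miRNAs are credible in humans.

* `curate_sc()` aligns each DE feature against the full human mature set
  with global (Needleman–Wunsch) dynamic programming under affine gaps:
  gap open 10, gap extension 0.1 per position, match +5 / mismatch −4.
  A nucleotide substitution scheme is used because a protein matrix is
  undefined for RNA; the heuristic k-tuple/window stages of classical
  multiple-alignment tools are unnecessary at this scale (thousands of
  short sequences), so the alignment is exact — verified against
  exhaustive enumeration of all alignments for short sequences. Percent
  identity is matching columns over alignment columns. A feature is
  sequentially conserved (sc) when its best match reaches 90% identity, a
  conservative default exposed in configuration; all tied best targets are
  retained.
* `curate_fs()` approximates re-quantification against the human
  reference at mature-sequence granularity: each measured feature is
  re-assigned to its best human match (requiring 60% identity so unrelated
  sequences do not map), counts are aggregated per human ID, and the full
  prefilter–TMM–fold-change–ANOVA screen is re-run. The functionally
  similar (fs) set is the resulting DE union. With the identity reference
  this reproduces the species-A DE union exactly, which is tested.
* `intersect_sets()` forms the conserved pool: sc features whose mapped
  human ID re-emerged in fs (cnvd = sc ∩ fs).

Alignment scores pass through a single-precision representation of the gap
penalties inside the alignment engine, so scores are exact only to about
1e-5; comparisons in tests use that resolution.

## Dose- and time-response markers

`dose_response_fit()` and `time_response_fit()` regress fold change on
numeric dose (Gy) or day, by default using per-level stratum means pooled
over the other axis — the convention consistent with the very small
residual degrees of freedom of published marker fits. The published F/p
pairs are not mutually consistent about whether a zero point is included:
time-axis pairs imply four regression points while dose-axis pairs imply
six. The package resolves this per axis: the time fit includes the day-0
baseline point (fold change is identically zero there by construction),
the dose fit adds no (0 Gy, 0) origin; both choices are arguments.
The slope F test (equal to the squared slope t statistic) at p < 0.05
flags a marker; `classify_marker()` labels it sex-independent when the
pooled fit is significant and male-/female-specific when exactly one sex
stratum is, with pooled significance not masking a sex-exclusive pattern.

Under the frozen generator conditions, planted time markers are recovered
essentially always, while planted dose markers — deliberately planted at
the strength of published markers — are recovered in roughly seven of ten
fits at the default six-point means convention, with null features flagged
at about the nominal 5%. This is a real property of six-point slope tests
at that effect size, and the package reports it rather than inflating the
planted effects.

Single-marker discrimination (`single_marker_auc()`) uses the rank
(Mann–Whitney) AUC with midranks for ties — identical to exhaustive pair
enumeration — with a stratified percentile bootstrap (2000 resamples) for
the confidence interval, since no closed-form CI convention is assumed.

## Panel discovery (2BDP)

`discover_panels()` implements the wrapper search for multi-miRNA logistic
panels predicting survival, operating on one row per animal (mean
post-irradiation fold change per feature):

1. **Candidate ranking.** Random forests are trained on bootstrap
   resamples of the cohort (2000 repetitions at study scale; reduced in
   tests), each repetition recording its top features by impurity
   importance; features are ranked by selection frequency and the
   distinct top sets become seed panels (200 at study scale). The
   published procedure is ambiguous about what varies across repetitions;
   bootstrap resampling of animals is used, with repetition count, panel
   count and recorded-set size as configuration.
2. **Subpanel enumeration.** Every subset of each seed panel with 2 to 10
   features, deduplicated globally, in deterministic order.
3. **Logistic fitting.** Maximum likelihood via IRLS; McFadden's pseudo
   R² (1 − lnL/lnL₀) and a likelihood-ratio χ² p-value against the
   intercept-only model measure fit quality. Perfect separation — common
   with 36 animals and strong markers — is detected (warning, divergence,
   or near-zero deviance) and refitted with a small ridge penalty (1e-4,
   intercept unpenalised) to keep coefficients finite; such fits are
   flagged.
4. **Evaluation.** Two routes. RSBMR: repeated stratified 70:30
   train/test splits (10 repeats), reporting mean test AUC and
   sensitivity/specificity at the Youden-optimal threshold (no threshold
   rule is published; Youden's J is the standard choice). k-fold:
   stratified 10-fold, reporting the mean of per-fold AUCs; folds left
   with one class have no defined AUC and are skipped with a warning.
   Splitting is stratified throughout because unstratified splits of a
   36-animal cohort regularly produce single-class test sets.
5. **Screening.** Panels with mean AUC strictly above 0.80 and fit
   p below 0.05 are retained, ranked by AUC, ties broken by fewer
   features then lexical order.

One practical observation: with strong markers, per-fold AUCs on
three-to-four-sample folds saturate at 1 and produce many exact ties, so
the k-fold route ranks panels coarsely and the lexical tie-break decides
among dozens of equivalent panels; the RSBMR route, whose test sets hold
eleven animals, discriminates panel quality more finely and is the route
used when the search itself is being validated against planted truth.

## Descriptive reports and orchestration

`pca_report()` (centered PCA of samples; explained-variance fractions sum
to one) and `hclust_report()` (Euclidean distances, average linkage — the
distance is published, the linkage is the package's documented choice)
provide the standard overview figures' numbers. `run_pipeline()` chains
every stage — simulation or file input, normalization, screening,
conservation, marker regression, panel search, reports — writing TSV/JSON
artifacts and an md5 manifest; a fixed configuration and seed reproduce
identical checksums, which is tested. Every stochastic function takes a
seed, restores the caller's RNG state, and runs forests single-threaded,
so the entire pipeline is deterministic given (data, configuration, seed).

## Problem sizes used by the test suite

The packaged tests run the generator at 25–100 features (500 for null
calibration) with the full 144-sample design, 10–20 seeded replicates per
recovery claim, and the panel search at 15–50 forest repetitions with 3–10
seed panels and subpanels up to size 4 — sizes at which every claim is
measurable in seconds while preserving the cohort's sample dimension,
which is what the statistics actually depend on. Study-scale defaults
(2000 repetitions, 200 panels, subpanels to size 10) remain the function
defaults.

## Known limitations

* The fs route approximates genome re-alignment by mature-sequence
  re-assignment; features whose human homologue diverges mainly outside
  the mature sequence are treated the same as those that diverge within it.
* The split-plot screen assumes each animal contributes a complete,
  equally-sized set of post-irradiation samples; strongly unbalanced
  designs would need mixed models, which are out of scope.
* Six-point slope tests have limited power at published-marker effect
  sizes (see above); per-animal regression points are available as an
  option when more residual degrees of freedom are wanted.
* With 36 animals, cross-validated AUCs carry wide uncertainty; single
  permutation draws of the outcome scatter roughly between 0.3 and 0.7,
  and only averages over permutations are meaningful as a null reference.
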