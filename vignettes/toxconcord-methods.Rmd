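---
title: "Methods: from targeted panels to in vitro / in vivo concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from targeted panels to in vitro / in vivo concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxconcord)
```

# The problem

Regulatory hazard assessment of pesticide active substances still rests on
rodent studies, while cell-based new-approach methodologies (NAMs) promise
organ-specific mechanistic readouts without animals. `toxconcord`
implements the complete analysis chain for one such two-organ workflow: a
liver model (differentiated HepaRG cells) and a kidney model (RPTEC
proximal tubule cells) are exposed to the highest non-cytotoxic
concentration of each test substance, profiled with a targeted qPCR array
and an 8-marker protein panel, the evidence is graded on an ordinal scale,
mapped onto curated in vivo effect categories, and scored against the
effects reported in regulatory rodent dossiers. The headline statistic is
*indicative concordance* — the percentage of in vivo-positive effect
categories that the in vitro system flagged — together with *negative
agreement*, the percentage of in vivo-negative categories left unflagged.

This vignette records the modelling choices, the defaults and why they were
chosen, and what the synthetic validation does and does not demonstrate.

# Viability screen

Plate readings are normalized to percent of the solvent control:
dual-wavelength absorbance readouts as
$100\,\frac{(A_{450}-A_{620}) - (B_{450}-B_{620})}{A^{ctrl}_{net}}$
(`normalize_absorbance()`), fluorescence readouts with a single blank term
(`normalize_fluorescence()`). `select_highest_noncytotoxic()` picks the
largest tested concentration at which *every* assay's mean viability
strictly exceeds 80%.

Three decisions were genuinely open:

* **"greater than 80%" is strict** — a concentration at exactly 80.0%
  fails. The selection is monotone in the threshold.
* **Conjunction over assays.** When both a metabolic-activity and a
  lysosomal-uptake assay are available, both must pass. The assays probe
  different injury modes; accepting a concentration one of them flags as
  cytotoxic would contaminate every downstream readout.
* Technical replicates are averaged before thresholding.

The companion exposure concentration is fixed at
`second_concentration()` = 0.33 × the selected concentration.

# Quantification of targeted qPCR arrays

Threshold-cycle values are censored at 35 cycles (`censor_ct()`):
late-amplifying and undetected wells are replaced by the cutoff, the most
conservative detectable value. Per sample, the delta-Ct is
$\Delta C_t(g) = C_t(g) - \overline{C_t(\mathrm{HK})}$ with the arithmetic
mean over the housekeeping genes (`delta_ct()`); missing housekeeping genes
are a hard error naming gene and sample. Relative expression follows the
classic comparative-Ct form
$\mathrm{FC} = 2^{-\Delta\Delta C_t}$, with
$\Delta\Delta C_t = \overline{\Delta C_t}_{treated} -
\overline{\Delta C_t}_{control}$ against the *untreated* control
(`ddct_expression()`). Fold regulation is the signed representation:
$\mathrm{FR} = \mathrm{FC}$ if $\mathrm{FC} \ge 1$, else
$-1/\mathrm{FC}$.

Two choices deserve a note:

* **Significance is tested on the log scale.** The one-sample t-test runs
  on per-replicate $\Delta\Delta C_t$ values against 0, not on
  $2^{-\Delta\Delta C_t}$: cycle-scale noise is approximately Gaussian and
  symmetric, the exponentiated values are not.
* **Replicates are paired by order** when treated and control counts match
  (each biological replicate carries its own control in this design), which
  makes the per-replicate $\Delta\Delta C_t$ well defined and the null
  distribution exactly Student-t. With unequal counts the function falls
  back to treated-minus-control-mean differences and flags the row; that
  fallback is anticonservative and only used where the paired design is
  broken.

Genes censored in *every* treated and *every* control replicate are
reported with fold change 1 and excluded from DEG calling: the ratio of two
censored values carries no information. The cross-platform QC
(`qc_range_check()`) accepts array and single-assay fold changes within a
3-fold ratio by default; the instrument's fluorescence-threshold settings
are acquisition parameters and outside computational scope.

# DEG calling, pathway percentages and overlap p-values

A gene is differentially expressed when $|\mathrm{FR}| \ge 2$ (inclusive)
and $p < 0.05$ (strict) — the inclusive/strict split mirrors how the
cutoffs are printed. `pct_deg()` reports per pathway the share of its genes
that are DEG; DEG outside the panel background are ignored with a warning.
`fisher_overlap()` supplies the right-tail hypergeometric probability
$P(X \ge k)$ of an observed DEG/gene-set overlap. It is a transparent
stand-in for the overlap statistic of commercial annotation engines so that
synthetic end-to-end runs need no external service; it does not reproduce
any curated knowledge base, and the packaged pathway catalogs used in tests
are synthetic and user-replaceable.

# Protein-marker evidence

Each of the 8 markers (translation, transcription, protein degradation,
cell division, oxidative/heat stress, apoptosis, autophagy, hypoxia) is
measured at 2 concentrations × 2 timepoints × ≥3 replicates, as percent of
solvent control. Replicates are averaged per condition and the grading
matrix applied (`grade_protein()`):

| grade | rule over condition means |
|---|---|
| very_strong | ≥ 2 conditions > 200% |
| strong | 1 condition > 200%, or ≥ 2 conditions in (150, 200] |
| medium | 1 condition in (150, 200] |
| none | otherwise |

The printed band "150–200%" is read as the half-open interval (150, 200]
so the bands partition; "2 conditions" is read as "at least 2"; decreases
below 100% never contribute, since every readout is an increase-type
endpoint.

Significance against the control is reported by a percentile bootstrap of
the mean (`bootstrap_test()`, 10 000 resamples by default, two-sided,
seed-reproducible, order-invariant). **The bootstrap p-values are
descriptive, not calibrated**: with three replicates the resample
distribution has only ten atoms, and any mean-resampling bootstrap rejects
far too often (the acceptance suite measures the realized type-I error
under a lognormal null at n = 3; it is dominated by the ~25% chance that
all three replicates fall on one side of the null). This is precisely why
grading uses magnitude only and the bootstrap p is reported *alongside*
the grade rather than gating it; a `null_resampling` method is available
but shares the small-n limitation. Positive-evidence decisions in this
package therefore never hinge on a bootstrap p-value at n = 3.

Cell lines are OR-combined (`combine_cell_lines()`): per substance and
cellular function the combined grade is the maximum — a positive
prediction from either line suffices.

# Transcript evidence

Annotation exports (category, annotation, overlap p-value) are filtered to
liver/kidney-relevant categories via a packaged, user-extensible whitelist;
predicted effects on other organs are discarded. Within a category the
**most significant** annotation p is kept (`collapse_to_category()`): the
alternative literal reading ("the highest p-value") would make a category
weaker than its own best annotation and contradict the ≤-direction of the
grading thresholds; it remains available as `collapse_rule = "max_p"` for
sensitivity analysis. Grades follow the p-value matrix: very_strong at
p ≤ 0.0005, strong at p ≤ 0.005, medium at p ≤ 0.05 (all inclusive);
the expression-side input filter retains $|\mathrm{FR}| \ge 1.5$ and
$p \le 0.05$.

# The concordance engine

`map_predictions()` sends every endpoint whose grade reaches the threshold
through the curated mappings — cellular functions for the protein panel,
annotation categories (including multi-category combination rows, which
fire only when *all* members pass and contribute their weakest member
grade) for transcripts — onto (substance, organ, effect) triples.
Endpoints with no in vivo counterpart (protein degradation, hypoxia)
legitimately predict nothing.

`compute_concordance()` scores a prediction set on an evaluation universe.
Three denominator decisions matter:

* **Absence is negative.** An effect category missing from a substance's
  in vivo profile counts as observed-negative, matching how negative
  agreement is computed in practice; an explicit unknown marker can be
  layered on via a restricted universe.
* **Unreachable effects leave the denominator.** Effects no endpoint of the
  active mapping can express (e.g. calculi under the protein-only mapping)
  are excluded — the system should not be scored on endpoints it cannot
  articulate. `score_unmapped_effects = TRUE` keeps them as automatic
  misses for sensitivity analysis.
* **Display percentages are rounded to integers**; machine outputs keep the
  raw ratios.

`threshold_sweep()` evaluates 7 scopes × 3 thresholds (at least medium /
at least strong / very strong only). Each scope keeps its own universe:
single-cell-line protein scopes score against their organ, combined
protein and all transcript scopes against both organs, and the overall
protein+transcript combination against the union of both mappings'
reachable effects. Two structural properties hold by construction and are
property-tested: within a scope, tightening the threshold never increases
indicative concordance and never decreases negative agreement; and on a
*shared* universe, OR-combining prediction sets never lowers concordance.
Note the second property is a theorem only on a common universe — across
scopes with different denominators the combined scope can print a lower
percentage than a constituent, which is visible in real report tables and
is not a defect.

# The synthetic-data generator

`simulate_study()` produces a full input bundle with known ground truth:

* **Ct tables** — gene-wise baselines in 22–30 cycles (housekeeping 19–21),
  Gaussian replicate noise of 0.25 cycles on the cycle scale (the standard
  qPCR error model), treated expectation shifted by the true log2 fold
  change; 370 liver targets and 84 kidney targets plus 5 shared
  housekeeping genes, 3 replicates — the study's panel shape.
* **Protein panels** — lognormal replicate noise (positive support) with
  cv 0.3 around condition truths; active markers are induced to 250% in
  both high-exposure conditions, inactive markers sit at 100%.
* **Annotation exports** — active categories draw overlap p-values below
  the very-strong threshold, inactive ones clearly non-significant ones,
  plus off-organ decoys that exercise the organ filter. The combined scope
  concatenates both panel exports.
* **In vivo profiles with controllable truth** — given the ground-truth
  prediction set $P$ over the evaluation universe (fraction
  $\hat p = |P|/|U|$), a triple is drawn observed-positive with probability
  $q_1 = c\,\pi/\hat p$ inside $P$ and $q_0 = (1-c)\,\pi/(1-\hat p)$
  outside, where $c$ is the target concordance and $\pi$ the positive
  prevalence (clamped when infeasible). Conditional on being observed
  positive, a triple is ground-truth predicted with probability exactly
  $c$, independently — so the pipeline's estimate is a binomial proportion
  around the target, which is what the recovery checks assume. Setting
  $c = 1$ and $\pi = 1$ yields the perfect-information limit (100%
  concordance, 100% negative agreement).

What the generator does **not** emulate: plate and batch effects,
correlated noise across genes beyond the shared housekeeping term,
bead-level immunoassay signal processing, dose–response shapes in the
panels, and the biology of real annotation knowledge bases. Passing the
synthetic suite therefore demonstrates that the *computational chain* is
correct and calibrated where calibration is possible — not that the
underlying assays predict rodent toxicity; the latter claim can only come
from real call tables.

Because active endpoints are simulated as strongly induced (the regime the
grading matrix is designed to flag), the three threshold rows of a
synthetic sweep often coincide for transcript scopes; protein scopes
differentiate through replicate noise.

# Numerical choices and problem sizes

* Boundary conventions: DEG |FR| inclusive / p strict; transcript filter
  and grade thresholds inclusive; protein bands half-open; viability
  strictly greater-than.
* All randomness flows from one integer seed: bootstrap p-values derive
  per-condition seeds from `rng_seed`, the generator derives fixed offset
  streams per stage, and RNG state is always restored
  (a pipeline run is a pure function of inputs, config and seed).
* Tie-breaks: equal grades combine to themselves (idempotent max);
  duplicate genes across panels are deduplicated keeping the liver-panel
  measurement, logged.
* Test problem sizes were chosen to keep the full suite in a few minutes
  on one core: calibration uses 1000 null genes and 1000 null panels of
  3 replicates, recovery uses 100 simulated studies of 6 substances with a
  96-triple universe, and exhaustive combinatorial checks cap the
  background at 12 genes.

# Known limitations

* Bootstrap p-values at n = 3 are descriptive (see above); they are
  reported, never used as gates.
* The packaged ontologies are transcriptions of published curation; the
  category whitelist cannot anticipate every organ-relevant category name
  an annotation engine may emit and is meant to be extended.
* Concordance percentages on small universes are coarse (one triple moves
  the combined scope by ~1–2 percentage points), which is why raw counts
  accompany every percentage.
* The engine takes annotation exports as given; it does not attempt to
  reproduce a commercial knowledge base's annotation calls, only the
  downstream evidence integration.
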