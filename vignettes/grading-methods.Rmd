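---
title: "Methods: multi-platform chemometric grading of AMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-platform chemometric grading of AMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amrgrade)
```

## The problem

Commercial grades of Atractylodis Macrocephalae Rhizoma (AMR, *baizhu*) are
assigned by origin and appearance, yet the chemical basis of those grades is
diffuse: volatile terpenoids measured by headspace GC–MS, non-volatile
lactones and sugars measured by LC–MS, and holistic odor/taste fingerprints
from electronic-nose and electronic-tongue arrays each carry part of the
signal. `amrgrade` implements the full analysis chain for such a study —
fuzzy sensory scoring, OPLS-DA differential screening, sensor-array
screening with correlation mapping, and mid-level data fusion into grade
classifiers — together with a synthetic-data generator that emulates the
study conditions so every stage is testable without access to the original
measurements, which were never deposited.

Because the real tables are unavailable, nothing in this package attempts to
reproduce instrument-specific numbers (model R²/Q² values of the original
software, or absolute classifier accuracies). What the generator is designed
to reproduce is the *structure* of the findings: the grade layout, the
differential-compound counts and their shared cores, the informative sensor
sets, the repeatability bound, and the qualitative classification results.

## Study design emulated by the generator

`study_design()` encodes 39 batches in four specification groups — ZJ
(Zhejiang genuine origin, grade 1, 10 batches), AH-HN-1 (grade 2, 13),
AH-HN-2 (grade 3, 7) and HB (grade 4, 9) — each observed as 5 replicate
preparations, 195 observations per platform. The replicate count is not
stated anywhere as such; it is implied by the classification arithmetic
(85.19% = 115/135 and 98.33% = 59/60 force a 135/60 split of 195 = 39 × 5).
The E-nose protocol by itself retains 3 valid injections per sample; the
generator nevertheless emits 5 replicate observations uniformly on all four
platforms because cross-platform feature fusion requires row-aligned tables.

### Abundance model

Compound tables are log-normal. For batch $b$ in group $g$, replicate $r$,
compound $j$:

$$\log x_{brj} = \mu_j + \sigma_{pool}\,\Delta_{gj} + \lambda_j L_b
  + \beta_{bj} + \pi_{brj} + \varepsilon_{brj}$$

with baseline $\mu_j$, planted group effect $\Delta_{gj}$ expressed in units
of the pooled within-group SD $\sigma_{pool}$, a shared batch-level
technical factor $L_b$ (sample amount / matrix, loading $\lambda_j \approx
1$ on every compound), per-compound batch biological noise $\beta$
(σ = 0.08), per-replicate preparation noise $\pi$ (σ = 0.10) and
per-acquisition noise $\varepsilon$ (σ = 0.012). The acquisition σ is
calibrated so that six repeated acquisitions of one sample have RSD
comfortably below the 3 % repeatability bound the protocols report: a σ of
0.012 gives ≈1.2 % expected RSD, leaving room for the sampling variability
of an RSD estimated from six draws (at σ = 0.02 the *estimate* exceeds 3 %
for some sensor in over half of runs, although the generating process
satisfies the bound).

The shared factor $L_b$ is drawn *balanced within groups* (group-mean
centred). This emulates randomized acquisition order, in which technical
drift is orthogonal to the class layout. It is also statistically load
bearing: with only 17–23 batches per pairwise contrast, an unbalanced
technical factor acquires chance correlation with the class labels, and
that class-correlated component is — correctly — *not* removed by the
orthogonal filter, leaking into the predictive component and blurring the
planted/unplanted VIP separation. Balanced drift is the regime the
screening method is designed for.

### Planted effects

Differential structure per platform (defaults in `effect_spec()`):

* **Volatile (49 compounds, 22 shared peaks).** The four shared majors
  (atractylone, aromadendrene, γ-elemene, caryophyllene) follow the grade
  ordering AH-HN-1 > AH-HN-2 > ZJ > HB with adjacent gaps of 2 pooled SD.
  Twelve further compounds shift equally in both AH-HN groups (±2.5 SD) and
  nine only in HB, giving per-contrast sets of 16/16/13 whose union is 25
  and whose three-way intersection is exactly the four majors.
* **Non-volatile (51 compounds, 31 positive / 20 negative ion mode).** Six
  named compounds differ from ZJ in every contrast (isoatractylode A and
  atractylenolide I higher in ZJ than HB; sucrose higher in HB), twelve
  shift in the AH groups and seven in HB, making the union 25 with a
  17 positive / 8 negative split and the six named compounds as the core.
* **Sensors.** Responses are non-negative mixtures of latent odor/taste
  class abundances through a fixed loading matrix: three grade-varying odor
  latents (terpenoid, oxygenated, ester) read by the nine informative
  E-nose sensors (S17, S11, S1, S18, S13, S12, S14, S5, S7), one
  grade-varying taste latent read by PKS and ANS, and one grade-constant
  background latent per platform read by every sensor. Uninformative
  sensors load on the background only.

A deliberate asymmetry: the ZJ-vs-AH-HN-1 and ZJ-vs-AH-HN-2 differential
sets coincide. If each AH contrast had private differentials with all other
groups at the reference mean, those compounds would separate AH-HN-1 from
AH-HN-2 by the full planted effect — contradicting the study's central
difficulty, that the two middle grades are nearly indistinguishable. With a
common AH effect, the middle grades differ only on the four (respectively
six) ordered shared compounds and on small sensor-latent gaps, which is
exactly where the classifiers' confusion concentrates.

`effect_scale = 0` collapses every group difference and empties the
informative sensor sets, giving the null generator used for calibration
tests.

### Sensory coupling

Batch score targets are the group bases (ZJ 75, AH-HN-1 68, AH-HN-2 52,
HB 46 — centred in the reported bands) plus a positive coupling
(κ = 3.5 score points per SD) to the batch's *within-group standardised*
levels of caryophyllene, γ-elemene, aromadendrene and atractylenolide I.
Within-group standardisation matters: globally standardised levels would
simply re-encode the group pattern, and the batch-level association the
correlation analysis is meant to recover would be an artifact of the group
bases. Evaluator counts are multinomial draws (panel of 10) whose
expectation places the fuzzy score at the target; the two-level bracket
construction makes the expectation exact, and a concentration exponent
(∞ = all evaluators on one level) controls panel agreement.

## Fuzzy sensory evaluation

Weights come from binary pairwise comparison: each pair of criteria is
compared once (1 for the winner, 0 for the loser) and each criterion scores
1 against itself, so a strict ranking over four criteria yields weights
(0.4, 0.3, 0.2, 0.1). The self-comparison convention avoids a zero weight
for the least important criterion; ties are rejected rather than split,
matching the 1/0 scoring rule. The study's actual weights live in
supplementary material that is not available, so the defaults here are
declared, not recovered.

Level values default to (90, 70, 50, 30) — the centres of 20-point bands
consistent with the reported 40–60 / 60–80 grade bands. The score is
$B = w' M V$ with $M$ the membership (evaluator-fraction) matrix. Bands are
lower-closed, upper-open, topmost band upper-closed, so a score of exactly
60 is Grade I; scores outside every band get an explicit `out-of-range`
label instead of silent clamping.

## OPLS-DA, VIP and validation

The chemometric core is written from first principles (NIPALS). After
centring and unit-variance scaling (the default of the software named in
the field; zero-variance columns are dropped with a record), class-
orthogonal structured variation is deflated component by component: each
orthogonal weight is the X-loading of a provisional PLS component projected
off the span of $X'Y$, which makes every orthogonal score *exactly*
uncorrelated with the class block (machine precision, asserted in tests).
Two classes are coded as one 0/1 column with one predictive component;
four classes as a one-hot block with three. Predictive scores are oriented
so the first class level has a negative mean score, for reproducible plots
and tests.

VIP is computed over the predictive components only (screening targets
between-class variation):
$VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\lVert w_a \rVert)^2 / \sum_a SSY_a}$,
so mean VIP² = 1 exactly; screening uses the strict inequality VIP > 1.

Q² uses seeded, class-stratified 7-fold cross-validation with
preprocessing refit inside every training fold; $k = n$ reduces to
leave-one-out and is tested against an exhaustive per-observation PRESS.
The permutation test (default 200 permutations) recomputes R²Y and Q² under
permuted labels; the empirical p-value
$(1 + \#\{Q^2_{perm} \ge Q^2_{obs}\})/(n_{perm}+1)$ gates validity at 0.05.
The regression-intercept diagnostic is reported but not used as the gate.

Two deliberate deviations from the naive recipe:

* **Block permutation for replicate-level tables.** Grade labels are
  constant within a batch; observation-level permutation destroys that
  structure, so a model that merely memorises batches outperforms its
  permutation null and the test becomes anti-conservative (under the null
  generator it declared most sensor models "valid"). `permutation_test()`
  therefore accepts `blocks` and the sensor screenings permute whole
  batches — the exchangeability-correct unit.
* **Permutation-gated screening.** Because mean VIP² = 1 by construction,
  raw VIP > 1 flags roughly a third of variables *on any data, including
  noise*. The pipeline screening (`differential_screening()`,
  `sensor_screening()`) therefore empties a differential set whose model
  fails permutation validation. Under the null generator this yields 0 %
  flagged variables; the plain `screen_differentials()` operation remains
  ungated for direct use on validated models.

Compound models are fitted at batch level (replicates averaged — replicate
rows would pseudo-replicate the biological unit); sensor models at
replicate level, as the sensor protocols treat each acquisition as an
observation. Non-volatile models are fitted per ion mode and unioned per
contrast, mirroring separate positive/negative LC-MS models. The number of
orthogonal components defaults to 1 everywhere; the original software's
component counts, scaling and CV scheme are unreported, so printed R²/Q²
values of the study are not reconstruction targets.

## Correlation mapping

Spearman rho uses average ranks (tie-corrected) with two-sided p-values
from the t approximation, no multiplicity correction (none is reported in
this literature; a Benjamini–Hochberg adjustment can be applied to the
returned p matrix). Pairs involving a constant column are reported as
missing, never as zero. Sensor–compound maps correlate batch-level flagged
sensor responses with batch-level differential-compound contents; the
sensory map correlates batch fuzzy scores with the four coupled compounds.

## Fusion and classification

Per-platform PCA (autoscaled — the platforms' units are incommensurate)
keeps the smallest number of components reaching 95 % cumulative explained
variance, with deterministic component signs (largest-magnitude loading
positive). PCA is fitted on the full table before splitting, as the
features-first-then-split workflow implies; a leakage-free variant (PCA on
training rows only) would be the stricter choice for new-batch prediction
but is not what the emulated workflow does. Blocks are concatenated
column-wise with platform provenance into the fused input.

The split is seeded and stratified by grade: per-class training counts are
floored at 0.7 and topped up to the global floor (136/59 of 195); the
`study_size` flag keeps the plain per-class floors, reproducing the
135/60 partition implied by the study's accuracy denominators. Replicates
of one batch may cross the split — this matches the study arithmetic but
lets classifiers exploit batch memory, which is why single-platform test
accuracies here run high; the `group_by_batch` option keeps batches intact
and is used for the null-calibration test, where replicate-level splitting
would predict labels from batch identity even with zero class signal.

Classifiers use the stated hyperparameters: KNN with K = 2 (Euclidean on
the PCA features; vote ties broken by the nearest neighbour's class, equal
distances by training-row order, so predictions are deterministic — the
reason KNN is implemented in-package rather than via a library routine
with random tie-breaking); a single-hidden-layer softmax network with 5
units trained up to 1000 iterations (`nnet`, seeded initialisation); and a
random forest with 500 trees and 3 candidate variables per split
(`randomForest`). Training accuracy is measured by predicting the training
split directly (not out-of-bag), which is how a 100 % random-forest
training accuracy on every source arises.

## What the synthetic results do and do not show

Passing tests demonstrate that the pipeline recovers *planted* structure at
the stated effect sizes and noise levels: the 25-compound unions with their
4- and 6-compound shared cores, the 9 + 2 informative sensors, the
RSD < 3 % repeatability, the grade-ordered group means, positive sensory
correlations, 100 % RF training accuracy, fusion matching or beating the
best single platform, and confusion concentrated on the two middle grades.
They do not show that the method would recover these numbers from the real
measurements: real compound tables have correlated biochemical modules,
heavier tails, and batch effects that are not group-balanced, and real
per-contrast differential counts are a property of the samples, not of the
method. Synthetic compound names beyond the ten anchored ones are
placeholders (`V05`–`V49`, `N07`–`N51`) because identities play no role in
the computation.

Problem sizes throughout (39 batches × 5 replicates, ≤ 51 variables,
200 permutations, 500 trees) are the study's own dimensions; a full
pipeline run takes well under a minute of compute on one core.

## Reproducing the analysis

The numbered scripts under `analysis/` run the five stages on the default
conditions and write their tables under `results/`;
`scripts/acceptance.R --seed 42 --out results/acceptance.json` recomputes
the headline counts from scratch. `run_pipeline(pipeline_config())` drives
the same chain from a single seeded configuration with a manifest, and each
stage draws from a named substream of the master seed so adding a stage
never perturbs another stage's draws.
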