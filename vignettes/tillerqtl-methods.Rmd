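---
title: "Methods: field adjustment, tillering traits, and association mapping in tillerqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: field adjustment, tillering traits, and association mapping in tillerqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tillerqtl)
```

`tillerqtl` implements the statistical chain used to dissect natural
variation in barley tiller development from a large unreplicated field
panel: check-based spatial adjustment, ANOVA heritability, trajectory
metrics, regression variance partitioning, linkage-disequilibrium (LD)
characterisation, and a principal-component-corrected association scan
with QTL interval merging.  This vignette records the models, the
tunable parameters and their defaults, the design decisions taken where
the procedure was genuinely open, and what the synthetic-data generator
does and does not emulate.

## The augmented design and its adjustment

A Type-2 modified augmented design grows hundreds of unreplicated test
entries in blocks of 15 plots (5 plot-rows x 3 plot-columns).  The
central plot of every block carries the same repeated primary check
cultivar, and a few blocks additionally carry two repeated secondary
checks; with a split field, each half (2-row and 6-row germplasm) has
its own check set.  Because checks are the only replicated material,
they carry all the information about field heterogeneity.

Two corrections are implemented.  Method 1 (M1) subtracts primary-check
block-row and block-column margins:

$$\mathrm{adj} = \mathrm{raw} - \overline{C}_{\mathrm{row}} -
  \overline{C}_{\mathrm{col}} + 2\,\overline{C}$$

M1 exactly annihilates any field surface of the form $f(\mathrm{row}) +
g(\mathrm{col})$ evaluated at block level — this is an algebraic
identity, and the test suite verifies the cancellation to machine
precision on zero-noise simulations.  Method 3 (M3) regresses
primary-check values on within-block secondary-check means and removes
the scaled block deviation:

$$\mathrm{adj} = \mathrm{raw} - b\,(C_{\mathrm{block}} - \overline{C})$$

M3 uses the block-level signal directly, so it can remove heterogeneity
that is not additive in rows and columns, at the price of injecting the
(single) primary check's plot error into every value of the block.

Whether to correct at all, and how, follows a two-criterion rule: a
two-way fixed-effect ANOVA of primary-check values on block-row and
block-column factors must find an effect at `alpha` (default 0.05, as
the procedure's sources report p-values without naming a level), and the
chosen method must achieve relative efficiency above one, where relative
efficiency is the mean per-secondary-check-entry variance of raw values
divided by the same for adjusted values.  Ties between M1 and M3 go to
M1, which needs no slope estimation.  All context terms are computed
within a single (year, check-set) stratum — the two field halves have
different check cultivars and are never mixed — and
`adjust_trait_table()` loops the rule over strata.  Two degenerate cases
are defined explicitly: identical check values yield missing ANOVA
p-values (treated as "no spatial effect"), and an adjusted
secondary-check variance of exactly zero reports an infinite relative
efficiency flagged as degenerate.

## Heritability, group letters, correlations

Broad-sense heritability uses line values observed in every environment
(year, or replicate), the additive fixed-effect ANOVA
`Trait ~ Env + Line`, and the mean-square identities
$V_g = (MS_{line} - MS_{resid})/n_{env}$ and
$H^2 = V_g / (V_g + MS_{resid}/n_{env})$.  Environments are fixed
effects; lines missing any environment are dropped and counted.
Negative $V_g$ (line mean square below the residual) is reported as
computed with a flag, not clamped — the estimator is unbiased around
zero for null traits and clamping would bias summaries.  The sampling
standard deviation of this estimator at 500 lines, two environments and
$H^2 = 0.5$ is about 0.045 (the mean-square ratio is
$2\,F(499, 499)$), which is worth keeping in mind when interpreting
single-trial estimates.

Group comparisons run one-way ANOVA, Tukey–Kramer pairwise tests (exact
for unequal group sizes via the studentized range), Benjamini–Hochberg
adjustment of the pairwise p-values, and an insert-and-absorb compact
letter display; two groups share a letter exactly when their adjusted
p-value is at least `alpha`.  Correlation matrices (Pearson or
Spearman) use pairwise-complete observations and mask coefficients with
p above `ns_alpha` (default 0.01, matching the "n.s." convention of the
field's trait-correlation tables).

## Tillering metrics and the trajectory embedding

Weekly mean tiller counts run from two to seven weeks past emergence.
The overall tillering rate is the maximum count divided by the week at
which that maximum is attained; when several weeks tie, the earliest
week is used, so the rate reflects the fastest attainment (the
definition does not disambiguate ties, and the early tie-break is the
conservative reading).  Finer rates are consecutive-week differences
and least-squares slopes over windows of at least three consecutive
weeks; windows with gaps return missing slopes rather than silently
interpolating.  Percent productive tillers is
$100 \cdot \mathrm{productive}/\mathrm{max}$ and may exceed 100 when a
late tiller heads after the last weekly count; values are reported, not
clipped.

The trajectory embedding builds the per-line feature vector (weekly
counts plus the productive count), computes Euclidean distances, and
applies classical metric scaling (double-centering and
eigendecomposition).  Features are not standardized by default — the
features share a scale (tiller counts), and standardizing would
up-weight the low-variance early weeks — but `standardize = TRUE` is
available.  Variance explained is each eigenvalue over the sum of the
positive eigenvalues.

## Regression variance partitioning

The tiller-number regression pipeline runs, in order: listwise deletion
of rows missing any used trait; a preliminary lmg pass whose only role
is to order predictors for reporting; bootstrap bidirectional stepwise
selection; a refit on the kept predictors; iterative Cook's-distance
pruning; a variance-inflation-factor check; and the final lmg
decomposition.

The lmg share of a predictor is its incremental $R^2$ averaged over all
$p!$ orderings of model entry — the Shapley value of $R^2$.  It is
computed exactly by subset enumeration (Shapley weights over the
$2^p$ lattice, algebraically identical to averaging orderings) up to 12
predictors, and by a seeded permutation sample (at least 5000 draws)
above that.  Shares are non-negative and sum to the full-model $R^2$ to
within $10^{-9}$; the unit tests verify the exact path against a
literal loop over all orderings with `lm()` refits.

Selection runs `stats::step` (AIC; BIC by option) from the full model in
both directions on each of `B` bootstrap resamples (default 1000) and
keeps predictors selected in at least 60 % of resamples.  The source
procedure reports inclusion frequencies without a cutoff; 0.6 demands a
clear majority while tolerating bootstrap noise, and is configurable.
"Refit until $R^2$ stops improving significantly" is operationalised as:
remove the single highest-Cook's-distance row, refit, and stop when the
improvement falls below `delta_R2_stop` (default 0.005) or 5 % of rows
have been removed — the cap guarantees termination and bounds the
fraction of data an outlier sweep may discard.  Predictors with
VIF > 5 on the final model raise a hard warning.

## Linkage disequilibrium

Pairwise LD is the squared Pearson correlation of minor-allele dosages
over pairwise-complete lines.  Background LD per chromosome is the 75th
percentile (type-7 linear interpolation) of r2 between that
chromosome's markers and all markers elsewhere; the quadratic pair count
is subsampled (2 x 10^6 pairs per chromosome, seeded) with an exact
mode for small inputs — subsample quantiles converge, which the tests
check by comparing against the exact value on small panels.

Chromosomal decay fits the drift-sampling expectation of r2 at
recombination intensity $C = \rho d$:

$$E[r^2] = \frac{10 + C}{(2 + C)(11 + C)}
  \left(1 + \frac{(3 + C)(12 + 12C + C^2)}{n(2 + C)(11 + C)}\right)$$

by nonlinear least squares (Levenberg–Marquardt, $\rho > 0$), with $n$
the number of lines.  The decay distance solves $E[r^2](d) =$
background by one-dimensional root finding; it is 0 when the curve
starts below background and capped at the largest observed distance
when the curve never crosses.  One caution established during
development: this expectation's tail falls off polynomially
($\sim 1/C + 1/n$), so when it is fitted to data whose LD decays
exponentially — as the package's own generator does — the fitted curve
systematically overestimates far-tail LD and the background crossing
lands well beyond the exponential curve's own 95 %-decay point.  Decay
distances from this model are therefore comparable between datasets fit
with the same model, but are not interchangeable with decay lengths
defined on other functional forms; the tests assert the sound relation
(fitted decay distance decreases as the generator's true decay rate
increases) rather than a cross-family equality.

Windowed profiles order a chromosome's markers by position, average r2
and pair-midpoint positions over non-overlapping 100-SNP windows (4950
pairs per complete window; a trailing partial window is flagged), and
smooth by LOESS with span 0.3 (the procedure names LOESS but no span; a
span of 0.3 resolves chromosome-arm-scale structure on a few dozen
windows).  Greedy tagging retains, per chromosome, the marker covering
the most untagged markers at r2 at or above the threshold (0.95),
repeating until all are covered, with deterministic position-then-id tie
breaks; minimum tag sets are NP-hard, so optimality is asserted only
against exhaustive search on small instances, where near-duplicate
structure makes the greedy solution optimal.  Thinning keeps markers in
a left-to-right scan whenever the gap to the last kept marker reaches
the requested spacing (e.g. the decay distance).

## Genotype QC, imputation, and the association scan

Marker filters drop markers whose missing-plus-heterozygous fraction
exceeds the platform threshold (0.5 for GBS, 0.2 for array data) or
whose minor allele frequency is below 0.03 — removal is strictly
less-than, so a marker exactly at the MAF cutoff survives.  After
platform merging and imputation a second pass refilters markers and
lines at 5 %.  The panel is inbred, so heterozygous calls are retained
as dosage 1 but counted against the heterozygosity thresholds.

LD-kNN imputation fills each missing call from the 20 markers in
highest r2 with the target (genome-wide; no distance cap), measuring
taxa distance as the mismatch fraction over those markers and taking an
inverse-distance-weighted vote among the 5 nearest lines with observed
calls; vote ties break toward the major allele.

The association scan is a fixed-effect, principal-component-corrected
single-marker regression: trait on dosage plus the leading PCs of the
centred dosage matrix, with the per-trait PC count (0 to `max_pcs`)
chosen by minimum BIC of the trait-on-PCs regression.  Compressed mixed
linear models with kinship are deliberately out of scope; the PC scan
covers structure correction in a transparent, testable way, which means
marker lists from kinship-model analyses are not directly comparable.
MAF cutoffs are 0.03 for the full panel and 0.05 for subsets (row-type
or photoperiod-allele groups, minimum 30 lines); significance is
Benjamini–Hochberg FDR at 0.05 by default (Bonferroni by option), as
the upstream significance convention is unstated.  Per-SNP percent
variance is the $R^2$ difference between models with and without the
marker.  The scan residualises trait and dosages on the covariates once
and then vectorises the per-marker regressions, so a 700 x 2000 scan
takes well under a second.

Significant markers merge into QTL by single-linkage clustering within
2 cM per chromosome; chains may therefore span more than twice the
cutoff, matching how multi-centimorgan intervals arise.  Two QTL from
different trait classes overlap when they share a chromosome and their
interval gap is at most the same cutoff; Venn cells are counted per
class of origin.

## The synthetic-data generator

The generator exists so that every stage above can be exercised, with
known truth, at the study's scale: a 56-block design split into two
28-block halves (768 test entries, one primary check per block at the
central plot, two secondary checks in each of 8 random blocks), or any
smaller layout.

Genotypes come from a latent copying chain: along a chromosome a line
carries a uniform value that is copied from the previous marker with
probability $e^{-\rho d}$ and refreshed otherwise, and the allele is
the indicator that the uniform falls below the marker's frequency.
Marker frequencies are uniform on `maf_range`; a two-subpopulation
mixture offsets frequencies by ±`structure_delta`.  The construction
has an exact closed-form pairwise r2 (`expected_pair_r2()`), used as
the generator-truth oracle, and within a population at equal
frequencies decays as $e^{-2\rho d}$.  Lines are fully inbred (calls 0
or 2); heterozygous and missing calls for QC tests are planted
explicitly.

Phenotypes are built per line from explicit loci (a row-type locus,
heading loci in days, standalone QTL whose *effect* is the mean
difference between homozygote classes) plus a polygenic term whose
variance is solved from the target broad-sense heritability,
$V_g = h^2/(1-h^2) \cdot V_e/n_{env}$, after subtracting the variance
the explicit loci already contribute — the target is met by
construction, not by rescaling realized data.  Weekly counts follow a
logistic rise to a genotype-specific asymptote (midpoint week 4, peak
week 6, 8 % weekly decline after the peak), with a plot-level vigour
noise shared across weeks, a small weekly measurement jitter, and
rounding to non-negative integers; the calibration accounts for the
jitter and rounding variances.  Productive counts multiply the maximum
by a line-plus-plot survival fraction.  Checks carry fixed genotypes
(the second half's checks are 6-row), so check-based adjustment can
never absorb genetic signal.

Field effects are block-level: additive row and column gradients and a
smooth surface, all evaluated at block positions, with plot-level
heterogeneity entering only through noise.  The smooth surface is a
sinusoid product at 0.7 periods across the block grid with a small
random phase jitter.  The frequency is deliberately incommensurate with
the grid: an exactly periodic surface has identically zero row and
column margins, which no physical fertility patch has, and would make
block-level heterogeneity invisible to the check ANOVA that gates the
adjustment decision.  In the multi-directional test scenario the
amplitude is set to four times the trait's residual SD so that
correction is unambiguously warranted.

A separate line-level generator, `simulate_mlr_panel()`, serves the
regression pipeline: standardized heading-date and seeds-per-spike
predictors carry exact population variance shares of the response
(response $= \sqrt{s_h}X_h + \sqrt{s_s}X_s + \sqrt{1-s_h-s_s}\,E$), and
the remaining predictors are pure noise, so the pipeline's summed
shares have a known target.

What the generator does not emulate — and what passing tests therefore
do not establish about real data: coalescent-accurate haplotype
structure (LD is exponential, not drift-shaped; see the decay-model
caution above), genotype-by-environment interaction beyond additive
year shifts, non-Gaussian trait residuals, spatial autocorrelation
below block scale, and measurement processes such as GBS allele-calling
error.

## Problem sizes and numerical choices

The shipped test-and-verification runs use: 28-block halves (376-500
lines) for adjustment scenarios, 200 seeded trials for the
method-selection majority, 50 two-year panels of 500 lines for
heritability recovery, 20 seeds of a 700-line panel (bootstrap B = 60
per seed) for the variance-partition recovery, 600 expectation-generated
pairs for decay-model recovery, and 50 replicates of a 700-line x
2000-marker scan for power; these sizes give Monte-Carlo error
comfortably inside each check's tolerance while keeping a full run in a
few minutes.  Root finding uses a 1e-10 tolerance on the decay-distance
bracket; the Levenberg-Marquardt fit starts at rho = 1 with a lower
bound of 1e-8 and 200 iterations; lmg enumeration is exact to p = 12
(4096 subsets).  Seeded determinism is end to end: identical seeds give
bit-identical designs, genotypes, phenotypes, and pipeline outputs.

## Known limitations

Kinship-aware mixed models, spline or AR(1) spatial field models, REML
variance components, haplotype-phase-aware LD, and candidate-gene
annotation are out of scope.  The ANOVA heritability estimator's
sampling noise at two environments is substantial (see above), and the
greedy tagger is an approximation with a coverage guarantee but no
global optimality guarantee beyond small instances.
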