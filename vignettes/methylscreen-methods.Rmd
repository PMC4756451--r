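---
title: "methylscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical models it
implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the choices made where the
design was genuinely open. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

# The measurement scale

A 450k probe reports β, the fraction of methylated copies, in [0, 1].
β is heteroskedastic (variance collapses near 0 and 1), so all linear
modelling happens on the logit scale, `M = log2(β / (1 − β))`, and
effect sizes are reported back on the β scale, where a difference has a
direct biological meaning. β is clipped to [0.001, 0.999] before the
transform — the bound at which M reaches about ±9.97 — so fully
(un)methylated probes stay finite. The two transforms are exact
inverses inside the clipping bounds (`betaToM()`, `mToBeta()`).

# Per-CpG differential methylation

For each probe, `fitProbeModels()` fits ordinary least squares of M on
NTD status (CON reference) plus additive sex (F = 0, M = 1) and
gestational age (weeks) covariates, using only that probe's non-missing
samples; probes sharing a missingness pattern are solved together, so
the computation is a handful of matrix cross-products even at 450k
scale. A probe needs at least `minPerGroup = 3` observations in both
compared groups, and a full-rank reduced design, to be reported for a
contrast.

Variance moderation (default on) shrinks the residual variances toward
an inverse-chi-square prior fitted across probes
(`limma::squeezeVar()`) and evaluates t on residual-plus-prior degrees
of freedom. The `moderated = FALSE` switch gives plain OLS t — used by
the calibration tests, because the OLS p values are exactly
t-distributed under the generator's Gaussian M-scale noise, which makes
a 1-million-p-value binomial check of the 5% level meaningful.

Effect sizes: `adjustedBeta()` removes the fitted sex and
gestational-age contributions *evaluated relative to the covariate
means* (so the grand level and the status effect are retained), then
transforms to β; `groupDeltaBeta()` takes missing-stripped group means
and subtracts the CON mean. The dual call (`callDM()`) requires
`q < 0.05` **and** `|deltaβ| ≥ 0.05`. The magnitude criterion is
two-sided by default — volcano plots of such studies show effects in
both directions — with a `twoSided = FALSE` switch. BH adjustment is
`stats::p.adjust(method = "BH")` with missing p values excluded from
the number of tests.

# Quality control

* **Identity.** Pairwise Pearson correlation across the trimodal SNP
  (rs) probes; samples of a multi-sample individual must find a
  same-individual nearest neighbour.
* **Sex.** Average-linkage clustering on chrX/chrY β; the cluster with
  higher mean chrY β is male. A between-cluster chrY gap below 0.1
  triggers a single-sex warning instead of a labelling.
* **Sample quality.** Three metrics: detection failures
  (p > 0.01), low-bead probes (< 3 beads), and mean detection p over
  *passing* cells (outright failures are already the first metric;
  including them would double-count and makes the mean hypersensitive).
  A sample is an outlier when any metric is more than 3 MADs from the
  across-sample median. The study this design follows reports that
  outlier samples were removed but not the rule; median ± 3·MAD is this
  package's documented choice. Count metrics get a scale floor of
  `sqrt(median + 1)` — counts are Poisson-like, and a collapsed MAD
  would otherwise flag every fluctuation.
* **Probe filters**, in order, each probe counted once: systemically
  poor (detection p > 0.01 or beads < 3 in > 20% of samples),
  sex-chromosome, polymorphic, cross-hybridizing. Masking then sets the
  remaining unreliable probe–sample pairs to missing; all downstream
  means strip missing values.
* **Replicates.** Technical replicates (same individual and tissue) are
  collapsed keeping the first by sheet order — deterministic, since
  nothing distinguishes the copies — and the pair correlation is
  reported so it can be tracked across pipeline stages.

# Batch adjustment

`ebBatchAdjust()` implements the parametric empirical-Bayes
location/scale model: per-probe standardization against the pooled fit
(covariates in `preserve` are protected), per-batch location (normal
prior) and scale (inverse-gamma prior) estimates shrunk by the
iterative solver, adjustment, and restoration of the grand location and
pooled scale. It is written in-package because the pipeline needs
missing-value support — masked cells are excluded from every estimate
and a probe-batch cell with fewer than two observations is an error
pointing to `dropUnderrepresented()`. On complete data it agrees with
the reference implementation in `sva` to numerical tolerance (a test
asserts this, with and without protected covariates). Degenerate
guards: when the across-probe spread of the batch estimates is zero
(noise-free data) shrinkage is disabled rather than producing NaN
priors, and scale estimates are floored at 1e-12.

`sequentialAdjust()` applies the correction once per variable in the
order plate → chip row → chip id. The order matters (the rounds do not
commute) and is recorded with each round's hyperparameters in
`metadata(mset)$batchReport`. Status, sex and gestational age are
protected by default; whether the original analyses protected them is
not stated, so this is a documented default with a `preserve` switch.

**Known limitation.** Removing batch structure and then testing the
adjusted data as if it were raw is mildly anti-conservative: the
adjustment consumes degrees of freedom and rescales residuals, which
downstream per-probe tests do not know about, and finite-sample
batch–group imbalance leaks a small correlated component into every
probe. The effect is visible in the package's own null simulations when
batch shifts are planted and corrected (~8–13% of p below 0.05 instead
of 5%), while the dual deltaβ criterion suppresses most of the
resulting calls. This is a property of the
correct-then-test design itself, faithfully reproduced; it is one
reason the persistence cascade exists.

# Genome-wide metrics

The array average is the missing-stripped mean adjusted β per sample.
The outlier-probe percentage is computed within tissue: a cell is an
outlier if it is more than 3 MADs from its probe's median; the count is
normalised by the sample's non-missing probes. The MAD uses the
normal-consistency constant 1.4826 by default (`constant = 1` gives the
raw MAD; the source this follows does not state its constant). Probes
with zero MAD are skipped — otherwise every non-identical value would
be flagged — and counted in the `zeroMad` attribute. Tissues with fewer
than three samples give a warning and missing metrics.

`permMannWhitney()` permutes group labels and scores each permutation
by the centred statistic `|U − n1·n2/2|`; the two-sided p is the
add-one-corrected fraction of permutations at least as extreme, so p is
never exactly zero and is bounded below by `1/(nPerm + 1)`. The
`exact = TRUE` mode enumerates all label assignments (used as the
oracle for n ≤ 8, where the two-sided conventions — centred statistic
vs doubling the smaller tail — agree on the canonical toy). Clinical
tables use plain Mann–Whitney (`wilcox.test`) for continuous and
Fisher's exact test (`fisher.test`, exact for 2×k) for categorical
variables.

# Regions and enrichment

`findDMRs()` is a bump-hunting scan over the stated region definition:
per chromosome, coefficients are smoothed with a 3-probe running mean
(partial windows at the edges), and maximal runs of same-sign smoothed
coefficients above a threshold, with inter-probe gaps ≤ 300 bp and ≥ 3
members, become regions scored by area (sum of |smoothed
coefficient|). The original tool's internal smoothing/regression
machinery is not reproduced — the published criteria specify the region
definition, not that tool's internals. The default threshold is the
75th percentile of |smoothed coefficients|, recomputed per call and
held fixed across permutations. Probes are sorted internally, so the
result is input-order invariant, and scaling coefficients and threshold
by the same positive constant leaves the segmentation unchanged.
`dmrQvalues()` permutes status labels within tissue, rebuilds the
per-probe coefficients and rescans at the *observed* threshold; the
empirical p of a region is the add-one-corrected fraction of
permutation *maximum* areas reaching its area (a max-statistic,
family-wise null — conservative by construction), followed by BH across
regions.

Gene-set enrichment: `geneScoreResampling()` scores each gene by its
best probe (−log10 p), each set by the median member score, and builds
the null by resampling equally sized gene draws from the background
(defaults: sizes 10–200, best-score gene replicates, median class
score; 10,000 iterations by default with the published 200,000
available by argument). `ora()` is the hypergeometric upper tail.
`featureEnrichment()` is a 2×2 Fisher test per genomic feature against
the clean-probe background, with direction from the odds ratio.

# The persistence cascade

Starting from the FDR-significant sites of the internal comparison,
four ordered filters: (1) the |deltaβ| ≥ 0.05 magnitude criterion;
(2) the post-hoc covariate filter; (3) control concordance; (4)
external replication. Survivor sets are nested by construction and the
report records every count and per-probe removal stage.

Two design choices deserve explanation:

* **Filter 2 threshold.** For each hit, the status effect is removed
  and the residuals are F-tested against each covariate (gestational
  age, sex, plate, chip, row). Applying a nominal α = 0.01 to each of
  five covariates separately gives a ~5% per-probe false-removal rate,
  which would dominate the filter's removals on realistic hit lists.
  The default therefore Bonferroni-corrects the per-probe minimum p
  across the covariates tested and applies α = 0.01 to that
  (`adjust = "none"` restores the per-covariate rule). The published
  analysis states no threshold; this is a documented stand-in.
* **Filters 3–4 use Welch statistics.** The external cohort is small
  (five controls in the motivating study) and carries its own variance
  structure. A pooled-variance t lets the large internal group dominate
  the variance estimate and is badly anti-conservative exactly when the
  small external group is the variable one (the Behrens–Fisher
  situation), and cross-cohort moderation would shrink genuinely
  unstable probes' variances toward the array-wide prior, inflating
  their t. Per-probe Welch t with Satterthwaite degrees of freedom is
  the defensible choice; the filters are therefore not configurable on
  this point.

`supervisedCluster()` restricts average-linkage clustering to the hit
probes and reports the adjusted Rand index of the two-cluster cut
against status.

# The synthetic-data generator

`generateDataset()` draws everything from one seeded stream in a fixed
documented order, so identical configurations reproduce bit-identical
datasets and configurations differing only in planted effects share all
other draws (planted shifts are deterministic). The defaults are the
study conditions of the cohort this pipeline was designed around: 19
CON / 22 SB / 15 AN individuals, per-group male fractions 7/19, 16/22
and 5/15, gestational ages uniform on the groups' reported ranges
(14.5–23.9, 19.4–23.7 and 16.7–23.3 weeks), 65 rs probes, three
plates, twelve-sample chips with six rows, and two technical replicate
pairs.

What it emulates: the canonical bimodal β distribution (three-component
mixture, modes near 0.05 and 0.95, weights 0.4/0.2/0.4); probe-specific
noise on the M scale (sd 0.45 scaled by a chi-square draw with 10
degrees of freedom, giving the realistic heavy spread of probe
variances); group effects specified as target β-scale differences and
applied as the equivalent additive M shifts; sex and gestational-age
covariate effects; probe-invariant batch location shifts (plate ±0.2 M,
row and chip ±0.1 M at the extreme levels); island-like probe
clustering along chromosomes; gene annotations with multi-gene and
empty gene fields; trimodal rs genotypes identical within an
individual; chrX compression toward 0.5 in females and background-level
chrY signal; sporadic detection and bead failures (0.1% of cells);
technical replicates with 0.1 M technical noise.

What it does not emulate: raw two-colour intensities, type I/II probe
chemistry, probe-specific batch sensitivity, cell-composition
heterogeneity, spatial chip artefacts, or correlated methylation
between neighbouring probes (planted DMR blocks are block-shifts, not
smoothly varying signals). Passing tests therefore validate the
statistical machinery under a clean generative model, not robustness to
every artefact of real arrays.

A planted β-scale effect is only realisable where the baseline leaves
room — a +0.15 shift at a 0.95 baseline is clipped away — so validation
experiments plant effects at probes whose (deterministically
reproducible) baselines lie in mid-range windows.

`simulateCascadeScenario()` builds the four-class validation scenario
for the cascade at the kidney cohort's sizes (16 CON, 20 SB, 5 external
controls): `true_effect` probes carry a consistent Δβ = 0.25 shift;
`batch_driven` probes acquire their apparent status effect through a
plate shift combined with moderate plate–status confounding of the
layout (sampling weights 0.7/0.2/0.1 vs reversed); `cohort_shift`
probes shift the external controls by 0.3; `internal_only` probes are
*unstable* in the external cohort — external values midway between the
internal groups with 1.2 M noise. The instability modelling is forced
by arithmetic: the three pairwise group contrasts are linearly
dependent, so a probe cannot simultaneously separate SB from CON,
match the external controls to both, and be removable only at the
replication stage — non-replication must come through external
variance or low power, which is also how it arises in practice.

# Validation problem sizes

The test suite validates null calibration on 200 datasets of 5,000
probes × 40 samples (pooled binomial check of the 5% level at its 99%
confidence half-width), recovery of 500 planted Δβ = 0.15 effects at
n = 20/group, DMR detection against a 1,000-permutation null on 400
probes × 24 samples, the cascade scenario at 4,000 probes, and one full
end-to-end run at 50,000 probes × 60 samples covering QC, sequential
batch adjustment, differential methylation, genome-wide metrics, DMR,
enrichment and the cascade. Per-stage cascade precision and recall are
measured against the planted class members that reach each stage, since
a stage can only remove what earlier stages passed through.

# Known limitations

* The correct-then-test inflation discussed under batch adjustment.
* The max-statistic DMR null is family-wise and conservative for
  secondary regions.
* Gene-score-resampling ignores gene multifunctionality and probe-count
  bias beyond best-score collapsing.
* The sample-quality outlier rule, the post-hoc covariate threshold and
  the ComBat covariate-protection default are documented stand-ins for
  choices the motivating study does not state; all are exposed as
  arguments.
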