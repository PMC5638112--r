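---
title: "Copy-number analysis of a hybrid lineage: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number analysis of a hybrid lineage: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridCNV)
```

# The scientific problem

Homoploid hybrid lineages — admixed populations with the same ploidy as
their two parental species — are a natural experiment in structural-genome
evolution: do gene duplications, deletions and transposable-element
amplifications accumulate after hybridization, and do they preferentially
amplify material from one ancestor? `hybridCNV` implements a three-arm
analysis of this question for a design with two parental species
(`parentA`, `parentB`), an admixed lineage, and laboratory F2 crosses:

1. **Gene arm (aCGH).** Two-colour comparative genomic hybridization
   arrays compare each test genome (Cy5) against a common diploid
   reference (Cy3). Copy-number differences appear as shifts in the
   normalized log2 intensity ratio.
2. **Repeat arm (read counts).** Whole-genome reads mapped against a
   library of repetitive elements give per-element counts per individual;
   counts-per-million (CPM) comparisons between groups detect element
   amplification.
3. **Validation arm (ddPCR).** Droplet digital PCR with a single-copy
   reference gene yields absolute copy numbers for candidate loci, used
   both to validate array candidates and to screen F2 individuals for de
   novo changes.

Because the original raw data are array images and sequencing runs, the
package ships a first-class synthetic-data generator that reproduces the
*statistical structure* of every input, so the full pipeline is testable
end to end and its operating characteristics (sensitivity, false discovery
rate, estimator bias) can be measured against known truth.

# The gene arm

## Probe calibration

Each probe's fluorescence response is calibrated on a dilution series of
eight DNA amounts (25, 50, 100, 200, 400, 800, 1,200, 1,600 ng; two
replicate features per probe). Per probe and channel an ordinary
least-squares line

$$\text{signal} = \text{intercept} + \text{slope} \cdot \text{DNA}$$

is fitted on the linear scale. Quality control removes three failure
classes:

* **unresponsive** — slope not significantly positive (one-sided t-test,
  $\alpha = 0.05$);
* **nonlinear** — coefficient of determination $R^2 < 0.95$;
* **low signal-to-error** — fitted signal at the top dilution divided by
  the residual standard error below 10.

The signal-to-error ratio is not a universally standardized quantity; the
definition above is scale-free and penalizes exactly the noisy probes the
screen is meant to remove. A probe must pass in *both* channels.

Among a gene's passing probes, the one whose **log–log response slope** is
closest to 1 is retained: on that scale a slope of 1 means the signal is
proportional to input DNA, which is the property that makes ratio-based
copy-number inference clean. (The raw a.u./ng slope cannot be "close to 1"
in any scale-free sense, so the log–log reading is used; the two channels'
slopes are averaged.) Ties are broken by lexicographically smaller probe
id, so selection is deterministic.

Observed experimental intensities are then back-transformed into DNA
equivalents,
$$\mathrm{DNA}_{\mathrm{cal}} = (\text{observed} - \text{intercept}) / \text{slope},$$
which removes probe-specific binding behaviour. Non-positive calibrated
values (possible when an observed signal falls below the fitted intercept)
are clamped to half the smallest positive calibrated value on that array
and flagged, so downstream logarithms are always defined.

## Spatial artifacts and replicate summarization

Hybridization bubbles depress intensities in contiguous regions. Regions
are described as polygons in grid coordinates; every feature inside or on
the boundary of a polygon is masked (boundary-inclusive ray casting —
removing a borderline feature is the conservative choice). Masking is
idempotent. Among the surviving replicates of a probe on an array, Tukey
fences ($Q_1 - 1.5\,\mathrm{IQR}$, $Q_3 + 1.5\,\mathrm{IQR}$; type-7
quartiles) drop outlying intensities per channel; fences are skipped below
three values, where quartile fences are meaningless. The survivors are
averaged. Probes losing all replicates on an array are simply absent
there.

## Normalization

Per array, $M = \log_2(\mathrm{DNA}_{\mathrm{cal}}^{\mathrm{test}} /
\mathrm{DNA}_{\mathrm{cal}}^{\mathrm{ref}})$ is regressed on
$A = \tfrac12(\log_2 \mathrm{DNA}_{\mathrm{cal}}^{\mathrm{test}} +
\log_2 \mathrm{DNA}_{\mathrm{cal}}^{\mathrm{ref}})$ with a robust LOESS
(span 0.3, four total fitting passes, i.e. three bisquare reweights, local
linear, no background correction; the fit is delegated to
`limma::loessFit`, the standard implementation of exactly this smoother).
The residuals are the normalized log2 ratios. With fewer than 50 (M, A)
pairs a LOESS fit is not meaningful and the array falls back to
median-centering with a warning.

## Tests and calls

Copy-number differences between the admixed group and the combined parents
use two-sample Wilcoxon rank-sum tests per probe with Benjamini–Hochberg
FDR control across probes, significant at $q < 0.05$, with the direction
taken from the sign of the group mean difference. The rank-sum engine is
exact (null distribution of the Mann–Whitney U) for combined sample sizes
up to 25 without ties — which covers the 8-vs-16 design exactly — and
otherwise uses the normal approximation with tie and continuity
correction, matching `stats::wilcox.test` conventions (the tests verify
that equivalence directly).

Threshold calls label a gene a putative duplication when *any* individual
exceeds a log2 cutoff (strictly), a putative deletion when any individual
falls below its negative; a gene can be both. Cutoffs 0.5 and 0.4 are the
defaults. Distributional asymmetry between gains and losses is tested with
a D'Agostino (1970) skewness test on the per-probe difference of group
means (the transformation is implemented from the published formulas and
checked against an independent implementation to $10^{-6}$; it requires
$n \ge 8$). Variance structure is compared per probe with a one-sided
F-test of the variance ratio by default; a Levene-style engine (one-sided
Welch t-test on absolute deviations from the group median) is provided as
a robust alternative, because "t test on variances" admits both readings.

# The repeat arm

Counts of reads mapped to each of the library's elements are normalized to
$\mathrm{CPM} = \text{count} / \text{total reads} \times 10^6$, which
removes sequencing-depth differences exactly (the tests assert full
invariance of all p-values under depth rescaling). One-tailed rank-sum
tests (admixed above combined parents), BH-corrected across elements,
define increase candidates at $q < 0.05$; the opposite tail yields
decrease candidates. Within the candidate set, both one-tailed parental
contrasts (B > A and A > B) are BH-corrected *within the candidate set* —
the decomposition is a sequential analysis of an already-selected set, so
the family is the candidate set. The mean relative increase of candidates
is $100 \cdot (\bar{c}_{\mathrm{admixed}} -
\bar{c}_{\mathrm{parents}})/\bar{c}_{\mathrm{parents}}$ averaged
unweighted over candidates, excluding (and counting) elements whose
parental mean is zero.

Composition summaries count candidates per TE class (Class I
retrotransposons, Class II DNA transposons, host genes, unclassified) and
per Wicker-style order, with percentages rounded half-up to one decimal —
the convention used for printed report tables. Class representation is
tested with Fisher's exact test, implemented as the exact hypergeometric
enumeration (sum of all tables at fixed margins whose probability does not
exceed the observed table's) and validated against brute-force enumeration
over all small tables.

## Power: what a ~30% shift can and cannot do

With negative-binomial dispersion 0.05, per-individual counts have a
coefficient of variation of at least $\sqrt{0.05} \approx 22\%$ no matter
how deep the sequencing. A +30% group shift against that noise gives a
one-tailed 10-vs-20 rank-sum test an AUC near 0.80, and after BH
correction across ~1,000 elements the per-element power lands near 50–60%.
The acceptance script measures exactly this: recovered sensitivity sits
around 0.5, with empirical FDR well under 0.05. This is a property of the
design (group sizes, dispersion, effect size), not of the implementation;
detecting individual 30% abundance shifts reliably at these sample sizes
would require either lower biological dispersion or larger groups. Results
on such data are therefore best read as a conservative candidate screen —
the false-discovery side is controlled tightly, while weak effects go
undetected.

# The ddPCR arm

Droplet digital PCR partitions a reaction into ~20,000 droplets of
~0.85 nL. With a positive-droplet fraction $f$, the Poisson correction
gives the mean template load per droplet $\lambda = -\ln(1 - f)$ and the
concentration $\lambda / V$. The copy number per diploid genome is
$2 \cdot c_{\mathrm{target}} / c_{\mathrm{reference}}$ against a
single-copy reference gene; droplet volume cancels in the ratio, so the
volume default matters only for reporting concentrations. Saturated wells
(all droplets positive) are an error, not an infinity. Group differences
use one-way ANOVA with Tukey HSD post-hoc pairs (`stats::aov` /
`stats::TukeyHSD`; the F statistic is verified against a direct
sums-of-squares computation in the tests).

The F2 de novo screen flags an individual whose estimated copy number
falls outside the parental range of the same assay widened by a margin of
one copy on each side. The margin reflects that assays are integer-like
(copies per diploid genome) while estimates carry sampling noise; it is
configurable.

# The synthetic-data generator

The generator is the package's study-conditions oracle; every downstream
module consumes only its outputs. Defaults encode the experimental design
the pipeline targets:

| parameter | default | meaning |
|---|---|---|
| `dilution_levels_ng` | 25…1,600 (8 levels) | calibration series |
| `n_replicates_calibration` / `experiment` | 2 / 5 | features per probe per array |
| `n_genes` | 12,105 | probes on the experimental array |
| `group_sizes` | 8/8/8 | array cohort |
| `divergence_fraction` | 0.159 | genes with parental CN divergence |
| `ancestry_bias` | 0.6 | P(admixed allele from parent B) |
| `cn_effects` | 12 genes at CN 3; 13 at CN 1 | lineage-fixed admixed effects |
| `n_elements` | 1,005 | repeat library size |
| `element_effect_fraction` / `size` | 0.207 / 0.305 | increased elements, mean relative increase |
| `total_reads_distribution` | lognormal around 2×10⁶ | sequencing depth |
| `nb_dispersion` | 0.05 | count overdispersion |
| `droplet_count` / `droplet_volume_nl` | 20,000 / 0.85 | ddPCR partition model |

Design choices worth knowing:

* **Noise is additive Gaussian on linear-scale intensities** (negative
  draws clamped at zero). Scenario noise is usually specified on the
  log2-ratio scale; `noise_sd_for_m_sd()` converts a target per-feature
  M-scale standard deviation into the intensity-scale value via
  $\mathrm{sd}(M) \approx \sqrt{2}\,\sigma/(S \ln 2)$ at the design's
  typical signal $S$.
* **Per-locus representation.** On experimental arrays every probe gets a
  lognormal multiplier (sdlog 0.6) on the effective DNA of *both*
  channels. This models locus-to-locus differences in genomic
  representation and hybridization efficiency: it spreads the average
  intensity A over several log2 units — as real two-colour data show —
  while leaving M untouched. Without it, calibration collapses all probes
  onto nearly the same A and an intensity-dependent smoother would absorb
  genuine copy-number signal.
* **Admixed individuals are independent ancestry mosaics**: each
  individual inherits each gene's state from parent B with probability
  0.6. The injected `cn_effects` sets are lineage-fixed (shared by all
  admixed individuals), which is what makes them detectable as
  group-level differences. A lineage-fixed mosaic for *all* genes would
  make every divergent gene a near-certain discovery in the
  admixed-vs-parents contrast, contradicting how such cohorts behave.
* **Bubbles are simulated as ×0.2 multiplicative attenuation**, not
  missingness, so masking is a real decision downstream; the default
  places a central octagon covering ~30% of the grid on the first nine
  arrays (~11% of all features).
* **Dye bias** is injected as a polynomial in A added to M
  (symmetrically into the two channels), so LOESS normalization is
  exercised rather than decorative.
* **Counts are negative binomial** with configurable dispersion
  (dispersion 0 falls back to Poisson); per-element relative increases
  are uniform within ±25% of the configured mean. Parentally biased
  elements get a 1.5× ratio between the high and low parent.
* **All randomness flows from one seed through named substreams**, so the
  generators are mutually independent and individually bit-reproducible;
  the caller's RNG state is saved and restored.

What the generator does *not* emulate: probe sequence effects and
cross-hybridization, spatial intensity gradients other than bubbles,
GC-dependent sequencing bias, mapping ambiguity between related repeat
families, and droplet-volume variability. Passing parameter-recovery tests
on synthetic data therefore demonstrates the statistical machinery is
correct and calibrated under the modelled noise — not that any particular
real dataset satisfies the model.

# Numerical conventions

* Quartiles: type 7 (linear interpolation), fixed for reproducibility.
* Outlier fences interpreted as Tukey fences around the quartiles; the
  fence multiplier (1.5) is configurable in the pipeline configuration.
* Rank-sum exact/approximate switch at combined n = 25; mid-ranks for
  ties; continuity correction in the approximation.
* Percentages in report tables: half-up rounding to one decimal.
* Probe selection and all set operations are deterministic (lexicographic
  tie-breaks).
* LOESS `iterations = 4` means four total fitting passes (three
  robustifying reweights) — the convention of the underlying
  implementation.
* The skewness input vector is the per-probe difference of group means;
  pooled per-individual ratios are a plausible alternative reading, and
  the function accepts any numeric vector.

# Problem sizes used by the checks

The test suite runs the full gene arm at 12,105 probes × 24 arrays over 20
simulation replicates (a few minutes on one core), the repeat arm at 1,005
elements × 30 individuals over 20 replicates, and the ddPCR consistency
checks at 5k/20k/80k droplets × 200 replicates. Unit tests use scaled-down
configurations (typically 120 genes, 60 elements) chosen to keep the suite
fast while still exercising every code path; the statistical acceptance
checks are the ones that need realistic scale.

# Known limitations

* The pipeline calls per-probe CNV only; it performs no segmentation
  along chromosomes (probes are exon-level and unordered here).
* The calibration model is linear in DNA amount; probes whose true
  response saturates within the dilution range are excluded rather than
  modelled.
* Per-probe calibration noise propagates into a probe-specific constant
  offset of normalized ratios (identical across arrays); it cancels in
  all between-group contrasts but means single-array log2 ratios carry a
  probe-level bias floor set by the calibration design.
* The repeat arm's rank tests control FDR tightly but, at the default
  design, have limited power for shifts near 30% (see the power note
  above).
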