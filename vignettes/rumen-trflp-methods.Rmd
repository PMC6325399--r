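---
title: "Methods: T-RFLP fingerprinting, qPCR quantification and split-plot statistics"
author: "rumenTRFLP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T-RFLP fingerprinting, qPCR quantification and split-plot statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenTRFLP)
```

# Scope

`rumenTRFLP` implements the computational path of a comparative rumen
microbiome study design: three ruminant species (a beef breed, a dairy
breed, and a goat), four animals per species, each sampled under a
high-forage (HF) and then a high-concentrate (HC) diet. Three kinds of
measurements flow through the package:

1. **T-RFLP electropherograms** — tabulated peaks (terminal restriction
   fragment size in bp, height in RFU) per sample, processed into a
   standardized bins-by-samples community profile, per-sample diversity
   indices, and ordination summaries;
2. **qPCR Ct tables** — replicate quantification cycles per sample and
   target taxon, converted to relative abundances as a percentage of
   total bacteria and summarized as diet fold changes;
3. **fermentation records** — pH, NH~3~-N, and VFA variables per
   animal-by-diet observation, analyzed with the classic balanced
   split-plot ANOVA and Tukey pairwise comparisons.

Because raw electropherograms from such studies are rarely deposited,
the package also carries a first-class synthetic-data generator with
known ground truth; all recovery properties quoted below are measured
on its output.

# True-peak detection

A sized electropherogram contains a handful of genuine community
fragments on top of many low instrument-noise peaks. After discarding
fragments outside the reliable sizing window (inclusive bounds, default
27–520 bp), `detect_true_peaks()` applies an iterative rule:

* the background height distribution is assumed to have **true mean
  zero**, so its scale is estimated as the root mean square of the
  heights still in the pool, $\hat\sigma = \sqrt{\sum_i h_i^2 / n}$
  (divisor $n$, not $n-1$, because the mean is known rather than
  estimated);
* every pooled peak with height strictly greater than
  $k\hat\sigma$ (default $k = 3$) is declared true and removed;
* the estimate and threshold are recomputed over the remainder until an
  iteration declares nothing (a cap of 100 iterations guards
  pathological inputs and is reported as non-convergence).

While large peaks remain in the pool they inflate $\hat\sigma$, so the
rule peels peaks off from the top down; the reported `final_sd` is the
background scale after the last sweep.

Two structural properties of this rule are worth knowing:

* **Detectability requires sparsity.** For $k$ true peaks of a common
  height $H$ among $n$ pooled peaks, the first-pass threshold is about
  $3H\sqrt{k/n}$, so equal-height true peaks are only detectable when
  $k/n < 1/9$. A profile that is "all signal" (for instance a noise-free
  uniform community with no background) yields *no* true peaks: the rule
  needs a dominated background to calibrate against. The generator's
  defaults (≤ 20 planted taxa over 200 background peaks) respect this
  condition with margin.
* **An unbounded background implies a false-positive floor.** With
  background heights drawn from any distribution with unbounded support
  (here half-normal), the expected number of background peaks above
  $3\hat\sigma$ is about $0.003 n$ per sweep — roughly 0.5 spurious
  "true" peaks per 200-background sample, irrespective of
  implementation. Spurious bins carry a negligible share of the
  standardized mass (they are bounded near the threshold while genuine
  peaks are an order of magnitude higher), so the package's recovery
  tests assert completeness of the planted community and abundance
  accuracy rather than an exact set match.

# Binning and standardization

`bin_fragments()` pools all true-peak fragment lengths across samples,
sorts them, and chains consecutive lengths whose gap is at most
`tolerance_bp` (default 0.5 bp) into one bin — a single pass over the
sorted pool. The bin representative is the arithmetic mean of its
*distinct* member lengths: a length observed identically in several
samples counts once, so duplicates do not drag the representative. Within
each sample, heights of peaks in the same bin are summed.

Two genuinely open choices were settled as follows. The source
description of duplicate handling is ambiguous between de-duplicating
lengths before averaging and discarding singleton fragments; the package
de-duplicates within bins and keeps singletons, which loses no data and
preserves the "average length" reading. The chaining tolerance is not
stated anywhere; 0.5 bp matches typical capillary sizing precision and
is exposed in the configuration. Note that chaining can in principle
link a run of lengths wider than the tolerance end-to-end; with the
generator's enforced minimum spacing of twice the tolerance between
planted fragments this does not arise in testing.

`standardize()` divides each sample column by its summed height, so
values are within-sample relative abundances. A sample with no true
peaks stays all-zero and is flagged rather than dropped.

# Diversity

For a relative-abundance vector $p$, `shannon()` returns
$H = -\sum_{p_i > 0} p_i \ln p_i$ and `inverse_simpson()` returns
$D = 1/\sum p_i^2$. The Shannon logarithm base is not fixed by
convention in fingerprinting software; natural log is the default and
the base is configurable. No rarefaction or coverage correction is
applied — peak heights are not counts, and the upstream standardization
is the only normalization. The Hill-number ordering
$e^H \ge D$ holds for every valid input and is enforced as a property
test. All-zero profiles have undefined diversity and return `NA`.

# Ordination

Samples are compared by Euclidean distance between standardized
profiles, clustered by complete linkage (smallest maximum inter-cluster
distance; merge heights are non-decreasing), and ordinated by PCA with
samples as observations and bins as variables. The PCA **centers but
does not rescale** variables — the profiles are already on a common
relative-abundance scale, and variance-scaling near-constant bins would
amplify noise. Variance explained is reported as
$100\,\lambda_k/\sum_j \lambda_j$.

Reproducibility details the method descriptions leave open are pinned
by convention: each principal component's sign is chosen so its
largest-magnitude loading is positive, and clustering ties follow the
deterministic agglomeration order of `stats::hclust`. Dendrograms are
serialized as Newick with branch lengths equal to parent–child merge
height differences.

# qPCR relative quantification

Replicate Ct values are aggregated by arithmetic mean — the convention
for $\Delta C_t$ methods, since Ct is already a log-scale quantity — and
a replicate SD above 0.5 cycles raises a QC flag. Relative abundance is
$100 \times 2^{-\Delta C_t}$ with
$\Delta C_t = C_t^{\text{target}} - C_t^{\text{total}}$, assuming
perfect doubling per cycle (no efficiency correction, matching the
base-2 form of the transform). A target amplifying earlier than the
total-bacteria assay yields an abundance above 100%; it is flagged,
never clamped, because the raw transform is the right quantity for QC.

Fold changes between diets are computed per species or across species,
as a ratio of group means (default) or a mean of per-animal ratios —
published "x-fold" statements do not always say which, so both are
available. Presentation rounding is nearest integer, and nearest hundred
above 1,000. On the shipped reference group means, the across-species
ratio of means reproduces the study-style readings: a 39-fold
*Lactobacillus* increase, a 13-fold *F. succinogenes* decrease in goats
and 12-fold on average, and an *M. elsdenii* increase exceeding
1,000-fold (the computed ratio is 1,636; its source rounds it to
"approximately 1,700").

# Split-plot analysis

Fermentation, diversity and abundance responses follow the model
$$y_{ijk} = \mu + \tau_i + b_{j(i)} + \rho_k + (\tau\rho)_{ik} + e_{ijk},$$
with species $\tau$ a whole-plot fixed effect, animal-within-species
$b_{j(i)}$ random, diet $\rho$ and the interaction sub-plot fixed
effects. On a balanced design (equal animals per species, every animal
on every diet equally often) the classic split-plot decomposition is
exact: species is tested against the animal-within-species mean square,
diet and species-by-diet against the residual. This coincides with
REML-based mixed-model F tests (including small-sample df adjustment)
on balanced data, which is why the package uses the closed
decomposition rather than a general mixed-model engine. **Unbalanced
input is rejected with an explicit error** directing the user to a
general mixed-model tool — approximating the decomposition on, say, a
design with a lost sample would silently change the hypotheses tested.

Variance components are reported from the expected mean squares
($\hat\sigma^2_e = MS_{res}$,
$\hat\sigma^2_{animal} = (MS_{animal} - MS_{res})/n_d$); a negative
animal component is reported as computed, not truncated. When an error
mean square is zero to rounding (exactly replicated data), the affected
F is reported as infinite with p = 0 and the fit is marked as
overflowed.

Tukey pairwise comparisons use the studentized range distribution
(`stats::ptukey`, computed numerically — no lookup tables) on the error
stratum of the effect being dissected; the package compares
species-by-diet cell means against the sub-plot residual stratum.
Reporting conventions follow the field: p < 0.05 significant,
0.05 ≤ p < 0.1 a trend. Each response is analyzed independently with no
multiplicity correction across responses.

# The synthetic-data generator

The generator exists to make every downstream stage testable against
known truth; its defaults are fixed once and are the conditions under
which all quoted operating characteristics were measured.

* **Community**: fragment lengths uniform in the 27–520 bp window with a
  minimum spacing of twice the binning tolerance (rejection sampling),
  so bins map one-to-one to planted taxa. Abundance models: uniform
  (default), geometric, broken-stick.
* **Peaks**: true peak height is `signal_scale` × abundance × (1 +
  multiplicative Gaussian noise with CV 2%, a typical replicate height
  reproducibility for capillary runs); `signal_scale` = 5,000 RFU.
  Background: 200 peaks at uniform-random sizes with heights
  $|N(0, 15)|$. The half-normal keeps heights positive (RFU) while
  preserving the zero-anchored scale that the detection rule estimates —
  the distributional form of real instrument noise is not published, so
  this is a stand-in chosen for that property, not an inference about
  the instrument. The configuration enforces
  `signal_scale > 10 × background_scale` so planted peaks are
  recoverable; under the defaults the smallest planted peak exceeds
  three background SDs in over 99% of seeds.
* **Ct tables**: a taxon at $a$% of total amplifies
  $\log_2(a/100)$ cycles late; replicate noise SD 0.3 cycles (a typical
  SYBR triplicate scatter), three replicates, and a total-bacteria
  record always emitted. At zero noise the round trip through
  `abundance_table()` is exact; at positive noise it is unbiased on the
  $\Delta C_t$ scale.
* **Fermentation**: balanced 3 species × 4 animals × 2 diets with
  additive fixed effects, animal intercepts $N(0, \sigma^2_{animal})$
  and residuals $N(0, \sigma^2_e)$. The study-like dataset plants the
  shipped reference group means as cell means, with animal and residual
  SDs of 5% and 2% of each response's grand mean — coefficients of
  variation in the range reported for repeated rumen measurements.
* **Seeding**: one global seed fans out to per-stream sub-seeds by fixed
  offsets (`sub_seed()`), so adding or reordering one stream never
  perturbs another, and identical seeds give bit-identical output.

What the generator does **not** emulate: dye pull-up, stutter and
size-standard artifacts; the merging of multiple restriction digests
into one profile (each input table is processed independently);
phylogenetic structure linking fragments to taxa; and realistic
long-tailed rumen abundance distributions (the uniform default is
chosen for unambiguous recovery, not realism). Passing recovery tests
therefore demonstrate the correctness of the processing chain, not
field performance on real electropherograms.

# Numerical and testing choices

* Detection is invariant to peak order and to uniform height rescaling;
  raising `k_sd` never adds true peaks. Both are enforced as property
  tests, and the iterative rule is checked against an independent
  brute-force loop on 1,000 random tables.
* End-to-end recovery (simulate → filter → detect → bin → standardize)
  is measured over 200 seeds at 5–20 planted taxa: every planted length
  must appear among bin representatives within the tolerance and every
  planted abundance must be recovered within 2 percentage points.
* Ordination (distances, merge structure, PCA eigenvalues, score
  isometry) is verified against brute-force references at 10^-8^.
* Split-plot sums of squares are verified against a cell-means oracle at
  10^-8^; the diet test's type-I error (null, $\sigma_{animal} = 0.3$,
  $\sigma_e = 0.1$, 4 animals/species) and power (diet effect
  $2\sigma_e$) are measured over 2,000 simulations each. Tukey adjusted
  p-values are compared with a 10,000-shuffle permutation of cell
  residuals.
* Problem sizes throughout (200 recovery seeds, 1,000 oracle tables,
  2,000 Monte-Carlo fits, 10,000 shuffles) are the package's chosen
  compromise between Monte-Carlo error and a test suite that runs in
  about a minute.

# Limitations

* The package computes diversity and ordination for *new* data; the
  original study's printed diversity values and ordination geometry
  cannot be reproduced because its raw electropherograms were never
  deposited.
* `split_plot_anova()` deliberately supports balanced designs only; the
  unbalanced case (e.g. one damaged sample) requires an external
  mixed-model fit, and the package does not guess at one.
* Multi-enzyme digests are treated as independent profiles; no fusion
  rule is offered because none is established.
* The qPCR model fixes amplification efficiency at 2; assays with
  calibrated efficiencies need a correction upstream of this package.
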