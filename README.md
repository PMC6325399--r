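# rumenTRFLP

A tested R pipeline from raw T-RFLP fragment peak tables and qPCR Ct
values to microbial community diversity, community-structure ordination,
relative bacterial abundances, and species-by-diet statistics for rumen
fermentation variables.

## Who this is for

Rumen microbiologists (and fingerprinting users generally) who have:

* **peak tables** exported from fragment-analysis software — per sample,
  terminal restriction fragment size (bp) and peak height (RFU);
* **qPCR Ct tables** — replicate quantification cycles per sample and
  target taxon, including a total-bacteria assay;
* **fermentation records** — pH, NH₃-N, VFA variables per
  animal-by-diet observation from a species × diet design with repeated
  measures on each animal.

The motivating design is a diet-switch (acidosis induction) trial: three
ruminant species × four animals × two diets (high forage HF vs high
concentrate HC).

## What it computes

* **True-peak detection.** After discarding fragments outside the
  27–520 bp sizing window, peaks are called iteratively against a
  zero-mean background: the background scale is `sqrt(sum(h²)/n)` over
  the peaks not yet declared true, every remaining peak with
  `h > 3·SD` is declared true, and the loop repeats until no peak
  exceeds the threshold.
* **Binning and standardization.** True-peak lengths pooled over
  samples are chained into bins (gap ≤ 0.5 bp), represented by the mean
  of their distinct member lengths; within-sample heights in a bin are
  summed and each sample is divided by its total, giving relative
  abundances.
* **Diversity.** Shannon `H = −Σ p·ln p` and inverse Simpson
  `D = 1/Σ p²` per sample.
* **Ordination.** Euclidean distances between standardized profiles,
  complete-linkage clustering (Newick export), and centered, unscaled
  PCA with percent variance explained.
* **qPCR quantification.** Replicate Ct means with QC flags, relative
  abundance `100 × 2^−(Ct_target − Ct_total)`, and diet fold changes
  (ratio of means or mean of ratios, per species or across species).
* **Split-plot ANOVA.** The balanced species × diet decomposition with
  animal-within-species as the whole-plot error stratum, plus Tukey
  pairwise comparisons from the studentized range.
* **Synthetic data.** Electropherograms, Ct tables and fermentation
  records with known ground truth (planted communities, planted
  abundances, planted effects), used throughout the test suite.

## Worked example

```r
library(rumenTRFLP)

# Diet fold change from the shipped reference group means
gm <- group_means_as_samples(reference_abundance())
group_fold_change(gm$abundance, gm$meta, "Lactobacillus",
                  "HC", "HF", "across_species")
#>   species     fold fold_rounded
#> 1     all 39.36207           39
```

The HC:HF ratio of cross-species mean *Lactobacillus* abundances is
39.4 — reported as a 39-fold increase under the high-concentrate diet.

```r
# A full simulated study through the pipeline
cfg <- default_config()
ds  <- simulate_dataset(cfg, seed = 1)
res <- run_trflp_pipeline(ds$peak_tables, cfg, meta = ds$meta)
head(res$diversity, 3)
#>      sample_id species animal_id diet richness  shannon inverse_simpson
#> 1 Hanwoo_A1_HF  Hanwoo Hanwoo_A1   HF       10 2.302363        9.995575
#> 2 Hanwoo_A2_HF  Hanwoo Hanwoo_A2   HF       13 2.395906       10.550003
#> 3 Hanwoo_A3_HF  Hanwoo Hanwoo_A3   HF       11 2.336399       10.197078
```

Each sample's planted community has 10 equally abundant taxa, so
Shannon diversity sits at `ln 10 ≈ 2.30` and the inverse Simpson index
near 10; occasional spurious low bins nudge richness above 10 without
materially moving the indices.

```r
split_plot_anova(ds$fermentation, "pH")
#> Split-plot ANOVA of 'pH'
#>           effect df sum_sq mean_sq   error_stratum       F         p
#>          species  2 0.5063 0.25316 animal(species)   1.999 1.912e-01
#>  animal(species)  9 1.1397 0.12663            <NA>      NA        NA
#>             diet  1 3.3014 3.30143        residual 220.886 1.222e-07
#>     species:diet  2 0.4402 0.22012        residual  14.727 1.452e-03
#>         residual  9 0.1345 0.01495            <NA>      NA        NA
```

The simulated diet effect on pH (planted from the reference cell means,
a drop of ~0.8 pH units on average) is recovered as a highly significant
sub-plot effect, with species tested against the animal-within-species
stratum.

A thin command-line wrapper (`inst/cli/rumen-trflp.R`) exposes the same
stages as subcommands (`simulate`, `peaks`, `bin`, `diversity`,
`ordinate`, `qpcr`, `anova`, `run-all`) with `--config`, `--seed`,
`--out-dir` and `--log-level` flags, reading and writing the
delimited-text formats described in `?read_peak_table`.

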