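# cbsprio

Prioritization of CTCF binding-site (CBS) variants from three orthogonal
signals: cross-biosample **binding activity**, allelic **ΔPWM** scores with
importance-sampling significance, and population-genetic constraint via the
**mutability-adjusted proportion of singletons (MAPS)**.

## The problem

CTCF anchors chromatin loops and TAD boundaries at tens of thousands of
genomic sites. Whole-genome sequencing cohorts contain millions of
single-nucleotide variants that fall inside CTCF motif matches, but a motif
match alone says little: most matches are unbound (the motif futility
theorem), and most substitutions in a bound site barely change affinity.
`cbsprio` is for statistical geneticists and regulatory genomicists who want
to rank such variants by the joint evidence that (a) the locus is actually
bound across biological contexts, (b) the allele substitution changes
predicted affinity more than a background substitution would, and (c) the
class of such variants is depleted of common alleles in the population.

## The method

* **Binding activity**: an rDHS × biosample ChIP Z-score matrix, with
  zero-signal entries masked (sentinel −10), is summarized per locus as
  `Σ z_i / N` over unmasked biosamples and binned into 100 rank quantiles
  (10 deciles for MAPS strata). Motifs inherit the maximum activity of
  overlapping rDHSs; motifs without rDHS support are dropped.
* **ΔPWM**: for each SNV in the CBS catalog, REF and ALT windows (14-bp
  flanks) are scored against the PWM over every motif-length subwindow
  covering the variant, both strands; `ΔPWM = best(REF) − best(ALT)`
  (> 0 loss of binding, ≤ 0 gain). Significance is the one-sided tail of
  ΔPWM under a background-sequence null, estimated by importance sampling
  and validated against exact enumeration on small motifs; `p < 0.05`
  marks high-confidence calls.
* **MAPS**: singleton proportion of a variant class minus the proportion
  expected from trinucleotide mutation rates, calibrated by weighted least
  squares on synonymous-like variants; `SEM = sqrt(p(1−p)/n)`.

A synthetic-data module generates every input (genome, planted motifs,
activity matrix, gnomAD-like variants with a planted selection effect,
mutation rates, conservation track) with known ground truth, so the whole
pipeline is testable end to end offline.

## Worked example

```r
library(cbsprio)

cfg <- simulation_config(
  seed = 11, n_variants = 1e5, n_control_variants = 30000,
  selection_effect_by_decile = seq(0, 0.09, by = 0.01)  # monotone planted selection
)
res <- run_cbs_pipeline(cfg, n_is_samples = 5e4, seed = 99)

res$decile_maps_correlation$pearson
#> $r
#> [1] 0.8925718
#> $p_value
#> [1] 0.0005108994

subset(res$maps_by_stratum, binding_class == "loss" & confident,
       select = c(decile, n_variants, maps, sem))
#>  decile n_variants         maps        sem
#>       1        754 -0.005506300 0.01802809
#>       2        770  0.010198566 0.01791121
#>       3        828 -0.007484671 0.01719275
#>       4        723  0.033065802 0.01855587
#>       5        941  0.048673015 0.01628951
#>       6        610  0.049805656 0.02023559
#>       7        858  0.034589834 0.01703588
#>       8        602  0.055817037 0.02037443
#>       9        813  0.051727203 0.01752875
#>      10        618  0.073164929 0.02011126

res$maps_calibration_self$maps
#> [1] 0
```

Reading: confident loss-of-binding variants in the top activity decile are
observed as singletons ~7 percentage points more often than their
mutability predicts (planted: 9, within sampling error), the effect rises
monotonically with activity decile (Pearson R = 0.89 across deciles), and
the synonymous calibration class — the neutral control — scores exactly 0
against its own model. Low-activity deciles are indistinguishable from
neutral, which is the core claim of the framework: allelic-binding
predictions are only interpretable in the context of binding activity.

A thin CLI mirrors the stages (`simulate`, `activity`, `motifs`,
`score-variants`, `maps`, `enrich`, `run-all`):

```sh
Rscript inst/cli/cbsprio run-all --out-dir out --seed 1
```

## Package layout

```
R/                  implementation (activity, motif catalog, allelic scoring,
                    significance, MAPS, enrichment stats, simulation, IO)
tests/testthat/     unit + property tests, incl. test-acceptance.R
scripts/acceptance.R
inst/cli/cbsprio    command-line wrapper
inst/extdata/       synthetic CTCF-like PFM (JASPAR text format)
vignettes/          methods vignette
```
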