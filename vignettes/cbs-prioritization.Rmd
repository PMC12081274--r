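---
title: "Prioritizing CTCF binding-site variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing CTCF binding-site variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbsprio)
```

CTCF binds DNA at tens of thousands of loci and anchors much of the 3D
organization of the genome. Variants that disrupt a CTCF binding site (CBS)
are candidate regulatory mutations, but most motif matches in the genome are
not bound in any cell type, and most substitutions in a bound motif are
innocuous. `cbsprio` implements a framework that triangulates three signals
to prioritize CBS variants:

1. **Binding activity** — a per-locus summary of ChIP-seq evidence across
   many biosamples;
2. **Allelic affinity change (ΔPWM)** — how much a substitution shifts the
   position-weight-matrix score, with a significance estimate against a
   sequence background null;
3. **Population-genetic constraint (MAPS)** — whether variants of a class
   segregate at unusually low frequencies once trinucleotide mutability is
   regressed out.

Everything runs on synthetic data with planted ground truth, so each claim
the package makes about recovery is demonstrated by its own tests.

## Binding activity

The input is a matrix of ChIP-seq Z-scores: one row per rDHS (representative
DNase hypersensitive site), one column per biosample. Combinations with zero
raw signal carry the sentinel value −10; `mask_zero_signal()` turns the
sentinel into an explicit boolean mask, and the mask — not the sentinel — is
authoritative downstream.

Activity for an rDHS is the meta-analytic summary of its unmasked Z-scores,

$$a = \frac{\sum_i z_i}{N},$$

over the $N$ unmasked biosamples — the arithmetic mean; the conventional
Stouffer combination divides by $\sqrt{N}$ instead.
`summarize_activity()` defaults to the mean (`"mean"`) and exposes
`stouffer_sqrt` as an option; the two differ only by a per-row monotone
factor when $N$ is constant, but can reorder loci when $N$ varies, so the
choice is kept explicit and neither is asserted to be "correct".

Scored rDHSs are placed into $k$ equal-sized rank bins
(`assign_activity_quantiles()`, default $k = 100$; $k = 10$ gives the
deciles used for MAPS strata). Binning is by rank, not value: bin sizes
differ by at most one, and ties are broken by a stable sort on
(activity, rDHS id) so the assignment is deterministic. A thresholded
binding call (`call_bound()`, strict $z > 1.64$) is provided for
sensitivity analyses of call-by-threshold behavior; it is not used by the
main pipeline.

Motifs inherit activity by interval intersection (≥ 1 shared base, 0-based
half-open coordinates throughout). When a motif overlaps several scored
rDHSs — bookended loci, for example — it receives the **maximum** activity;
motifs with no overlap are excluded from the CBS catalog.

## The motif catalog

The position frequency matrix is converted to log-odds with a total
pseudocount of 0.8 distributed by the background composition (a common
JASPAR-ecosystem convention; the downstream quantities are insensitive to
it because the relative score normalizes by the achievable range, and the
pseudocount largely cancels in score differences):

$$W_{bj} = \log_2 \frac{(c_{bj} + 0.8\,\pi_b) / (\sum_{b'} c_{b'j} + 0.8)}{\pi_b}.$$

`scan_sequence()` scores every window on both strands (minus strand via the
reverse-complement PWM, reported in plus-strand coordinates), skips windows
containing N, and reports hits at or above a relative score
$(s - s_{\min})/(s_{\max} - s_{\min})$ threshold, default 0.8. The default
is a stand-in for the unstated match threshold of precompiled motif tracks;
it is a tunable argument everywhere it is used. Hits on non-autosomal
contigs or sharing any base with an exclusion track (assembly gaps,
blacklist, coding exons) are removed by `filter_motifs()`, which tallies
removals per track (a hit overlapping two tracks counts in both).

The packaged motif (`synthetic_ctcf_pfm()`) is a **synthetic** 19-bp
CTCF-like PFM constructed for this package — a strongly constrained core
with degenerate flanks. It emulates the shape, not the values, of the
canonical CTCF motif, and the package is agnostic to which PFM it is given.

## Allelic scoring

For each candidate SNV inside a catalog motif, `score_alleles()` extracts
14 bp of flanking reference sequence on each side (a 29-bp window, N-padded
at contig edges), substitutes the ALT base at the center, and scores every
motif-length subwindow that fits inside the window and covers the variant,
on both strands. The per-allele score is the maximum; the statistic is

$$\Delta\mathrm{PWM} = s^{best}_{REF} - s^{best}_{ALT},$$

classified loss-of-binding when positive and gain-of-binding when ≤ 0.
Both strands are scored because CTCF's motif is strand-asymmetric; ignoring
the minus strand would misclassify minus-strand CBSs. With a 19-bp motif and
14-bp flanks, subwindows are constrained to the eleven offsets that fit
entirely in the window — the window is deliberately not extended beyond the
printed 14-bp flanks.

### Significance

The null model is fully specified so that it can be checked against an
exact oracle: the 29-bp window is drawn iid from a zeroth-order background,
and the center base is replaced by one of the other three bases uniformly.
The p-value is the one-sided tail of ΔPWM in the observed direction
($P(\Delta \ge \delta_{obs})$ for loss, $P(\Delta \le \delta_{obs})$ for
gain).

Two estimators are provided:

* `exact_change_pvalue()` — exact summation over all windows and
  substitutions, feasible for toy motifs (enumeration bound: window length
  ≤ 10, i.e. ~10⁶ windows).
* `delta_null_sample()` / `importance_sampling_pvalue()` — importance
  sampling in the spirit of allele-specific binding testers: the proposal
  mixes the background (weight 0.5) with the motif emission model embedded
  at a uniformly chosen valid offset and strand. The weight of a draw is
  the background-to-proposal density ratio, computed from the emission
  probabilities directly (the familiar $2^{score}$ shortcut holds only on
  the plus strand under a non-uniform background — the reverse-complement
  PWM's log-odds divide by the complementary base's background).

The null depends only on (PWM, background, flank), not on the observed
variant, so the pipeline draws one sample (default $5 \times 10^4$ draws)
and evaluates all observed deltas against it. Estimated p-values of exactly
0 in the far tail are floored at a dummy value of $10^{-7}$
(`encode_truncated_pvalues()`; one figure-level convention in the source
analysis used $10^{-5}$, so the floor is an argument). Confidence is strict:
`confident = (p < 0.05)`. When a variant lies in several overlapping
motifs, the per-variant record keeps the smallest p-value, ties broken by
larger |ΔPWM|, then by motif coordinate.

## MAPS

The mutability-adjusted proportion of singletons compares the observed
fraction of singletons (allele count AC = 1) in a variant class against the
fraction expected from its trinucleotide mutability. Contexts are literal
plus-strand 3-mers read off the genome (`annotate_context()`; no collapsing
to pyrimidine-centered contexts — the rate table must use the same
convention, and the synthetic generator emits it so).

Calibration (`maps_calibrate()`) groups a neutral class — variants whose
most severe consequence is `synonymous_variant` — by (context, alt), and
fits singleton proportion on mutation rate $\mu$ by weighted least squares
with group counts as weights. The linear-in-$\mu$ form with count weights
is the simplest model consistent with "regress out the expected number of
singletons given the average mutation rate"; because WLS with count weights
reproduces the weighted mean, the calibration class scores exactly 0
against its own model — asserted to $10^{-12}$ in the tests.

Expected counts are computed per variant, $\sum_v \mathrm{clip}_{[0,1]}
(\hat\alpha + \hat\beta \mu_v)$, which by linearity equals
$n(\hat\alpha + \hat\beta \bar\mu)$ whenever no clipping occurs; both are
computed and their agreement asserted, bridging the per-variant and
per-bin-average readings of the procedure. Then

$$\mathrm{MAPS} = \frac{n_{singleton}}{n} - \frac{E[\text{singletons}]}{n},
\qquad \mathrm{SEM} = \sqrt{\frac{\hat p (1-\hat p)}{n}}.$$

`maps_by_stratum()` computes one result per non-empty stratum (binding
class × confidence × activity decile in the pipeline); small strata are
flagged `wide_uncertainty` rather than dropped.

## Enrichment statistics

`proportion_above()` uses ≥ (a value at the threshold counts as conserved /
pathogenic; the conventional thresholds are 2, 0.8, 0.8, 1 for GERP++,
LINSIGHT, PhastCons100 and PhyloP100, and 10 for scaled CADD).
`bootstrap_proportion()` implements "resample 10,000 times over 10
iterations" as 10 independent iterations of 10,000 size-$n$ resamples with
pooled 2.5/97.5 percentile CIs; both knobs are arguments. Since the
statistic is a proportion of a 0/1 indicator, the resampled success count
is exactly Binomial($n$, $\hat p$) and is drawn as such — statistically
identical to literal index resampling, and fast. Coverage of the 95% CI is
verified by simulation (95% ± 2% over 500 replicates).

Correlations are reported with both Pearson and Spearman (the source
analyses name Spearman in one place and print Pearson in another; both are
always available). Group comparisons of per-quantile proportions use the
two-sample Student's t-test.

## The synthetic-data generator

`simulate_cbs_bundle()` generates every input with known truth. Defaults
are chosen once as desk-scale analogues of the real study conditions:

| parameter | default | rationale |
|---|---|---|
| genome | 1 Mb, 2 chromosomes, 41% GC | human-like composition, desk scale |
| rDHSs | 2,000 × 300 bp | non-overlapping, slot-jittered |
| biosamples | 214 | the real ChIP compendium's biosample count |
| active rDHSs | 30% | order of the real motif-bearing fraction |
| active Z | N(6, 2), 20% masked | clearly separated from N(0, 1) noise |
| inactive masking | 90% | zero-signal combinations dominate |
| motifs | 1,000 planted, 10% outside rDHSs | fidelity 0.95/position |
| variants | 20,000 + 20,000 synonymous-like controls | module default |
| singleton base rate | 0.45 | gnomAD-scale synonymous singleton fraction |
| mutability slope | −0.02 per rate unit | mutable contexts recur, fewer singletons |
| AN | constant 152,312 | coverage variation out of scope |

A planted motif's sequence takes the consensus base with probability 0.95
per position, otherwise one of the other three bases uniformly — bound CBSs
are high-affinity matches, and at this fidelity most planted sites clear
the 0.8 relative-score discovery threshold.

Selection is planted through the singleton mechanism: each variant's
singleton indicator is Bernoulli with

$$p = p_0 + \beta(\mu - \bar\mu) + \delta_{d} \cdot
\mathbb{1}[\text{truth loss-of-binding}],$$

clipped to [0, 1] (clipping is reported), where $\delta_d$ is the planted
excess for activity decile $d$. Truth binding class comes from the sign of
the planted motif's column-weight difference, strand-aware. Deciles are
computed from the **realized** activity matrix — the generator and the
pipeline apply the same deterministic summary to the same data, so planted
effects are keyed to exactly the strata the analysis recovers. This is a
deliberate design: the ground truth is defined in terms of the measured
activity rank, which is what the real analysis stratifies on.

What the generator does **not** emulate: mutational clustering, coverage
variation in AN, real allele-frequency spectra beyond the singleton
mechanism, LD, per-tissue binding heterogeneity, and real chromosome
sizes. Passing tests therefore demonstrate internal correctness and
recovery of the planted statistical structure, not performance on real
gnomAD/ENCODE data.

## Study sizes and numerical choices

* The end-to-end study (`run_cbs_pipeline()` on the monotone-selection
  config) uses 100,000 candidate SNVs and 30,000 controls: a power choice —
  per-stratum SEM (~0.015–0.02 at ~700–900 confident loss variants per
  decile) must sit well below the planted decile step (0.01–0.09 range) for
  the decile–MAPS correlation to be resolvable. The module-level default
  (20,000) is deliberately smaller for fast iteration.
* The importance-sampling null uses $5 \times 10^4$ draws in the pipeline
  and $10^5$ in the oracle comparisons; agreement with the exact
  enumeration is asserted within 3 estimated standard errors on toy motifs
  (L ∈ {3, 5, 6}, uniform and skewed backgrounds).
* Exact-vs-brute-force comparisons probe tail probabilities at midpoints
  between well-separated achievable deltas; probing at achievable values
  would make the ≥ comparison sensitive to last-ulp floating-point
  differences between implementations.
* The substituted-allele score is computed as
  `score + (W[alt] − W[ref])` — grouped so an identity substitution is
  exactly zero in floating point.
* Degenerate inputs: fully masked rDHS rows receive no activity score and
  are excluded from quantiles; variant windows with no N-free subwindow are
  dropped with a log message; a REF allele disagreeing with the genome is a
  hard error naming the position (data-integrity, exit code 3 in the CLI).

## Interfaces

All coordinates are 0-based half-open internally; VCF's 1-based positions
are converted exactly once at the reader/writer boundary. Standard formats
go through Bioconductor: FASTA via `Biostrings`, BED/bedGraph via
`rtracklayer`-compatible readers, VCF via `VariantAnnotation` (multi-allelic
records are expanded to one row per ALT with per-allele AC/AF), intervals
via `GenomicRanges`/`IRanges`. A thin command-line wrapper
(`inst/cli/cbsprio`) exposes the pipeline stages as subcommands
(`simulate`, `activity`, `motifs`, `score-variants`, `maps`, `enrich`,
`run-all`); the R functions are the primary interface.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(
  seed = 11, n_variants = 1e5, n_control_variants = 30000,
  selection_effect_by_decile = seq(0, 0.09, by = 0.01)
)
res <- run_cbs_pipeline(cfg, n_is_samples = 5e4, seed = 99)
res$decile_maps_correlation$pearson
res$maps_by_stratum
```

On this seed the confident loss-of-binding strata rise from MAPS ≈ 0 in
decile 1 to ≈ 0.07 in decile 10 (planted: 0 to 0.09, each within sampling
error), the decile–MAPS Pearson correlation is ≈ 0.89, and the synonymous
calibration class scores 0 against its own model. The same computation, at
the same sizes, is what `scripts/acceptance.R` re-runs from scratch.

## Known limitations

* Binding activity aggregates across biosamples; per-tissue stratification
  is explicitly out of scope.
* The significance null is the package's own fully specified
  background-change test; it is checkable against an exact oracle but is
  not a verbatim reproduction of any external tool's conditional scheme.
* The calibration regression family is linear in μ; the generator plants a
  linear mechanism, so recovery tests do not probe misspecification.
* First-order (dinucleotide) backgrounds, indels/MNVs, methylation-aware
  CpG rates, and coverage corrections beyond the AN filter are not
  implemented.
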