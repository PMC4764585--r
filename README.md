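# netdecay

Do transcriptional networks evolve at different speeds in different animal
lineages? Comparative studies of mammals, birds and insects have answered
this question both ways, largely because each study measured divergence with
its own analytical pipeline. `netdecay` implements a unified statistical
framework for comparing evolutionary divergence rates between lineages, and
the measurement machinery for applying it to successive layers of the
transcriptional network: genome segment retention, nucleotide identity of
retained segments, gene-specific transcription factor (GSTF) occupancy,
cis-regulatory motif retention, and mRNA expression correlation.

It is written for computational biologists who have (or simulate)
cross-species similarity measurements and want a principled, layer-agnostic
answer to "do these lineages diverge at the same rate?".

## The statistical framework

Cross-species similarity *s* (a correlation, a retained fraction, a percent
identity) is modelled as an exponential decay over divergence time *t* in
millions of years (Myrs), fitted by least squares in log-linear space:

    log s = a + b t

Three nested parameter-sharing structures are fitted:

* **lineage-naive** — one shared intercept and slope for all observations;
* **lineage-aware** — a shared intercept, one slope per lineage;
* **lineage-specific** — independent intercept and slope per lineage.

The naive and aware fits are compared with an extra-sum-of-squares F test
(the test `anova()` applies to nested fits; a chi-squared likelihood-ratio
variant is available). The **effect size** is the largest absolute pairwise
difference between lineage-specific predicted similarities at 100 Myrs, in
percentage points. Lineages are declared to diverge at **different** rates
only when *p* < 0.05 **and** the effect size exceeds 5 percentage points;
otherwise they are **indistinguishable**.

Around this core the package provides:

* `power_grid()` / `detection_frequency()` — Monte-Carlo power assessment of
  the framework over rate differences and noise levels;
* `evolve_clade()`, `simulate_chip_reads()`, `simulate_expression()`,
  `implant_motifs()` — synthetic clades (substitutions, indels, segment
  loss) with ground-truth UCSC-style chain maps, ChIP read sets, orthologous
  TPM tables and implanted motifs, so every downstream stage is testable
  without any downloads;
* `read_chain()`, `filter_one_to_one()`, `lift_intervals()`,
  `sample_retention()`, `ungapped_identity()` — chain-based coordinate
  lifting with LiftOver-style minMatch semantics, segment-retention
  sampling (5000 × 75 bp segments, 20 trials by default) and
  Smith–Waterman (EDNAFULL, gap 10/0.5) ungapped identity;
* `estimate_fragment_size()`, `impute_density()`, `mappability_track()`,
  `normalize_density()`, `correlate_profiles()` — nucleotide-resolution
  occupancy comparison: strand cross-correlation fragment-size estimation,
  imputed-fragment density, adaptive mappability masking, one-to-one
  cross-species transfer and genome-wide Pearson correlation;
* `pipeline_choices()`, `run_chip_grid()` — the 108-combination
  segment-resolution sensitivity grid (caller variant × quality filter ×
  minMatch × reference subset × overlap rule);
* `pwm_pvalue_threshold()`, `scan_genome()`, `motif_retention()` — exact-DP
  PWM p-value thresholds (FIMO-style, *P* < 10⁻⁴), genome scanning and the
  motif retention statistic *F*;
* `pair_orthologs()`, `correlate_expression()` — expression-layer
  similarity with the 5 TPM floor and Spearman/Kendall/Pearson-log2 metrics;
* `replay_synthetic()` — an end-to-end replay of all four layer analyses on
  two synthetic lineages with known ground truth.

Functions take data frames first and return tibbles; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate two lineages whose similarities decay at −0.005 and −0.009 per Myr
with 1% measurement noise, and ask whether the framework can tell them
apart:

```r
library(netdecay)
set.seed(42)

obs <- simulate_two_lineages(
  power_config(base_rate = -0.005, rate_delta = 0.004, noise_sd = 0.01))
cmp <- compare_rates(obs)
cmp
#> <rate_comparison>
#>   verdict: different (p = 1.78e-26, effect size 19.92 pp at 100 Myrs)
#>   decision rule: p < 0.05 and effect > 5 pp; test: ftest

tidy(cmp)
#> # A tibble: 1 x 5
#>   lineage_a lineage_b predicted_a predicted_b effect_size_pct
#>   <chr>     <chr>           <dbl>       <dbl>           <dbl>
#> 1 L1        L2              0.608       0.409            19.9
```

The lineage-aware model fits significantly better than the lineage-naive
one (*p* ≈ 2 × 10⁻²⁶), and the lineage-specific fits predict similarities of
0.61 vs 0.41 after 100 Myrs — a 19.9-percentage-point effect, well past the
5-point gate — so the verdict is `different`. `autoplot(cmp)` draws the
observations with the naive and per-lineage decay curves.

The same call works unchanged on any layer's similarity series: feed it the
tibble produced by `sample_retention()`, `correlate_profiles()`,
`motif_retention()` or `correlate_expression()` across your species pairs.
`replay_synthetic(seed = 1)` runs all four layers on a synthetic two-lineage
clade in which segment loss runs 3× faster in one lineage while binding-site
turnover, motif decay and expression drift are identical — and reports the
genome layer as `different` and the transcriptional layers as
`indistinguishable`, the decoupling the framework is designed to expose.

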