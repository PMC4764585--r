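---
title: "Comparing evolutionary rates across transcriptional network layers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing evolutionary rates across transcriptional network layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented in `netdecay`, the
assumptions behind them, the tunable parameters that matter, and the design
choices made where the methodology left genuine room for judgement. It is
the package's reference for *why* the code does what it does; the function
reference documents *what* each function does.

## The decay model and the rate comparison

Every layer of the analysis reduces to the same data shape: one cross-species
similarity value per species pair, with a divergence time in millions of
years (Myrs) and a lineage label. Similarity is modelled as exponential
decay, fitted by ordinary least squares on the log scale,

$$\log s_{i} = a + b\,t_{i} + \varepsilon_{i},$$

which is equivalent to a nonlinear least-squares fit of
$s = e^{a + bt}$ on log-transformed data. Three nested structures are
fitted: *lineage-naive* (shared $a$, $b$), *lineage-aware* (shared $a$,
per-lineage $b_\ell$) and *lineage-specific* (per-lineage $a_\ell$,
$b_\ell$). Because the design is linear after the log transform, all three
are solved in closed form by the normal equations; there is no iterative
optimiser and therefore no initialisation or convergence question.

An exponential decay is deliberately the simplest model that fits all the
similarity measures reasonably well. Similarity data near 100 Myrs often sit
above a linear-space exponential fit, which is why fitting happens in
log-linear space; richer decay families would invite over-fitting at the
sample sizes available (a handful of species pairs per lineage).

**Non-positive similarities.** Log transformation requires $s > 0$. Values
$\le 0$ (possible for correlations, or for high-noise simulations) are
dropped with a warning, and the count is recorded on the fitted object.
Flooring them at a small positive constant was rejected because it would
bias slopes in exactly the high-noise settings where it would trigger.

**The test.** The naive and aware fits are compared by the
extra-sum-of-squares F statistic

$$F = \frac{(\mathrm{RSS}_0 - \mathrm{RSS}_1)/\Delta p}{\mathrm{RSS}_1 / (n - p_1)},$$

referred to $F(\Delta p, n - p_1)$. This is the test `anova()` performs on
nested least-squares fits in R and it is exact under Gaussian errors, so
null p-values are uniform even at the small $n$ typical here (a property the
test suite checks directly with a Kolmogorov–Smirnov test over 500 null
replicates). The chi-squared likelihood-ratio variant, with statistic
$n \log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ and $\Delta p$ degrees of freedom,
is asymptotically equivalent but measurably anti-conservative at
$n \approx 30$; it is kept behind `test = "lrt"` for sensitivity analyses.

**Effect size.** From the lineage-specific fits, the predicted similarity of
lineage $\ell$ at the horizon $h = 100$ Myrs is
$\hat s_\ell(h) = \exp(a_\ell + b_\ell h)$. The effect size is the largest
absolute pairwise difference $|\hat s_i(h) - \hat s_j(h)|$ in percentage
points. With more than two lineages the *maximum* over pairs is used — a
difference is declared if any pair differs — and the full pairwise table is
returned by `effect_size(..., pairs = TRUE)` and `tidy()` so no information
is hidden by the aggregation.

**Decision rule.** Rates are called `different` only when $p < 0.05$ *and*
the effect size exceeds 5 percentage points. Both thresholds are arguments
(`alpha`, `effect_threshold`), defaulting to these values. The two gates
play complementary roles: with very precise data the F test detects
biologically negligible slope differences (the effect gate filters these);
with noisy data effect estimates scatter widely (the significance gate
filters those).

## Power simulation

`detection_frequency()` measures the framework's sensitivity by simulation:
lineage 1 decays at a base rate in {−0.007, −0.005, −0.003} per Myr,
lineage 2 faster by an absolute difference $\Delta$; at each divergence time
in the distance panel, two similarity values per lineage are drawn from
$N(e^{bt}, \sigma)$ with $\sigma$ = 0.005 or 0.05 on the similarity scale;
and the full decision procedure is applied to each of 1000 simulated
datasets. Headline frequencies aggregate the three base rates.

The distance panel is the one genuinely under-determined ingredient: the
real species panels span roughly 2–100 Myrs with most mass at the extremes
(e.g. mouse–human at 91 Myrs, mouse–dog at 97.4 Myrs, and several very
close mouse and *Drosophila* relatives). The default panel
{2, 7, 13, 25, 45, 60, 91, 97} Myrs mirrors that span; it is a
`power_config()` argument, and detection frequencies — particularly at the
smallest rate difference — are sensitive to it, because the effect size at
100 Myrs is an extrapolation whose variance depends strongly on the panel's
leverage. Negative similarity draws (possible at $\sigma = 0.05$) are
handled by the fitting step's drop rule.

## The synthetic clade generator

`evolve_clade()` produces descendant genomes from a common reference along a
star phylogeny, with three processes per branch:

* **Substitutions** — Poisson with rate `sub_rate` per site per Myr
  (default 2 × 10⁻³, the order quoted for neutral metazoan sequence).
  Positions are drawn with replacement and each hit applies a uniform
  non-identity base change; repeated hits compose, so back-substitution
  arises naturally and the observed mismatch fraction follows the
  multiple-hit (Jukes–Cantor-style) correction the tests verify.
* **Indels** — Poisson events (default 2 × 10⁻⁴/site/Myr), geometric
  lengths ($p = 0.3$) capped at 50 bp, insertions and deletions equally
  likely. The cap keeps block bookkeeping exercised without pathological
  cases.
* **Segment loss** — each tile of `loss_tile_bp` (default 2000 bp) survives
  a branch of length $t$ with probability $e^{-ht}$. The hazard $h$ can be
  chromatin-class specific (accessible vs inaccessible tiles), which is how
  the accessible-sequence retention contrast is simulated. Tiles are large
  relative to the 75 bp sampling segments so that the segment-retention
  fraction tracks surviving-sequence coverage; the residual edge bias is of
  order (segment length)/(tile size) ≈ 1 pp at the defaults.

The exact surviving-block correspondence is recorded as a ground-truth
chain map, which makes every coordinate-lifting operation verifiable
against the generating history. What the generator does *not* emulate:
transposable-element dynamics, codon or selection structure, rate variation
along the genome, non-star phylogenies, or sequencing error. Tests passing
on these clades therefore validate the analysis machinery, not the realism
of any particular biological rate.

Chain maps follow UCSC conventions throughout: 0-based half-open
coordinates, and minus-strand query coordinates stored internally on the
forward strand with reflection (`q_forward = qSize - q_reversed`) applied at
file I/O.

## Homology lifting and segment retention

`lift_intervals()` reproduces LiftOver semantics: an interval lifts if at
least `min_match` of its bases fall within blocks of a *single* chain (the
best-covering one; coverage is not pooled across chains), and the spanning
query interval must not exceed `max_target_span` (default 1000 bp, the
standard exclusion for segments that map to a region longer than 1 kb).
`min_match` presets follow the stringent/lenient/none convention
(0.95 / 0.5 / 0.001).

`filter_one_to_one()` resolves overlapping chains by score: chains are
processed in decreasing score order (ties broken by chain id for
determinism) and keep only block portions unclaimed on *both* genomes by
higher-scoring chains. The test suite checks this block-level algorithm
against an independent per-base greedy oracle.

`sample_retention()` places 5000 non-overlapping 75 bp segments uniformly
within the allowed regions by rejection sampling, lifts them at
`min_match = 0.001`, and averages the retained fraction over 20 independent
trials (all four numbers are arguments).

**Ungapped identity.** Retained segments are aligned to their lifted images
with Smith–Waterman local alignment under the EDNAFULL matrix (embedded
verbatim; +5/−4 for unambiguous bases) with affine gap penalties 10 / 0.5.
The alignment itself is computed by `Biostrings::pairwiseAlignment()`, under
the convention that a gap of length $L$ costs
$\mathrm{open} + L \cdot \mathrm{ext}$; the test suite validates it against
a hand-written full-DP oracle on hundreds of random sequence pairs. Identity
is matches over aligned non-gap columns — the identity of the ungapped
alignment columns. Segments whose best local alignment is empty (score 0)
are excluded from the average and counted; including them would require an
arbitrary identity value for a non-alignment.

## Nucleotide-resolution occupancy

The occupancy comparison never discretizes profiles into peaks:

1. **Fragment size.** Only 5′ read start sites enter the estimator, per
   strand. The Pearson correlation $r(k)$ between the plus-strand start
   density and the minus-strand density shifted by $k$ is computed for
   $k$ from `read_length + 1` (skipping the read-length phantom peak) to
   600 bp. The first peak is located on the finite-difference derivative,
   smoothed with a Gaussian kernel of bandwidth 10 (interpreted as a
   standard deviation in bp, truncated at ±4σ): the estimated fragment size
   $L$ is the first downward zero-crossing. A crossing only counts after
   the smoothed derivative has risen to at least 5% of its maximum — on
   flat noise floors the derivative flips sign constantly, and without this
   guard the estimator would latch onto noise below the true peak.
2. **Imputed fragments.** Each start site is extended $L$ bp in the 3′
   direction (leftward from the 3′-end start for minus-strand reads), and
   per-position fragment counts are accumulated per strand. Reads with the
   same strand-specific start site are presumed PCR duplicates and removed
   by default (`dedup = TRUE`). Replicates are merged by adding density
   vectors *before* normalization.
3. **Mappability.** A position is uniquely mappable for read length $k$ iff
   its $k$-mer occurs exactly once in the two-stranded genome — exact
   k-mer counting, equivalent to error-free alignment with zero mismatches
   and multi-mapper removal.
4. **Normalization.** The density at each position is divided by the
   fraction of the $L$-bp upstream window (strand-appropriate direction)
   covered by uniquely-mappable start sites; positions with an empty window
   are masked. Strands are normalized separately and then summed — the
   per-strand reading of the 5′/3′ window directions — with
   `pre_sum = TRUE` available to normalize the summed signal instead for
   sensitivity analysis.
5. **Correlation.** Query profiles are transferred onto the reference
   genome position-by-position through a one-to-one filtered chain map;
   positions unmapped or masked in either species are excluded; a single
   Pearson correlation is computed over the concatenated chromosome
   vectors. Raw per-bp densities are used, not binned ones.

## The segment-resolution pipeline grid

`run_chip_grid()` enumerates the five analytical choices whose combinations
define 108 pipelines: peak caller variant (2) × quality filter (3) ×
minMatch (3) × reference subset (3) × overlap rule (2). External peak
callers are deliberately **not** reimplemented. `call_peaks_standin()` is a
sliding-window Poisson-enrichment caller against a depth-scaled control
(floored at the global background rate), with two variants differing in
window size (150 / 300 bp) so the caller axis genuinely changes results,
and two significance tiers: lenient at $p < 10^{-5}$, stringent at
$p < 10^{-22}$ for one variant and the top-scoring tie class of windows for
the other (emulating a lowest-attainable-q-value rule). Lenient calls are
merged across replicates, stringent calls intersected (merge, then keep
merged segments supported by at least one segment in each replicate); the
asymmetric quality filter is stringent in the reference species and lenient
in the query. The q-value semantics of external callers on real data cannot
be matched exactly by any stand-in; the grid's scientific point — parameter
sensitivity — is preserved, not the per-cell verdicts on real data.

## Motif retention

PWMs are built from count matrices with a pseudocount of 0.1 per cell
against a 0-order background (uniform by default; set the reference genome
composition for FIMO-default behaviour). The match threshold for
$P < 10^{-4}$ is computed from the exact null score distribution by dynamic
programming on a score lattice with granularity $10^{-4}$ log₂-odds units;
the returned cutoff is the smallest achievable score with tail probability
below $\alpha$, relaxed by half the worst-case rounding
($w \cdot \mathrm{granularity}/2$) so boundary words are never lost to
discretization. The suite checks the threshold against exhaustive
enumeration for motifs up to length 8.

For the retention statistic, reference matches are lifted
(minMatch 0.001), each lifted segment is extended by 50 bp *in both
directions* (the extension's sidedness is not standardized anywhere;
`two_sided = FALSE` gives the one-sided variant), and

$$F = \frac{\mathit{Mapped_{with\,motif}} - \mathit{Shuffled_{with\,motif}}}{\mathit{Mapped}} \times 100,$$

where the shuffled background places segments of the same lengths uniformly
at random on the same query chromosomes, once per analysis (seed the RNG
for reproducibility). A match counts only when it lies fully inside the
extended segment, and opposite-strand matches at the same location count
once.

## Expression correlation

Gene pairs are discarded when *either* species' abundance is at or below
5 TPM — the symmetric reading of the abundance floor; `filter_scope =
"ref"` restricts the filter to the reference species, and `tpm_floor =
NULL` disables it (the robustness checks in the tests use all variants).
Spearman uses midranks, Kendall is the tau-b flavour, and `pearson_log2`
takes `log2(tpm)` after filtering (all values > 5, so no pseudocount) or
`log2(tpm + 1)` when the filter is off.

## The end-to-end replay

`replay_synthetic()` ties everything together on two synthetic lineages:
segment loss runs at hazard 0.012/Myr in lineage A and 0.004/Myr in
lineage B (3×), while binding-site turnover (half-life 30 Myrs, which puts
the cross-species profile correlation near 0.1 at 100 Myrs), motif decay
and expression drift (Spearman target $e^{-0.004t}$) are identical in both
lineages. The expected read-out is the decoupling the framework exists to
expose: the genome layer `different`, the transcriptional layers
`indistinguishable`.

The default problem sizes — 200 kb genomes, six descendants per lineage at
{10, 25, 40, 60, 75, 90} Myrs, 600 binding sites, 30 000 reads, 5000 genes,
1000 × 75 bp retention segments over 5 trials — are chosen so that each
layer's similarity estimates carry sampling noise well below the 5-point
effect gate, as they do at the scale of real transcriptomes and
genome-wide binding maps. Much smaller simulations put several percentage
points of Monte-Carlo scatter on the 100-Myr effect estimate and produce
spurious `different` calls on ground-truth-equal layers; that is a property
of tiny simulations, not of the method. Expression drift is calibrated
through the bivariate-normal identity
$\rho_S = (6/\pi)\arcsin(\rho/2)$: the per-branch drift variance is set so
the log-scale Pearson correlation equals $2\sin(\pi s/6)$ for the target
Spearman $s$.

Each stage draws its own seed from the global one via `split_seed()`
(a named-stream splitter), so stages are independently reproducible and
adding a stage never perturbs another's draws.

## Known limitations

* The decay model is a single exponential; layers with multi-phase decay
  are summarized, not modelled.
* The F test assumes independent homoscedastic Gaussian errors in log
  space. Real similarity series violate this (shared reference species,
  correlated drift within a lineage, variance growing as similarity
  shrinks), which makes significance anti-conservative; the effect-size
  gate absorbs much of this in practice, but p-values near 0.05 should not
  be over-read.
* Power results depend on the divergence-time panel, which real studies fix
  by their species choice; comparisons of power numbers between studies are
  only meaningful with matched panels.
* The synthetic generator's star phylogeny has no shared internal branches,
  so it cannot produce the phylogenetic correlation structure of a real
  clade.
* The stand-in peak caller preserves the grid's combinatorics but not the
  numerical behaviour of any specific external caller.
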