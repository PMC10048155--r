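---
title: "Validating RT-qPCR reference genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating RT-qPCR reference genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrstab)
```

# Scope and model

`qpcrstab` covers the reference-gene (RG) validation chain for
comparative RT-qPCR in a multi-condition cell-culture design: screening
candidates from proteome abundance tables, scoring Cq-level stability
with four published algorithm families, combining their rankings, and
quantifying target genes with efficiency-corrected normalization. The
package's own contributions are the implementations of these statistics
and a generative model for synthetic Cq data; standard machinery (linear
fits, t-tests, ANOVA arithmetic, correlation tests) is delegated to base
R's `stats`.

Throughout, a *Cq table* is a complete genes-by-samples matrix of
quantification cycles with a sample-to-condition map and per-gene
amplification efficiencies E (fold of product per cycle; E = 2 is 100%).
Technical replicates are always averaged on the Cq scale to
biological-replicate means before any statistic is computed — all of the
stability algorithms assume one column per biological sample — and
missing cells are an error: the algorithms have no principled treatment
of incomplete matrices, so the only supported remedy is dropping the
affected replicate explicitly upstream.

# The stability algorithms

**BestKeeper.** Each gene is described by the standard deviation and
coefficient of variation of its raw Cq across samples (SD ≥ 1 cycle
flags a gene unsuitable) and by the Pearson correlation of its Cq with
the *BestKeeper index*, the per-sample geometric mean Cq over all
candidates. Genes are ranked by descending index correlation. The
full pairwise gene–gene correlation matrix is also returned, because the
scalar-vs-index convention is only one reading of "pairwise correlation
analysis"; the index correlation is the one that yields a single
rankable statistic per gene. Zero-variance genes have an undefined
correlation and are reported as `NA` while still being assessed on SD.

**geNorm.** The M value of gene *j* is the mean over partners *k* of
SD over samples of log2(rq_j / rq_k), on relative
quantities rq = E^(calibrator Cq − Cq). Because any positive rescaling
of rq cancels in the log-ratio, the calibrator (we use the per-gene
minimum Cq) is cosmetic. Genes are *ranked by their full-panel M*. The
classic stepwise-exclusion trajectory (drop the worst, recompute) is
also computed and reported, but it is not used for the headline ranking:
the exclusion path ends in a two-gene step that cannot resolve the final
pair, and resolving it from the three-gene step uses only two pair-SDs —
in simulation this tie-break is close to a coin flip, while the
full-panel M uses all partner information and, unlike the stepwise M,
assigns the top pair distinct values. Normalization factors NF_n
(geometric means of the n most stable genes' rq) give the pairwise
variation V_{n/n+1} = SD(log2(NF_n / NF_{n+1})); the smallest n with
V < 0.15 (the conventional cutoff, configurable) is the recommended
number of RGs.

**NormFinder.** Log2 relative quantities are sample-centered across
genes, which removes per-sample loading exactly. Within each condition
group the model splits a gene's centered signal into an intergroup
deviation d and intragroup variance σ². Three estimation choices matter
at the design sizes this package targets (three samples per group):

- intragroup variance is pooled across groups per gene (a group-shared
  variance model) — per-group estimates would carry two degrees of
  freedom each and produce frequent zero-clamps and rank noise;
- the variance of true intergroup deviations is estimated by the method
  of moments *pooled across genes*, treating the candidates' intergroup
  deviations as draws from one common distribution, and each observed d
  is shrunk by the empirical-Bayes factor γ²/(γ² + var(d));
- the sampling variance of d is taken on the *centered* scale
  (uncorrected pooled variance): the across-gene centering noise of a
  group is shared by every gene's group mean, and ignoring it lets pure
  centering noise masquerade as intergroup signal for low-noise genes.

The reported stability value is the mean over groups of |shrunken d|
plus the standard error of a group mean computed from the gene's own
bias-corrected variance (floored at a small fraction of the centered
variance so that zero-clamped genes remain strictly ordered). Lower is
more stable. With a single group the estimator reduces to the
bias-corrected centered SD.

**Comparative ΔCT.** For every ordered gene pair the SD across samples
of the per-sample Cq difference; a gene's score is the mean over
partners, ranked ascending.

**Consensus.** The unweighted geometric mean of the four per-algorithm
ranks (average ranks on ties), rounded to two decimals for reporting.
The published consensus values of the packaged panel are reproducible by
this rule for three of the seven genes (PPP6R1, B2M, EHD3); the
remaining rows evidently derive from the aggregator service's internal
re-derivation of each algorithm from raw Cq, whose weighting is
unpublished, so the package reproduces — and asserts — only the
self-consistent rows.

# Quantification

Relative quantities for quantification use the control-condition mean Cq
as calibrator, which fixes the control-arm fold at 1. The multi-RG
normalized relative quantity is NRQ(s) = RQ_target(s) divided by the
geometric mean of the RG RQs. The fold change is, by default, the ratio
of *arithmetic* mean NRQs between a treated arm and the control arm,
with a two-tailed t-test (Welch by default, pooled-variance and
log2-scale options available). A `fold_mean = "geometric"` option
computes the ratio of geometric means instead; with a single RG that
variant reduces *exactly* to the Pfaffl ratio
E_t^ΔCq_t / E_r^ΔCq_r on mean ΔCqs (geometric averaging commutes with
exponentiation), whereas the arithmetic default reduces to it only when
Cq values are constant within arms. No multiple-testing correction is
applied by default — fold-change p-values are reported raw, as is
conventional in small validated panels — but `p.adjust` can be applied
downstream by the caller.

Standard curves are least-squares fits of Cq on log10(amount);
E = 10^(−1/slope). Dropping points at the range ends is supported only
through explicit arguments — never silently — with at most two per end,
a warning below five remaining points, and an error below three. A
non-negative slope marks the curve invalid and E is withheld.

# The synthetic-data generator

`simulate_cq()` draws, for gene g in well (condition c, biological
replicate r, technical replicate t):

Cq = base_g − log(effect_gc)/log(E_g) + L_cr + b_gcr + ε_gcrt

with L ~ N(0, load_sd²) shared across genes of a replicate (RNA
input/RT-yield variation — the artifact normalization exists to remove),
b ~ N(0, bio_sd_g²) per-gene biological noise, and ε ~ N(0, tech_sd_g²)
technical noise. Additive Normal noise on the Cq scale is the standard
qPCR error model; the fold effect enters as an exact Cq shift so the
implied efficiency-corrected ratio is exactly the designed effect in
expectation. Draws come from substreams keyed by (seed, gene, condition,
replicate) through a string hash with a multiplicative avalanche step
and a short burn-in, so tables are reproducible regardless of generation
order and independent across nearby keys; the caller's RNG state is
untouched. What the generator does *not* emulate: amplification-curve
shapes, non-Normal outliers, inhibitor-driven efficiency shifts between
samples, or correlated condition responses among candidates — so passing
recovery tests demonstrate correctness of the estimators under the
stated error model, not robustness to every failure mode of real assays.

The packaged preset (`eadmsc_truth()`) encodes a nine-gene equine
ADSC-differentiation panel: seven candidate RGs with baseline Cq 16.2 to
24.5 cycles, technical SDs 0.04 to 0.37 cycles and efficiencies 1.84 to
2.10 fold/cycle following the panel's published primer
characterization, plus two targets with induction effects inside the
observed fold window (FABP5 ~6-fold adipogenic, ~5.5-fold osteogenic;
RUNX2 ~2-fold adipogenic only). Biological noise (0.1 cycles) and
loading SD (0.2 cycles) are not separately published for this panel and
were fixed once at values typical of careful cell-culture qPCR.

# The recovery experiment and its honest limits

`recovery_experiment()` simulates the full study design (3 conditions ×
3 biological × 3 technical replicates, 7 candidates), scores how often
each algorithm ranks the designed most-stable gene first over seeded
replicates, and estimates a 6-fold target effect. The truth panel gives
the stable gene a 0.1-cycle technical SD against competitors at 0.40 to
0.50 cycles (the top of the plausible per-gene range) with 0.12 cycles
of biological noise, under a 0.5-cycle shared loading SD.

Measured over 200 seeds, the stable gene is ranked first by the
comparative ΔCT method and geNorm in roughly 93% of replicates, by
NormFinder in roughly 91%, and by BestKeeper in roughly 82%; the median
estimated target fold is within a few percent of the designed 6-fold
effect, and V2/3 < 0.15 (two RGs suffice) in essentially every seed.
These recovery rates are not implementation slack; they are ceilings of
the statistics themselves at nine samples:

- BestKeeper's index contains every competitor's noise (SD ≈ √6·σ_c/7),
  which bounds the stable gene's achievable index correlation and caps
  the Fisher-z separation from a competitor near 1 regardless of how the
  noise parameters are set; with se(z) = 1/√6 at n = 9 that binds the
  joint top-1 probability over six competitors near 0.8.
- For the pairwise statistics (M, ΔCT), the stable gene's score is
  dominated by its partners' noise — mean_k √(σ_s² + σ_k²) — so even a
  noiseless gene scores only ~1/√2 of its competitors, and with
  8-degree-of-freedom SD estimates the joint top-1 probability
  integrates to roughly 0.90–0.94.

The same arithmetic explains why NormFinder's *complete* ordering of a
heterogeneous panel is unstable at this design size (pooled variance
estimates carry six degrees of freedom), which is why the test suite
asserts strong rank agreement and extreme-pair separation rather than
exact full orderings. Practically: at a 3 × 3 design these tools
reliably separate clearly stable from clearly unstable candidates, but
single-rank distinctions near the top should not be over-read — one more
reason to normalize with three RGs rather than crown one winner.

# Numerical and interface choices

- Coordinates in primer tables are 1-based inclusive; the amplicon
  length is reverse_end − forward_start + 1, which reproduces all nine
  declared sizes of the packaged panel.
- Efficiencies are fold/cycle in (1, 2.2]; values above 2 (over 100%,
  possible with inhibitor dilution artifacts) are accepted with a
  warning, never clamped. Percent input is converted via E = 1 + pct/100.
- All rankings break exact metric ties deterministically by gene id;
  undefined metrics (`NA` correlations) rank last. Consensus ties carry
  average ranks.
- Degenerate t-tests: identical arms give p = 1; distinct means with
  zero variance in both arms give p = 0 with a warning.
- The ANOVA null-calibration experiment uses a small replicate CV
  (0.05), where the generator's log-normal noise is effectively
  Gaussian; at large CV the skew is real and ANOVA p-values are no
  longer exactly uniform — a property of ANOVA, not of the
  implementation.
- Screen thresholds default to top-25 and p > 0.05; the screen fixture's
  replicate values are synthetic around the published condition-mean
  differences, wide enough that every tabulated protein passes the
  ANOVA filter, with two labelled padding proteins that fail it.
- Reported tables round metrics to 3 decimals (consensus to 2); JSON
  companions keep full precision and round-trip to 1e-12.

Problem sizes used by the test suite and the acceptance script — 200
seeded replicates for recovery experiments, 2,000 proteins for the null
calibration, 100 random instances for brute-force equivalence checks —
were chosen to make Monte-Carlo fractions stable to a couple of percent
while keeping the whole suite fast on a single CPU.

# Known limitations

- The consensus reproduces only the self-consistent published rows, as
  discussed above; matching an external aggregator's unpublished internal
  weighting is out of scope.
- NormFinder's published stability values for the packaged panel are on
  an unknown input scale and are not numerically asserted; the
  implementation follows the model structure, not a value-for-value
  reproduction.
- The manual "also low in the third pairwise comparison" shortlist step
  of candidate screening is judgment-based in the source workflow and is
  deliberately not automated; the report exposes all pairwise
  differences so the user can apply it.
- Quantification treats biological replicates as the unit of inference;
  technical replicates never enter t-tests.
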