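---
title: "Detecting diurnal rhythms in single-cell time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diurnal rhythms in single-cell time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rhythmsc` infers diurnal rhythmicity from single-cell RNA-seq
experiments sampled at a few Zeitgeber timepoints with biological
replicates. This vignette is the package's account of its methods: the
models and their assumptions, the thresholds and what they mean, what
the synthetic generator does and does not emulate, and the numerical
and design choices that were genuinely open.

## The experimental design assumed

The canonical design is 4 timepoints spaced 6 h apart (ZT0, ZT6, ZT12,
ZT18), 3 biological replicates (animals) per timepoint, and several
immune cell types of unequal abundance per sample. Timepoints are
carried as real hours so phase arithmetic stays numeric; whether time
is Zeitgeber (entrained) or circadian (free-running) is a metadata flag
only.

## Pseudobulk testing

Counts are summed per gene over all cells of a cell type within a
biological replicate. Replicate-level testing avoids treating cells as
independent replicates; the animal is the experimental unit.

Normalization is median-of-ratios: reference genes are those with
nonzero counts in every sample, and each sample's factor is the median
ratio of its counts to the per-gene geometric mean, rescaled to unit
geometric mean. If no gene is positive everywhere the code falls back
to library-size ratios with a warning.

The two-group test is a negative-binomial Wald test. Per gene, the
dispersion is estimated by method of moments on normalized counts
(pooled within-group variance), floored at 1e-8, and shrunk 50/50
toward a fitted mean–dispersion trend `a0 + a1/mean`. Group means are
profile NB maximum likelihood with size-factor offsets (a 1-d Newton
solve per group, which makes the test exactly symmetric under group
swap), and the Wald statistic uses the Fisher information of the two
group log-means. BH correction runs across all genes that are not
all-zero in both groups; the correction family is the full tested set
of one contrast. A gene "passes" when its adjusted p is below `alpha`
(default 0.05) and its |log2FC| is at least the contrast's cutoff.

This is deliberately a simplified engine: no shrunken fold-change
estimator, no independent filtering, no outlier replacement. The
inferential contract — BH-adjusted p plus an effect-size cutoff — is
what downstream counting uses, and the simplification is visible in the
null-calibration test rather than hidden behind a library call. A gene
whose fitted group mean is zero gets a 0.5 normalized pseudocount so
fold-changes stay finite.

### Thresholds, with units

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | BH-adjusted p cutoff everywhere |
| `lfc_pseudobulk` | 0.2 | |log2FC| for timepoint contrasts (~15% change); chosen low because clock output genes oscillate with small amplitudes |
| `lfc_aged` | 0.58 | adult-vs-aged contrast (~50% change) |
| `lfc_cell` | 0.15 | cell-level shift cutoff (~10% change) |
| `min_pct` | 0.05 | detection screen: fraction of cells expressing in at least one side |
| `min_cells_per_timepoint` | 250 | inclusion floor for per-cell-type DEG counting |
| `marker_min_pct`, `marker_lfc` | 0.25, 0.405 | one-vs-rest marker calling |

`lfc_to_percent()` makes the conversion explicit:
`100*(2^|L| - 1)`, with a convenience rounding to the nearest multiple
of 5 for quoting cutoffs as "approximately an X% change" (0.15 → 10.9 →
10; 0.24 → 18.1 → 20; 0.58 → 49.5 → 50).

### Power bound

`min_detectable_lfc(n, s2, alpha, power)` returns the smallest absolute
log2-scale difference a two-sided two-sample t-test can detect at the
given level and power, solving the noncentral-t power equation by
bisection to 1e-6. This is a log-scale t approximation, not an NB power
formula: it answers "with n = 3 per group and this log2-scale variance,
what effect were we powered to see?" The variance must be supplied or
estimated from data. An empirical check against 10,000 simulated
t-tests at the returned effect is part of the acceptance suite.

## The cell-level hurdle model

Single-cell data are zero-inflated by detection; cells also differ
globally in how many genes they detect. The hurdle model handles both:

- **Discrete part:** logistic regression of detection (count > 0) on
  timepoint indicators plus the cellular detection rate (CDR, the
  fraction of genes detected per cell, centered and scaled). A ridge
  penalty of 1e-4 on non-intercept terms guards complete separation;
  IRLS runs at most 100 iterations to tolerance 1e-8.
- **Continuous part:** ordinary least squares of log2(1 +
  median-library-normalized count) on the same design, over detected
  cells only. Zero residual variance flags the fit degenerate instead
  of crashing.

For each timepoint τ the full model is compared to a reduced model in
which τ's coefficient is constrained to the mean of the other
timepoints (the τ cells get weight 1/(T−1) on each other indicator).
This is a 1-df reduction in each part, so the summed likelihood-ratio
statistic is χ² with df = 2. "Shift from the average" therefore means
τ versus the pooled mean of the *other* timepoints; the alternative
reading (average including τ) differs only by a factor (T−1)/T in
balanced designs. One consequence used as a test invariant: in a
balanced design the T shift estimates of a gene sum to exactly zero.

The reported shift is on the expected-expression scale: detection
probability times continuous mean, evaluated at average CDR, at τ minus
the mean of the others. BH correction is applied jointly across all
gene × timepoint tests — the conservative choice, since the correction
family is not dictated by the calling rule itself.

### Peak-and-trough filter

A gene is called rhythmic only if at least two timepoints are
significant (adjusted p < `alpha`, |shift| ≥ `lfc_cell`, expressed in
at least `min_pct` of cells on one side), with at least one positive
and one negative significant shift. Requiring both signs suppresses
monotone drifts and single-timepoint artifacts; it encodes that a
rhythm must go up *and* come down within the cycle. The peak is the
timepoint of the largest significant positive shift and the trough the
most negative; ties break toward the smaller timepoint for determinism.
An open interpretive point: the effect-size cutoff is applied to the
shift estimate itself, not to a pairwise ZT-vs-ZT fold change; the
latter reading would be roughly 4/3 larger at the extrema of a cosine.

### Wilcoxon cross-check

`wilcoxon_de()` is the quick cell-level cross-check and the marker
engine. The two-sided rank-sum p is exact (via the null rank-sum
distribution) when there are no ties and group sizes are small, and a
tie-corrected normal approximation without continuity correction
otherwise. The log2FC is the difference of group means of log2(1 +
normalized) expression. Cells are not independent replicates, so this
is a screen, not the inferential endpoint.

## Temporal ordering by a small signature

`build_signature()` computes per-sample mean log-normalized expression
of a small gene set (the motivating use is a 13-gene
clathrin-mediated-endocytosis panel) restricted to one cell type,
z-scored per gene across samples. `kmeans_order()` clusters samples
with Lloyd's algorithm (20 restarts by default, best within-cluster SS
kept; the implementation tolerates duplicate rows, which `stats::kmeans`
rejects, and re-seeds empty clusters from the farthest point of a donor
cluster with ≥ 2 members). Clusters are labeled by the majority true
timepoint of their members, competing clusters resolved greedily by
majority fraction, remaining labels assigned in timepoint order.
Concordance is the number of samples whose cluster label equals their
own timepoint.

How to rank clusters "by time" was an open design point; the majority +
greedy scheme is this package's operationalization. Its calibration is
the permutation null: `permutation_null_concordance()` freezes the
fitted assignment and permutes the sample labels, giving expected
chance concordance total/k under balance. The null deliberately does
*not* re-run the majority relabeling on permuted labels — the
relabeling would adapt to them (for 4 clusters of 3, the unconstrained
expected majority sum is 6.75 of 12, well above the chance 3), and the
quantity being calibrated is the label–signature association, not the
relabeling's flexibility.

## Cosinor fitting

Fixed-period cosinor is exact linear least squares on the basis
{1, cos(2πt/τ), sin(2πt/τ)}; amplitude and acrophase come from the
coefficient pair, with acrophase reported as a peak time in hours
(mapped to [0, τ)) rather than the classical negative-radians
convention, because peaks are discussed in ZT/CT hours. The
zero-amplitude test is F(2, n−3) against the mesor-only model; a
constant series yields F = 0, p = 1 by convention. A period equal to
the sampling interval aliases the basis and is rejected as
rank-deficient.

Free-period fitting profiles the RSS over a 0.01-h grid on the search
interval (default 20–28 h) and refines the minimizer by golden-section
search to 1e-4 h. With 6–12 points and 3–4 parameters, per-fit period
confidence intervals are unreliable; the function returns the
profile-RSS curve for inspection instead, and a spread of periods
across genes (e.g. "24.01 ± 0.32") should be read as a cross-gene SD,
not a per-fit CI.

## E-box scanning

The canonical E-box CACGTG is reverse-complement palindromic, so it is
scanned on the forward strand only and reported once per site. The
degenerate class CANNTG is scanned on both strands, with a site
matching from both strands collapsed to one hit (forward wins);
canonical sites are not double-reported as non-canonical. Coordinates
are 0-based half-open (BED convention), overlapping sites are all
reported, and `N` never matches. No PWM scoring or background
enrichment statistics are attempted — the deliverable is position-exact
mapping.

## The synthetic world

`simulate_cell_counts()` generates the stated design: for rhythmic gene
g, `log2 mean(t) = log2(baseline) + A_g cos(2π(t − φ_g)/24)`, so
planted amplitudes translate analytically into expected log2FCs (2A at
antiphase extrema). Counts are NB (default dispersion 0.1) scaled by
log-normal(0, 0.3) per-cell size factors; an independent Bernoulli
detection step then zeroes counts with probability
`1 − plogis(slope·(log2 mean − midpoint))` (defaults: slope 1, midpoint
1 on the log2 scale), producing a genuine hurdle structure with dropout
tied to expression. Baseline means are log-normal(log 2, 1). Each
sample is generated from its own RNG stream derived from (seed, sample
index), so samples are reproducible independently of generation order.
Per-gene dispersion and dropout magnitudes are conventions, not
measured values; the defaults are in the realistic range for droplet
data but are explicitly tunable.

Two opt-in panels are appended beyond the `n_genes` background genes
(so the rhythmic-fraction bookkeeping of the background stays exact
even at fraction 0): an 11-gene clock panel with positive-arm genes
(Arntl, Clock, Npas2, Nfil3) at phase 0 h and repressor-arm genes
(Per1/2, Cry1/2, Nr1d1/2, Dbp) in antiphase at 12 h, planted with
amplitude ≥ 1 (core clock genes oscillate strongly) and moderate
baselines; and the 13-gene CME signature with acrophases spread evenly
over the cycle, which is what makes 4 timepoints distinguishable by
k-means — a panel with all phases at 0 h cannot separate ZT6 from ZT18.

What the generator does **not** emulate: ambient RNA, doublets, batch
effects, UMI duplication, replicate-level biological variation beyond
sampling (cells are i.i.d. within a sample), and gene–gene correlation.
Consequently a green recovery test establishes correctness of the
estimators under the assumed model, not robustness to those artifacts.
One concrete effect: pseudobulk replicates aggregated from i.i.d. cells
are nearly Poisson, which is an unrealistically easy world for
dispersion estimation; the null calibration of the NB engine therefore
uses a replicate-level NB null with dispersion 0.02 (a realistic
tightness for inbred-mouse biological replicates, CV ≈ 14%) rather
than the aggregated cell-level null.

## Fixture choices pinned in the tests

- Standard recovery fixture: 4 × 3 samples, 400 cells/sample of one
  cell type, 600 background genes with 10% rhythmic at peak-to-trough
  log2FC 0.8, clock and CME panels planted, fixed seed. The gene count
  keeps the suite inside a desk-scale time budget; recall is measured
  on background genes only and the clock panel is required to come out
  rhythmic with correct antiphase peaks.
- Null fixtures: 2000 genes cell-level (no planted rhythm) for the
  hurdle LRT; 2000 genes × 6 samples replicate-level NB for the Wald
  engine. Calibration is judged at 3 Monte-Carlo σ around 0.05 plus a
  KS uniformity check.
- All Monte-Carlo tolerances are stated in σ units of the simulation
  itself, never tuned to outcomes.

## Known limitations

- The NB Wald test with moments/trend dispersion is slightly
  anti-conservative at high dispersion and conservative in
  near-Poisson regimes; it is calibrated in the tested world but is
  not a substitute for a mature shrinkage estimator on real data.
- The hurdle model has no per-replicate random effect, so cell-level
  p-values understate between-animal variability; pair it with the
  pseudobulk route for inference, as the calling workflow does.
- Free-period estimates from 6-point series are point estimates;
  see the profile curve before believing them.
- The CLI's config format is flat JSON (no YAML dependency in the
  supported environment).
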