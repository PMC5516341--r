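---
title: "methylDMR: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylDMR: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylDMR)
```

This vignette documents the statistical model behind the package, the
meaning and defaults of every tunable parameter, what the synthetic-data
generator does and does not emulate, and the numerical conventions chosen
where the underlying methodology leaves room.

## The measurement model

An Infinium-style methylation array reports, for each CpG probe and
sample, a methylated channel intensity $M$ and an unmethylated channel
intensity $U$.  The methylation level is summarised as the beta value

$$\beta = \frac{M}{M + U + \alpha}, \qquad \alpha = 100,$$

which lies in $[0, 1)$ and reads as the fraction of methylated copies.
The offset $\alpha$ is the long-standing Illumina convention: it shrinks
betas of dim probes toward 0 instead of letting the ratio explode, at the
cost of a small multiplicative attenuation ($T/(T+\alpha)$ for total
intensity $T$; under the simulator's default $T \approx 8000$ this is about
1%).  $\alpha$ is exposed as `betaOffset` in `runQC()` for sensitivity
analyses.

### Preprocessing

`runQC()` applies, in a fixed order:

1. **Background correction.** Negative-control probes carry no genomic
   target, so their intensities estimate per-array background.  We subtract
   the per-sample median of the negative controls from every entry of both
   channels and floor at 1.  This is a deliberately minimal, closed-form
   background model — median-offset subtraction, not a
   normal-exponential deconvolution — chosen because it is deterministic,
   exactly testable against hand arithmetic, and sufficient for the
   quantities this package is validated on (group-mean differences are
   invariant to any per-sample additive offset up to the floor).
2. **Quantile normalisation**, separately per channel, across samples.
   Each column's sorted values are replaced by the per-rank mean of all
   columns' sorted values; within-column ranks are preserved; tied entries
   all receive the mean of the rank means over their tied block, making the
   result invariant to permutations among ties.  This is plain quantile
   normalisation, not a probe-type-stratified variant, for the same
   reason as above: an exactly specified, oracle-testable primitive.
3. **Failed-probe removal.** A probe is failed when *both* channels are
   below `intensityThreshold` (default 1000 units, strict `<`) in *every*
   sample — a conjunction over channels and a universal quantifier over
   samples; one bright channel in one sample rescues the probe.  Ties at
   exactly the threshold are retained.  The rule is applied to the
   corrected, normalised intensities.
4. **chrY removal** (the intended cohorts are single-sex; chrY probes are
   uninformative and in female cohorts measure only cross-hybridisation).
5. **Blacklist removal** of cross-reactive/multi-mapping probes, supplied
   as a one-id-per-line file.  Probe alignment itself is out of scope; the
   blacklist is an input.

Removal counts are attributed to the *first* filter that removes a probe,
so the `QCReport` counts are disjoint and sum to input minus retained.

A consequence of quantile normalisation worth keeping in mind: it assumes
the vast majority of probes carry no group difference.  If a large share of
probes is genuinely shifted in one group, forcing all samples onto a common
intensity distribution partially absorbs the shift.  The package's own
simulation tests keep planted probes at a realistic few percent of the
array, where the attenuation (together with the beta offset and background
noise) is small but measurable — realised effects of a planted +0.15 shift
come out near +0.14.

### Per-CpG testing and prioritisation

For each retained CpG, `findDMPs()` computes a two-group one-way ANOVA:

$$F = \frac{\mathrm{SS}_{\text{between}} / 1}
           {\mathrm{SS}_{\text{within}} / (n - 2)}
  \;\sim\; F(1,\, n-2) \text{ under } H_0,$$

which for two groups is exactly the squared pooled-variance t statistic —
the test suite asserts $F = t^2$ to $10^{-10}$ relative tolerance against
`t.test(var.equal = TRUE)` on 1000 random rows.  The effect size is
$\Delta\beta = \bar\beta_{\text{case}} - \bar\beta_{\text{control}} \in
[-1, 1]$, readable as percentage-point differential methylation.

Degenerate rows are defined explicitly: zero within-group variance with
equal means gives $F = 0,\ p = 1$; zero within-group variance with unequal
means gives $p = $ `.Machine$double.xmin` with a warning (the statistic is
formally infinite; a hard error would abort a genome-wide scan over one
constant probe).

No variance moderation (empirical-Bayes shrinkage) is applied.  At
$n \approx 50$ the per-CpG variance estimate on 48 degrees of freedom is
stable enough that shrinkage would change little, and the plain test has an
exact finite-sample null distribution that the calibration tests verify
directly (type-I error within [0.04, 0.06] at nominal 0.05 on ~10,000
simulated null probes).

A **DMP** must pass `p_value < 0.05` (strict) *and*
`|delta_beta| >= 0.1` (inclusive).  The boundary conventions matter for
determinism: an observed $|\Delta\beta|$ of exactly 0.1 is kept, a p-value
of exactly 0.05 is dropped.  No multiple-testing correction is applied at
this stage — by design the workflow trades genome-wide error control for a
prioritisation cascade (nominal p, then effect size, then regional
consistency), the appropriate stance for small underpowered cohorts where
the deliverable is a short list of robust candidate loci, not a
significance claim.  `bhFDR()` is available where an FDR is wanted (and is
used inside `runORA()`).

### DMR calling

`callDMRs()` sorts prioritised DMPs genomically and chains a CpG onto the
current run iff it is (i) on the same chromosome, (ii) at most `maxGap`
(default 1000 bp, inclusive) downstream of the previous member, and
(iii) methylated in the same direction (sign of $\Delta\beta$).  Runs with
at least `minCpgs` (default 2) members become DMRs.  Three conventions are
worth spelling out:

- **Gap, not span.** The 1000-bp rule binds consecutive-CpG gaps, so a
  long region of densely spaced CpGs can exceed 1000 bp overall.  On the
  packaged reference set the two readings coincide (all six regions also
  span < 1000 bp).
- **Adjacency over prioritised CpGs only.**  Sub-threshold array probes
  lying between two DMPs do not sever a region: the caller chains the
  prioritised list, not the raw manifest.
- **Sign flips sever.**  A single opposite-signed CpG terminates the run
  and starts a new one at the flipped CpG; a (+, −, +) triplet within a
  few hundred bp yields no region at `minCpgs = 2`.

Because all three constraints are local to consecutive pairs, the greedy
scan provably returns exactly the maximal valid runs; the test suite
checks this against an independent $O(n^2)$ exhaustive maximal-interval
oracle on all sign patterns of length ≤ 4 and on randomised inputs of up
to 12 CpGs with gaps straddling the 1000-bp boundary.

Equal genomic positions among prioritised CpGs are a hard error (array
coordinates are unique; duplicates indicate a corrupted manifest rather
than something to tie-break silently).

Coordinates are 1-based inclusive internally (`GRanges` convention, and
the convention of published probe tables); the BED6 exporter converts to
0-based half-open, prefixes chromosomes with `chr`, and encodes
`round(1000·|mean Δβ|)` as the score.

### Over-representation analysis

`runORA()` tests a gene list against gene sets with the one-sided
hypergeometric tail $P(X \ge k)$ — equivalently a one-sided Fisher exact
test, and asserted equal to `fisher.test(alternative = "greater")` to
$10^{-12}$ in the tests — followed by Benjamini–Hochberg adjustment across
sets.  Two choices:

- **Universe = genes annotated on the post-QC probe set**, not the whole
  genome: the gene list was sampled from what the array (after QC) could
  have reported, and using a larger universe would inflate enrichment.
  The universe is a parameter, so callers can override it.
- **A gene counts once**, no matter how many CpGs map to it; ORA is a
  gene-level test.

The hypergeometric test is discrete: with small sets and lists its exact
size at nominal 0.05 can be far below 0.05.  The package's null
calibration simulation therefore uses a design chosen analytically
*before* running it — universe 1000, sets of 100, lists of 200 — whose
exact rejection probability under the null is 0.0466 (computable in closed
form from the hypergeometric tail), so that the Monte-Carlo check is a
test of the implementation rather than of discreteness.

## The synthetic-data generator

`simulateMethylation()` emulates the data-generating process the pipeline
assumes:

- Per probe $i$, a baseline mean methylation $\mu_i$; per cell
  $(i, j)$ a true fraction $m_{ij} \sim
  \mathrm{Beta}(\mu c, (1-\mu)c)$ with shared concentration
  $c = $ `betaPrecision` (default 50, giving a per-CpG biological SD of
  about 0.07 at $\mu = 0.5$ — mid-range for immune-cell methylation
  variability).  Planted DMRs shift $\mu$ by `effect` in case samples
  only, *on the beta scale*, so planted effects are directly comparable
  to the $\Delta\beta$ the pipeline estimates.
- Total intensity $T_{ij} \sim \mathrm{LogNormal}(\log 8000,\ 0.3)$,
  split as $M = T m + \epsilon_1$, $U = T(1-m) + \epsilon_2$ with
  half-normal channel noise of scale 5% of the median total intensity;
  negative controls (96 per sample) are drawn from the same background
  distribution, so background correction has a real signal to estimate.
- Failed probes are rescaled so both channels sit below 1000 units in
  every sample (targets uniform in 100–400 units), guaranteeing the
  failed-probe rule fires on exactly the planted set; chrY and blacklist
  probes are disjoint random subsets of the null probes.
- Default group sizes are 28 cases / 22 controls, the cohort geometry of
  the motivating study design; planted effects in the tests are +0.15,
  inside the 0.10–0.27 band where published regional effects live.
- Null probes are laid out with at least 2 kb between neighbours and 2 kb
  clearance around planted regions.  Chance sub-1000-bp adjacency among
  null probes is therefore structurally impossible, which makes the
  null-specificity test (no DMRs on fully null data) a test of the
  prioritisation-plus-chaining logic rather than of the random layout.

What it deliberately does **not** emulate: the genome-wide bimodal
baseline distribution (baselines are drawn from a smooth rescaled
Beta(2, 2) on [0.1, 0.9] to keep per-probe skewness mild), Infinium
type I/II probe-chemistry differences, dye bias, batch and chip effects,
cell-composition heterogeneity, spatially correlated backgrounds, and
SNP-driven trimodal betas (the `betaSpreadSummary()` trimodality score
exists to *detect* that pattern in real data, and is tested on constructed
mixtures).  Passing the simulation-based tests therefore demonstrates
correctness of the algorithms under the stated generative model — it does
not certify performance on real arrays affected by those artefacts, which
is the role of the QC filters and of study design.

## Problem sizes and runtimes

The packaged statistical checks use: 1000 random rows for the $F = t^2$
oracle; 100 random tables for the Fisher equivalence; ~10,000 null probes
at $n = 28/22$ for type-I calibration; 100 × 200 set draws for ORA
calibration; 50 replicates for planted-DMR recovery (criterion: ≥ 9 of 11
member CpGs recovered in ≥ 95% of replicates) and 12 replicates of 10,000
null probes for specificity.  These sizes give Monte-Carlo standard errors
comfortably inside the asserted bands (e.g. ~0.002 for both calibration
fractions) while keeping the full suite in a few minutes on one CPU.

## Reference DMP set

`rrmsReferenceDMPs()` ships 33 published MS-associated DMPs (six regions:
*PM20D1*, *HCG4P6*, *RNF39*, *HLA-DRB5*, *HLA-DRB1*, *ERICH1*) with their
printed F statistics, p-values, group means and $\Delta\beta$ values.  Four
p-values are published only as "0.000"; they are stored as 0.0005 with
`p_truncated = TRUE` and nothing downstream asserts on them — a display
truncation is not a measurement.  The stored group means reproduce every
printed $\Delta\beta$ within ±0.0015 (printed rounding), and the DMR caller
reproduces the published six regions, member counts, spans (346 bp at
*RNF39*, 45 bp at *HCG4P6*) and directions from the coordinates alone.
The printed p-values of this set are *not* recomputable from the printed
F statistics under an $F(1, 48)$ reference (the originating analysis may
have used different degrees of freedom or moderation); the package
accordingly treats the printed F and p as data, and validates its own test
only against simulation and the $t^2$ oracle.

## Known limitations

- No covariate adjustment (age, batch, cell composition); the test is a
  two-group comparison by design.
- Beta-scale t/F tests are approximate near the boundaries of [0, 1];
  with $n \ge 20$ per group and betas clamped away from the extremes the
  calibration tests show nominal behaviour, but heavily skewed CpGs in
  small cohorts deserve caution (M-value analysis is a standard
  alternative and is out of scope here).
- The DMR caller reports descriptive summaries, not region-level
  p-values; permutation-based family-wise inference is out of scope.
- ORA results depend on the gene-set snapshot supplied by the user; no
  live database retrieval is performed.
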