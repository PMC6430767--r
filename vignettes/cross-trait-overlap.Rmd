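---
title: "Methods: cross-trait pleiotropy, concordance and conditional FDR"
author: "crossPleio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-trait pleiotropy, concordance and conditional FDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossPleio)
```

# The question and the data

Given only GWAS summary statistics for two traits — per-SNP effect
sizes, standard errors and p-values, no individual-level genotypes —
how much of their genetic architecture is shared? Two distinct notions
are tested here:

* **pleiotropy** — the same variants are associated with both traits,
  regardless of the direction of effect;
* **concordance** — among variants associated with both traits, the
  effect directions agree (or systematically disagree).

The motivating setting is psychiatric imaging genetics: a disorder
GWAS (tens of thousands of case/control samples) against GWASs of
subcortical brain volumes, where a "negative concordance" means risk
alleles align with volume-decreasing alleles. The package makes no
assumption specific to that setting; any pair of summary-statistics
tables in METAL/PLINK-style layout can be analysed.

# Pipeline overview

1. **Harmonization** (`harmonize()`). SNPs are matched across studies
   by identifier and the secondary study's effect sign is re-expressed
   relative to the primary study's effect allele. Four allele
   orientations are recognized (identical, swapped, and both after
   strand complement). Palindromic SNPs (A/T, C/G) cannot be oriented
   from alleles alone and are dropped by default; an optional
   frequency-based rescue keeps those whose effect-allele frequency is
   clearly away from 0.5 in both studies (`|eaf − 0.5| > 0.08`, both
   sides consistent). The 0.08 margin is a conventional
   ambiguous-frequency buffer: closer to 0.5, sampling noise can flip
   which allele is the minor one between studies.

2. **LD clumping** (`ldClump()`). The shared SNP set is greedily
   reduced to approximately independent index SNPs: rank by one
   trait's p-value, repeatedly take the best remaining SNP, and remove
   every SNP on the same chromosome within ±500 kb *and* with
   r² > 0.2 with it. Both conditions must hold. Ranking uses the
   *secondary* trait by default, so each secondary trait induces its
   own independent SNP set — the conditioning that the downstream
   tests assume. Ties in the ranking p-value are broken by
   (chromosome, position, SNP id), making the output invariant to
   input row order. SNPs missing from the LD reference are treated as
   unlinked and survive as their own clumps.

3. **Grid tests** (`pleiotropyGrid()`, `concordanceGrid()`). Both
   traits' p-values are thresholded at the 12 nested cutoffs
   {0.01, 0.05, 0.1, 0.2, …, 0.9, 1.0}, giving a 12 × 12 grid. Per
   cell (t₁, t₂):
   * pleiotropy: a one-sided exact hypergeometric (Fisher-type)
     p-value for over-representation of SNPs with
     p₁ ≤ t₁ *and* p₂ ≤ t₂, given the margins;
   * concordance: among SNPs in the cell, one-sided exact binomial
     p-values against 0.5 for an excess of sign agreements and,
     separately, for an excess of disagreements. Empty cells are
     non-informative (p = 1 on both sides).

4. **Permutation calibration** (`secaPermutation()`). The grid is
   summarized by a single statistic and calibrated against a null in
   which the secondary trait's (p, sign) pairs are randomly re-paired
   across SNPs — this preserves both traits' marginal distributions
   exactly while destroying cross-trait linkage. The empirical p-value
   uses the add-one rule (1 + #{permuted ≥ observed})/(1 + n_perm),
   which can never return 0, and carries an exact 95% Clopper–Pearson
   interval on that proportion. For concordance the excess and deficit
   directions are tested separately and the smaller empirical p is
   reported (not doubled) together with a direction label: "+" for
   concordance, "−" for discordance.

5. **Conditional FDR** (`runCfdr()`, `conditionalFdr()`). The
   secondary trait's p-values on the index SNPs are converted to
   Benjamini–Hochberg q-values, and 14 nested conditioning subsets are
   formed at q ≤ {1e-5, 1e-4, 1e-3, 0.01, 0.1, 0.2, …, 0.9, 1}. BH is
   re-applied to the primary trait's p-values *within* each subset; a
   SNP's conditional q is the minimum across the subsets containing
   it, and it is declared significant when that minimum is ≤ 0.05 —
   i.e. when it passes FDR control conditioned on *any* subset.
   Because the last level is 1, the minimum can never exceed the
   unconditional q: conditioning can only help. Taking a minimum over
   nested subsets is a per-SNP best case; this multiplicity is
   documented, not corrected, matching how such conditional
   discoveries are conventionally reported.

6. **Stratified TDR** (`stratifiedTdr()`). For conditioning strata at
   p₂ ≤ {1.0, 0.1, 0.01, 0.001}, the true discovery rate at a primary
   threshold t is estimated conservatively as
   TDR(t) = max(0, 1 − t / F̂(t)), with F̂ the self-inclusive
   empirical CDF of the primary p-values inside the stratum. Under a
   global null F̂(t) ≈ t and TDR ≈ 0; shared architecture concentrates
   small primary p-values in strict strata and pushes their curves up
   — the conditional-QQ "leftward shift".

7. **Orchestration** (`runAll()`). One primary trait against a list of
   secondary traits, with a Bonferroni family threshold
   0.05 / (n_traits × n_volumes × n_methods) (`bonferroniThreshold()`)
   and the three-band annotation convention (significant / nominal
   p < 0.05 / trending p < 0.1). Outputs are TSV tables, TDR plot
   data, and a JSON run log recording the seed and full configuration,
   so every emitted number is recomputable.

# The choice of grid summary statistic

This was the one genuinely open design decision. The statistic
historically reported for this style of analysis is the *count* of
grid cells whose cell-level p is ≤ 0.05. That count is integer-valued
and, after clumping, has a large atom at zero under the null; the
permutation p then has a matching atom at 1 (published tables of this
analysis show rows with p = 1 and CI "1–1" for exactly this reason)
and is conservative everywhere. It cannot be uniformly distributed
under the null, whatever the simulation parameters.

The package therefore defaults to the **minimum cell-level p** over
the grid (`statistic = "minp"`), which is near-continuous: in our
null-calibration runs (200 independent-trait simulations, 199
permutations each — recomputed by the test suite and
`scripts/acceptance.R`, not quoted from anywhere) its empirical p is
uniform by a Kolmogorov–Smirnov check and rejects at α = 0.05 at the
nominal rate. The count statistic remains available via
`statistic = "count"` for comparability with the historical output;
both are valid tests, the count merely conservative.

# What the simulator emulates — and what it does not

`simulatePair()` draws paired GWAS summary statistics over an LD-block
genome: by default 2 chromosomes × 250 blocks × 8 SNPs (4,000 SNPs),
compound-symmetry LD within a block (r² = 0.64, i.e. dosage
correlation 0.8 — a tight, clumpable block), 10 kb SNP spacing and
600 kb gaps between blocks. The gap exceeds the 500 kb clumping
window, so "one index SNP per block" is an exact ground truth, which
is what makes clumping correctness decidable in tests.

Per block and trait, Z-scores are multivariate normal with mean
√n·β·rᵢ (rᵢ the dosage correlation of SNP i to the block's single
causal tag; β = 0 in non-causal blocks) and the block's
compound-symmetry correlation. Null blocks therefore have exactly
standard-normal marginals, and a causal tag has E[χ²] = 1 + n·β².
Defaults: n = 10,000 per study and β = 0.02, putting the causal tag's
expected |Z| at 2 — a deliberately sub-genome-wide-significant,
polygenic-scale signal, the regime in which cross-trait enrichment
methods are actually needed. Causal-block counts are deterministic
(`round(π·B)`) so that power is stable across seeds.

The architecture is controlled by (π₁, π₂, π_shared, p_sign_agree).
One subtlety matters for calibration: *forcing* π_shared = 0 makes the
two causal sets disjoint, which is negative dependence (small p₁
avoids small p₂), not independence — the pleiotropy test rightly
reacts to it. Genuinely independent traits are simulated with
`piShared = NA`, which draws the two causal sets independently and
lets them overlap by chance (π₁·π₂ of blocks in expectation); the
`null_pair` fixture uses this regime, and it is the regime under
which the null-calibration guarantees are stated. All randomness
flows from a single seed through `withr::with_seed()`, leaving the
caller's RNG untouched; identical seeds give byte-identical bundles.

Deliberately **not** modelled: realistic allele-frequency spectra,
genotype-level sampling, case-control liability scales, population
stratification, variable block sizes, or inter-block LD. Passing
tests on this generator therefore demonstrate the statistical
machinery's correctness and calibration — not robustness to the
messiness of real consortium data (strand errors, build mismatches,
inflation), of which only the first is addressed (by harmonization).

Named fixtures (`makeFixture()`) pin the regimes the pipeline must
distinguish: `null_pair` (independence), `concordant_pair` /
`discordant_pair` (π_shared = 0.3 with sign agreement 1 / 0),
`pleiotropy_no_concordance` (shared blocks, random relative signs),
and `cfdr_enriched` — a sparser shared architecture (π = 0.1,
β = 0.025) with a deliberately better-powered conditioning study
(n₂ = 40,000 vs n₁ = 10,000), the asymmetry that makes conditional
FDR genuinely rescue SNPs that are underpowered unconditionally.

# Numerical choices and degenerate inputs

* p-values of exactly 0 are clamped to the smallest positive double
  with a warning; TDR's ratio and BH's step-up require p > 0.
* The TDR ECDF is self-inclusive (F̂(t) ≥ 1/|S| wherever some p ≤ t),
  so the ratio never divides by zero; TDR is clamped to [0, 1].
* Per-SNP TDR curves default to the stratum's own sorted unique
  p-values. The fixed export grid `tdrEvalGrid()` is log-spaced on
  [0.05, 1]: at a grid point t the ECDF's relative error scales like
  1/√(t·n), so points with t·n in the thousands are required before
  a "TDR ≈ 0 under the null" statement is meaningful at the 0.05
  level; at the smallest order statistics TDR is dominated by noise
  (at the minimum p-value it behaves like 1 − n·p₍₁₎, which is large
  with appreciable probability under uniformity at any n). The null
  flatness check in the test suite is therefore stated on the fixed
  grid.
* Clumping ties are broken by (chromosome, position, SNP id);
  chromosome labels are compared as normalized strings
  ("chr1" ≡ "1") and ordered numerically where numeric.
* Permutation sub-seeds in `runAll()` are derived per trait pair from
  the master seed (seed + 1000·pair), keeping runs reproducible and
  pairs independent.
* Empty conditioning subsets are skipped with a log note; an empty
  TDR stratum drops its curve with a warning; a trait pair that fails
  inside `runAll()` is caught and reported without stopping the run.
* `varianceExplained()` uses the single-regressor identity
  100·z²/(z² + n − 2). It is exact for simple linear regression on a
  quantitative trait and approximate otherwise; it feeds descriptive
  table columns only and no test or decision depends on it.

# Problem sizes used by the checks

The test suite and the acceptance script run entirely on the
simulator at desk scale, chosen to finish in minutes on one CPU while
leaving no statistical check underpowered: 200 null replicates at 199
permutations for calibration, 50 replicates each for concordant and
discordant recovery, 500 random instances (n ≤ 50) against the
brute-force clumping reference, 1,000 random vectors against the
brute-force BH oracle, exact enumeration for the binomial (2ⁿ,
n ≤ 12) and hypergeometric cell tests, and 10⁵ SNPs for the
uniform-null TDR check. The default `nPerm = 9999` (empirical-p
resolution 10⁻⁴) is intended for real analyses; tests use 99–999.

# Known limitations

* The min-over-subsets conditional q is reported uncorrected for the
  number of subsets; it is a ranking/discovery tool, not a calibrated
  per-SNP error rate.
* The concordance empirical p is the better of two one-sided tests
  without doubling; treat it as directional evidence accompanied by
  its label, not as a two-sided p.
* Harmonization trusts SNP identifiers; no coordinate liftover or
  multi-allelic handling is attempted.
* The LD reference is taken as given (PLINK-style r² pairs); the
  package never computes LD from genotypes.
* With the `count` statistic, empirical p-values are conservative and
  mass at 1 — a property inherited from the historical method, kept
  for comparability.
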