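---
title: "Methods: guild extraction, diversity, and null-model assembly inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guild extraction, diversity, and null-model assembly inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feassembly)
```

`feassembly` analyses the biogeography and assembly of iron redox cycling
bacterial guilds (FeOB/FeRB) from 16S OTU tables. This vignette is the
package's account of its methods: the models and statistics it computes,
the assumptions and numerical choices behind them, what the synthetic
generator does and does not emulate, and the design decisions that were
genuinely open.

## Guild extraction

An OTU is retained as a potential iron redox cycling bacterium when two
gates both pass: its genus appears in the guild reference
(`load_guild_reference()`, a flat user-extensible genus → FeOB/FeRB list),
and its best-hit percent identity to a verified FeOB/FeRB sequence passes
the threshold. The threshold is 97% and the comparison is strict (`>`) by
default; a `strict = FALSE` flag switches to `>=`, since boundary handling
at exactly 97.00 is a convention, not a biological fact. An OTU with a
reference genus but a missing similarity value is conservatively assigned
`none`, with a warning: the two-gate AND rule never fills in missing
evidence. Consequences worth knowing: retention is monotone in the
threshold, and filtering commutes with sample subsetting.

## Alpha diversity

- Shannon `H = -sum(p_i * log(p_i))`, natural log (the common default of
  amplicon toolchains); a `base` argument is provided.
- Simpson is the finite-sample probability of identity
  `D = sum(n_i (n_i - 1)) / (N (N - 1))` — two reads drawn without
  replacement are the same species — so smaller means more diverse and a
  single species gives exactly 1. The complement `1 - D` and inverse
  `1 / D` variants are available behind an argument because "Simpson"
  is ambiguous across toolchains.
- Good's coverage `1 - F1/N` estimates sequencing completeness.
- Group differences use the classical one-way ANOVA F
  (`stats::oneway.test` with equal variances); only the omnibus test is
  computed, not post-hoc letters.

## Distances

Bray–Curtis is computed on relative abundances by default (sample totals
may differ between samples); `relative = FALSE` applies the count
formula directly. Geographic distance is the Haversine great circle on a
6371.0 km sphere — at the regional scale of peatland surveys the
difference from ellipsoidal geodesics (< 0.5%) is irrelevant next to
arc-minute coordinate precision. Environmental distance follows the
pipeline log(x+1) → z-score → Euclidean, in that order; pH is z-scored
but never log-transformed (it is already a log-scale quantity).
"Standardized at the same scale" is implemented as z-scoring (mean 0,
sd 1) rather than min–max scaling: z-scores keep Euclidean contributions
proportional to variance rather than range, and are the convention of
`vegan::decostand(method = "standardize")`. Variables with zero variance
after transformation are dropped with a warning. An `env_distance`
caller can disable the log step (`log_vars = character(0)`) for
already-standardized gradients, which may be negative.

## Permutation tests

All permutation tests share one convention: a sampled p-value is
`(1 + #extreme) / (1 + n_perm)`, never below `1/(n_perm + 1)`; when the
full permutation group has at most `n_perm` elements (n ≤ 8) it is
enumerated exhaustively and the p-value is the exact proportion of
permutations at least as extreme, identity included. Mantel permutes
rows and columns of the second matrix jointly and is two-sided on |r|;
the distance–decay regression reports the OLS slope of pairwise
similarity on pairwise distance but takes its p-value from the same
matrix permutation (pairs sharing a sample are not independent, so the
OLS t would be anticonservative); ANOSIM and PERMANOVA permute group
labels, one-sided on large R / F. Ties in ANOSIM ranks are averaged. On
Euclidean distances from univariate data the PERMANOVA pseudo-F equals
the classical ANOVA F exactly, which the tests assert as a cross-module
oracle. Degenerate inputs are defined rather than NaN: an all-zero
distance matrix gives F = 0 and p = 1.

## The null model and assembly classification

The null scheme ("abundance-based") randomizes a community table while
preserving, for every sample, its exact species richness and read total:
OTU identities are drawn without replacement with probability
proportional to occupancy frequency, each drawn OTU receives one read,
and the remaining reads are allocated multinomially in proportion to the
OTUs' regional relative abundances. Occupancy and regional abundance are
taken over **all samples of the table passed** — the regional species
pool (in practice: all samples of a medium) — while only the tested
stratum's samples are randomized. The scheme is pluggable (`scheme`
argument of `generate_null_communities()`) so fixed–fixed or other nulls
can be swapped in.

The standardized effect size is
`SES = (beta_obs - mean(beta_null)) / sd(beta_null)` on mean pairwise
Bray–Curtis dissimilarity, sample (n−1) sd, sign retained: positive SES
means the observed communities are more dissimilar than their null
expectation, and magnitudes near zero indicate stochastic assembly.

The per-stratum significance test is a **two-group PERMANOVA of the
observed samples against one null-community realization** on their
pooled Bray–Curtis matrix. This was a genuinely open design point — a
single F and p per stratum can be constructed in several ways — and the
choice is deliberate: pooling the observed and null *pairwise values*
into a one-way F is far too powerful, because a richness-preserving
identity-redraw null has an intrinsic turnover baseline (≈ 0.25
Bray–Curtis on typical guild tables) different from the multinomial
noise floor (≈ 0.08), so even communities that differ from their
expectation by sampling noise alone would always be declared
significant. The sample-level PERMANOVA instead asks whether the
observed community cloud *sits somewhere else* than the null cloud:
coincident clouds give F near 0 however tight the observed cloud is,
which is exactly the behaviour wanted for neutral data, while
environmental filtering pulls a stratum away from the regional-pool null
and yields large F. The construction is isolated in
`observed_vs_null_test()` so alternatives can be swapped. Classification
is `Determinism` iff p < alpha (default 0.05, strict), else
`Stochasticity`.

Null-model iterations default to 999. Every stratum derives its RNG seed
from the run seed plus a stable hash of the stratum name, so adding a
stratum never perturbs another stratum's draws.

## The synthetic generator

The generator is first-class, tested code: it provides ground truth for
parameter-recovery tests of every downstream statistic. Expected relative
abundance of species *s* at site *i* is

    p_i(s) ∝ A_s * ( w * exp(-(E_i - mu_s)^2 / (2 sigma^2)) + (1 - w) * K_i(s) )

with `A_s` a lognormal (sdlog 1) regional abundance normalized to sum 1,
`mu_s ~ Uniform(-2, 2)` niche optima, `E_i` the site gradient, and
`K_i(s)` a lognormal drift field (mean 1, sd parameter `drift_sd`,
default 2) whose between-site correlation decays as
`exp(-lambda * d_km)`. Counts are multinomial at `reads_per_sample`
trials; replicate plots share the site expectation and differ only by
the multinomial draw. `w = 1` is pure species sorting; `w = 0` with
`lambda = 0` makes every site share one drift realization, so
communities differ by read noise only — the fully mixed neutral limit.
The gradient is `rho * z(latitude) + (1 - rho) * noise` rescaled to unit
sd, so `rho` (default 0.7) sets spatial–environmental collinearity.

Defaults mirror a regional peatland survey at desk cost: 15 sites × 3
replicate plots × two media, 500 species, 5000 reads per sample, guild
fraction 0.15 with 20% of guild species drawn at or below the 97%
identity threshold (so the filter is exercised), sites scattered around
four regional centres spanning the same extent as the packaged tables
(~1100 km).

Two scale choices deserve explanation:

- **Dispersal decay.** `lambda` is per km against between-site distances
  of roughly 50–1500 km, so recoverable values must place the correlation
  length `1/lambda` inside that range; the "strong dispersal" condition
  used in recovery tests is `lambda = 0.005`/km (200 km correlation
  length). Much larger values (e.g. 0.05/km) decorrelate *every* site
  pair at this extent and leave no distance–decay trend to recover at
  any sample size.
- **Niche breadth.** `sigma` is in sd units of the standardized gradient;
  the "sharp niche" recovery condition uses 0.3, i.e. a species' fitness
  falls off well within the observed gradient range.

What the generator does **not** emulate: overdispersed (non-multinomial)
read noise, sequencing error and chimeras, phylogenetic structure among
species, explicit migration dynamics, temporal turnover, and
medium-specific physiology (media are independent realizations of the
same process on one landscape). Passing recovery tests therefore shows
the statistics recover the assembly regime of this generative model —
not that real peatland data are free of the confounders above.

## Problem sizes and reproducibility

The test suite computes its calibration and recovery results at fixed
sizes chosen for a desk machine: type-I error at n = 20 samples, 1000
simulations × 199 permutations (rejection within [0.03, 0.07]);
parameter recovery at the default simulator scale over 10 seeds per
condition with 199 null iterations and 199–999 permutations, with a
run's classification taken as the majority call over its four regional
strata, mirroring per-stratum reporting. `scripts/acceptance.R` recomputes
the same quantities from an installed copy of the package with a
user-supplied seed. All randomness flows through explicit seed
arguments; identical seeds give bit-identical datasets, reports, and
pipeline manifests.

## Known limitations

- Region and peatland-type labels for the packaged site tables: region is
  assigned from the printed coordinates; per-site peatland type is not
  recoverable from the published tables and is `NA` there, so type-wise
  strata require user metadata (or the simulator, where type is known).
- The observed-vs-null F depends on one null realization per stratum; its
  p-value integrates over permutations but not over null draws. Seeds
  make this reproducible, and `n_iter` only affects the SES and null-mean
  estimates.
- Coordinates carry arc-minute precision (~1.9 km); distances between
  co-printed sites can be exactly zero.
- The Simpson variant and Shannon base must match whatever toolchain a
  user compares against; both are arguments, not constants.
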