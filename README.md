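# feassembly

Iron redox cycling bacteria — Fe(II)-oxidizers (FeOB, e.g. *Gallionella*,
*Leptothrix*, *Sideroxydans*) and Fe(III)-reducers (FeRB, e.g. *Geobacter*,
*Geothrix*, *Shewanella*) — drive the coupled carbon/nitrogen/iron
biogeochemistry of peatlands, yet they are a small functional guild hidden
inside whole-community 16S surveys. `feassembly` is an R toolkit for asking,
from an OTU table, a taxonomy with best-hit similarities, and site
metadata: **where are these guilds, how do their communities turn over in
space and along environmental gradients, and is their assembly governed by
deterministic (niche) or stochastic (dispersal/drift) processes?**

The package provides, as composable functions:

- **Guild extraction** — an OTU is "potential iron redox cycling bacteria"
  iff its genus is in an FeOB/FeRB reference list *and* its best-hit
  similarity to a verified sequence exceeds 97% (strict `>` by default).
- **Alpha diversity** — Shannon *H* = −Σ pᵢ ln pᵢ, Simpson's
  probability-of-identity *D* = Σ nᵢ(nᵢ−1)/(N(N−1)), Good's coverage
  1 − F₁/N, plus one-way ANOVA across regions/peatland types.
- **Distance structure** — Bray–Curtis dissimilarity
  d(u,v) = Σ|uᵢ−vᵢ| / Σ(uᵢ+vᵢ), great-circle (Haversine, R = 6371 km)
  geographic distance, and environmental Euclidean distance after
  log(x+1) transformation (pH exempt) and per-variable z-scoring.
- **Permutation inference** — Mantel tests, distance–decay regressions
  (community similarity 1−d against distance, matrix-permutation p),
  ANOSIM and PERMANOVA, with exact enumeration for small n.
- **Assembly classification** — an abundance-based null model that
  preserves each sample's richness and read total while drawing OTU
  identities by occupancy and allocating reads by regional abundance; the
  standardized effect size SES = (β_obs − mean β_null) / sd β_null; and a
  per-stratum observed-vs-null PERMANOVA whose p < 0.05 reads
  **Determinism**, otherwise **Stochasticity** (a Table-3-style report).
- **A synthetic metacommunity generator** in which the expected relative
  abundance of species *s* at site *i* is
  `A_s * (w * exp(-(E_i - mu_s)^2 / (2 sigma^2)) + (1 - w) * K_i(s))` —
  a tunable mixture of species sorting along a gradient (weight `w`) and
  spatially autocorrelated lognormal drift `K` whose correlation decays as
  `exp(-lambda * d_km)` — so every statistic has a ground truth.

The packaged fixtures `table1_soil` (15 sites) and `table2_water`
(18 sites) carry the physicochemistry of peatland sites across four
regions of Northeast China, and `guild_default` is the genus→guild
reference.

## Worked example

```r
library(feassembly)

soil <- load_env_table("table1_soil")
summarize_env(soil, "pH", "min")   # 4.11
summarize_env(soil, "pH", "max")   # 5.59

# a niche-assembled landscape: strong sorting (w = 0.9), sharp niches
cfg <- simulation_config(assembly_weight = 0.9, niche_breadth = 0.3,
                         dispersal_decay = 0, media = "soil", seed = 42)
ds    <- simulate_communities(cfg)
asn   <- classify_otus(ds$taxonomy)            # >97% + reference genus
guild <- subset_by_guild(ds$otu_table, asn)    # 45 samples x 55 guild OTUs

head(alpha_diversity(guild), 3)
#>     sample_id  shannon    simpson goods_coverage
#> 1 S01_soil_r1 2.830663 0.09338985      0.9901768
#> 2 S01_soil_r2 2.735737 0.09995183      0.9847328
#> 3 S01_soil_r3 2.840723 0.08611622      0.9818182

md <- ds$metadata
ed <- env_distance(data.frame(site_id = md$sample_id, env = md$env),
                   variables = "env", log_vars = character(0))
mantel_test(bray_curtis(guild), ed, n_perm = 999, seed = 1)
#> Mantel test: r = 0.8071, p = 0.001 (sampled, 999 permutations)

assembly_report(guild, ds$metadata, strata = "region",
                n_iter = 199, n_perm = 999, seed = 1)
#>          stratum mean_observed_similarity mean_null_similarity     F     p  SES classification
#> 1 soil|region|SJ                    0.630                0.684  7.37 0.001 2.44    Determinism
#> 2 soil|region|CB                    0.617                0.698 14.51 0.001 3.92    Determinism
#> 3 soil|region|LK                    0.591                0.660  9.54 0.001 2.87    Determinism
#> 4 soil|region|GK                    0.573                0.650  5.92 0.008 2.60    Determinism
```

The Mantel r of 0.81 (p = 0.001) says guild community dissimilarity tracks
the environmental gradient; every regional stratum's community cloud sits
significantly away from its null expectation (p < 0.05) with SES well
above zero — the signature of deterministic, niche-based assembly. Rerun
with `assembly_weight = 0` and the same strata read Stochasticity.

`run_pipeline(config)` chains all of the above (inputs or simulation →
validation → guild filter → diversity → distances → Mantel/DDR/ANOSIM/
PERMANOVA → assembly report) into an output bundle with an MD5 manifest;
identical config + seed gives identical hashes.

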