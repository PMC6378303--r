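# NicheAssembly

Niche-breadth partitioning and community-assembly inference for gradient
metacommunities — an R package for microbial ecologists who want to ask
whether habitat **generalists** and **specialists** in an OTU table are
assembled by the same processes.

## What it does

Given a taxa × samples OTU count table and per-sample metadata (elevation,
coordinates, gradient group, soil variables), the package:

1. rarefies samples to a common depth and removes taxa with mean relative
   abundance < 2×10⁻⁵ (which would spuriously look like specialists);
2. computes **Levins' niche breadth** for each taxon j over the n sites,

   B_j = 1 / Σᵢ p²ᵢⱼ,   1 ≤ B_j ≤ n,

   classifies taxa as habitat generalists (B > 8.7), specialists
   (B < 1.5) or other taxa (thresholds configurable or derived from the
   outlier area of the B distribution), and confirms **strict
   specialists** by indicator-species analysis (IndVal > 0.3, permutation
   p < 0.05);
3. contrasts the assembly of the resulting subcommunities:
   α-diversity (observed, bias-corrected Chao1, Shannon, Gini–Simpson),
   Bray–Curtis PCoA and ANOSIM, PCNM spatial eigenvectors with
   permutation-based forward selection, variation partitioning of
   community variance into pure environmental / pure spatial / shared /
   unexplained adjusted-R² fractions, Mantel and partial Mantel tests,
   and **β-diversity null deviation** — the relative difference
   (β_obs − β̄_null)/β_obs between observed β-diversity and its
   expectation over stochastically assembled communities drawn from the
   regional species pool. Deviations near 0 indicate stochastic
   assembly; large positive deviations indicate deterministic,
   niche-based assembly.

A synthetic elevational-gradient generator (`simulateMetacommunity()`)
produces 13-site metacommunities with known specialist / generalist /
neutral structure and realistic soil covariates, so the whole chain is
testable end-to-end without sequencing data.

## Worked example

```r
library(NicheAssembly)

x  <- simulateMetacommunity(simulationConfig(nSpecialist = 60,
                                             nGeneralist = 60,
                                             nNeutral = 300,
                                             depth = 5000), seed = 1)
xf <- filterRare(rarefyCounts(x, depth = 5000, seed = 2))
xf
#> OTUExperiment: 412 taxa x 13 samples
#>   total reads: 64993
#>   sample variables: sample_id, elevation_m, x_m, y_m, gradient, pH, ST, ...
#>   taxon annotation: class, optimum, sigma

part <- nichePartition(xf, nPerm = 99, seed = 3)
part
#> NichePartition: 412 taxa classified
#>   thresholds: specialist B < 1.5, generalist B > 8.7
#>   generalists 62, specialists 55 (strict 0), other 295

nd <- subcommunityNullDeviation(xf, part, nNull = 49, seed = 4)
round(sapply(nd, function(d) mean(deviationPairs(d)$deviation,
                                  na.rm = TRUE)), 3)
#>        all generalist specialist      other
#>      0.611      0.035      0.511      0.627
```

Reading the output: of the 412 taxa that survive the rare-taxon filter,
62 are classified as generalists and 55 as specialists against the
generator's 60/60 truth. The β null deviation of the generalist
subcommunity is ~0.04 — its turnover is statistically indistinguishable
from multinomial draws out of the regional pool (stochastic assembly) —
while the specialist subcommunity deviates strongly (0.51): its
site-to-site turnover cannot be produced without niche structure. (No
strict specialists appear here because single-site specialists have
within-gradient fidelity ≤ 0.25 < 0.3; specialists spanning two or more
sites of a gradient group can pass the IndVal rule.)

`runPipeline(pipelineConfig(...), outdir)` executes the whole chain and
writes partition.tsv, alpha.tsv, bray_curtis.tsv, pcoa_coords.tsv,
anosim.tsv, pcnm_scores.tsv, selected_vars.tsv, vpa.tsv, mantel.tsv,
nulldev.tsv plus a manifest with every seed and parameter; a thin CLI
wrapper lives in `inst/scripts/nba.R`.

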