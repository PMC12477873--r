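# wbmflux

Constraint-based modeling of host–gut-microbiome co-metabolism for
case–control cohorts. `wbmflux` builds abundance-personalized community
metabolic models, couples them to a compartmentalized host model, predicts
each sample's maximal blood-metabolite production capacities by flux
balance analysis (FBA), and decomposes every prediction into per-species
**contribution potentials** using the linear program's own dual solution —
so the question "which microbes could be driving this blood metabolite?"
is answered from one solve per sample and metabolite, with no per-species
re-simulation.

It is aimed at microbiome researchers who want mechanism-based
microbe–metabolite hypotheses (which species is the bottleneck for blood
butyrate? who consumes the nicotinic acid?) rather than abundance
correlations alone, and at methodologists who want the whole chain —
synthetic data, community assembly, LP duals, statistics — testable end to
end.

## The method in brief

For each sample, species-level (pan) reconstructions are joined in a
shared gut lumen; a `communityBiomass` reaction consumes each species'
biomass metabolite with its relative abundance *rᵢ* as coefficient; the
community is merged into a host model's large-intestine lumen and fed a
daily diet. Maximal blood fluxes solve

  max cᵀv  s.t.  S·v = 0,  lb ≤ v ≤ ub

with a demand sink for the metabolite of interest as objective. Coupling
constraints (|v| ≤ 400·v_bio per species) silence non-growing organisms,
and fixing the community-biomass excretion to 1 mmol/day/person pins every
species' biomass flux to its relative abundance.

Shadow prices are reported as π = −δZ/δb (δb = extra availability of a
metabolite). Because biomass fluxes are pinned, the contribution potential
of species *i* to a predicted flux is

  δZᵢ = −π_bio,i · v_bio,i

which is validated in the test suite against a brute-force species-removal
oracle. Downstream, the package runs the cohort statistics: an influence
filter on biomass shadow prices, ALS-PCA outlier scores, log2+z flux
transforms, confounder-adjusted logistic regressions of diagnosis on flux
with Benjamini–Hochberg FDR, 50,000-resample bootstrap ranking of species
contributions, pruning to 95% cumulative contribution, Spearman
flux–microbe correlations, and an exhaustive search for the species
combination (pairs up to quintets) that best explains each flux.

A seeded synthetic generator provides every input — strain catalogs with a
guaranteed sole producer, a miniature whole-body host, compositional
cohorts with planted case effects, metadata, diets with trace entries — so
the entire pipeline is exercised and calibrated on data with known ground
truth.

## Worked example

A synthetic case–control cohort (40 + 40 samples) in which the sole
butyrate producer is depleted 5-fold in cases:

```r
library(wbmflux)
cfg <- pipeline_config(
  synthetic = synthetic_config(n_pd = 40, n_ctrl = 40,
                               effect_map = c(synthetic_sp01 = 0.2), seed = 7),
  n_boot = 5000, seed = 7)
res <- run_pipeline(cfg)

res$regression[, c("metabolite", "beta", "ci_lo", "ci_hi", "p", "q")]
#>   metabolite   beta    ci_lo  ci_hi        p       q
#> 1        but -2.099 -3.28064 -0.917 0.000498 0.00299
#> 2        ppa  0.379 -0.32326  1.080 0.290420 0.34850
#> 3        nac  0.721  0.01610  1.426 0.044992 0.10086
#> 4     pnto_R  0.771 -0.00144  1.543 0.050430 0.10086
#> 5      leu_L  0.444 -0.25716  1.145 0.214574 0.32186
#> 6         ac -0.195 -0.88714  0.497 0.581048 0.58105

res$significant_metabolites
#> [1] "but"

subset(res$contribution_summaries, metabolite == "but")
#>   metabolite        species mean_contribution  ci_lo   ci_hi
#> 1        but synthetic_sp01           14.8200 11.431 18.5668
#> 2        but synthetic_sp02            0.0000  0.000  0.0000
#> 3        but synthetic_sp03           -0.0924 -0.109 -0.0776
#> 4        but synthetic_sp04            0.0000  0.000  0.0000
#> 5        but synthetic_sp05            0.0000  0.000  0.0000
#> 6        but synthetic_sp06            0.0000  0.000  0.0000

res$clusters
#>   metabolite k        species       rho
#> 1        but 1 synthetic_sp01 0.9998359
```

Reading the output: butyrate's blood production capacity carries a
negative log-odds coefficient (β = −2.10 per SD of transformed flux,
q = 0.003) — cases have lower predicted capacity. The contribution table
attributes essentially all of the microbial butyrate capacity to
`synthetic_sp01` (mean potential 14.8 mmol/day/person; the small negative
entry for `synthetic_sp03` is a forced consumer), and the cluster search
confirms that this one species' abundance explains the flux variation
(ρ ≈ 1.00) — exactly the planted mechanism. `write_reports(res, dir)`
writes the flux matrix, regression, contribution, correlation, cluster,
outlier, coverage and cohort-summary tables as CSV.

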