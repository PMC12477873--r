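---
title: "Host–microbiome community flux modeling and species contribution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host–microbiome community flux modeling and species contribution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbmflux)
```

## The model

`wbmflux` asks a mechanistic question about case–control gut-microbiome
cohorts: which blood metabolites *could* the gut microbiome push up or down,
and which microbial species are the bottlenecks? It answers it with
constraint-based community metabolic modeling.

Each sample's microbiome is represented as a stoichiometric community model.
Species-level ("pan") models — unions of strain reconstructions by reaction
ID, with widest-interval bound merging — are connected to a shared gut
lumen. A `communityBiomass` pseudo-reaction consumes each species' biomass
metabolite with its relative abundance $r_i$ as the stoichiometric
coefficient and produces one unit of community biomass. The community is
joined to a compartmentalized host model (diet boundary → large-intestine
lumen → blood → urine/feces) and parameterized with a daily diet.

Maximal blood production capacities are predicted by flux balance analysis:

$$\max_v \; c^\top v \quad \text{s.t.}\quad S\,v = 0,\; lb \le v \le ub,$$

where the objective is an unbalanced demand sink $DM\_{met}[bc]$ for the
blood metabolite of interest. Fluxes are in mmol/day/person and are rounded
to six decimals to suppress numerical artifacts.

Three structural constraints make the species decomposition work:

1. **Coupling** (factor 400): every non-biomass reaction $j$ of species $m$
   satisfies $v_j \le 400\, v_{bio,m}$ (and $v_j \ge -400\, v_{bio,m}$ if
   reversible), so non-growing organisms carry no flux. We implement the
   standard upper-envelope form; the verbal description of coupling as a
   "minimal flux" requirement in parts of the literature describes the same
   inequality seen from the biomass side.
2. **Pinned community biomass**: the excretion of the community biomass
   compound is fixed to `[1, 1]` mmol/day/person, which forces
   $v_{bio,i} = r_i$ for every species in every feasible solution
   (abundance pinning — verified to 1e-6 in the test suite).
3. **Pinned whole-body objective**: host organ biomass production is fixed
   to `[1, 1]` so host maintenance draws are identical across samples.

## Shadow prices and contribution potentials

For the steady-state row of metabolite $i$, the solver's dual $y_i =
\partial Z / \partial b_i$ is reported as a shadow price in the convention

$$\pi_i = -\,\frac{\delta Z}{\delta b_i},$$

where $\delta b_i > 0$ is a production surplus (extra availability) of
metabolite $i$. A negative $\pi$ marks a metabolite whose extra
availability would raise the objective. The mapping from the LP dual to
this convention is a single sign flip, pinned down by finite-difference
perturbation tests. Values with $|\pi| < 10^{-6}$ are reported as exactly
zero; a metabolite is *microbiome-influenced* when any species biomass
metabolite has a nonzero shadow price at that tolerance.

Because $v_{bio,i}$ is pinned to $r_i$, the *contribution potential* of
species $i$ — the maximal change in the predicted blood flux if the species
were removed with all other abundances held fixed — is available directly
from the FBA solution:

$$\delta Z_i = -\,\pi_{bio,i}\, v_{bio,i}.$$

This is a linear extrapolation of the dual over the removal range. The
package ships a brute-force oracle (`brute_force_contribution()`) that
recomputes $\delta Z_i$ by closing the species' biomass reaction while
supplying its biomass metabolite exogenously. When the optimal basis is
stable over the removal range the two agree to numerical tolerance; when
the basis changes (e.g. another producer of the same metabolite takes
over), the linear estimate deviates and the pair is flagged by comparing
the species' shadow price between the full and the reduced solution. Two
genuine caveats, both surfaced by the oracle rather than hidden:

* removals that starve an obligate consumer species make the reduced model
  infeasible — the removal question is then outside the contribution
  definition's domain and the pair is flagged with an undefined oracle;
* duals need not be unique under degeneracy; the solver's basic dual is
  used as-is and disagreements are flagged, never silently averaged.

## The statistical layer

Downstream of the flux matrix the pipeline mirrors a standard
epidemiological analysis:

* metabolites not microbiome-influenced in 95% of samples or more are
  dropped (strictly-greater-than-5% retention rule);
* outlier samples are scored by alternating-least-squares PCA on
  column-z-scored fluxes (3 components by default; ALS tolerates missing
  cells), each sample scored by the Euclidean norm of its component scores
  weighted by explained-variance fractions, and flagged above
  $Q3 + 3\,\mathrm{IQR}$. Flagging is automated but the scores are
  reported for review, since a fixed multiplier can never fully substitute
  for inspecting a score distribution;
* fluxes are log2-transformed (pseudocount: half the smallest positive
  value, only when zeros are present; the value used is recorded) and
  z-scored;
* case status is regressed on the transformed flux by maximum-likelihood
  logistic regression, adjusting for age (z), sex, six binary
  lifestyle/medication covariates and log10 total read count (z), with
  optional flux-by-sex or flux-by-age interactions; Wald 95% CIs; perfect
  separation is flagged and no finite coefficient is reported;
* p-values are Benjamini–Hochberg adjusted; the default significance
  threshold is FDR < 0.1, and near-misses are reported but never
  auto-included;
* per-species contributions are ranked by the magnitude of their
  bootstrap mean (50,000 resamples, percentile 95% CI) — magnitude, because
  consumers carry negative contributions yet are influential — pruned to
  the smallest prefix covering 95% of the total magnitude, correlated with
  fluxes by mid-rank Spearman, and fed to an exhaustive subset search over
  sizes 1–5. The search keeps the largest size whose best $|\rho|$ beats
  the best at *every* smaller size by more than 0.05. (The alternative
  reading — comparison only against the best nested subset — is noted; we
  implement the all-smaller-sizes rule, which is the stricter of the two.)

Cohort description uses Fisher's exact test with *sample* odds ratios
(cross-product of the 2×2 cell counts, Wald CI on the log OR; the
conditional-MLE OR that `fisher.test()` reports does not reproduce printed
cohort tables) and two-sided Wilcoxon rank-sum tests (exact enumeration up
to 10 per group without ties, mid-rank normal approximation otherwise).

## The synthetic generator

No real metagenomes, strain reconstruction resources, or whole-body model
files are bundled; the generator produces structurally faithful miniatures
of each:

* **Strain catalogs.** Each species grows on an always-present staple
  (`glc_D`), converts dedicated dietary precursors into 1–3 product
  metabolites (butyrate, propionate, nicotinic acid, pantothenate,
  L-leucine, acetate) with seeded yields, and optionally *requires* half a
  unit of another species' product per unit of biomass (a forced consumer —
  the mechanism behind negative contributions). Strains of a species share
  the pathway core and differ in filler reactions, so within-species
  reaction overlap exceeds between-species overlap. The first product is
  assigned to the first species only, so every catalog contains a
  guaranteed sole producer for planted-effect experiments.
* **Host template.** Diet, lumen, blood and excretion compartments;
  transports for every universe metabolite from lumen to blood; two organ
  biomass reactions feeding a `Whole_body_objective_rxn` with sex-specific
  organ-weight coefficients; one sex-specific hormone pathway.
* **Diet.** Defaults to 192 entries of which 92 are trace
  (< 0.1 mmol/day/person). The staple is fixed at 400 mmol/day and the
  precursors at 150–500 mmol/day — the magnitude of daily sugar and
  amino-acid intakes — which makes the 400× biomass coupling, not the
  diet, the binding constraint for microbial production, so abundance
  changes are visible in the fluxes. Product metabolites are microbially
  sourced and never dietary. The staple is last in line for trace
  assignment, so communities remain viable for any `trace_fraction < 1`.
* **Cohorts.** Log-normal abundance draws (per-species log-means drawn
  once, per-sample log-SD 0.8) with case-group means multiplied by the
  planted effects before compositional closure; metadata covariates are
  independent Bernoulli draws with group rates loosely matching a PD
  case–control cohort (male fraction 0.63 vs 0.30, laxative use 0.30 vs
  0.11, and so on), exercising confounder adjustment without claiming
  distributional realism.

What passing tests therefore show: the machinery — mapping, assembly,
pinning, duals, contribution decomposition, calibrated statistics — is
correct on data whose generating process is known. What they do not show:
that any particular real cohort's biology matches the toy universe;
genome-scale networks have pathway redundancy, transport diversity, and
degeneracy far beyond the miniature, where basis-change flags would be
correspondingly more frequent.

## Numerical choices

* The LP solver is a dense two-phase bounded-variable revised simplex with
  an explicitly maintained basis inverse (product-form updates,
  refactorization every 100 pivots), Dantzig pricing with an automatic
  Bland's-rule fallback under degeneracy, and bound-flip ratio tests. The
  compiled engine and a pure-R reference implementation of the same
  algorithm are cross-checked on random instances; both are tested against
  exhaustive vertex enumeration and finite-difference dual checks.
  Unconstrained reaction bounds use ±1e6 mmol/day/person; demand sinks use
  [0, 1e6].
* Pivot tolerance 1e-9, reduced-cost tolerance 1e-7, phase-1 feasibility
  tolerance 1e-7; shadow-price zero tolerance 1e-6 (the reporting
  tolerance, distinct from the solver tolerances).
* The relative-abundance filter defaults to 1e-7 as a fraction (0.00001%).
  Where two thresholds circulate for this filter (1e-7 and 1e-6), the
  Methods-level value 1e-7 is the default and the parameter is exposed.
* Removal at the threshold is strict (`< threshold`); an entry exactly at
  the threshold is retained.
* Ties in pruning and in the cluster search break lexicographically by
  species ID, making both invariant to input order.
* Samples sharing a sex and species set share one model skeleton; only the
  `communityBiomass` coefficients are personalized per sample
  (`personalize_abundances()`, tested equal to reassembly from scratch).

## Problem sizes

The shipped tests and the acceptance script run, by choice, at: 100 seeded
toy communities (3–6 species) for the contribution-oracle comparison; 8
joined models for abundance pinning; 500 null cohorts of n = 400 for
type-I calibration; 50,000-resample bootstraps; and 20 seeded cohorts of
100 + 100 samples for planted-effect recovery (0.2× depletion of the sole
butyrate producer, full 6-metabolite panel). These sizes give stable rates
while keeping a full run in the minutes range on one core.

## Known limitations

* Dual non-uniqueness under degeneracy is flagged, not resolved; a
  lexicographic or interior-point tie-break could make contribution
  estimates unique but would no longer match the field's solver behavior.
* The host miniature has no organ resolution beyond two biomass terms and
  no gut-barrier physiology; joint host–microbe flux trade-offs richer than
  lumen competition are out of scope.
* The generator's covariates are independent given the group; real
  confounding structure (age–microbiome interactions, for instance) is not
  emulated.
* `fisher_2x2()` reports Wald CIs on the log sample OR; exact conditional
  CIs would disagree slightly near empty cells (a continuity correction is
  applied and noted there).
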