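# streamMOX

Methane oxidation (MOX) kinetics and methanotroph (MOB) community
landscapes in stream sediments.

Streambed sediments consume much of the methane produced in their anoxic
layers before it escapes to the atmosphere. `streamMOX` is for
biogeochemists and microbial ecologists who measure that sink with
closed-chamber sediment incubations and 16S amplicon surveys. It links the
two: Michaelis–Menten kinetics of sediment MOX,

V(S) = V<sub>max</sub> · S / (K<sub>S</sub> + S),

with V<sub>max</sub> the maximum areal oxidation velocity
(nmol CH₄ m⁻² h⁻¹) and K<sub>S</sub> the half-saturation constant (µM), and
an enterotype-style "community landscape" that places methanotrophic OTUs
(*Methylococcaceae*) in a Bray–Curtis nMDS of the whole community,
clusters them, and asks which other taxa co-occur with each MOB guild.

The package provides:

* **Chamber simulation and inversion** — `simulate_incubation()` integrates
  the chamber mass balance with discrete withdrawal/replacement sampling
  events; `mm_kinetics()` recovers (V<sub>max</sub>, K<sub>S</sub>) by
  trajectory or pointwise nonlinear least squares, with dilution and blank
  corrections, and returns a classed model object with
  `coef`/`predict`/`plot`/`residuals`/`simulate` methods.
  `in_situ_rate()` and `carbon_fixation()` derive putative field rates and
  CH₄-derived biomass carbon.
* **Headspace gas chemistry** — `simulate_headspace()` /
  `dissolved_from_headspace()` convert between dissolved concentrations and
  analyzer mixing ratios for the two-step N₂ headspace-equilibration
  protocol, under a temperature-dependent Henry's-law model.
* **Community landscape** — `mob_landscape()`: relative abundances →
  Bray–Curtis → in-package nMDS (Kruskal stress-1 with isotonic
  regression) → kernel-density landscape with peak calling → k-means MOB
  clusters with an outlier rule → convex-hull co-occurrence and taxonomic
  overrepresentation. `pca_env()`, `fit_vectors()` and `fit_surface()`
  characterize the environmental gradient.
* **Associations** — `fit_linear()`, `associate()`,
  `ks_vs_porewater_ratio()`, `pmoa_fraction()` with explicit site-exclusion
  bookkeeping.
* **Synthetic data with known truth** — `gen_sites()`, `gen_depth_profile()`,
  `gen_otu_table()` (planted MOB co-occurrence clusters), `gen_pmoa_counts()`,
  so every stage has a recovery test.

## Worked example

Simulate triplicate chamber incubations for a site with true
V<sub>max</sub> = 12 nmol m⁻² h⁻¹ and K<sub>S</sub> = 4 µM, with 5%
measurement noise, and fit them jointly:

```r
library(streamMOX)
sim <- lapply(1:3, function(r)
  simulate_incubation(12, 4, schedule = seq(0, 96, 12),
                      noise_cv = 0.05, seed = r,
                      site_id = "agr-3", replicate = r))
fit <- mm_kinetics(sim)
fit
#> Michaelis-Menten MOX kinetics (trajectory fit, site agr-3)
#>   V_max = 11.2 nmol m-2 h-1 (se 0.147)
#>   K_S   = 3.73 uM (se 0.0841)

in_situ_rate(fit, 2.5)       # putative MOX at 2.5 uM in-situ CH4
#> [1] 4.503719
carbon_fixation(in_situ_rate(fit, 2.5))   # nmol C m-2 h-1 at CUE 0.5
#> [1] 2.251859
```

The fitted V<sub>max</sub> and K<sub>S</sub> recover the planted truth to
within the noise level; the in-situ rate evaluates the fitted law at the
field CH₄ concentration (a lab-kinetics extrapolation), and at the default
carbon-use efficiency of 0.5 half of the oxidized CH₄-carbon is counted as
biomass production.

The landscape side, end to end on synthetic data:

```r
panel <- gen_sites(14, seed = 1)          # 2 alpine, 4 forested, 8 agricultural
otu   <- gen_otu_table(panel$sites, 2000, seed = 1)
land  <- mob_landscape(otu$table, k = 2, cutoff = 0.5, seed = 1)
land
#> MOB community landscape
#>   nMDS stress-1 0.0001 over 12 samples (excluded: alp-1, alp-2)
#>   1 density peaks above cutoff 0.50 (max density 29.59)
#>   MOB clusters: 1=23, 2=10, unassigned=3
#>   cluster 1 hull contains 40 non-MOB OTUs
#>   cluster 2 hull contains 94 non-MOB OTUs
```

Samples with at most one methanotrophic OTU (the alpine sites) are excluded
before ordination; the planted 23-member core cluster and the
subset-restricted second cluster are recovered exactly (adjusted Rand index
1 on the 30 planted members), with the remaining low-abundance outlier MOB
OTUs split between "unassigned" and the nearest cluster.

See the methods vignette (`vignettes/stream-methane-oxidation.Rmd`) for the
model, its assumptions, all tunable parameters and the generator's design.

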