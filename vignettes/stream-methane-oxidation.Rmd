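---
title: "Methods: methane oxidation kinetics and MOB community landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methane oxidation kinetics and MOB community landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamMOX)
```

## The scientific problem

Streambed sediments host methane-oxidizing bacteria (MOB) that consume a
large share of the CH4 produced in anoxic sediment layers before it reaches
the atmosphere. Two quantities summarize that sink: the maximum areal
oxidation velocity $V_{max}$ (nmol CH4 m$^{-2}$ h$^{-1}$) and the
half-saturation constant $K_S$ (µM), connected by the Michaelis–Menten rate
law

$$V(S) \;=\; \frac{V_{max}\, S}{K_S + S},$$

where $S$ is the dissolved CH4 concentration. Low-affinity (µM-range $K_S$)
type-I methanotrophs of the family *Methylococcaceae* dominate this guild in
stream sediments. `streamMOX` implements the full chain from raw
closed-chamber incubation measurements to fitted kinetics, putative in-situ
rates and methane-derived carbon fixation, together with the
"community landscape" analysis that places MOB OTUs in an ordination of the
whole microbial community and asks which other taxa co-occur with them.
Because the corresponding field data are not distributed with the package,
a first-class synthetic-data generator reproduces the study design with
known ground truth, so every stage has a recovery test.

## Chamber incubations and the kinetic model

The incubation geometry follows the standard protocol: a closed,
headspace-free 760 cm$^3$ chamber (11 cm diameter × 8 cm height) containing
~25 g wet sediment in a thin layer, filled with streamwater pre-equilibrated
with 1% CH4 in air (≈15 µM dissolved CH4 at 20 °C under the package's
Henry-law model), stirred, dark, at 20 °C. At each sampling, 30 mL of water
is withdrawn for headspace analysis and replaced by air-equilibrated
streamwater, which dilutes the chamber:

$$C \;\leftarrow\; C\,\frac{V_w - v}{V_w} + C_{repl}\,\frac{v}{V_w}.$$

Between samplings the simulator integrates

$$\frac{dC}{dt} = -\frac{A}{V_w}\,\frac{V_{max} C}{K_S + C}$$

with `deSolve::lsoda` (relative tolerance $10^{-11}$), where $A$ is the
sediment surface area in the chamber and $V_w$ the water volume. CO2 is
produced and O2 consumed in configurable stoichiometric ratios (defaults: 1
mol CO2 per mol CH4, and $2(1-\mathrm{CUE}) + \mathrm{CUE}$ mol O2 with
carbon-use efficiency CUE = 0.5); these series are used only for quality
control (intervals with dissolved O2 below 50 µM are flagged as potentially
oxygen-limited and excluded from fitting). Measurement noise is
multiplicative lognormal — concentrations are positive, so no truncation is
needed — and applies to the reported values only, leaving the internal
state and mass ledger exact. The per-event ledger
(initial + added − removed − consumed − remaining) closes to the solver
tolerance and is asserted to $10^{-9}$ relative in the tests.

The sediment surface area is wet mass × specific surface area. Specific
areas of the sediments are not part of the published record, so the default
(1 m$^2$ g$^{-1}$) is an explicit convention carried through every per-area
normalization; rescaling it rescales $V_{max}$ and leaves $K_S$ untouched
(a property the tests assert).

## Parameter estimation

`mm_kinetics()` is the package's central fitting function and returns a
classed object with the usual `coef`/`predict`/`residuals`/`plot`/
`simulate` methods. Two modes are provided:

* **Trajectory mode (default).** The Michaelis–Menten state is propagated
  exactly through the event ledger using the implicit integrated form
  $K_S \ln(C_0/C) + (C_0 - C) = (A/V_w) V_{max}\, t$, solved per interval by
  a safeguarded Newton iteration, and $(V_{max}, K_S)$ minimize the squared
  error between predicted and observed concentrations **on the log scale**.
  The log scale matches the multiplicative error model and keeps the
  low-concentration tail — which carries most of the information about
  $K_S$ — from being drowned out by the early high-concentration points.
  Replicate chambers share parameters. Note the deliberate dual route: the
  simulator integrates the ODE numerically while the fitter uses the exact
  implicit solution, so round-trip recovery tests cross-validate both.
* **Pointwise mode.** Per-interval consumption is computed with the
  dilution correction above, optionally blank-corrected by subtracting the
  interval-matched mean consumption of sediment-free chambers, converted to
  rate points $(S, V)$ — with $S$ the geometric mean of the adjusted
  interval endpoints, since concentration decays roughly exponentially at
  $S \ll K_S$ — and the rate law is fit by nonlinear least squares.

Optimization is bounded ($V_{max} \in [0, 10\times$ max observed rate$]$,
$K_S \in [10^{-3}, 10\times$ max $S]$) on the log scale, with five starts:
a fixed grid of scale multiples covering the near-zero-order and
high-affinity corners (which trap single-start fits) plus seeded jitter for
any additional starts. Ties break by lowest RSS, then lowest $K_S$.
Standard errors come from the local quadratic approximation of the
objective. A series whose total consumption does not exceed 0.1% of the
initial chamber content is reported as $V_{max} = 0$, $K_S = 0$ — an
explicit convention for "no detectable MOX", mirroring how undetectable
activity is reported for alpine sites, rather than a fitted value.

Blank correction is defined on per-chamber amounts (nmol) before any
per-area normalization and assumes the blank and sediment chambers traverse
comparable concentration ranges; when the sediment chamber depletes its CH4
much faster than the blanks, interval-matched subtraction over-corrects
late intervals. The tests therefore exercise it in the mild-depletion
regime where the assumption holds.

Putative in-situ rates evaluate the fitted law at the field CH4
concentration; they are a laboratory-kinetics extrapolation, not a field
measurement. Carbon fixation multiplies the oxidation rate by CUE (default
0.5, 1 C per CH4).

## Headspace gas chemistry

Dissolved CH4 and CO2 are measured by the two-step headspace equilibration:
30 mL of sample equilibrates with 30 mL N2 in a closed syringe, and the
headspace is then diluted to 50 mL with N2 before analysis. The forward
model solves the two-phase mass balance $C_w V_w = K_H p V_w + pV_g/(RT)$
under Henry's law with van 't Hoff temperature dependence (CH4:
$1.4\times10^{-3}$ M atm$^{-1}$ at 298.15 K, 1700 K; CO2:
$3.4\times10^{-2}$, 2400 K; O2: $1.3\times10^{-3}$, 1500 K; validity
0–40 °C). The model is linear in concentration, so the inversion is exact;
tests verify the round trip to $10^{-6}$ relative and the forward model
against a brute-force bisection of the mass balance. CO2 is treated as free
dissolved CO2: carbonate speciation is deliberately out of scope, which
understates total dissolved inorganic carbon but matches what the analyzer
sees after equilibration. Ionic-strength corrections are omitted
(freshwater). The equilibration temperature defaults to the sample
temperature and is configurable, since field and laboratory equilibration
temperatures may differ.

## The community landscape

The landscape pipeline mirrors enterotype-style community typing:

1. Samples containing at most one methanotrophic OTU are excluded — they
   cannot inform MOB co-occurrence (the most oligotrophic sites).
2. Relative abundances → Bray–Curtis dissimilarities → two-dimensional
   non-metric multidimensional scaling. The nMDS is implemented in the
   package: Kruskal stress-1 minimized by alternating isotonic regression
   with Guttman-transform updates, 20 seeded restarts (the first from the
   classical-scaling solution), convergence at stress change $<10^{-6}$ or
   500 iterations, and a guard that terminates a restart should an update
   ever increase stress, so the stress trace is non-increasing by
   construction. Species scores are relative-abundance-weighted averages of
   sample scores, the conventional choice. No additional transformation is
   applied to the abundances.
3. A Gaussian kernel density of all OTU scores on a 100×100 grid (Scott's
   rule bandwidth $h_d = \sigma_d n^{-1/6}$ per axis; the grid is padded by
   the larger of a 5% margin and 3.5 bandwidths so the density integrates
   to ≈1). Peaks are connected components (8-connectivity) of the region
   above a density cutoff, 0.5 by default. Absolute density values depend
   on bandwidth and grid and are not comparable across datasets; only peak
   counts and structure are asserted on synthetic data.
4. MOB OTUs are clustered by seeded multi-start k-means (k = 2). OTUs
   farther than `outlier_rule` (default 3) × the cluster median radius from
   every centroid are labeled "unassigned"; the radius is floored at 10% of
   the inter-centroid distance so the rule stays defined when planted
   clusters are perfectly tight. The published analysis left 6 of 36 MOB
   OTUs outside both clusters without stating the mechanism, so this
   explicit, configurable rule is the package's stand-in. Clusters are
   relabeled by decreasing size, making labels deterministic.
5. Non-MOB OTUs inside each cluster's convex hull (boundary counts as
   inside; collinear hulls degrade to a thin buffered segment with a
   warning) are the co-occurring set, summarized by taxonomic
   overrepresentation at a configurable rank (class by default): share
   among members versus share in the background, with an optional one-sided
   permutation p-value from equally sized random member sets.

PCA of site environmental variables (centered, unit-scaled SVD) and vector
fitting — regression of a variable on the ordination axes with an $R^2$
permutation test — characterize the gradient; `fit_surface()` provides a
penalized low-rank thin-plate smoother (via `mgcv`, GCV penalty selection,
leave-one-out $R^2$ reported) of site variables such as pmoA counts over
ordination space, a deliberately simpler stand-in for a full generalized
additive model analysis.

## What the synthetic generator emulates — and what it does not

`gen_sites()` draws 14 sites from three archetypes (2 alpine, 4 forested, 8
agricultural/urban) spanning the land-use gradient: alpine sites are cold,
ion- and CH4-poor and have no detectable MOX; forested sites have elevated
streamwater CH4; agricultural sites have elevated porewater CH4, ions and
pH. One forested site drains a wetland (both CH4 pools doubled — the
panel's kinetic maxima) and one has anomalously low porewater CH4
(porewater below streamwater, so its $K_S$ far exceeds its porewater
concentration, the kind of site excluded from $K_S$:porewater summaries).
Site-to-site spread is lognormal with CV 0.15. Ground truth ties kinetics
to supply: $V_{max} = 150 \times$ streamwater CH4 (zero at alpine sites),
spanning ≈0–54 nmol m$^{-2}$ h$^{-1}$ across the panel, and
$K_S = 0.88 \times$ porewater CH4 clamped to [0.5, 10.6] µM — so fitted
$K_S$ sits near the porewater concentration, $V_{max}$ regresses strongly
on streamwater CH4, and the ratios and ranges the association layer
computes have a planted expectation. Porewater concentrations are kept in
the low-µM range that matches those affinities; the generator does not
attempt wetland-scale (hundreds of µM) porewater pools. Depth profiles
place the CH4 peak at 10 cm with the porewater value as amplitude and
monotonically decreasing O2.

`gen_otu_table()` plants the community structure: 23 core MOB OTUs present
panel-wide with abundance proportional to streamwater CH4; 7 cluster-2 MOB
OTUs confined to the forested sites plus one agricultural site, carrying
65% of the MOB mass there; 6 low-abundance outlier MOB OTUs, each hosted by
a single peripheral site; and a background of ~2000 OTUs with 2-D Gaussian
niches along the gradient plus an independent local-habitat axis. Three
generator choices deserve emphasis because the ordination degenerates
without them, a lesson from development that applies equally to real data:

* Roughly half the background is cosmopolitan (very broad niches). Stream
  communities share most of their abundant taxa across sites; without that
  core, between-site dissimilarities saturate toward 1 and nMDS collapses
  site groups to single points (a rank-degeneracy: an extreme sample
  dominates the stress denominator and the rest can shrink freely).
* Sites within a land-use class are not replicates: each gets an
  independent secondary niche coordinate, giving the dissimilarity ranks
  the fine texture real data have.
* Library sizes are 150,000–250,000 reads (multinomial sampling), matching
  the sequencing depth of modern amplicon surveys; at a few tens of
  thousands of reads the counting noise on rare MOB members overwhelms
  their co-occurrence signal.

A fraction of the background (10% and 4%) co-varies with each MOB cluster
and is taxonomically enriched in Gammaproteobacteria, Deltaproteobacteria
and Acidobacteria, planting the overrepresentation signal the hull analysis
is meant to recover. The alpine sites carry exactly one MOB OTU, so the
exclusion rule has samples to act on. pmoA counts are proportional to MOB
relative abundance × total cells (one copy per genome) with lognormal noise
and a detection limit (censored values reported as such).

What passing tests therefore show: the estimators recover the truth under
the generative model — Michaelis–Menten depletion with known events and
lognormal measurement error, multinomial counts over planted profiles.
What they do not show: robustness to model misspecification in real
sediments (temperature drift, diffusion limitation despite stirring,
heterogeneous sediment layers, compositional artifacts of relative
abundance, chimeric or mistaxonomized OTUs). The generator makes no attempt
to simulate reads, chimeras or methanogenesis dynamics.

## Numerical choices and problem sizes

* Simulator: `lsoda`, rtol $10^{-11}$, atol $10^{-12}$; the oracle
  comparison against the implicit closed form is asserted at $10^{-6}$
  relative, the mass ledger at $10^{-9}$.
* Closed-form propagation: Newton with bisection bracket on
  $(0, C_0]$, terminating at $10^{-13}$ relative; $K_S = 0$ falls back to
  the zero-order solution (and is otherwise rejected as an undefined
  Michaelis–Menten form unless explicitly requested).
* Fitting: `optim` L-BFGS-B on log parameters, 5 starts, `factr = 1e4`;
  non-convergence is reported in the object, never silently ignored.
* nMDS: 20 restarts, 500 iterations, tol $10^{-6}$; k-means: 20 restarts.
* The test suite and the acceptance script use the panel sizes of the
  emulated design throughout: 14 sites, 3 replicate chambers, twice-daily
  sampling over 4 days, 2000 OTUs, 200 Monte-Carlo fits at 5% noise, 100
  random chamber configurations for the mass-balance property, 150
  replicates × 999 permutations for the null-calibration checks.

## Known limitations

* Trajectory-mode fitting does not subtract measured blanks; it assumes
  streamwater MOX is negligible relative to the sediment. Use pointwise
  mode when blanks matter.
* Rates are reported at the 20 °C incubation temperature; no Arrhenius
  correction to field temperature is attempted.
* A single low-affinity Michaelis–Menten component is assumed; sediments
  hosting an additional high-affinity guild would need a two-component
  model, which is out of scope.
* p-values in the association layer are raw by default (a
  Benjamini–Hochberg option exists); with a 14-site panel the power of any
  multiplicity correction is limited, and the layer is descriptive, as in
  the study design it mirrors.
* Whether CH4 regressions should use log-transformed concentrations is
  left to the user (`log_x`); defaults are raw.
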