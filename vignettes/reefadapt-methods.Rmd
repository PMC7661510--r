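---
title: "Methods: from sea-surface fields and SNPs to per-reef indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sea-surface fields and SNPs to per-reef indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`reefadapt` chains five analyses that together ask whether coral reefs that
have adapted to heat stress, or that are well supplied with larvae, lose
less coral cover after marine heatwaves. This vignette explains each model,
its assumptions, the tunable parameters, and the design choices made where
the underlying methodology leaves room.

```{r setup, eval = FALSE}
library(reefadapt)
```

## 1. Thermal stress metrics

The heat-stress chain follows the Coral Reef Watch accumulation logic.
For each reef cell:

* **Monthly climatology** — mean SST per calendar month, by default over the
  full series (`monthly_climatology()`); the **MMM** is the warmest month's
  mean, the reference temperature corals are acclimatized to.
* **Hotspot** — `SST − MMM`, kept only when SST is at least `min_excess`
  (default 1 °C, boundary inclusive) above the MMM; smaller excesses are
  treated as 0. This retention rule encodes the observation that sub-degree
  excursions do not bleach corals.
* **Bleaching alert** — a day is flagged when the hotspot sum over the
  trailing window (default `window_days = 84`, i.e. three months) is
  positive. Because hotspots are non-negative, "sum > 0" is equivalent to
  "some day in the window was a hotspot day".
* **BAF_year** — flagged fraction of each calendar year; years before
  `first_valid_year` are dropped, because an MMM estimated from too few
  early years would bias the flags. **BAF_overall** is the unweighted mean
  of BAF_year.

**Window convention.** Whether "the previous 84 days" includes the current
day is a genuine ambiguity; we take the window to *end at and include* the
day, matching the accumulation style of degree-heating metrics. The first
`window_days − 1` days use the available prefix; they precede any valid BAF
year, so the choice is inconsequential downstream. Both the window length
and the retention threshold are arguments.

**Missing data.** Missing SST days are excluded from climatological means
and yield missing hotspots; a flag is raised if any non-missing hotspot in
the window is positive. Synthetic series use a 365-day calendar (no leap
days) so planted truths are closed-form; real calendars only change the
month bookkeeping.

## 2. The current-driven transition graph

Sea currents make dispersal asymmetric: going with the flow is easy,
against it hard. The graph encodes this with one node per sea pixel and,
for each ordered pair of adjacent pixels (8-neighborhood by default,
diagonals at `L√2`), a cost

```
cost(i → j) = L / ( max(0, w̄ · d̂) + ε )
```

with `L` the center distance (km), `w̄` the mean current vector of the two
pixels (m/s), `d̂` the unit step direction and `ε > 0` a base conductance
(default 0.01 m/s). The literature behind this workflow states only that
transition costs are *inversely proportional to the frequency of transition
under the currents*; the projected-velocity-plus-ε form is this package's
codification and is the main modelling knob: `ε` sets how permeable the
seascape is against the flow (upstream steps cost at most `L/ε`). Cost
units are therefore km/(m/s) — dimensionless "cost units" for all practical
purposes, since only ratios and thresholds matter.

The temporal mean field over the full current record defines one static
graph; each reef cell is represented by the sea pixel nearest its centroid
(one node per cell keeps the distance matrix cells × cells). Directed
least-cost distances are exact Dijkstra shortest paths (igraph); unreachable
pairs are kept as `Inf` rather than dropped. Reversing every current vector
provably transposes the matrix — one of the package's property tests.

## 3. Connectivity indices and the CDt threshold

`OCI(i)` is the total reef area within `d(i → j) ≤ CDt`, `ICI(i)` the total
area with `d(j → i) ≤ CDt`; the focal cell is excluded from its own
neighborhood by default (`include_self = FALSE`) since the indices describe
*neighboring* reefs. `CDt` is calibrated to the widest neighborhood that
cannot reach beyond the study area: the largest multiple of `granularity`
(default 100 cost units) strictly below the smaller of the two border
minima. With border minima of 836 and 801 units this gives 800. On the
synthetic toy seascapes, whose cost scale is smaller, the pipeline uses
granularity 10; the rule is the same.

## 4. Adaptation models and PA_HEAT

Each putatively adaptive genotype g gets a logistic genotype–environment
model `logit P(presence) = a_g + b_g · BAF_overall`, fitted by Newton
iteration on the ridge-penalized Bernoulli likelihood
(`ℓ − λ‖(a,b)‖²`). The default `λ = 1e-4` is negligible for well-behaved
data but keeps estimates finite under the quasi-separation that extreme
sites produce; `λ = 0` gives the plain MLE and explicitly signals
non-convergence under complete separation. "Presence" means the individual
carries at least one copy of the associated allele (dominant coding).

**Cross-validation.** Leave-one-population-out: refit without one site,
predict its genotype frequency from its BAF, and correlate predicted with
observed frequencies across sites (Pearson), per genotype; genotypes whose
observed frequency does not vary have undefined r and are excluded from the
per-species mean ± sd (our reading of the ambiguous "mean ± sd" aggregation:
over genotypes within species). The same procedure applied to genotypes
drawn at random from a non-adaptive pool (with replacement, `n_draws`
default 1000) gives the chance baseline. Note the baseline is *negatively*
biased, not zero-centred: predicting a signal-free site frequency from the
remaining sites anticorrelates mildly with the observation — the same
slightly negative baselines the original analysis reports. What matters is
the contrast: adaptive genotypes sit far above the baseline.

**Pooling.** One binomial GLMM of presence on BAF with crossed random
intercepts for genotype, individual and species, estimated by Laplace
approximation via glmmTMB — the estimation route standard for this model
class (adaptive quadrature is not available for crossed designs in the
installed stack, and glmmTMB is what the field uses). Random terms that are
unidentifiable on the data at hand (fewer than two levels, or one
observation per individual) are dropped with a warning and reported as zero
variance; a variance estimated at the zero boundary triggers a classed
"boundary" warning rather than an error, since the fixed effects remain
valid. **PA_HEAT** is the population-level prediction
`plogis(â + b̂ · BAF)` (random effects at zero) — a deterministic, strictly
monotone transform of BAF.

## 5. Genetic structure vs seascape distance

The response matrix is per-site minor-allele frequencies (minor allele
defined globally, then per-site frequency = copies / 2·called; sites with
fewer than 5 samples dropped), Hellinger-transformed (square root of the
row-normalized entries, making Euclidean distances between sites
ecologically meaningful), then reduced by PCA to the smallest set of axes
reaching 80% cumulative variance.

The predictors are dbMEMs of the seascape distances: the two directed
least-cost distances of each site pair are reconciled by their arithmetic
mean (min/max available behind a flag; the methodology is silent on this),
then the classical PCNM construction — truncation at the longest edge of
the minimum spanning tree, distances beyond it replaced by four times the
threshold, principal-coordinate analysis of `−D²/2`, positive-eigenvalue
axes scaled by `√λ`. Our construction matches `vegan::pcnm` to numerical
precision (a cross-check in the test suite; the implementation here is
independent so permutation seeds and truncation stay under package
control).

**RDA and selection.** The redundancy analysis regresses the centered PC
scores on the predictors; `pseudo-F = (SS_fit/m) / (SS_resid/(n−m−1))`,
significance by unrestricted row permutations of the response
(`p = (1 + #{F* ≥ F}) / (n_perm + 1)`; 999 permutations plus the observed
ordering = the conventional "1000 permutations"). Forward selection uses
the field's double stopping rule *plus the global pre-test*: no variable is
considered unless the full model is itself significant, then candidates are
admitted by largest adjusted-R² gain while their marginal permutation p is
≤ α and the running adjusted R² stays below the full model's. The global
gate is what keeps the procedure's type-I error near nominal (verified at
α = 0.05 over 400 null replicates in the tests); without it the best-of-k
selection step alone rejects too often.

## 6. Coral-cover models

Cover rates in (0,1) are modelled as
`y ~ Beta(μφ, (1−μ)φ)` with `logit μ = Xβ + u_station`,
`u_station ~ N(0, σ²)` — a beta-regression mixed model with a single
precision parameter and station random intercepts absorbing the repeated
visits of irregular survey histories. Estimation is Laplace via glmmTMB
(same rationale as §4). Covariates are standardized to mean 0 / sd 1 before
fitting, so coefficients are comparable across indicators. Cover values of
exactly 0 or 1 are undefined under the beta likelihood; with
`squeeze = TRUE` (default) they are pulled inside by `(y(n−1)+0.5)/n`, the
standard beta-regression compromise, and with `squeeze = FALSE` they are an
error.

The model sets mirror the analysis design: four univariate fits (one
indicator each) and three interaction fits with fixed effects
`{BAF_prev, BAF_prev × M}` for each moderator M ∈ {PA_HEAT, ICI, OCI} —
deliberately *without* the moderator's main effect, following the stated
two-fixed-effect design (a with-main-effect variant is a flag). Wald z
tests per coefficient, `AIC = 2k − 2 logLik` for comparison, no multiplicity
correction.

## 7. The synthetic seascape and what it does (not) show

The generators are pure functions of their arguments and a seed
(bit-reproducible; each pipeline stage derives its own seed from the global
one). They emulate:

* a sinusoidal annual SST cycle (default mean 26 °C, amplitude 2 °C,
  maximum mid-February as in the southern-hemisphere summer) with
  rectangular warm-season heat anomalies and i.i.d. Gaussian daily noise —
  the simplest signal that exercises the ≥1 °C retention rule and yields a
  closed-form planted truth (on noise-free series the thermal module must
  reproduce the planted alert days *exactly*, and does);
* a smooth directed current field: constant drift plus Gaussian daily
  noise;
* genotype tables in which adaptive genotypes follow a planted logistic law
  in site BAF and neutral genotypes are BAF-independent Bernoulli draws;
* diploid SNP tables whose site allele frequencies follow the leading
  dbMEM axes of the actual seascape distances (so the structure stage has a
  recoverable signal);
* cover surveys from the exact beta mixed model of §6, with a latent
  station heat level linking BAF covariates to a logistic PA response and
  correlated lognormal connectivity indices.

The defaults (12×10 grid with a 3-cell offshore margin, 25 km² cells, 8
years of SST, 14 warm-season anomalies of 2.5 °C × 15 days, 8 sites × 20
individuals, slope 15 per unit BAF, 60-SNP diploid tables, 15 stations,
station sd 0.2, precision 40) are one fixed set of "study conditions" —
chosen to be of realistic magnitude for a reef system while keeping the
demo pipeline under ~10 s — not dials to be adjusted per analysis.

What passing on synthetic data does *not* show: real SST products have
clouds, gaps and autocorrelated anomalies; real currents are eddying, not
drift+noise; real allele frequencies carry drift, admixture and
linkage; real surveys have observer effects. The synthetic world validates
the *machinery* (definitions, algorithms, inference), not the ecological
conclusions.

## 8. Numerical choices and test problem sizes

* Newton logistic: step-halving line search, tolerance 1e-10 on the step,
  100 iterations max; complete separation detected combinatorially.
* RDA: QR-based least squares; a numerically zero residual sum of squares
  yields `F = ∞` (so a noiseless response gets the extreme permutation
  p-value `1/(n_perm+1)`), a numerically zero added SS in forward selection
  yields partial F = 0; admission requires an adjusted-R² gain above 1e-9
  to avoid floating-point ties.
* dbMEM eigenvalues are kept when above `1e-9 × max`; MST by Prim's
  algorithm.
* glmmTMB's "singular convergence" (a variance at the zero boundary) is
  reported as a boundary warning, not a failure.
* Test suite problem sizes: 200 random ≤12-node worlds for the brute-force
  shortest-path oracle; 25 random ≤20-cell instances for the index oracle;
  200 replicates at n = 2000 for GEA slope recovery and 40 for the CV
  contrast; 400 null replicates (99 permutations each) for RDA calibration;
  100 replicates of 600 records / 60 stations for cover-model recovery and
  40 for the AIC ranking. These sizes give stable pass/fail behavior at
  conventional Monte-Carlo error.

## 9. Known limitations

* The conductance form and `ε` are a modelling choice; only the qualitative
  downstream/upstream asymmetry is identified by the source methodology.
* One sea node per reef cell ignores within-cell heterogeneity; reef
  polygons are out of scope.
* No temporal structure in the cover models beyond the station intercept
  (no AR terms, no spatial random fields) and no zero-inflation.
* No Degree Heating Weeks or alert severity levels; a single binary alert.
* Upstream SNP discovery (the genotype–environment scan that labels
  genotypes adaptive) is out of scope; genotype tables arrive labelled.
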