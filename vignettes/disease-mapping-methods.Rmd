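---
title: "Small-area disease mapping with sirbym: models, choices and limits"
author: "sirbym maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area disease mapping with sirbym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sirbym` implements a complete inference chain for areal case-count
epidemiology — the kind of analysis a cancer registry runs when it asks
whether a disease's incidence clusters geographically and whether an
area-level exposure explains the pattern. This vignette is the package's
account of its methods: the models, the tunable parameters and their
defaults, the numerical choices, what the synthetic-data generator does
and does not emulate, and the known limitations.

## The data model

The analysis unit is a *geographic area* (GA): a privacy-aggregated
spatial unit with a planar centroid (km), a male population aged 35+, a
family-physician density (physicians per 1000 population), a remoteness
index, and observed prostate-cancer case counts in four risk levels —
the three GUROC clinical levels (high, intermediate, low) plus
"metastatic". A `StudyRegion` stores these as a
`SummarizedExperiment`: rows are areas, columns are risk levels, the
`counts` assay holds the observed counts, and `rowData` carries the
area attributes. The row ordering is fixed at construction and shared by
every downstream vector and matrix.

## Standardized incidence ratios

Expected counts use indirect standardization: the region-wide rate is
applied to each area's population,

$$E_i = n_i \frac{\sum_i O_i}{\sum_i n_i},$$

so $\sum_i E_i = \sum_i O_i$ and the crude SIR $O_i/E_i$ measures
departure from regional parity. Areas with zero population are retained
in tables (SIR undefined) but excluded from all SIR and clustering
vectors — mirroring how registries drop unpartitionable regions rather
than zero-filling them.

SIR bins follow the reporting convention of six categories. The verbal
labels overlap at their boundaries, so the package fixes a convention:
the central "within 10%" bin is closed, $[0.9, 1.1]$, because a value
exactly 10% from parity is still "within 10%"; the outward bins are
half-open — $(1.1, 1.5]$, $(1.5, 2.0]$, $(2.0, \infty)$, mirrored below
one — so the six bins partition $[0, \infty)$ exactly and bin counts are
reproducible.

The annual coefficient of variation uses the sample (n−1) standard
deviation over yearly totals; on the five-year reference case series the
verification suite uses (564, 640, 659, 565, 563 cases) this convention
gives 7.9%, where the n-denominator version would give 7.1% — the
convention matters at n = 5 and is therefore fixed and documented.

## Spatial weights

Two neighbourhood structures are built from the same 120-km
distance band over centroids (inclusive at exactly the radius; planar
Euclidean distances, so inputs must be pre-projected):

* **inverse-distance weights** $w_{ij} = 1/d_{ij}$ for the Moran
  statistics, row-standardized by default. Row standardization is the
  GeoDa default and makes the spatial lag an average of neighbours; the
  unstandardized path is kept selectable (`standardize = FALSE`) for
  sensitivity checks because source analyses do not always state the
  convention.
* **binary adjacency** for the intrinsic CAR prior. The CAR
  neighbourhood is genuinely a modelling choice; reusing the 120-km band
  keeps the prior aligned with the correlation structure the weights
  already assume, and the radius is configurable.

Isolated areas (no neighbour within the band) are permitted: they
contribute nothing to Moran sums and their structured effect is pinned
at zero in the BYM model (below).

## Moran statistics

Global Moran's I is
$I = (n/S_0) \sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2$ with $z$ the
deviations from the mean; its null expectation under random relabelling
is $-1/(n-1)$. Inference is by permutation: the observed values are
reassigned uniformly over the areas and the pseudo p-value is
$(1 + \#\{I^{perm} \ge I\})/(n_{perm}+1)$, one-sided toward the observed
tail (mirrored when $I$ falls below its expectation). 999 permutations
is the default.

A note on calibration: a "reject when the directional pseudo-p is below
$\alpha$" rule is two-tailed in disguise — under a flat surface it fires
at about $2\alpha$, since either tail can trigger it. The calibrated
$\alpha$-level test, and the scientifically relevant one for cluster
detection, is the one-directional test of *positive* autocorrelation
($I$ above its expectation with small high-tail p). The package's
calibration suites therefore measure that one-directional rejection
rate, and it sits inside the exact binomial band around 0.05 across 200
null simulations. The same applies to the scan statistic's
higher-than-average cluster.

Local Moran's I per area is
$I_i = z_i \sum_j w_{ij} z_j / m_2$ with $m_2 = \sum_k z_k^2/n$ (the
n-denominator variance; conventions differ and this one makes
$\sum_i I_i$ proportional to the global numerator). Inference holds
$z_i$ fixed and permutes the remaining values among the other areas
(conditional permutation). Significant areas are classified by the signs
of $(z_i, \text{lag}_i)$ into High-High, Low-Low, Low-High, High-Low;
everything else is Not Significant. LISA p-values are deliberately
*not* multiplicity-adjusted by default — reported cluster counts in the
field are based on raw $\alpha = 0.05$ — but `adjust = "fdr"` is
available. One master seed derives a deterministic per-area substream,
so results do not depend on the order areas are processed.

## Kulldorff's spatial scan

Candidate zones are circles centred on area centroids, grown by adding
areas in increasing centroid distance while the zone population stays
within a maximum fraction of the total (default 0.25; configurable per
risk level — the pipeline default uses 0.30 for metastatic and 0.25
otherwise). Under the conditional Poisson model the
log-likelihood ratio of a zone with $O$ observed, $E$ expected and $T$
total cases is

$$\Lambda = O\log\frac{O}{E} + (T-O)\log\frac{T-O}{T-E},$$

zero-count terms evaluated as zero; direction is "high" when $O > E$.
The most-likely cluster per direction is the max-LLR zone; secondary
clusters are reported greedily in LLR order, skipping any zone that
shares even one member area with an already-reported cluster (the
strictest non-overlap convention, chosen for determinism). LLR ties
break toward the smaller population, then the lexicographically smaller
centre id. Monte-Carlo inference conditions on the observed total:
replicates redistribute $T$ cases multinomially with probabilities
$E_i/\sum E$, and each reported cluster's p-value compares its LLR to
the replicate-wide maxima of its own direction.

The maximum window fraction is treated as an analysis *setting* (the
published phrasing could also describe resulting cluster sizes); it is
exposed per risk level precisely because of that ambiguity.

## The BYM model

Counts are modelled as $O_i \sim \text{Poisson}(E_i \theta_i)$ with

$$\log \theta_i = c + \beta x_i + u_i + v_i,$$

where $u$ is a spatially structured effect with an intrinsic CAR prior
(pairwise-difference form
$\frac{\tau_u}{2}\sum_{i \sim j}(u_i - u_j)^2$), $v_i \sim N(0,
1/\tau_v)$ exchangeable, $c$ and $\beta$ flat over the real line, and
$\tau_u, \tau_v \sim \text{Gamma}(0.5, 0.0005)$ — read as shape-rate,
the OpenBUGS convention; shape-scale would change the prior spread
substantially, so the pair is exposed as arguments. The null model drops
$\beta$; ecological models are "unconditional" — one covariate per run —
and covariates enter unstandardized so that $\exp(\beta)$ is the
incidence rate ratio per one unit (e.g. per 1 physician per 1000
population).

### Sampler

`runBYM` is Metropolis-within-Gibbs, with the sweep in compiled code:

* random-walk Metropolis for each $u_i$, $v_i$, $c$ and $\beta$;
* conjugate Gamma draws for the precisions —
  $\tau_u \sim \Gamma(0.5 + \mathrm{rank}/2,\; 0.0005 + \frac{1}{2}\sum_{i\sim j}(u_i-u_j)^2)$
  with rank = (non-isolated areas) − (connected components), and
  $\tau_v \sim \Gamma(0.5 + n/2,\; 0.0005 + \frac{1}{2}\sum_i v_i^2)$;
* the iCAR impropriety is handled by recentring $u$ to sum to zero
  within each graph component after every sweep (the GeoBUGS-style
  constraint) with the flat intercept absorbing the level; isolated
  areas have $u_i$ fixed at zero and are excluded from the pairwise term
  and the rank;
* proposal step sizes adapt toward 30–45% acceptance during burn-in
  only, in windows of 100 sweeps, and are frozen afterwards to preserve
  detailed balance. Acceptance rates outside [0.05, 0.95] after
  adaptation raise a warning.

The default schedule — 3 chains × 30,000 iterations, burn-in 10,000,
thinning 10, overdispersed intercept starts and distinct initial
precisions — is a desk-scale working default sized so that full
parameter-recovery suites run on one CPU in minutes; registry-scale
schedules (the original analyses ran hundreds of millions of iterations
in OpenBUGS) are available through the same arguments. A pure-R
`logPosterior` implements the same joint density as an independent
cross-check path; unit tests verify the precision full-conditionals
against it symbolically and the no-neighbour limit against an external
sampler of the reduced exchangeable model.

Smoothed SIRs are posterior means of $\theta_i$: strictly positive even
where $O_i = 0$, and pulled toward the neighbourhood/regional level
where expected counts are small — on moderate-count regions the
smoothed range sits inside the crude range. IRRs are reported as
$\exp(\bar\beta)$ — exp of the posterior mean rather than the posterior
mean of $\exp\beta$; the former is the convention under which a
three-decimal coefficient maps deterministically to a three-decimal IRR
(−0.067 gives 0.935) — with the 95% CrI as exp of beta's 2.5% and 97.5%
quantiles; an association is "significant" when that interval
excludes 1.

## Convergence diagnostics

Four checks per monitored scalar (intercept, coefficient, both
precisions):

* **PSRF** $\hat R = \sqrt{((n-1)/n \cdot W + B/n)/W}$;
* **Geweke** $z$ comparing the first 10% with the last 50%;
* **Heidelberger-Welch** Cramér-von-Mises stationarity with iterative
  10%-discards up to 50%, plus the relative half-width test;
* **Raftery-Lewis** two-state run-length control at
  $(q, r, s) = (0.025, 0.005, 0.95)$, whose i.i.d. floor is
  $\Phi^{-1}(0.975)^2 q(1-q)/r^2 \approx 3746$.

Spectral variances use non-overlapping batch means with
$\lfloor\sqrt{n}\rfloor$ batches. The batch-size-$\sqrt{n}$ rule is
chosen over fewer-larger-batch alternatives because Geweke's 10% first
window is short: with only a handful of batches the variance estimate
has so few degrees of freedom that $z$ is t-tailed and the nominal
$|z| \le 1.96$ rate is visibly exceeded; with $\sqrt{n}$ batches the
statistic is calibrated once chains are reasonably long, which is how
the calibration suite checks it. Two guards: a constant chain returns
$z = 0$, and when a segment's mean is within sampling noise of zero
(|mean| ≤ 5 standard errors) the half-width verdict is *indeterminate*
(`NA`) rather than failed, because relative precision of a zero mean is
meaningless.

Verdict aggregation (the sources name the tests but no rule): a
parameter *passes* when $\hat R \le 1.1$, $|z| \le 1.96$, both HW flags
hold and the retained draws meet the Raftery-Lewis requirement; one
failed check gives *warn*, two or more give *fail*. The Raftery-Lewis
check is treated as met when the retained chain is shorter than its
pilot minimum (it then carries no evidence either way). Heavy-tailed
precision chains under near-null data commonly draw a *warn* here; that
is the diagnostic being honest, not a sampler defect.

## The synthetic-data generator

`syntheticScenario()` describes the study conditions the package is
exercised under, and its defaults are fixed once:

* **82 areas** on a jittered 60-km grid (~540 × 480 km domain — the
  scale of a prairie province's populated half), so the 120-km band
  yields a connected graph;
* log-normal populations, median 2500 men 35+ per area (log-sd 1,
  total ≈ 3×10⁵);
* per-level 5-year case rates (0.00135, 0.0036, 0.0035, 0.0015 for
  metastatic/high/intermediate/low), sized so level totals land around
  400/1100/1050/450 — roughly a 13/36/35/15% risk-level mix;
* a physician-density-like covariate, log-normal with median 1 per 1000
  (log-sd 0.6), i.i.d. by default with a spatially smooth option;
* risk surfaces $\log\theta = c + \beta x + u + v$ with $u$ drawn from
  the intrinsic CAR distribution — a centred multivariate normal on the
  graph Laplacian's pseudo-inverse, per connected component, scaled by
  `sdU` — and $v$ i.i.d. normal. This is the same density the sampler
  assumes, written as an independent code path; defaults
  `sdU = 0.3, sdV = 0.1` give moderate autocorrelation, and
  `sdU = sdV = 0` is the flat null surface;
* optional planted circular clusters multiplying $\theta$ before
  Poisson sampling.

Three fixed-seed fixtures ship with the package (null, clustered,
covariate-effect regions, labelled synthetic in their filenames); tests
verify they regenerate byte-identically from their scenarios.

One property of iCAR draws matters for interpretation: an individual
draw is occasionally rough (its low-frequency modes happen to be small),
so a fixed `sdU` does not guarantee a visibly clustered surface on every
seed. The generator-to-Moran detection property is therefore stated
conditionally: among surfaces whose *true* relative-risk field is
autocorrelated, the Moran test detects ≥95%.

What the generator does **not** emulate: real provincial geography and
its coastline/river irregularities, registry residence-code privacy
aggregation, demographic age structure (indirect standardization is on
total male 35+ population), covariate-confounded spatial trends, and
reporting artefacts. Passing tests demonstrate the chain recovers what
it assumes — CAR-structured log-linear risk with Poisson sampling — not
that real registry data satisfy those assumptions.

## Pipeline and reproducibility

`runPipeline()` mirrors the published workflow per risk level: SIR table
always; Global Moran gate (p ≤ α) jointly enabling LISA and the scan —
the gate reflects the reported practice of studying only levels with
significant global autocorrelation further, and `forceClustering`
overrides it; BYM null and one-covariate models always, each with a
diagnostics report. All randomness funnels through one master seed via
pre-drawn stage seeds, so a rerun with the same configuration reproduces
every output byte-for-byte. `summarizeTables()` reshapes a run into the
four report-style tables (bin counts, Moran/LISA counts, crude-vs-
smoothed ranges, coefficient/IRR table with "Not significant" exactly
when the IRR CrI spans 1).

Problem sizes used by the shipped verification suites (chosen as the
package's working scale): brute-force oracles at n ≤ 12 areas;
calibration at 200 null regions of 82 areas with 999
permutations/replicates; covariate recovery at 50 regions of 82 areas
with the default 3 × 30,000 schedule; diagnostics calibration on chains
of 5,000–20,000 draws.

## Known limitations

* The scan implements circular windows and the Poisson model only — no
  elliptic windows, space-time scan, or Bernoulli/ordinal variants.
* The BYM implementation is the classical parameterization; Leroux/BYM2
  reparameterizations and INLA-style approximations are out of scope, as
  are multivariable (conditional) ecological models.
* Moran inference is permutation-based only (no analytical variants);
  Getis-Ord statistics are not provided.
* Distances are planar: coordinates must arrive in a projected CRS in
  km; no geodesic computation is attempted.
* The Gamma(0.5, 0.0005) hyperprior is informative about precision
  scale; analyses of very sparse counts should consider sensitivity to
  it (both parameters are exposed).
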