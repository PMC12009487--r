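---
title: "Methods: Bayesian space-time disease mapping and cluster detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian space-time disease mapping and cluster detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stsir)
```

# The problem

County-level cancer registries report observed case counts $Y_{ij}$ and
populations $n_{ij}$ for a handful of regions $i = 1,\dots,I$ over a run of
years $j = 1,\dots,J$. Two questions recur: *where and when* is incidence
higher or lower than the province-wide experience, and *how should
small-county rates be stabilized* so that a county of 50,000 people is not
declared a hotspot on the strength of a handful of cases? `stsir`
implements the standard answer to both: crude and Bayesian-smoothed
standardized incidence ratios, a retrospective space-time scan statistic
for formal cluster detection, and a model-comparison battery to choose
among competing space-time smoothing models.

# Standardization

Expected counts are indirectly standardized:
$E_{ij} = n_{ij}\,\hat r_j$ where $\hat r_j = \sum_i Y_{ij} / \sum_i
n_{ij}$ is the pooled rate of year $j$ (`per_year`, the default), or the
single decade-pooled rate (`overall`). Per-year standardization calibrates
$\sum_i E_{ij} = \sum_i Y_{ij}$ exactly in every year, which is also the
calibration the scan statistic assumes ($E[C] = C$). The crude SIR is
$Y_{ij}/E_{ij}$; a value above 1 means more cases than the pooled rate
predicts. No age or sex standardization is attempted: expected counts are
population-proportional only, so differences in county age structure are
absorbed into the spatial effects. That is a documented limitation, not an
oversight.

# The space-time scan

Candidate clusters are cylinders: a circular base (the $k$ nearest
regions to a center, by great-circle centroid distance, $k \ge 1$)
crossed with a year window. Caps bound the search: a cylinder may span at
most half the study period and at most half the population at risk. The
population cap is evaluated on person-time — the cylinder's population
summed over member regions and window years against the same sum for all
regions over that window — which reduces to the usual base-population rule
when populations are constant over time.

Each cylinder is scored with the discrete-Poisson log-likelihood ratio

$$\mathrm{LLR} = c \log\frac{c}{e} + (C - c)\log\frac{C - c}{C - e},$$

with $c$ and $e$ the observed and expected counts inside, $C$ the total,
and $0\log 0 = 0$. The maximum-LLR cylinder with $c > e$ is the primary
high-rate cluster (symmetrically $c < e$ for low-rate); secondary clusters
are the next-best cylinders sharing no region with a better-ranked
reported cluster of the same direction. Relative risk contrasts inside
versus outside: $\mathrm{RR} = (c/e) / \left[(C-c)/(C-e)\right]$.

Significance uses conditional Monte Carlo. Because per-year expecteds fix
each year's total by construction, the null replicates redistribute each
year's observed total over its regions as a multinomial proportional to
$E_{ij}$ (with `overall` expecteds, a single multinomial over all cells is
used instead). Each replicate contributes its direction-restricted maximum
LLR, and $p = (1 + \#\{\text{null max} \ge \mathrm{LLR}\})/(1 + B)$, so
with the default $B = 999$ the smallest attainable $p$ is 0.001. We
verified the device is calibrated: under a null generator the primary
cluster rejects at 5% close to 5% of the time (the acceptance suite runs
this experiment with 200 replications).

# The six Bayesian space-time models

Counts follow $Y_{ij} \sim \mathrm{Poisson}(E_{ij}\theta_{ij})$. The
nonparametric decomposition is

$$\log\theta_{ij} = \alpha + v_i + u_i + \gamma_j + \phi_j\;(+\,\delta_{ij})$$

with $v_i$ exchangeable Gaussian (unstructured spatial), $u_i$ intrinsic
CAR on the queen-contiguity graph (structured spatial; full conditionals
$u_i \mid u_{-i} \sim N(\bar u_{\delta_i},\, \sigma_u^2/n_{\delta_i})$),
$\gamma_j$ a second-order random walk (structured temporal; penalizes
second differences, so its null space is any linear trend), and $\phi_j$
exchangeable temporal. The interaction $\delta_{ij}$ takes one of the four
Knorr-Held types, formed by crossing unstructured/structured space with
unstructured/structured time: type I iid over cells, type II independent
random walks in time within regions, type III independent ICAR fields
within years, type IV the Kronecker combination (ICAR $\otimes$ walk).
The parametric alternative replaces the temporal terms with a linear
trend, $\log\theta_{ij} = \alpha + u_i + v_i + (\beta + \delta_i)t_j$,
with $t_j$ the year index centered at the period midpoint and the slope
deviations $\delta_i$ iid Gaussian. These six variants — no interaction,
types I-IV, parametric — are the comparison set of `all_model_specs()`.

**Priors.** Every random-effect precision has a $\mathrm{Gamma}(1,
5\times10^{-5})$ prior (equivalently a log-gamma prior on the log
precision, the default many disease-mapping analyses inherit from
standard software). $\alpha$ and $\beta$ get vague Gaussians (precision
0.001). The interaction walk order defaults to 1 and is configurable to 2;
only the main temporal trend is hard-wired RW2.

**Identifiability.** Sum-to-zero constraints are imposed on $v$, $u$,
$\phi$; on $\gamma$ additionally orthogonality to the linear trend (its
null space); interactions carry the corresponding margin constraints
(type II rows, type III columns, type IV both). The parametric
$\delta_i$ are also constrained to sum to zero so $\beta$ alone carries
the global slope. All constraints are enforced *exactly* by sampling each
effect in the orthonormal eigenbasis of its structure matrix restricted to
positive eigenvalues: a field $u = V z$ with
$z_k \sim N(0, 1/(\tau\lambda_k))$ reproduces the pairwise-difference ICAR
(or difference-penalty walk) kernel on precisely the identified subspace.
For an RW2 interaction walk this removes the full Kronecker null space,
i.e. slightly more than the margin constraints (per-region linear-in-time
directions as well); the posterior is proper either way.

# Sampling

At $9\times10$ cells the exact-likelihood posterior is cheap, so inference
is MCMC rather than an approximation. The sampler combines four moves per
sweep:

1. **Joint latent-field update.** All coefficients (intercept, every
   effect block) are proposed at once from a Gaussian approximation at the
   *mode* of their conditional posterior given the precisions — Newton/IWLS
   iterated to convergence (the target is log-concave, so the mode is
   unique), then a Metropolis-Hastings accept step. Because the proposal
   does not depend on the current state, it is an independence sampler;
   acceptance rates run 0.85-0.97 on panels at registry scale. Chains are
   initialized at the conditional mode: a flat start sits so deep in the
   tail that the first proposal would essentially never be accepted.
2. **Conjugate precision updates.** Given an effect block $z$ with
   eigenvalues $\lambda$, $\tau \mid z \sim \mathrm{Gamma}(1 + k/2,\;
   5\times10^{-5} + \tfrac12\sum\lambda_k z_k^2)$.
3. **Interweaved rescaling.** For each block, a proposal that moves
   $\tau$ while holding the *standardized* effects fixed (so the field
   amplitude moves with the precision). Without it a block whose precision
   drifts high during warmup pins its field at zero and cannot re-enter.
4. **Re-allocation and mode swap within confounded pairs.** The
   unstructured and structured spatial effects span the same sum-to-zero
   subspace; the likelihood sees only their sum (similarly for the
   temporal pair, and for a type-I/III interaction against the main
   effects). Holding the summed field fixed, the split is re-sampled from
   its exact Gaussian conditional, and a deterministic involution proposes
   exchanging the two fields together with their precisions, letting
   chains hop between the "$v$ explains it" and "$u$ explains it" modes.

Convergence is monitored with the split-chain potential scale reduction
factor over every scalar (all coefficients and log precisions); a fit with
any $\widehat R \ge 1.05$ is flagged invalid and refused by downstream
functions unless forced. Defaults are 4 chains of 1000 warmup + 1000 kept
draws; the recovery batteries in the test suite use 2 chains of 300 + 300,
which at this problem size gives Monte Carlo error well inside the
tolerances tested.

**What is, and is not, identified.** Because the BYM pair $(v, u)$ — and
the temporal pair $(\gamma, \phi)$ — are likelihood-identified only
through their sum, the allocation of variance between the members is
driven by the prior. The $\mathrm{Gamma}(1, 5\times10^{-5})$ precision
prior has density proportional to $\mathrm{sd}^{-3}$ on the
standard-deviation scale, so the posterior for the weaker member of a
confounded pair concentrates near zero. We validated this against an
exact computation (Laplace-marginalized likelihood with two-dimensional
quadrature over the two spatial precisions on a spatial-only toy): the
exact posterior mean of $\sigma_u$ was 0.04 when the generating value was
0.30, matching the MCMC. Users should therefore read the *composite*
field scales, cell-level $\theta$ and its intervals — which are identified,
and whose ~95% interval coverage the test suite confirms — rather than
individual confounded hyper-standard-deviations. Interaction and slope
standard deviations, which own 70-90 dimensions, are well recovered.

# Model comparison

All criteria are computed from the same per-draw per-cell Poisson
log-likelihood matrix; nothing is refitted. DIC uses the plug-in deviance
at the posterior mean of the *linear predictor*; WAIC uses the log
pointwise predictive density minus the summed posterior variance of the
log-likelihood; CPO is the per-cell harmonic-mean leave-one-out predictive
(cells with unstable or zero-likelihood weights are flagged, not silently
smoothed); the PIT uses the mid-correction for discrete counts,
$\overline{F(y)} - \tfrac12\overline{f(y)}$, since the plain PIT of counts
is non-uniform even under the true model. PIT uniformity is tested with
the Anderson-Darling statistic for a fully specified Uniform(0,1) null,
with p-values from the standard asymptotic null distribution implemented
in-package. $R^2$ is reported as the squared Pearson correlation between
crude and posterior-mean SIRs across cells — the published analyses this
package emulates never define their $R^2$, so the definition is an
explicit interpretation here, with a deviance-based pseudo-$R^2$
selectable. The "best" flag in `compare_models()` uses WAIC; the
conventional reading (lower DIC/WAIC, higher $\Sigma\log$CPO and $R^2$) is
printed alongside so disagreements are visible.

# The synthetic generator

`hamadan_fixture()` supplies a 9-county, 2010-2019 skeleton emulating a
western-Iran provincial registry: constant per-year populations at the
published order of magnitude (two county populations and four group sums
match published cluster-population totals; the splits inside those groups
and all centroid coordinates are invented placeholders near public census
figures, and are documented as synthetic). `simulate_panel()` draws every
effect from the same constrained Gaussians the models assume — ICAR and
RW2 fields via the eigenbasis, using the pseudo-inverse structure exactly
(no approximation is needed at $10\times10$ matrices) — computes $\theta$,
and draws $Y_{ij} \sim \mathrm{Poisson}(E_{ij}\theta_{ij})$ from a flat
baseline rate (default 107.72 cases per 100,000 per decade, giving roughly
1900 cases per decade at fixture scale). `inject_cluster()` multiplies
$\theta$ inside a chosen cylinder and redraws the affected counts, which
is how the scan's power experiments embed known clusters.

What the generator does *not* emulate: age/sex structure, registry
artefacts (late registration, death-certificate-only cases, geocoding
failures), population drift within the decade, and overdispersion beyond
what the random effects induce. Passing tests therefore demonstrate
correctness of the machinery under the model's own assumptions, not
robustness to real registry pathologies.

# Experiment sizes and numerical choices

The test-suite experiments use: 200 replications with 199 Monte Carlo
replicates for scan calibration; 20 seeds with 999 replicates for cluster
recovery (an RR 1.82 cylinder over two regions and five years, embedded
in a flat-risk panel); 20 replicates per model variant for parameter
recovery, simulated at roughly 200 expected cases per cell (the scale at
which the identified hyperparameters are informative) with 2 chains of
300 + 300 draws; and 10 seeds of six fits each for model recovery. These
sizes were chosen as the smallest at which the Monte Carlo error is
comfortably inside the tested tolerances.

Numerical details: linear predictors are clamped to $\pm 30$ before
exponentiation; eigenvalues below $10^{-8}$ of the largest are treated as
null space; centroid-distance ties are broken by canonical region order
(and logged); duplicate cylinders arising from different centers are kept
during search (the argmax is unaffected) and deduplicated by the
non-overlap rule at reporting time; the pseudo p-value uses $(1+r)/(1+B)$;
per-year strata with zero cases get zero expecteds with a warning, and
SIRs there are `NA`, never infinity. Islands (degree-0 regions) are
permitted but flagged; the ICAR eigenbasis then simply excludes the
island's constant direction, which is the "conditional mean 0" convention.

# Known limitations

Only population-proportional standardization; vertex-based queen
contiguity (a boundary point shared geometrically but present as a vertex
in only one polygon is missed); no covariate terms in the models; no
elliptical or prospective scan windows; the harmonic-mean CPO estimator
is flagged but not replaced by importance-sampling alternatives; and the
confounded hyper-standard-deviations discussed above are reported but
should not be over-interpreted.
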