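# stsir — Bayesian spatiotemporal disease mapping and space-time cluster detection

`stsir` is an R package for small-area spatiotemporal analysis of disease
incidence from region-by-year count panels, written for the setting of a
provincial cancer registry: a handful of counties, a decade of annual
counts, populations of 10^5–10^6, and a few thousand cases. It provides:

- **Standardized incidence ratios.** Indirectly standardized expected
  counts `E_ij = n_ij * (Σ_i Y_ij / Σ_i n_ij)` (per-year or pooled) and
  crude SIRs `Y_ij / E_ij`.
- **Space-time scan statistic.** Retrospective discrete-Poisson scanning
  over cylindrical windows (circular base of nearest regions × year
  window), scored by the log-likelihood ratio
  `LLR = c log(c/e) + (C−c) log((C−c)/(C−e))`, with high- and low-rate
  primary/secondary clusters, relative risks
  `RR = (c/e)/((C−c)/(C−e))`, and conditional Monte Carlo pseudo
  p-values.
- **Six hierarchical Bayesian space-time models** fitted by MCMC:
  `log θ_ij = α + v_i + u_i + γ_j + φ_j (+ δ_ij)` with BYM spatial
  effects (exchangeable `v`, intrinsic CAR `u` on queen contiguity), RW2
  temporal trend `γ`, exchangeable `φ`, the four Knorr–Held interaction
  types for `δ`, plus a parametric linear-trend variant
  `log θ_ij = α + u_i + v_i + (β + δ_i) t_j`.
- **Model comparison:** DIC, WAIC, Σlog CPO, mid-PIT with an
  Anderson–Darling uniformity test, and SIR-scale R².
- **A synthetic-data generator** (9 regions × 10 years, provincial scale)
  with known ground truth and cluster injection, so every stage is
  testable end to end.

## Worked example

```r
library(stsir)

fx <- hamadan_fixture()                       # 9 counties, 2010-2019
sim <- simulate_panel(fx$panel, fx$graph, model_spec(),
                      sd_v = 0, sd_u = 0, sd_gamma = 0, sd_phi = 0, seed = 7)
inj <- inject_cluster(sim$panel, sim$truth, c("Tuyserkan", "Hamadan"),
                      c(2015, 2019), rr = 1.82, seed = 8)

E <- expected_counts(inj$panel, "per_year")
scan_clusters(inj$panel, fx$centroids, E, scan_config(seed = 9))
```

```
space-time scan: 11 reported cluster(s) over 1120 cylinders
   cluster_rank direction           regions start  end population observed expected     oe     rr      llr p_value
1       primary      high Tuyserkan|Hamadan  2015 2019    3833070      753  580.435 1.2973 1.4370 32.10787   0.001
8       primary       low  Malayer|Nahavand  2015 2019    2464075      278  373.130 0.7450 0.7109 15.56059   0.001
...
```

The primary high-rate cluster recovers the injected cylinder — the two
central counties over 2015–2019 — with an observed/expected ratio of 1.30
and pseudo p = 0.001 (the smallest attainable with 999 Monte Carlo
replicates); the complementary low-rate cluster appears in the south
because the injected excess raises the province-wide expected rate. The `llr` column is the Poisson scan statistic above; `rr`
contrasts risk inside the cylinder against everywhere else.

Fitting and comparing the six Bayesian variants:

```r
graph <- fx$graph
fits <- lapply(all_model_specs(), function(sp)
  fit_st_model(inj$panel, E, graph, sp, chains = 2,
               warmup = 500, draws = 500, seed = 1))
compare_models(fits, crude_sir(inj$panel, E))
adjusted_sir_table(fits$typeII)   # smoothed SIR per county-year with 95% CI
```

`compare_models()` returns one row per model with DIC, WAIC, Σlog CPO,
the PIT Anderson–Darling test and R², flagging the WAIC-best model; lower
DIC/WAIC and higher Σlog CPO/R² indicate better fit.

## The analysis workflow

`analysis/` contains the numbered drivers that reproduce the full study
shape on synthetic registry panels, writing all tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # two panels (colorectal- and gastric-like)
Rscript analysis/02_sir.R        # crude SIR tables (map analogue)
Rscript analysis/03_scan.R       # cluster tables with pseudo p-values
Rscript analysis/04_models.R     # six fits per panel, comparison, adjusted SIRs
```

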