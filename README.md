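# meropk

Meropenem, the workhorse carbapenem of intensive-care antibiotic therapy, is
chemically unstable in aqueous solution: hydrolytic opening of its
beta-lactam ring converts it into an inactive open-ring metabolite (ORM).
`meropk` follows that degradation "from the bottle to the body" for
continuous-infusion regimens, for pharmacometricians and TDM laboratories:

* **In-vitro kinetics** — fit the first-order decay `C(t) = C0·exp(−k·t)` to
  infusate (saline, 22 °C) and buffered-serum (37 °C) concentration–time
  series; derive half-lives, 24 h recovery, the pharmacopoeial 90 %
  stability window `−ln(0.9)/k`, and the ORM mass-balance deficit against
  the theoretical equimolar-conversion curve.
* **Population PK** — a steady-state one-compartment model with zero-order
  input in which total clearance is partitioned,
  `CL_i = (GFR_i·0.06 + CL_nonGFR + CL_decay)·exp(η_i)`, with the renal part
  fixed per patient to the measured GFR, `CL_decay = k_serum·V` fixed from
  the in-vitro serum rate, and the residual part estimated. The nonlinear
  mixed-effects estimator (Laplace approximation, with adaptive
  Gauss–Hermite quadrature as an alternative) is implemented in the package,
  with finite-difference standard errors, empirical Bayes estimates,
  shrinkage, and goodness-of-fit tables.
* **Clinical metrics** — the ORM metabolic ratio
  `C_ORM/(C_ORM + C_meropenem)` on mass or molar basis, urine-collection
  creatinine clearance, and a permutation test for the ratio–GFR
  association.
* **Synthetic data** — seeded generators for stability series and
  steady-state TDM cohorts with the study's design (duplicate assays with
  ~5 % proportional noise; GFR 28–307 mL/min; 3–6 g/24 h continuous
  infusion; once-daily steady-state sampling), used throughout the tests
  and reproducibility scripts.

## Worked example

Simulate a serum stability experiment at the study's design and fit it:

```r
library(meropk)

serum <- sim_decay_series(k = 0.025, c0 = 50, noise = assay_noise(cv = 0.05),
                          seed = 2026, matrix = "serum")
fit <- fit_first_order_decay(serum)
stability_report(fit)
#> Stability report (threshold 90%)
#>   k = 0.0226 /h, t1/2 = 30.66 h
#>   stability window = 4.661 h, recovery at 24 h = 58.1%
#>   5/13 scheduled time points within specification
```

The fitted rate (0.0226/h here; true value 0.025/h, assay CV 5 %) yields a
half-life of ~31 h and only ~58 % recovery after 24 h at body temperature —
serum degradation is brisk enough to matter, which is exactly why it enters
the PK model as a fixed clearance component, `CL_decay = 0.025 × 26.2 L =
0.655 L/h`.

Now a steady-state cohort and the mixed-effects fit:

```r
cohort <- sim_cohort(cohort_spec(n_patients = 300, seed = 2026))
pk <- fit_poppk(cohort)
pk
#> Steady-state population PK fit (laplace; 300 patients, 1200 observations)
#>   CL_nonGFR  = 3.74 L/h (RSE 3%)
#>   omega CL   = 16.0 CV% (RSE 5%) [eta-shrinkage 7%]
#>   sigma prop = 13.2 CV% (RSE 2%) [eps-shrinkage 11%]
#>   -2LL = 5471.45 (NONMEM-comparable OFV 3266.00); status: converged

partition_clearance(result = pk, gfr_summary = 139)
#> Clearance partition (L/h):
#>   CL_GFR      8.34  (65%)
#>   CL_nonGFR   3.74  (29%)
#>   CL_decay    0.66  ( 5%)
#>   total      12.74
```

The cohort was simulated at `CL_nonGFR = 3.6` L/h, `ω = 14.9` CV % and
`σ = 13.5` CV %; the estimator recovers all three within a few percent, and
the partition shows the characteristic ordering — renal filtration dominates
total clearance, the unexplained (enzymatic/secretory) component is about a
third, and spontaneous decay contributes only a few percent.

A command-line interface over the same functions is installed under
`exec/meropk` (`simulate-decay`, `simulate-cohort`, `fit-decay`,
`fit-poppk`, `metrics`, `run-all`), and `run_full_pipeline()` /
`render_report()` run the whole chain — stability fits → decay-clearance
bridge → popPK → metrics — into a checksummed, seed-reproducible run
directory.

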