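Package: meropk
Title: Meropenem Degradation Kinetics and Steady-State Population Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the "bottle-to-body" analysis of meropenem under
    continuous infusion: first-order degradation kinetics of the infusate and
    of buffered serum with pharmacopoeial stability windows and open-ring
    metabolite (ORM) mass balance; a steady-state one-compartment population
    pharmacokinetic model whose total clearance is partitioned into a
    GFR-fixed renal component, an in-vitro-fixed spontaneous-decay component
    and an estimated residual component, with nonlinear mixed-effects
    estimation (Laplace approximation and adaptive Gauss-Hermite quadrature)
    implemented in the package; ORM metabolic ratios and creatinine-clearance
    utilities; and seeded synthetic-data generators for stability series and
    steady-state TDM cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
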