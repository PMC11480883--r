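Package: taueff
Title: Effective Rotational Correlation Times from 15N Spin Relaxation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes total effective rotational correlation times (tau_eff) of
    protein backbone N-H bonds directly from transverse 15N spin relaxation
    rates (R2). Provides forward Redfield calculators mapping multi-exponential
    spectral-density models to R1, R2 and heteronuclear NOE; a linear
    approximation tau_eff = k*R2 with per-field proportionality constants; a
    numerically inverted one-timescale estimator; feasible-region bounds on
    tau_eff for a given R2; and a multi-field chemical-exchange (Rex)
    correction. Includes a correlation-function toolkit (P2 autocorrelation of
    unit-vector trajectories, non-negative multi-exponential fitting, rotational
    diffusion simulation), readers for CSV and NMR-STAR relaxation tables,
    per-residue pipelines, region summaries and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
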