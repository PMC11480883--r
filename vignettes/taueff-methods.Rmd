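---
title: "Effective correlation times from 15N relaxation: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective correlation times from 15N relaxation: models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taueff)
```

## The model

The rotational dynamics of a backbone N–H bond is described by the
second-order orientational correlation function
$g(t) = \langle P_2(\mathbf{u}(0)\cdot\mathbf{u}(t))\rangle$, assumed to
decay multi-exponentially:
$$g(t) = \sum_{i} \alpha_i e^{-t/\tau_i}, \qquad \sum_i \alpha_i = 1 .$$
Its Fourier transform is the spectral density
$$J(\omega) = \sum_i \alpha_i \frac{2\tau_i}{1+\omega^2\tau_i^2},$$
normalized so that $J(0) = 2\tau_{\mathrm{eff}}$ with
$\tau_{\mathrm{eff}} = \sum_i \alpha_i\tau_i$, the **total effective
correlation time**: the area under $g(t)$, containing internal *and* overall
rotations. This is the quantity `taueff` estimates. It deliberately does not
separate order parameters from timescales — that separation (Lipari–Szabo)
requires more experimental parameters per residue and breaks down for
disordered and micelle-bound systems.

The forward map from dynamics to observables is the Redfield theory of
$^{15}$N relaxation by the $^1$H–$^{15}$N dipolar interaction and the
$^{15}$N chemical shift anisotropy (CSA), as implemented in
`relaxation_rates()`. Writing $d \equiv d_{NH}$ and evaluating $J$ at the
five frequencies $0$, $\omega_H-\omega_N$, $\omega_N$, $\omega_H$,
$\omega_H+\omega_N$:

$$R_1 = \tfrac{d^2}{40}\left[J(\omega_H{-}\omega_N) + 3J(\omega_N)
  + 6J(\omega_H{+}\omega_N)\right] + \tfrac{\Delta\sigma^2\omega_N^2}{15}J(\omega_N)$$
$$R_2^\circ = \tfrac{d^2}{40}\left[4J(0) + J(\omega_H{-}\omega_N) + 3J(\omega_N)
  + 6J(\omega_H) + 6J(\omega_H{+}\omega_N)\right]
  + \tfrac{\Delta\sigma^2\omega_N^2}{90}\left[4J(0) + 3J(\omega_N)\right]$$

The prefactor convention (dipolar $d^2/40$; axially symmetric CSA with
$\Delta\sigma^2\omega_N^2/90$ on $[4J(0)+3J(\omega_N)]$, hence
$\Delta\sigma^2\omega_N^2/15\,J(\omega_N)$ in $R_1$) is tied to the
$J(0)=2\tau_{\mathrm{eff}}$ normalization. It is validated two ways in the
test suite: against a brute-force oracle that computes $J$ by direct Fourier
quadrature of $g(t)$, and by reproducing the per-field proportionality
constants tabulated in `fitted_lines()` at all fifteen spectrometer
frequencies to two decimals.

### Physical parameters

| parameter | default | why |
|---|---|---|
| $\gamma_H$ | $2.6752218744\times10^8$ rad s$^{-1}$T$^{-1}$ | CODATA |
| $\gamma_N$ | $-2.7126180436\times10^7$ rad s$^{-1}$T$^{-1}$ | CODATA; the sign enters only the hetNOE |
| $\Delta\sigma$ | $-160$ ppm | standard amide $^{15}$N CSA |
| $r_{NH}$ | $1.01$ Å (effective) | motionally averaged $\langle r_{NH}^3\rangle^{1/3}$ |
| $N_H$ | 1 | one amide proton; not configurable |

All internal frequencies are rad/s, times s, rates s$^{-1}$; conversion to
ns and MHz happens only at the user-facing boundary. `nmr_constants()`
exposes the set, and `delta_sigma = 0` switches the CSA mechanism off (used
for closed-form limit checks).

## The estimators

Substituting the spectral density into $R_2^\circ$ splits it into a term
linear in $\tau_{\mathrm{eff}}$ plus Lorentzian terms:
$R_2^\circ = (4K_1+4K_2)\tau_{\mathrm{eff}} + \text{(non-negative)}$, with
$K_1 = d^2/20$, $K_2 = \Delta\sigma^2\omega_N^2/45$.

* **Linear** (`tau_eff_linear()`): $\tau_{\mathrm{eff}} = kR_2^\circ$,
  $k = (4K_1+4K_2)^{-1}$. Because every Lorentzian term is non-negative,
  this is an *exact upper bound* for any mixture of timescales; it
  overestimates when timescales below roughly 3 ns carry weight.
* **Fitted** (`tau_eff_fitted()`): the MD-calibrated per-field correction
  $\tau_{\mathrm{eff}} = mR_2^\circ + c$ with $c<0$, compensating that
  overestimation. The calibration is per-field, so the constants are applied
  only at the fifteen tabulated frequencies — interpolating between fields
  would use the lines outside the data that produced them, so it is refused
  rather than guessed (`0.5` MHz matching absorbs spectrometer-frequency
  conventions like 599.9 vs 600). Results at or below zero are returned
  flagged `non-physical`, never clamped: a clamp would silently turn a
  diagnostic (R$_2^\circ$ too small for this field's calibration) into a
  fake number.
* **One-timescale** (`tau_eff_one_timescale()`): solves
  $R_2^\circ(\tau) = R_2$ for a single-timescale model. $R_2^\circ(\tau)$ is
  strictly increasing on the search bracket, so the root is unique; it is a
  lower limit for fast rotation and approaches the linear estimate
  asymptotically (within 2% by 50 ns).
* **Feasible bounds** (`feasible_tau_bounds()`): both $R_2^\circ$ and
  $\tau_{\mathrm{eff}}$ are linear in the mixture weights, so the set of
  achievable $(R_2^\circ, \tau_{\mathrm{eff}})$ pairs is the convex hull of
  the single-timescale curve. The upper boundary is exactly $kR_2^\circ$;
  the lower boundary is read off the lower convex hull of the curve sampled
  on a log grid (default 800 points over $10^{-13}$–$10^{-6}$ s). The grid
  was chosen so the chord-interpolation error of the hull is below
  $10^{-4}$ relative; the range covers sub-ps librations to µs tumbling,
  beyond which no protein backbone signal is expected.

### Chemical exchange

Experimental $R_2$ contains an exchange term, $R_2 = R_2^\circ + R_{ex}$,
from µs–ms kinetic processes. With data at a single field it is invisible
and simply inflates $\tau_{\mathrm{eff}}$ (qualitatively the right
direction — such residues are slower — but quantitatively wrong). With
$\ge 2$ fields, `tau_eff_rex_corrected()` separates it by assuming
fast-exchange quadratic field scaling, $R_{ex} = \Phi\,\omega_N^2$. This
scaling is the standard fast-exchange limit and the only simple law that
renders $\tau_{\mathrm{eff}}$ field-independent; slow or intermediate
exchange would need dispersion experiments, which are out of scope. The fit
minimizes the summed squared residuals over $(\tau, \Phi\ge 0)$: $\Phi$ has
a closed-form least-squares solution at fixed $\tau$ (clamped at zero and
flagged `rex-pinned-zero` when negative), and $\tau$ is optimized on a log
scale — a profiled 1-D problem with no initialization sensitivity.

Two or three fields spanning 500–700 MHz determine $(\tau, \Phi)$ exactly
from noiseless data, but the two field-dependence patterns
($\partial R_2^\circ/\partial\tau$ vs $\omega_N^2$) are nearly collinear
over such a span, so measurement noise is amplified: with 2% relative noise
on three rates the linearized covariance of the fit puts the relative
standard deviation of $\hat\tau$ near 10%. Users should not over-interpret
single-residue exchange amplitudes from narrow field spans; wider spans or
more fields tighten the fit. The acceptance script computes the observed
median error under exactly these conditions.

## Correlation toolkit

* **ACF estimator** (`p2_autocorrelation()`): the all-origins average
  $\langle P_2(\mathbf{u}(t)\cdot\mathbf{u}(t{+}\Delta))\rangle_t$, computed
  via FFT cross-correlations of the six quadratic products $u_au_b$ —
  identical to the direct sliding window (a test asserts this) but
  $O(n\log n)$. Lag 0 is included and must equal 1; the constructor refuses
  to renormalize silently.
* **Multi-exponential fitting** (`fit_multiexponential()`): non-negative
  least squares on a fixed log-spaced timescale grid (default 64 points,
  1 ps–1 µs) rather than free nonlinear fitting. The problem is convex,
  reproducible and initialization-free. Individual $(\alpha_i,\tau_i)$ on
  the grid are not uniquely identified — only smooth functionals such as
  $\tau_{\mathrm{eff}}$ are, which is all the downstream estimators need.
  Weights are renormalized to $\sum\alpha=1$ with the achieved $g(0)$
  reported; when more than 90% of the weight lands beyond the observed lag
  window the fit is flagged `non-decaying`. For noisy single-trajectory
  ACFs the grid should be capped near the observed lag window: slower
  components are not identifiable from the data and act as a sink for the
  long-lag noise floor.
* **Integration** (`tau_eff_from_acf()`): trapezoidal integral plus a tail
  correction. The default exponential extrapolation fits $\log g$ over the
  last decade of lags; plain truncation biases $\tau_{\mathrm{eff}}$ low by
  the truncated tail area (for an exponential observed to $10\tau$, by
  $e^{-10}$), so it is opt-in.
* **Generator** (`simulate_rotational_diffusion()`): isotropic rotational
  diffusion as a unit-vector random walk with Gaussian per-step angular
  displacements of variance $2D_r\Delta t$ per axis, requiring
  $D_r\Delta t < 0.05$. Its closed form $g(t) = e^{-6D_rt}$, hence
  $\tau_{\mathrm{eff}} = 1/(6D_r)$, makes every stage of the chain testable
  without external data.

### What the generator does and does not emulate

The random walk emulates a bond undergoing single-timescale isotropic
rotational diffusion — the cleanest possible input. It does **not** emulate
anisotropic tumbling, restricted internal motion superimposed on overall
rotation, exchange contributions, or the noise structure of real relaxation
measurements (mixtures of timescales are covered separately by analytic
multi-exponential fixtures and random mixture models). Passing tests
therefore demonstrate correctness of the estimator chain, not robustness to
every pathology of experimental data.

### Validation problem sizes

End-to-end validation simulates $D_r = 5\times10^7$ s$^{-1}$ at
$\Delta t = 10$ ps for $2\times10^5$ frames per trajectory, averaging the
ACF over an ensemble of 16 independent bond vectors (as MD analyses average
over residues) with a 2000-frame lag window. ACF sampling noise scales as
$\sqrt{2\tau_{\mathrm{eff}}/T_{\mathrm{total}}}$, so the ensemble brings the
recovered $\tau_{\mathrm{eff}}$ reliably within a few percent of $1/(6D_r)$;
property tests use $10^4$ random mixture models per field.

## Numerical choices

* Root finding: `stats::uniroot` on $\log\tau$ over $[10^{-13},10^{-6}]$ s
  (uniform relative resolution across seven decades), tolerance $10^{-14}$
  in $\log\tau$; the residual is checked against $10^{-8}R_2$ and an
  out-of-range $R_2$ reports the achievable interval instead of
  extrapolating.
* Exchange fit: `stats::optimize` on $\log_{10}\tau$, tolerance $10^{-12}$;
  noiseless recovery is exact to $\sim10^{-7}$ relative.
* NNLS: `pracma::lsqnonneg`; weights below $10^{-12}$ of the total are
  dropped before building the model.
* Missing data: skip and warn, never impute; flagged estimates propagate as
  flags and are excluded from region means.
* Output: τ in ns to 2 decimals by default, full precision on request;
  internal values always full precision.

## Known limitations

* All single-field estimators assume the input is the exchange-free
  $R_2^\circ$; unrecognized exchange biases $\tau_{\mathrm{eff}}$ upward.
* The CSA is fixed at $-160$ ppm with an axially symmetric tensor;
  site-to-site CSA variation (±10–20 ppm) propagates into $k$ at the
  percent level.
* The fast-exchange $\omega_N^2$ scaling is an assumption; intermediate
  exchange regimes violate it.
* The fitted-line constants are calibration results tied to their fifteen
  fields and to the simulation ensembles behind them; they are not
  first-principles quantities.
* Anisotropic diffusion, $^{13}$C/$^2$H relaxation and cross-correlated
  relaxation are out of scope.
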