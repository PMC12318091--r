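---
title: "Phasor FLIM-tmFRET: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor FLIM-tmFRET: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasorfret)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters and their defaults, what
the synthetic data do and do not emulate, and the numerical choices made
where the design was genuinely open.

## The measurement model

### Decays on a circle

Frequency-domain FLIM excites the sample with a pulse train at modulation
frequency $f$ (default 20 MHz, period $T = 1/f = 50$ ns) and histograms
photon arrival times into $K$ bins over one period. Because a 12 ns donor
does not finish decaying within 50 ns, the decay must be treated as
*periodic*: the model histogram is the mixture of exponentials convolved
with the instrument response on the circle of period $T$ ("wrap-around").
`expected_decay()` evaluates this as a wrapped exponentially-modified
Gaussian — exponential lifetime $\tau$, Gaussian IRF of width
$\sigma_{\mathrm{IRF}}$ centered at $t_0$ — summing wrap terms until they
fall below machine precision. Each mixture component is normalized to unit
photon count before mixing, so component fractions are exact photon
(intensity) fractions and mixing is exactly linear; both properties are
load-bearing for the phasor algebra downstream.

Defaults: 256 bins over 50 ns; IRF width 0.2 ns centered at 2 ns. The
excitation pulse itself is picoseconds wide, but the detection chain is
not; 0.2 ns is a typical width for photon-counting FLIM and, because the
calibration step divides the IRF factor out exactly, its precise value is
immaterial to calibrated results. Photon budgets default to $10^4$–$10^5$
per membrane pixel, the range over which the unmixing readout reaches the
few-percent precision quoted below; dwell times that produce such counts
are an engineering choice, not a measured quantity.

### The phasor transform

`decay_to_phasor()` computes, per pixel and at harmonic $n$,

$$G = \frac{\sum_k c_k \cos(n\omega t_k)}{\sum_k c_k},\qquad
  S = \frac{\sum_k c_k \sin(n\omega t_k)}{\sum_k c_k},$$

with $t_k$ the *bin centers* — the rectangle rule implied by a phase
histogram, unbiased for symmetric bins. A mono-exponential decay has the
analytic phasor $G = 1/(1+(\omega\tau)^2)$, $S = \omega\tau/(1+(\omega\tau)^2)$,
which lies exactly on the universal semicircle; mixtures lie inside it, on
chords, by the phasor-addition law (the phasor of a sum of histograms is the
intensity-weighted mean of the component phasors — exact at any binning
thanks to the linear transform).

Two numerical facts matter. First, zero-intensity pixels are carried as an
explicit validity mask rather than NaN, so spatial filters cannot
contaminate their neighbors. Second, bin-center discretization leaves a
small, $\tau$-dependent bias relative to the continuous transform
($\sim 4\times10^{-5}$ in phasor units at 256 bins, falling quadratically
with bin count). Calibration against a reference of a *different* lifetime
cancels most but not all of it; tests that assert $10^{-6}$-level agreement
with the analytic phasor therefore run at 4096 bins, while default-binning
accuracy is asserted at its actual level. Poisson noise at realistic photon
counts dwarfs both.

### Calibration

A reference fluorophore of known mono-exponential lifetime (default 3.6 ns,
Atto 425 in water) is acquired through the same instrument. `calibrate()`
multiplies every pixel phasor, as a complex number, by
$\text{theoretical}/\text{measured}$ of the reference — equivalently,
subtracts the reference phase error and divides by its modulation error.
The construction guarantees the reference acquisition itself lands exactly
on its semicircle point, and removes the IRF factor from all pixels because
circular convolution multiplies Fourier coefficients.

## The two FRET readouts

### FRET trajectory (ensemble average)

FRET at efficiency $E$ shortens the donor lifetime to $\tau_D(1-E)$ *and*
dims the donor by the factor $(1-E)$, while background photons are
unaffected. The photon-weighted mixture of the quenched donor phasor and
the background phasor therefore traces a one-parameter curve from the
donor-alone point at $E=0$ to the background point at $E=1$. The background
phasor defaults to the origin — uncorrelated (time-uniform) background has
zero Fourier coefficient — which is also why the trajectory must terminate
there; a structured background can be configured. `fit_trajectory()`
minimizes the Euclidean phasor distance to the curve over $E$ by a dense
grid (step $10^{-3}$) with golden-section refinement in the bracketing
interval: one-dimensional, cheap, and robust to the curve's curvature, with
ties broken toward smaller $E$. The cluster is reduced to its
intensity-weighted mean before fitting, because the method is an ensemble
readout: when two states coexist it reports a photon-weighted *average*
efficiency, not either state — the reason the unmixing readout exists.

### Two-state linear unmixing

When the membrane population occupies two states — donor-alone and a
high-FRET state — pixels scatter along the chord between the two pure
phasors, and the state fraction is the relative position along that chord.
`unmix_two_state()` proceeds deterministically:

1. background-correct the cluster: $P \mapsto (P - b\,P_{bg})/(1-b)$,
   the exact inverse of uniform-background mixing;
2. fit the intensity-weighted total-least-squares major axis (first
   principal axis of the weighted covariance of $(G,S)$);
3. intersect the axis with the semicircle and take the larger-$G$ (shorter
   lifetime) intersection as the pure high-FRET endpoint $P_F$; the
   high-FRET efficiency is $E_{high} = 1 - \tau(P_F)/\tau(P_D)$;
4. project the intensity-weighted cluster mean onto the axis (suppressing
   off-axis noise) and report
   $f_{int} = |\bar P - P_D|/|P_F - P_D|$, clamped to $[0,1]$ with a
   warning when noise pushes it past an endpoint.

Design choices that were genuinely open:

* **Which fraction to report.** The chord position is an *intensity*
  fraction; because the quenched species is dimmer by $1-E_{high}$, the
  fraction of molecules is larger:
  $f_{mol} = f_{int} / ((1-E_{high})(1-f_{int}) + f_{int})$. Published
  percentages in this assay do not always say which is meant, so both are
  always reported and the default headline is $f_{int}$, the direct
  phasor-addition quantity.
* **Donor reference precedence.** A measured donor-alone phasor
  (background-corrected with its own fraction $b_1$) wins over a nominal
  donor lifetime when both are supplied, since it reflects the actual
  instrument.
* **Degenerate clusters.** An isotropic cluster (elongation below 1.2) has
  no usable major axis; the chord is then anchored at the donor reference
  and the result flagged. If the fitted axis misses the semicircle
  entirely, the nearest semicircle point is used and flagged — a pure
  quenched state inconsistent with the cluster should be visible, not
  fatal.
* **Replacing visual inspection.** Interactive cursor placement is replaced
  by this deterministic procedure end to end; identical inputs give
  identical results.

Under the default study conditions ($10^5$ photons/pixel, state-fraction
heterogeneity 0.1), the seeded sweeps in the test suite recover the state
fraction within $\pm 0.03$ and $E_{high}$ within $\pm 0.05$.

## Distances: the Förster-convolved Gaussian

A single FRET efficiency maps to a single distance only for rigid probes.
With flexible linkers the donor–acceptor separation is modeled as a
Gaussian with standard deviation $\sigma = 7.5$ Å (FWHM
$2\sqrt{2\ln 2}\,\sigma = 17.7$ Å), and the *apparent* efficiency is the
Förster curve averaged over it:

$$E_{app}(\bar r) = \frac{\int_0^\infty N(r;\bar r,\sigma)\,
  \frac{1}{1+(r/R_0)^6}\,dr}{\int_0^\infty N(r;\bar r,\sigma)\,dr}.$$

Numerical choices: the Gaussian is truncated at $r=0$ and renormalized —
negative distances are unphysical, and the choice only matters when
$\bar r \lesssim 2\sigma$; the integral uses 256-node Gauss–Legendre
quadrature on $[\max(0,\bar r - 6\sigma),\, \bar r + 6\sigma]$ (smooth,
compactly concentrated integrand; doubling the nodes changes $E_{app}$ by
$<10^{-8}$). The map is strictly decreasing in $\bar r$, so
`fcg_invert()` finds the unique root by bisection to better than 0.01 Å.
Averaging over the near-distance tail raises $E_{app}$ above the
point-distance Förster value for $\bar r > R_0$, so FCG-inverted distances
exceed naive Förster inversions — the expected convexity bias.

$R_0$ defaults to 13 Å (Cu²⁺-DOTA acceptor; 12 Å for Co²⁺-DOTA) and can be
recomputed from spectra via $R_0 = C\,(J\,Q\,\eta^{-4}\kappa^2)^{1/6}$ with
$J = \int \bar F_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4\,d\lambda$.
The unit convention is pinned in one place: $\lambda$ in nm and
$\varepsilon_A$ in M⁻¹cm⁻¹ give $J$ in nm⁴ M⁻¹cm⁻¹ and $C = 0.211$ yields
$R_0$ in Å; with $Q = 0.8$, $\eta = 1.33$, $\kappa^2 = 2/3$ this reproduces
the 13 Å Förster distance from the corresponding overlap.

## Energetics

`fit_boltzmann()` fits $G/G_{max} = 1/(1+\exp[(V_{1/2}-V)/V_s])$ by least
squares from a deterministic coarse grid over $(V_{1/2}, V_s)$ followed by
Nelder–Mead refinement — no random starts, hence no seed dependence — and
reports $\Delta G = RT\,V_{1/2}/V_s$ at $T = 297$ K with
$R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹.

From a FRET-measured activated fraction $p$, the gating energy is
$\Delta G = -nRT\ln(p/(1-p))$ and the open probability of a tetramer
needing at least $k$ active subunits is the binomial tail
$\sum_{j=k}^4 \binom{4}{j} p^j (1-p)^{4-j}$. The exponent $n$ is taken
equal to the activation threshold $k$ of the chosen subunit model (default
3): with $n = 3$ and $T = 297$ K, $p = 0.35$ gives 1.10 kcal/mol and
$p = 0.2$ gives 2.45 kcal/mol, and no other integer exponent reproduces
both of those conversions simultaneously; `scan_subunit_models()` tabulates
all four thresholds so the model comparison is explicit rather than
hard-wired. $R$ and $T$ are exposed because one-decimal roundings of these
energies are sensitive to them.

## What the synthetic scenes do and do not emulate

`make_scene()` renders a membrane ring (donor mixture, optionally
FRET-quenched at a controllable state fraction), a cytosol of nonspecific
donor fluorescence — the dominant real-world error source, which the
membrane mask exists to exclude — a time-uniform background at ≤5% by
default, Poisson photon noise, and a membrane-bright co-channel image for
masking. Pixel-to-pixel variation of the membrane state fraction
(`fraction_sd`, default 0.1, truncated to $[0,1]$) emulates conformational
heterogeneity across the channel ensemble; it is what elongates the phasor
cluster along the donor/high-FRET chord, and without it the cluster is an
isotropic Poisson blur with no major axis to fit — the unmixer then flags
`axis_ok = FALSE` and falls back to the donor-anchored chord.

Not emulated: detector afterpulsing and dead time, spectral bleed-through,
photobleaching, cell-to-cell variability, vendor file formats, and any
spatial correlation of conformational states. Passing recovery tests on
these scenes therefore demonstrates the correctness of the estimators under
Poisson statistics and the stated geometry, not robustness to every
instrumental artifact of a real microscope.

All scene randomness flows from one integer seed set at the start of
rendering, and regenerating a scene from its spec is bit-identical; ground
truth round-trips through JSON losslessly.

## Problem sizes and determinism

The test suite and the demo pipeline run on 48×48 scenes with 256 time
bins and $10^5$ photons per membrane pixel (about 100 masked membrane
pixels), sizes at which every estimator reaches its quoted precision while
the full suite completes in well under a minute. Sweeps use 150-pixel
clusters and fixed seeds; noise-free oracle tests use 4096 bins where
$10^{-6}$ agreement with analytic phasors is asserted. Identical
configurations and seeds reproduce byte-identical result bundles
(`write_result_bundle()` fixes the printed precision: phasor coordinates at
6 decimals, distances at 0.1 Å, fractions at $10^{-3}$).

## Known limitations

* Two lifetime species at most: systems with three FRET states violate the
  chord model and need multi-harmonic unmixing, which is out of scope
  (phasors at higher harmonics are computable, joint fits are not).
* The trajectory readout reports an average; it cannot separate a change in
  state fraction from a change in state efficiency.
* The FCG model fixes $\sigma$ a priori; the data do not constrain it.
* Interior phasor points such as a membrane donor displaced by background
  (e.g. phase/modulation lifetimes of 11.7/12.6 ns) are consistency checks,
  not recoverable targets — the displacing background fraction is not
  observable from one point.
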