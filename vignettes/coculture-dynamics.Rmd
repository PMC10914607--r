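---
title: "Modelling cross-feeding co-culture dynamics and their global sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cross-feeding co-culture dynamics and their global sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfeed)
```

## The model and its assumptions

`crossfeed` simulates batch cultures of engineered communities in which
each member may be auxotrophic for one or more essential metabolites
and may overproduce ("leak") metabolites its partners need. The state
comprises the shared carbon source $G$ (g l$^{-1}$), the exchanged
metabolite pools $x_i$ (mg l$^{-1}$) and the strain biomasses $y_i$
(OD$_{700}$ units, the plate-reader proxy for biomass):

$$
\frac{dG}{dt} = -\sum_i J^{y_i}_{\mathrm{upt},G}\, y_i, \qquad
\frac{dy_i}{dt} = \left(J^{y_i}_{\mathrm{grow}} - \eta_i\right) y_i, \qquad
\frac{dx_i}{dt} = J^{y_i}_{\mathrm{leak},i}\, y_i -
  \sum_{j \ne i} J^{y_j}_{\mathrm{upt},i}\, y_j .
$$

Uptake of glucose and of metabolites is Monod-saturating,
$J_{\mathrm{upt}} = V_{\max} S / (k_M + S)$. Leak flux is a fixed
fraction of the producer's glucose flux,
$J_{\mathrm{leak},i} = \phi_i\, \delta_i\, J_{\mathrm{upt},G}$, where
$\phi_i \in [0, 1)$ is the engineerable diversion (tuned experimentally
by promoter strength) and $\delta_i$ the glucose-per-metabolite
stoichiometry (default 1). Growth takes the rate of the scarcest
resource,

$$
J_{\mathrm{grow}} = \min\Big(
  \gamma_G \big(1 - \textstyle\sum_i \phi_i\big) J_{\mathrm{upt},G},\;
  \gamma_j J_{\mathrm{upt},j}\Big),
$$

a Liebig-minimum assumption appropriate for strict auxotrophy: no
amount of glucose substitutes for a missing amino acid. Death is
first-order at rate $\eta$ (default 0.01 h$^{-1}$). The model is
deliberately coarse-grained — uptake kinetics and yields, not
genome-scale metabolism — because its purpose is ranking control
knobs, not predicting titres.

Two optional extensions:

* **Toxicity.** Growth is multiplied by a Hill inhibition factor
  $\prod_i 1/(1 + (x_i/\theta_i)^n)$ over metabolites carrying a
  threshold $\theta_i$, with $n = 2$ by default. The factor is 1 far
  below threshold, exactly 0.5 at threshold, and decays to 0. The
  functional form is this package's own choice (a standard
  phenomenological inhibition); it is off by default and every
  threshold is configurable.
* **Division-of-labour pathway.** A two-stage heterologous pathway is
  split across the pair: the upstream strain diverts a further glucose
  fraction $\phi_{\mathrm{up}}$ to an intermediate (p-coumaric acid in
  the resveratrol case), and the downstream strain converts
  intermediate to inert product with Monod kinetics scaled by its
  biomass. The combined diversion $\sum\phi + \phi_{\mathrm{up}}$ must
  stay below 1.

## Nominal parameters

Biological ranges for the sensitivity analysis are fixed on a linear
uniform scale: $N_0 \in [0.01, 1]$ OD$_{700}$, $r_{0,i} \in [0.01, 1]$
(simplex-constrained), $x_{0,i} \in [0, 75]$ mg l$^{-1}$,
$\gamma_G = \gamma_i \in [0.01, 1]$, $V_{\max,G} \in [1, 30]$ g
h$^{-1}$, $k_{M,G} \in [1, 100]$ g, $V_{\max,i} \in [1, 120]$ mg
h$^{-1}$, $k_{M,i} \in [1, 1000]$ mg, $\phi_i \in [0.01, 0.5]$. The
package's *nominal* point parameterisation takes the midpoint of each
range (`nominal_parameters()`), with $\phi = 0.25$, $G_0 = 20$ g
l$^{-1}$ and $N_0 = 0.102$ OD$_{700}$ — the standard microplate
inoculum, related to spectrophotometer readings through the
OD$_{600}\!\leftrightarrow\!$OD$_{700}$ calibration pairs built into
`od_convert()`. Mid-range values are an explicit neutral choice, not a
fitted ground truth; every preset accepts overrides.

Two nominal-regime consequences worth knowing:

* In a producer monoculture the batch-maximum volumetric production
  rate $J_{\mathrm{leak}} y$ scales as $\phi(1-\phi)$ — biomass built
  is proportional to $(1-\phi)$ while per-biomass leak is proportional
  to $\phi$ — so production peaks at $\phi = 0.5$ regardless of the
  kinetic constants. The accumulated *concentration*, by contrast, is
  monotone in $\phi$ whenever glucose is exhausted within the window.
* On a $(\phi_1, \phi_2)$ grid the mutual pair shows high final
  populations at intermediate symmetric exchange and at strongly
  asymmetric corners, and starves near $(0, 0)$.

### The division-of-labour regime

The pathway preset (`dol_resveratrol`) needs two extra choices that
the coarse model does not pin down by itself: the upstream diversion
and the conversion kinetics. The preset uses
$\phi_{\mathrm{up}} = 0.3$ (the intermediate-producing strain carries
a substantial metabolic burden) and conversion $V_{\max} = 0.5$ µM
h$^{-1}$ per OD with $k_M = 50$ µM, which makes the *downstream
conversion step* — i.e. downstream biomass — the product bottleneck.
In this regime community growth is most sensitive to $\phi_2$ (the
exchange production of the product-forming strain, which feeds the
burdened upstream member), while productivity and yield are most
sensitive to $\phi_1$ (the exchange production of the intermediate
producer, which feeds the converting strain). A fast-conversion
parameterisation inverts the productivity ranking (product tracks
upstream biomass instead); the preset deliberately encodes the
conversion-limited regime, and both knobs are exposed in
`pathway_spec()`.

## Numerical choices

* **Stiff integration, hard minimum.** The growth law's `min()` kink
  is integrated as-is with `deSolve::lsoda` at rtol $10^{-8}$ / atol
  $10^{-10}$ rather than smoothed. A log-sum-exp soft-min is available
  (`smooth_min_k`) for solver-robustness comparisons; it uses the R
  reference right-hand side.
* **Compiled and reference right-hand sides.** The RHS is implemented
  twice: a C version (used by default and by the sensitivity ensemble,
  ~0.4 ms per 72 h batch) and an R reference version; the test suite
  integrates both and requires agreement.
* **Negative-state guard.** Fluxes are evaluated on
  $\max(\text{component}, 0)$, preventing spurious blow-ups from tiny
  negative solver excursions without altering dynamics beyond
  tolerance. Trajectories are required (and tested) to stay above
  $-10\times$ atol.
* **Batch time.** Defined as the first time $G(t)$ crosses
  $\varepsilon_G G_0$ (default $\varepsilon_G = 10^{-3}$), linearly
  interpolated between output grid points and capped at the window end
  (default 72 h). A population-plateau definition would also be
  defensible; the glucose-exhaustion definition is robust to
  metabolite-limited stalls and is configurable through
  `simulation_config()`.
* **Metric maxima on the dense grid.** Per-strain maximum growth,
  uptake and production rates are taken over the output grid (default
  0.25 h; 0.5 h in ensemble runs) rather than via event detection;
  grid-refinement stability is a tested property (halving the step
  moves metrics by well under 0.1%).
* **Degenerate composition.** If the final total population is ~0 the
  final ratios are reported as the inoculum ratios with a
  `degenerate_composition` flag, keeping ensemble outputs finite.
  Pathway metrics are absent (not zero) when no pathway is configured.

## The eFAST implementation

Each parameter traverses its range along
$x = \mathrm{lower} + \mathrm{range}\cdot(\tfrac12 +
\tfrac1\pi \arcsin(\sin(\omega s + \varphi)))$ with a random phase per
resampling. The focus parameter carries the driving frequency
$\omega = \lfloor (N_s - 1) / 2M \rfloor$ with $M = 4$ harmonics
retained; complementary parameters receive distinct low frequencies
spread over $[1, \lfloor \omega/2M \rfloor]$ (recycled when there are
more parameters than slots). This forces
$N_s \ge 4M^2 + 1 = 65$; the configuration rejects smaller designs
with the required minimum. First-order indices are the spectral mass
at the focus frequency and its first $M$ harmonics over total
variance; total-order indices are one minus the complementary
low-band share (frequencies $\le \omega/2$); both are clipped to
$[0, 1.05]$ to absorb estimator noise, and a constant output returns
$(0, 0)$ with a flag.

Inoculum ratios are sampled independently on $[0.01, 1]$ and
renormalised row-wise to the simplex — this generalises the two-strain
sum-to-one constraint to any community size. The dummy parameter is
sampled like any other but never written into the model; per
(parameter, metric) the resampled index draws are compared to the
dummy's by a Welch two-sample t-test (a pooled-variance variant is
available) at the Bonferroni-corrected threshold $0.01/n_k$, testing
both the first-order and the total-order index and flagging when
either differs. Failed simulations are mean-imputed within their
curve (the Fourier transform needs an equally spaced series), counted,
and the analysis aborts if more than 1% of rows fail. Everything is
deterministic given the seed; rows of a sample matrix are independent
and may be evaluated in any order.

Estimator accuracy is checked against closed forms recomputed in the
test suite: the Ishigami function ($a = 7$, $b = 0.1$) and an additive
linear model, with first-order indices required within 0.05 at
$N_s = 1285$, $M = 4$ — the reference protocol scale (1285 samples,
100 resamplings). Routine analyses and tests run scaled down (65–513
samples, 4–25 resamplings); the resampling spread shrinks
monotonically with $N_s$, which is itself a tested property. Weakly
identified first-order signals (e.g. pathway productivity, true
$S_i \sim 0.01$) need the finer end of that range — at 129 samples the
estimator noise floor can reorder them.

## The synthetic plate-reader generator

`generate_platereader()` emulates the data a microplate assay
produces: total OD$_{700}$ readings equal to the summed simulated
biomass, and one fluorescence channel per tagged strain (RFP/BFP/GFP)
reading $(\mathrm{gain}_c\, y_c + \mathrm{background}_c)$, each
corrupted by i.i.d. multiplicative Gaussian noise (default
$\sigma = 0.05$) — multiplicative because plate-reader OD error grows
with signal. Ground truth is retained so estimation and fitting
stages are testable end-to-end. `estimate_subpopulations()` unmixes
channels linearly (background-subtract, divide by gain, renormalise to
the observed total); gains are assumed calibrated, in practice from
monoculture wells. `fit_growth_parameters()` recovers kinetic
parameters from total-OD curves by Levenberg–Marquardt least squares
with seeded multi-starts (default 5), because the growth-law kink can
create local optima.

What passing these stages does **not** show about real data: the
generator has no well-to-well variation, no lag phase beyond what the
exchange bootstrap produces, no evaporation or drift, no fluorophore
maturation delay or spectral bleed-through between channels, and noise
is uncorrelated across readings. Parameter-recovery results (median
relative error < 10% at 5% noise) are therefore an identifiability
statement about the model-plus-noise-model, not an accuracy guarantee
for plate data.

## Known limitations

* Batch mode only — no chemostat, no spatial structure, no stochastic
  birth–death dynamics; communities are well-mixed and deterministic.
* The abstract donor/receiver metabolite roles ignore
  metabolite-specific chemistry (degradation, transport competition).
* The toxicity and pathway extensions are structurally minimal
  stand-ins for mechanisms that are not fully constrained at this
  level of coarse-graining; their parameters are exposed rather than
  asserted.
* Total-order indices from resampled eFAST carry a positive noise
  floor (visible on the dummy parameter); compare them against the
  dummy's index, not against zero.
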