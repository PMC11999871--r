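---
title: "Mechanochemical bistability of organoid crypt shape: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanochemical bistability of organoid crypt shape: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cryptmorph)
```

## The system and the question

An intestinal organoid is a closed epithelial monolayer around a fluid
lumen, with two cell populations: crypt cells (stem-cell compartment,
strongly contractile apical actomyosin) and villus-like differentiated
cells. During days 3–5 of development the lumen deflates from a swollen
state (normalized volume $v \approx 2.8$) to a shrunken one
($v \approx 0.7$) while crypt cells build up an apicobasal *differential
tension*; the crypt then closes into a bud. The striking experimental
fact this package models is *history dependence*: inflating the lumen
early in development prevents budding, while the same inflation applied
after budding leaves the bud intact. The package implements a minimal
mechanochemical model in which this asymmetry arises from morphological
bistability, drastically widened by a mechanosensitive feedback of crypt
curvature on actomyosin tension.

## Single-cell energetics and nondimensionalization

Each cell carries surface tensions $\Gamma_a$, $\Gamma_b$, $\Gamma_l$ on
its apical, basal and lateral faces, with per-cell energy
$f = \Gamma_a A_a + \Gamma_b A_b + \tfrac12 \Gamma_l A_l$ (lateral faces
are shared between neighbours, hence the factor $\tfrac12$). With
$\Gamma_l \equiv 1$, four dimensionless groups control organoid shape:
the crypt cell fraction $\varphi$, the normalized lumen volume $v$, the
in-plane tension ratio
$\alpha = (\Gamma_a+\Gamma_b)_c/(\Gamma_a+\Gamma_b)_v$, and the crypt
differential tension
$\sigma_c = \tfrac12\,(\Gamma_a-\Gamma_b)_c\,\sqrt{4\pi/N_t}$, where
$N_t$ is the total cell count. `landscape_params()`,
`build_tensions()` and `tensions_to_params()` implement this
nondimensionalization and its exact inverse, and
`sigma_c_from_epsilon()` converts a measured tension asymmetry
$\epsilon = (\Gamma_a-\Gamma_b)/(\Gamma_a+\Gamma_b)$ into $\sigma_c$ via
$\sigma_c = \tfrac12\,\epsilon\,\kappa\,\sqrt{4\pi/N_t}$ with
$\kappa = (\Gamma_a+\Gamma_b)/\Gamma_l$.

## The analytic large-volume landscape

In the large-lumen-volume limit the total mechanical energy as a
function of the crypt opening angle $\theta_c$ ($x = \cos\theta_c$)
reduces to

$$\Delta F(x) \;=\; \Bigl[\,1-\sigma_c\bigl(\tfrac{1+x}{2\varphi}\bigr)^{1/2}\Bigr]^{2/3}
\Bigl[\,1-\tfrac{1-x}{2\alpha}\Bigr]^{1/3}.$$

Local minima are crypt equilibria: $x = 1$ ($\theta_c = 0$) is the
budded (closed) crypt, interior minima are bulged (open) crypts. The
two brackets have a transparent origin. Writing the organoid energy as
$E(a) = P\,a + Q\,a^{-1/2}$ in the free cell scale $a$ — $P$ collecting
in-plane tension terms (linear in area) and $Q$ the lateral cohesion
minus the differential-tension work, both of which scale as
$h \propto \Omega / a$ under cell-volume conservation — minimizing over
$a$ yields $E^* \propto P^{1/3} Q^{2/3}$, which is exactly the
$\tfrac13/\tfrac23$ exponent structure above. The second bracket is the
in-plane term with the crypt's footprint relief on the surrounding
tissue; the first is the lateral-minus-differential bracket, and the
$((1+x)/2\varphi)^{1/2}$ factor is the inverse crypt radius of the cap
family at equal cell areas, $\bar R_c(x) = \sqrt{2\varphi/(1+x)}$.

`delta_f()` evaluates the formula, `scan_landscape()` enumerates minima
on a grid (default step $10^{-3}$, quadratic refinement of bracketed
minima, boundary-minimum probe offset $10^{-4}$, tie tolerance
$10^{-9}$ against floating-point plateaus) and classifies the regime as
`bulged_monostable`, `bistable`, or `budded_monostable`.
`budded_threshold()` gives the closed-form onset of the closed-crypt
minimum, $\sigma^* = \varphi^{(n+1)/2} / (1+\alpha(n+1))$, derived from
the sign change of $d\Delta F/dx$ at $x = 1$ and validated in the test
suite against a finite-difference bisection oracle. At
$\varphi = 0.2,\ \alpha = 2$ the bistable window without feedback is
$\sigma_c \in (0.149, 0.158)$ — a few per cent of the working tension,
i.e. bistability without mechanosensing requires fine-tuned tensions.

## Mechanosensitive feedback

Crypt curvature feeds back on actomyosin:
$\sigma_c = \sigma\,(R_c/\tilde R_0)^{-n}$, with $\sigma$ the intrinsic,
fate-set tension, $n$ the coupling strength and $\tilde R_0$ a reference
crypt radius before morphogenesis. Substituting the cap-family radius
$\bar R_c(x)$ gives the effective landscape (`effective_delta_f()`)
with first bracket $1-\sigma((1+x)/2\varphi)^{(n+1)/2}$; the budded
onset drops to $\varphi/(1+2\alpha)$ at $n = 1$ and the *relative* width
of the bistable window grows by an order of magnitude or more
(`bistable_window()`; the property is exercised over a
$\varphi \times \alpha$ grid in the tests). This widening — making
budded crypts robust rather than fine-tuned — is the central scientific
claim the package reproduces. Self-consistency is treated by
substitution: tension equilibrates within tens of minutes, faster than
morphogenetic volume changes, so $\sigma_c$ is always the instantaneous
function of the crypt radius, and every equilibrium satisfies
$\sigma_c = \sigma (R_c/\tilde R_0)^{-n}$ exactly
(`selfconsistent_states()`).

## The finite-volume model

At finite lumen volume the package uses a reduced two-cap model built
to have the analytic landscape as its zero-pressure limit. A state is a
crypt spherical cap (angle coordinate $x$, cell scale $a_c$) joined at a
rim circle to a villus cap (cell scale $a_v$), all cells incompressible
($h = \Omega/a$, $\Omega = 4\pi h_0/N_t$). The crypt energy is the
reservoir reduction $P(x)\,a_c + Q(x)\,a_c^{-1/2}$ with
$P(x) = \varphi N_t[\alpha - (1-x)/2]$ and
$Q(x) \propto 1-\sigma_c((1+x)/2\varphi)^{(n+1)/2}$; the villus carries
its own in-plane and lateral terms. The lumen enters through its
osmotic pressure: equilibria are minima over $x$ of

$$L_p(x) \;=\; \min_{a_c,\,a_v}\bigl[\,E(x, a_c, a_v) - p\,V(x, a_c, a_v)\,\bigr],$$

with $V$ the volume enclosed by the apical surfaces. The held-pressure
(grand) ensemble is the physically appropriate stability notion here:
water crosses the epithelium within 15–30 minutes (lumen inflation
by prostaglandin acts on that timescale, and the observed snap-through
of crypt closure is equally fast), whereas developmental volume changes
take hours to days. Volume is therefore the slow control variable: the
package walks the pressure along each branch so that the enclosed
volume matches the prescribed $v$ (`equilibrium_shape()` with an `init`
state), while stability at each instant is governed by $L_p$.

Two structural findings from the reconstruction work are worth
recording. First, with a *hard* volume constraint and fully relaxing
cell scales, the marginalized energy over the shape coordinate is
single-welled essentially everywhere — the extra relaxation freedom
irons out the landscape, and the bistable wedge that remains comes out
with the wrong orientation in $v$ (deflation would then stabilize the
open crypt). Second, the pressure-work term $-pV$ restores the correct
orientation automatically: inflation ($p>0$) rewards the
large-volume open sphere, suction rewards the smaller closed
configuration, so deflation plus a rising tension closes the crypt and
inflation preserves the open branch. The $p \to 0$ limit of $L_p$ is
exactly proportional to $\Delta F(x)$ (verified in the tests to
$10^{-5}$ relative), which anchors the finite-volume model to the
analytic one.

Volume is normalized so that $v = 1$ is the relaxed organoid ($p = 0$,
$\sigma_c = 0$): consistent with the ablation reading that a swollen
lumen ($v>1$) deflates on epithelial cutting. A pleasing emergent check:
at the package defaults the relaxed *budded* configuration sits at
$v \approx 0.86$–$0.72$ depending on $\alpha$, close to the measured
budded lumen state $v \approx 0.71$, without any tuning to that number.

### Default constants

* $\varphi = 0.2$, $N_t = 400$: a few hundred cells, one crypt carrying
  a fifth of them.
* $\alpha = 4$ for the finite-volume model: the crypt's summed in-plane
  tension well above the villus's, as expected for the strongly
  actomyosin-enriched crypt. With this choice the budded onset of the
  effective landscape ($\varphi/(1+2\alpha) \approx 0.022$) lies below
  the working intrinsic tensions, so a budded state exists at the
  deflated experimental condition with $\sigma = 0.02$. Analytic-module
  examples conventionally use $\alpha = 2$.
* $h_0 = 0.1$: reference thickness a tenth of the organoid radius.
* $c_p = 2\sqrt{\pi}$: disc-equivalent cell perimeter; any other tiling
  constant is absorbed by the nondimensionalization.
* $\tilde R_0 = 1.4$: the crypt-region radius of curvature of the
  swollen spherical organoid before morphogenesis ($v \approx 2.8$,
  radius $\approx 1.4$ in units of the relaxed radius).
* Scenario tension ramp to $\sigma = 0.03$ (the fitted intrinsic
  tension is $0.02$; the scenarios use a value in the upper half of the
  bistable window so all four categorical outcomes are comfortably away
  from the window edges); re-inflation of budded organoids to
  $v = 1.8$, i.e. a $\approx 2.5$-fold inflation of the budded volume,
  matching the experimental inflation ratios.

### Numerical choices

The inner scale minimization is performed by warm-started alternating
golden-section sweeps on $(\log a_c, \log a_v)$, iterated to an energy
change below $10^{-12}$, inside hard scale bounds; an optimum pinned at
the upper bound is the ballooning instability (a pressurized shell of
linear-tension material has a maximal sustainable volume, about four
times the branch's relaxed volume) and is reported as "no equilibrium"
rather than a state. Landscape minima are read off a 72-point $x$-grid
(denser near the closed-crypt end), refined by golden section, with a
$10^{-8}$ depth requirement separating genuine minima from inner-solver
noise. Continuation steps relax the previous state at its inherited
pressure (a vanished basin then drains into the surviving one — the
quasistatic snap-through) and walk the pressure by secant iteration
until the branch volume matches the waypoint, to $3\times10^{-4}$.
Equilibrium enumeration at fixed $v$ probes 19 pressures in
$[-0.6, 1.6]$, splits same-label states into continuity tracks, and
inverts each track's volume–pressure relation by bisection.
`certify_minimum()` re-tightens a state and checks it against 100
random perturbations of magnitude $10^{-3}$ in the
$(x, \log a_c, \log a_v)$ chart.

### The constant-thickness control

The thickness–curvature coupling is the mechanical heart of the model:
closing the crypt crowds its cells, thickens the epithelium
($h = \Omega/a$), and amplifies the active bending moment
$M \sim (\Gamma_a - \Gamma_b) h$. Pinning the crypt thickness at $h_0$
(with incompressibility this also freezes the crypt cell area) moves
the differential-tension work from the $a^{-1/2}$ bracket into terms
that scale like the in-plane energy — and a one-parameter family whose
tension terms all sit in the concave bracket admits at most one
minimum. `constant_thickness_scan()` confirms numerically that no
tension in the scanned range yields two coexisting states when the
thickness is pinned, while the incompressible model is bistable over a
broad range.

## Trajectories, hysteresis and scenarios

`continue_path()` implements quasistatic history: the state at each
waypoint is obtained by local relaxation from the previous state, so
hysteresis and path dependence arise by construction and
`detect_snap()` flags abrupt opening changes. `hysteresis_sweep()`
drives one control up and back and integrates the loop area between the
two opening curves; the area is positive exactly when the sweep crosses
a bistable window. `scenario_waypoints()` encodes the four experimental
protocols (normal development $v: 2.8 \to 0.7$ with a tension ramp;
early inflation with the volume held high; late inflation of the budded
organoid; contractility inhibition at high volume followed by washout),
and `run_scenario()` reports the categorical outcome. At the defaults
the four outcomes are budded / bulged / budded / bulged — the observed
timing asymmetry and the failure of budded crypts to re-form after
washout at high volume. In the normal scenario the largest single-step
opening drop exceeds half of the total change and is stable under
halving of the waypoint step: a finite jump at vanishing step size, the
signature of a snap-through bifurcation rather than a smooth descent.

## Morphometry

The estimators mirror the measurement pipeline. `circumcentre()` and
`opening_angle()` recover a region's opening angle from two boundary
points and one middle point on the tissue midplane,
$\theta = \pi - \arccos\bigl(\langle p_1 - c, p_2 - c\rangle /
(|p_1 - c||p_2 - c|)\bigr)$, exact for noise-free points on a circle and
invariant to rigid motions and scaling. `degree_of_opening()` forms
$\theta_c/(\pi - \theta_v) \in [0, 1]$ (0 budded, 1 spherical), clipping
slight overshoots near the spherical limit at a 0.02 tolerance with a
warning. `asymmetry_from_intensity()` maps an apical-to-basal myosin
intensity ratio $r$ to $\epsilon = (r-1)/(r+1)$, and `infer_v()` infers
the normalized lumen state from pre/post-ablation volumes,
$\hat v = V_{pre}/V_{post}$, with batch mean and standard deviation.

## Inference

`fit_power_exponent()` fits $y = x^{-b}$ by least squares in log–log
space with the intercept fixed at zero: both axes are self-normalized to
1 before the perturbation, so the power law has no free prefactor (a
free-intercept variant is available for sensitivity checks).
`fit_sigma()` performs 1-D least squares over the intrinsic tension:
bulged observations are matched to the open branch at the swollen
volume, budded ones to the closed branch at the deflated volume, and
the loss is minimized by golden-section search. Because each forward
evaluation involves branch continuation, `epsilon_predictor()`
tabulates the branch-consistent asymmetry on a tension grid once and
interpolates; `refine = TRUE` polishes the optimum with direct forward
evaluations when $10^{-4}$-level accuracy is wanted.

## Synthetic data

The generators produce every input the pipeline consumes, deterministic
under a seed: three-point annotations on circles with additive
coordinate noise; power-law radius/intensity pairs with multiplicative
lognormal noise (ratios are positive and right-skewed); ablation volume
pairs with relative Gaussian noise (relative noise above 0.5 is
rejected as a sign-flip risk); and forward-model tension-asymmetry
observations at the bulged/budded conditions. Default sample sizes
mirror the study: 52 radius/intensity pairs (24 + 28), 11 + 9 ablation
pairs, 7 + 19 asymmetry observations. What passing tests show is that
the *estimators and fits recover what the model generated* at the
study's noise levels and sample sizes; they cannot certify the noise
models against real measurements, which may have heavier tails,
annotation outliers, and shape deviations from spherical caps that the
generators do not emulate.

## Known limitations

* The finite-volume model is a reduced, semi-analytic reconstruction:
  the two-cap family with a reservoir villus. It does not resolve neck
  shape, invaginated geometries, or discrete-cell effects.
* The pressure ensemble caps the stably sustainable volume of each
  branch (ballooning); in particular the closed-crypt branch reopens if
  re-inflated much beyond $v \approx 2$ at the default tensions, so
  "robustness to arbitrary inflation" holds only up to that mechanical
  ceiling.
* Without mechanosensing the finite-volume bistable window is razor
  thin, so hysteresis demonstrations use the $n = 1$ model; this
  mirrors the fine-tuning problem that motivates the feedback in the
  first place.
* Only curvature-dependent feedback is implemented; stress-dependent
  feedback variants and open-tube (in vivo) geometries are out of
  scope, as are real-time viscoelastic dynamics — the model is
  quasistatic throughout.
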