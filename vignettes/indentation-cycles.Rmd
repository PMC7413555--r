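---
title: "Viscoelastic indentation cycles: model, numerics and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viscoelastic indentation cycles: model, numerics and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 7, fig.height = 3)
```

```{r setup}
library(viscoind)
```

## The physical problem

A rigid probe is driven into a flat, linear viscoelastic sample under
displacement control and withdrawn again: one *indentation cycle*.  The
recorded force-versus-depth curve is the workhorse observable of atomic
force microscopy and instrumented indentation, and in practice it is almost
always reduced with a purely elastic (Hertzian) contact model.  For
viscoelastic samples that reduction produces an *apparent* Young's modulus
that depends on how fast the cycle was run, a hysteresis loop between
approach and retraction, and a force-depth power law whose exponent falls
below the elastic value.  This package simulates such cycles exactly (within
linear viscoelasticity) and quantifies all three effects, so that
rate-dependent measurements can be interpreted rather than dismissed.

## Constitutive description

The material enters only through its relaxation modulus $E(t)$, the stress
response to a unit step of strain.  `relaxation_model()` catalogues fifteen
forms, from the elementary spring ($E$ constant), dashpot ($E(t) = \eta\,
\delta_D(t)$, a Dirac impulse), Kelvin-Voigt, Maxwell, standard linear
solid (SLS) and generalized Maxwell (Prony) models to the fractional
family built from *springpots*, whose relaxation is the power law
$E(t) = E_{\alpha 1}\, t^{-\alpha}$ with $0 < \alpha < 1$.

Two conventions to be aware of:

* **Springpot scale.** The modulus scale $E_{\alpha 1}$ of every fractional
  element is the value of its relaxation modulus at $t = 1$ s.  A scale
  quoted at another reference time converts with `rescale_springpot()`.
* **Dirac terms.** Models containing a free dashpot in parallel carry an
  impulsive part $\eta\,\delta_D(t)$ that is stored separately
  (`delta_coeff`) from the regular part of $E(t)$ and handled analytically
  everywhere, never discretized.

Serial combinations of springpots relax according to Mittag-Leffler
functions $E_{\alpha,\beta}(z)$; `mittag_leffler()` implements them for the
non-positive real arguments that occur here, by series summation for small
$|z|$ and a real-line integral representation beyond $|z| = 1.5$.  The two
branches agree to better than $10^{-10}$ at the crossover and the
implementation is tested against a frozen high-precision reference table at
$10^{-8}$ relative accuracy.

## From relaxation modulus to force curve

For a monotonically growing contact, the force under a probe with Hertzian
geometry exponent $n$ and constant $C_{geom}$
(`probe_geometry()`: cylinder $n=1$, sphere $n=3/2$, cone $n=2$) follows
the Lee-Radok hereditary integral

$$F(t) = C_{geom} \int_0^t E(t - \xi)\,
  \frac{\partial\, \delta^n(\xi)}{\partial \xi}\, d\xi .$$

During retraction the contact radius shrinks and the integral must be
truncated at the auxiliary time $t_1(t) \le t_m$ — Ting's solution — defined
as the root of

$$\int_{t_1(t)}^{t} E(t - \xi)\, \frac{\partial \delta}{\partial \xi}\,
  d\xi = 0 .$$

Physically, $t_1(t)$ is the approach time at which the contact radius was
the same as it is now; the contact is lost (the *detachment time*
`t_detach`) when $t_1$ reaches zero, and the force is identically zero
afterwards — for strongly viscous materials well before the depth returns to
zero.

`simulate_curve()` implements both phases; `analytic_curve()` provides the
closed-form oracle solutions (elastic solid on any probe and ramp, dashpot,
Kelvin-Voigt on a triangular ramp, Maxwell on a flat punch) used by the test
suite.

```{r curve}
m <- relaxation_model("sls", E0 = 1000, E_inf = 300, tau = 0.02)
p <- probe_geometry("sphere", radius = 5e-6)
h <- indentation_history("triangular", delta_max = 100e-9, t_m = 0.05)
fc <- simulate_curve(m, h, p, n_steps = 400)
fc
plot(fc)
```

## Numerical scheme

The solver uses *product integration* on a uniform grid of `n_steps`
intervals per phase: within each interval the rate
$\partial \delta^n / \partial \xi$ is frozen at its midpoint value while the
kernel is integrated **exactly**, through the closed-form running integral
$G(t) = \int_0^t E(s)\, ds$ that every catalogued model provides.  This
makes the integrable $t^{-\alpha}$ singularities of fractional kernels cost
nothing in accuracy, and reduces each force evaluation to a discrete
convolution over grid lags.

Further choices worth knowing:

* $t_1(t)$ is found by bracketed root finding (`uniroot`, absolute
  tolerance $h \times 10^{-8}$ with $h$ the grid step), warm-started from
  the previous sample since $t_1$ is non-increasing.
* The detachment time is located by linear interpolation of the
  hereditary residual between the last two grid samples.
* The retraction branch starts at $t_m$ with the right-limit force: the
  Dirac term switches sign there, which reproduces the instantaneous force
  drop of Kelvin-Voigt materials at the turning point (and their force jump
  at first touch under a flat punch).
* `method = "lee_radok"` continues the approach integral through
  retraction without truncation.  For a flat punch (constant contact
  radius) this is exact and must agree with the Ting branch to solver
  precision — a stringent cross-validation used in the tests.

Accuracy against the closed-form oracles is at the $10^{-5}$ level (relative
to the peak force) at `n_steps = 400` for curves with square-root kernel
behavior, and near machine precision where the midpoint rule is exact.

## Curve descriptors and their time dependence

Three descriptors summarize a cycle (`curve_metrics()`):

* **Apparent Young's modulus** — the Hertzian least-squares fit of the
  approach branch with the exponent fixed at the probe's $n$.
* **Normalized hysteresis area (NHA)** — the fraction of the indentation
  work dissipated, 0 for an elastic solid and 1 for a pure dashpot.
* **Curve exponent** — the free power in $F = A\,\delta^m$; relaxation
  drags it below $n$, by a full unit in the dashpot limit and by $\alpha$
  for a springpot.

`sweep_indentation_time()` repeats the cycle over a grid of cycle durations
$t_{ind} = 2 t_m$.  The sweep grid and the normalized time axis use this
*nominal* duration; the measured contact time (ending at detachment) is
reported per point in `t_contact_s`.

```{r sweep}
sw <- sweep_indentation_time(m, p, t_ind = 0.02 * 10^seq(-2, 2, length.out = 9),
                             n_steps = 200)
plot(sw)
```

The apparent modulus interpolates between the instantaneous plateau $E_0$
at fast cycles and the equilibrium plateau $E_\infty$ at slow ones, and
tracks the quarter-cycle time average of the relaxation modulus,

$$\langle E \rangle (t_{ind}) = \frac{4}{t_{ind}}
  \int_0^{t_{ind}/4} E(s)\, ds,$$

within about 15% for all catalogued models (`time_averaged_modulus()`,
`eq_average_check()`).  The NHA peaks where the cycle time crosses the
relaxation time and vanishes at both elastic extremes; materials with two
well-separated relaxation times show two NHA peaks.

## Limitations

* Linear viscoelasticity, small strains, no adhesion: the contact force
  cannot become negative, and detachment is purely viscoelastic.
* The parabolic (Hertz) sphere approximation degrades beyond depths of
  about 10% of the sphere radius; a warning is issued.
* The sinusoidal ramp uses a quarter-sine approach and continues the same
  sine through retraction; it is *not* a steady-state oscillation, so
  descriptors differ from dynamic-mechanical moduli.
* Bottom-effect (finite thickness) corrections enter only through the
  user-supplied multiplicative factor `f_bec`.
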