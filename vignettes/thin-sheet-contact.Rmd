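---
title: "Contact of thin elastic sheets with randomly rough surfaces: model and methods"
author: "gfmdlayer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact of thin elastic sheets with randomly rough surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gfmdlayer)
```

## The physical problem

Many biological adhesive systems — insect and spider setae, gecko
spatulae, skin — press *thin* elastic structures against rough
counterfaces.  A thin sheet backed by a fluid (constant pressure, no
shear coupling) accommodates roughness far more easily than a bulk
solid, so its real contact area at a given load can exceed the
half-space value by orders of magnitude.  `gfmdlayer` quantifies this
with a boundary-value solver in the Green's function molecular dynamics
(GFMD) family: the sheet's surface response is encoded per Fourier
mode, and the constrained equilibrium against a rigid rough substrate
is found by damped relaxation dynamics.

## Elastic model

The sheet is homogeneous, with contact modulus $E^*$ and width $w$,
loaded from behind by a uniform pressure $\sigma_0$.  Displacements
$z(\mathbf r)$ of the contacting face map onto interfacial stresses
mode by mode,
$$\tilde\sigma(\mathbf q) = \tilde z(\mathbf q)\, / \,G(q), \qquad
G(q) = \frac{2\,f(qw)}{q\,E^*},$$
where $G$ is the per-mode compliance and
$$f(t) = \frac{\sinh 2t + 2t}{\cosh 2t - 1 - 2t^2}$$
corrects the half-space response ($f \to 1$ for $t \gg 1$) for the
finite width.  For $t \ll 1$, $f(t) \to 6/t^3$, so
$1/G \to E^* q^4 w^3/12$ — precisely the bending stiffness of a thin
plate, which is why thin sheets are so compliant at long wavelengths.
The interpretation of $G$ as a *compliance* is fixed by both limits and
is unit-tested against them.  The $q = 0$ mode of a free sheet on fluid
has no elastic restoring force; it is excluded from $G$ and evolves
under the net force balance instead.

Numerical guards on $f$: below $t = 0.1$ the subtracted denominator
$\cosh 2t - 1 - 2t^2$ cancels catastrophically in floating point, so
Taylor series of numerator and denominator (through $t^9$/$t^{10}$) are
used; above $t = 19$ the hyperbolics overflow and the asymptote
$1 + (4t^2+4t+2)e^{-2t}$ takes over.  Branch mismatches are below
$10^{-9}$ relative.

## Rough substrate synthesis

The rigid counterface is a periodic, self-affine random field defined
by its isotropic power spectrum: a plateau below the roll-off $q_r$, a
power law $q^{-2(1+H)}$ between $q_r$ and the cut-off $q_s$, zero
beyond.  Fourier amplitudes get independent uniform (not Gaussian) real
and imaginary parts with the spectrum as second moment — uniform draws
avoid rare outlier modes while leaving all second-order statistics
unchanged.  Hermitian symmetry makes the field real; self-conjugate
(zero/Nyquist) modes are drawn real; the mean-height mode is zero.

The absolute spectral scale is a free convention: every surface is
rescaled to root-mean-square gradient
$\sqrt{\langle|\nabla h|^2\rangle} = 1$ (computed spectrally, exact for
band-limited fields) and then shifted so its maximum sits at $z = 0$.
The order matters: shifting does not change gradients, while
normalising after shifting would break the zero maximum.  All loads are
reported as $\sigma_0 / (E^* \sqrt{\langle|\nabla h|^2\rangle})$, which
the normalisation reduces to $\sigma_0/E^*$.

Default desk-scale geometry: $\lambda_s = 4a$, $\lambda_r = 16
\lambda_s$, system length $8\lambda_r$ ($n = 512$), chosen to keep the
scale separation $a < \lambda_s \ll \lambda_r \ll L$ at tractable cost;
larger production geometries are plain configuration changes.

## Finding equilibrium

Grid points carry mass $m$ (free parameter, set to 1 — only the
equilibrium matters) and obey Newton's equations under four forces:
external $-\sigma_0 a^2$, elastic (from the kernel), optional adhesion,
and viscous damping.  A velocity-Verlet integrator advances them; after
every step, points below the substrate are set exactly onto it and
their velocity is removed (hard-wall projection with maximal
dissipation — the most robust of the velocity treatments we tried).
The stationary states of these dynamics are exactly the
complementarity solutions: free points carry zero net force, contact
points carry non-negative reaction.

Two integration modes are provided:

* `accelerator = "fixed"`: constant time step
  $dt = 0.25 \cdot 2/\omega_{max}$ and constant damping chosen so the
  *slowest* elastic mode is slightly underdamped,
  $\eta = 0.9 \cdot 2\sqrt{\kappa_{min} m}/m$ with
  $\kappa_{min} = a^2/G(q_{min})$.
* `accelerator = "fire"` (default): the same Verlet dynamics with
  FIRE-style adaptive damping — velocities are steered toward the
  force direction while the motion is downhill and quenched to zero
  when it turns uphill, with the time step adapting between $0.02$ and
  $2.5$ times the stability step.  This reaches the same fixed point
  (areas agree to all reported digits on cross-checks) in one to two
  orders of magnitude fewer iterations, which matters for thin layers
  whose soft bending modes make the fixed-damping scheme crawl.

A tempting third option — per-mode inertia $m(q) \propto \kappa(q)$ so
all modes share one frequency — was evaluated and **rejected**: with a
real-space hard wall the stationary condition of mass-weighted
projected dynamics is $(M^{-1}F)_{free} = 0$ rather than
$F_{free} = 0$, and the long-ranged convolution $M^{-1}$ smears
contact reactions into the free region, visibly biasing the contact
area.  Uniform mass keeps the fixed point exact.

Convergence requires both (i) the maximum unbalanced force on
non-contact points, relative to $\sigma_0 a^2$, to drop below
`force_tol` ($10^{-4}$ by default) and (ii) the contact area to be
stationary to one part in $10^4$ over three consecutive checks.
Load sweeps are warm-started from the previous converged state, which
cross-checks against cold starts to within 0.5% in area.

### Adhesion

Short-range adhesion adds an attractive stress
$(\gamma_0/\rho)\exp[-(z-h)/\rho]$; its gap integral is the work of
adhesion $\gamma_0$.  The default range $\rho = 0.1\lambda_s$ keeps the
attraction short-ranged against the finest roughness wavelength.  The
adhesion energy is reported as $U_{ad} = \gamma_0 \times$ (touching
area) — the $\rho$-independent short-range definition; the gap-integral
variant is also returned (`Uad_potential`) for sensitivity checks.
Contact area always means *geometric* contact (points on the wall),
with or without adhesion.

## Observables and scaling analyses

* **Area–load curves**: $A/A_0$ versus dimensionless load; the
  half-space curve follows $\mathrm{erf}(k\,\sigma_0/E^*)$ with
  $k \approx 2$.  The erf fit is restricted to $A/A_0 < 0.9$, where
  the relation is meaningful.  (An erf coefficient and a low-load
  linear slope differ by $\sqrt\pi/2$; we fit the erf form and say so.)
* **Collapse coefficient** $c(W)$: the load rescaling
  $\sigma_0 \to c\,\sigma_0$ that superposes a thin-layer curve onto
  the half-space master.  Thin layers reach a given area at *lower*
  load, so $c \ge 1$ and grows as the sheet thins; the fit minimises
  the squared log-load distance at equal area fraction below
  $A/A_0 = 0.5$ (where the reduced-area statistic
  $A(A_0-A)/A_0^2$ is monotone).
* **Adhesion parameter** $\theta = U_{el}/U_{ad}$ at fixed target area
  fractions, located by warm-started secant iteration on the load; the
  ladder auto-extends until the targets are bracketed.  The default
  targets ($A/A_0 = 0.5, 0.55, 0.6$) lie in the range every studied
  width can reach: with short-range adhesion at the default strength a
  very thin sheet ($W = 0.0625$) snaps into roughly 44% contact even as
  the external load vanishes, so smaller targets would be unreachable
  there — itself a vivid demonstration that thin sheets are adhesive
  ($\theta < 1$ at those conditions).
* **Persson broadening** $\Delta\sigma$: the full-contact pressure
  standard deviation implied by the spectrum through the kernel,
  $\Delta\sigma^2 = \sum_{q\neq0} (qE^*/2f(qw))^2\,\langle|\tilde
  h(q)|^2\rangle/N^2$ — exact in full contact; on a unit-gradient
  surface the half-space value is $E^*/2$.  The predicted area-load
  relation is $\mathrm{erf}(\sigma_0/\sqrt2\Delta\sigma)$ (the
  $\sqrt2$ is a convention absorbed into fitted coefficients).

### The thin-plate scaling window

For $W = w/\lambda_s \ll 1$ every roughness mode deforms the sheet in
the plate regime, so $\Delta\sigma \propto W^3$, the low-load area
coefficient and the collapse coefficient scale as $W^{-3}$, and
$\theta \propto W^3$.  The crossover sits where the *finest* roughness
mode enters the plate regime, $q_s w \approx 1$, i.e.
$W \approx 1/2\pi \approx 0.16$: only widths well below this are
asymptotic.  The broadening integral makes this quantitative — its
log-log slope reaches $3.00$ on $W \in [10^{-2}, 10^{-1}]$ but is
visibly shallower when the window includes $W = 0.25$ and $0.5$.  The
default width scan `widths = c(0.0625, 0.125, 0.25, 0.5)` spans the
crossover, so its fitted exponents undershoot the asymptotic magnitude
3 (the pairwise slope between the two smallest widths is much closer);
the theory-predictor comparison (`run_theory_comparison()`) shows the
same shallowing over the same window, which is the appropriate
like-for-like check.  We keep the window as specified rather than
silently extending it to smaller widths, because $n = 256$ grids do not
resolve loads much below the $W = 0.0625$ ladder reliably.

## What the generator emulates — and what it does not

The synthetic substrates are periodic, isotropic, Gaussian-like (by the
CLT, despite uniform mode amplitudes) self-affine fields with a clean
plateau/power-law/cut-off spectrum and exactly unit rms gradient.  Real
measured topographies have anisotropy, non-Gaussian height statistics,
imperfect scaling, and no sharp cut-off; passing tests on synthetic
surfaces therefore validate the *solver and the scaling laws*, not any
claim about a specific material.  Single-cosine and flat substrates are
used as analytic oracles (Westergaard-type full-contact pressure
fields, zero-deformation flat contact).

## Problem sizes and tolerances

The package's own validation runs use: $n = 512$, 8 loads, 3 seeds for
the half-space erf coefficient; $n = 256$ and one seed for the width
and adhesion scans ($W \in \{0.0625, 0.125, 0.25, 0.5\}$,
$\gamma_0 = 5\times10^{-4}$, $\rho = 0.4a$); 20 seeds at $n = 512$ for
Hurst-exponent recovery (input $0.8$, tolerance $\pm0.1$); `force_tol`
$= 10^{-4}$ throughout.  Degenerate inputs are handled explicitly: a
zero spectrum yields a flat surface (normalisation skipped), a flat
substrate gives full contact with zero deformation and an undefined
separation, zero contact or zero $\gamma_0$ makes $\theta$ undefined,
and non-convergence is reported in the result rather than thrown.

## Known limitations

* The foundation is a pure fluid: the bonded-layer boundary condition
  (sheet glued to a rigid base) has a qualitatively different
  correction factor and is out of scope.
* Only normal loading; no friction, tangential compliance, plasticity,
  or true dynamics (the damping is a relaxation device, not rheology).
* Contact-patch morphology (cluster statistics, percolation) and gap
  distributions are not computed.
* The default width window spans the thin-plate crossover, as discussed
  above; asymptotic exponents should be read from the
  $W \lesssim 0.1$ regime.
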