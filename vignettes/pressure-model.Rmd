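---
title: "Modelling hydrostatic pressure with surface Gaussian potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hydrostatic pressure with surface Gaussian potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hipres` implements the GOSTSHYP picture of hydrostatic compression: the
molecule sits inside a closed cavity whose surface is discretized into
tesserae, and every tessera $j$ carries a repulsive potential
$p_j\,\tilde G_j(\mathbf r)$ with the normalized Gaussian

$$\tilde G_j(\mathbf r) = N_j\, e^{-\omega_j |\mathbf r - \mathbf r_j|^2},
\qquad N_j = (\omega_j/\pi)^{3/2}.$$

The exponent is tied to the tessera area $a_j$ by the *edge-halving*
condition — the potential drops to half its peak at the rim of the
(circular) tessera, $\tilde G_j(\sqrt{a_j/\pi}) = \tilde G_j(0)/2$ —
giving $\omega_j = \pi \ln 2 / a_j$.  Positions and areas of tesserae are
the only cavity quantities that enter the equations.

Each SCF iteration contracts the density matrix $D$ with two families of
three-center overlap integrals,

$$\tilde g_j = \sum_{\mu\nu} D_{\mu\nu} \langle\mu|\tilde G_j|\nu\rangle,
\qquad
\tilde f_j = \sum_{\mu\nu} D_{\mu\nu}\,
   \mathbf n_j \cdot \nabla_{\mathbf r_j} \langle\mu|\tilde G_j|\nu\rangle,$$

and the amplitudes follow from the semiclassical force balance on each
surface element — the force the potential exerts on the electron density
equals the applied pressure times the tessera area:

$$p_j = -\,p_{\mathrm{inp}}\, a_j / \tilde f_j .$$

The sign convention is chosen so that on a well-formed convex surface,
where moving a Gaussian outward along the normal *decreases* its overlap
with the density ($\tilde f_j < 0$), amplitudes come out positive.  A
negative amplitude therefore flags a surface region whose normal points
*toward* density — a crevice — and is reported as a diagnostic rather
than clamped.  The energy contribution and its conjugate volume are

$$E_G = \sum_j p_j \tilde g_j, \qquad V_{\mathrm{eff}} = E_G /
p_{\mathrm{inp}},$$

and the Fock-matrix contribution is the density derivative of $E_G$,

$$F^G_{\mu\nu} = \sum_j p_j \left[ g_{\mu\nu,j} -
\frac{\tilde g_j}{\tilde f_j} f_{\mu\nu,j} \right].$$

Because $E_G$ is a ratio $-p_{\mathrm{inp}} a_j \tilde g_j/\tilde f_j$ in
which the normalization constant $N_j$ cancels exactly, derivatives of
$N_j$ never enter the nuclear gradient; the gradient code omits them and
the finite-difference oracle in the test suite confirms the cancellation
empirically rather than trusting the algebra.

## Integral-direct evaluation

Nothing of size $N_{\mathrm{basis}}^2 \times N_{\mathrm{tess}}$ is ever
stored.  Each iteration makes two passes over (shell pair, tessera)
batches: pass one contracts the integrals with the density into
$\tilde g, \tilde f$ (length $N_{\mathrm{tess}}$), pass two accumulates
the Fock contribution ($N_{\mathrm{basis}}^2$) tessera by tessera.  The
integrals themselves are evaluated per Cartesian dimension by expanding
the basis-function pair in Hermite Gaussians; the overlap of a Hermite
Gaussian with the s-type tessera Gaussian has a closed form generated by
a two-term derivative recursion, and exponent derivatives (the d- and
f-type tessera Gaussians needed by the gradient) follow analytically from
the same expressions.  Batches are screened with a provably conservative
bound: pointwise Gaussian envelopes of the contracted shells
($|\phi(\mathbf r)| \le C e^{-\alpha_{\min}|\mathbf r-\mathbf A|^2/2}$)
combined with the closed-form overlap of three s-Gaussians.  The bound is
deliberately loose — skipping is only ever allowed when the bound falls
below the threshold, so enabling screening never changes a kept value.
The default threshold of `1e-12` changes fixture total energies by less
than $10^{-9}\,E_h$ (asserted in the tests, not assumed).

## Cavities

Two cavity constructions are supported, both smooth enough for analytic
gradients:

* **vdW** — atom-centered spheres with per-element radii (Bondi by
  default), each carrying a Lebedev grid.  A grid point's area is
  (Lebedev weight) × (switching weight) × $4\pi r^2$, where the switching
  weight fades points out as they penetrate neighboring spheres.  The
  literature on smooth discretized vdW surfaces specifies the idea but
  not one canonical polynomial; this implementation uses the quintic
  smoothstep $S(t) = t^3(10-15t+6t^2)$ of the signed penetration depth,
  with a switching-region width of $0.1\,r_{\mathrm{vdW}}$ of the
  neighbor sphere.  The smoothstep is $C^2$, which keeps the area
  derivatives (and hence the nuclear gradient) continuous.  Tesserae with
  weight below $10^{-8}$ are discarded as numerical noise.
* **vdW/OCC** — the same surface, but the switching weights are evaluated
  on a second surface inflated by an extension radius $r_{\mathrm{ext}}$
  (default 0.25 Å) and transferred to the inner tesserae through the
  one-to-one Lebedev mapping.  This screens away the crevice points that
  cause negative amplitudes, at the price of small holes in the
  parametrization.  Removed points are simply dropped; the remaining
  areas are *not* re-normalized to compensate, since the area sum is not
  a conserved quantity of the model.

Solvent-excluded, isodensity and pseudo-isodensity surfaces are out of
scope and rejected with a clear error: their derivatives are either
unavailable or inconsistent with the electronic energy, and only the
smooth vdW family optimizes reliably.

Cavity derivatives are analytic: tessera centers ride rigidly on their
parent atom ($\partial \mathbf r_j/\partial \mathbf R_I =
\delta_{I,\mathrm{parent}}\,\mathbb 1$), and area derivatives run through
the switching products (through the outer-surface switch for OCC).  The
Lebedev directions are fixed in the laboratory frame, a standard property
of this construction; areas are exactly invariant under rigid
translation, which the gradient tests exploit.

## Nuclear gradients

At the converged density the pressure-energy gradient has three pieces
that the package reports separately (they sum exactly to the total):

* the **center-derivative part** — constant-exponent derivatives of the
  three-center integrals, contracted on the fly with coefficients $p_j$
  (on $\mathrm d g$) and $-p_j \tilde g_j/\tilde f_j$ (on $\mathrm d f$).
  Only bra-side derivatives are coded; ket and tessera-center derivatives
  come from translational invariance (the three blocks sum to zero, a
  relation the tests check to $10^{-12}$);
* the **exponent part** — the precomputed exponent-derivative
  contractions routed through $\partial\omega_j/\partial a_j =
  -\omega_j/a_j$ and the area-derivative table;
* the **area part** — the explicit $a_j$ dependence of the amplitudes.

Density-matrix response is *not* part of this block: it is carried by the
host engine's energy-weighted density, which is built from the total Fock
matrix (pressure term included), so the analytic total gradient matches
central finite differences of the total SCF energy to below
$10^{-5}\,E_h/a_0$ on the fixtures at 10 GPa (step $10^{-3}\,a_0$ for
energies, $10^{-5}\,a_0$ for integral-level checks — documented so that a
failure is attributable to the term, not the stencil).

## The host SCF engine

No quantum-chemistry engine exists on CRAN or Bioconductor, so the
package carries its own compact restricted Hartree–Fock implementation:
McMurchie–Davidson one- and two-electron integrals over contracted
Cartesian Gaussians (angular momenta through *g*), DIIS-accelerated SCF,
and analytic RHF gradients.  It is validated independently of the
pressure model — the H2 minimal-basis energy against a closed-form
symmetric-orbital expression, water and methane against textbook
minimal-basis values, every integral family against a Gauss–Hermite
quadrature oracle, and gradients against finite differences.  The
shipped basis set is STO-3G (H, He, C, N, O, Ne); Gaussian94-format
files can be supplied for anything else.  Restricted (closed-shell)
references only; density functionals are not implemented.  The paper's
production setting (hybrid DFT, double-zeta bases, 90+-atom systems) is
therefore out of desk scale here, and the package's claims are the
*properties* of the model — exact zero-pressure limit, self-consistency
of the Fock term, gradient/energy consistency, the crevice diagnostic —
not the paper's absolute numbers.

## The crevice fixture

Negative amplitudes require concavity: a tessera whose outward normal
points toward another fragment's electron density.  Two *parallel*
stacked rings never produce them — every surviving normal still points
away from all density — which we verified empirically before settling on
the fixture.  `benzene_dimer_crevice` therefore hinges two benzene rings
into a wedge (tilt 0.3 rad, closest inter-ring C–C contact 3.2 Å, cavity
radii H 1.4 Å / C 2.1 Å, 110-point grids).  At 5 GPa the plain vdW
surface carries a handful of negative amplitudes while vdW/OCC at
$r_{\mathrm{ext}} = 0.25$ Å carries none; at 10 GPa the ill-defined
amplitudes destroy vdW SCF convergence outright (60+ cycles without
convergence) while the corrected cavity converges in about 19.  This is
the desk-scale analogue of the fullerene/pincer study: the wedge stands
in for the concave pincer, and the diagnostic-plus-rescue pattern is the
reproduced result.

What the synthetic fixtures do *not* emulate: dispersion-bound complexes
of realistic size, basis sets with polarization functions, correlation
effects, and cavities fitted to isodensity surfaces.  Passing tests
demonstrate the internal consistency and qualitative physics of the
implementation, not quantitative transferability to production systems.

## Numerical choices

* All internal math in atomic units; 1 Å = 1.8897261246 bohr,
  1 hartree/bohr³ = 29421.0265 GPa, 1 hartree = 2625.4996 kJ/mol.
* Amplitude regularization: $|\tilde f_j| < 10^{-12}$ sets $p_j = 0$ (a
  tessera the density cannot feel exerts no force); counted and
  reported.
* SCF convergence: energy change below $10^{-7}\,E_h$ by default
  (tightened to $10^{-11}$ wherever gradients are taken), DIIS error
  below $10^{-6}$, DIIS depth 8, no damping of amplitudes — they are
  recomputed from the current density every cycle, fully
  self-consistently.
* Geometry optimization: BFGS on the total analytic gradient;
  convergence at energy change $10^{-6}\,E_h$ and gradient norm
  $10^{-3}\,E_h/$Å.  Tesserae may appear or disappear *between* steps
  when switching weights cross the discard cutoff; within one gradient
  evaluation the cavity is fixed.
* Degenerate inputs: zero density gives zero auxiliary vectors and all
  amplitudes regularized to zero; a lone atom has a translation-invariant
  cavity and a vanishing pressure gradient; requesting
  $V_{\mathrm{eff}}$ at zero pressure is an error, not a NaN.
* Problem sizes: test fixtures use STO-3G with 50–110-point grids per
  atom (a few hundred tesserae), the sizes at which every property above
  is verified end to end.

## A worked run

```{r example}
library(hipres)
fx <- make_fixture("h2o")
s <- run_scf(fx$mol, basis = "sto-3g", pressure = 10, cavity = "vdw_occ")
s
g <- total_gradient(s)
opt <- optimize_geometry(fx$mol, pressure = 10, cavity = "vdw_occ")
```

## Known limitations

* Closed-shell RHF only; no DFT, no post-SCF correlation, no response
  properties, no enthalpy interpretation of $E_G$ (the effective volume
  is reported, nothing more is claimed for it).
* Cartesian AOs without a spherical-harmonic transformation; with the
  shipped s/p basis the two coincide.
* The screening bound is conservative but loose; it exists to guarantee
  correctness of what is kept, not to maximize the skip rate.
* Lebedev grids are laboratory-frame fixed, so cavity energies are not
  exactly rotationally invariant (standard for this construction; the
  effect is below the discretization error of the grid).
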