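# hipres

Hydrostatic pressure changes molecular structure, spectra and reactivity,
but single-molecule quantum chemistry has no box to squeeze: some model
must stand in for the compressing environment. `hipres` implements the
GOSTSHYP approach (Gaussians On Surface Tesserae Simulate HYdrostatic
Pressure) for R: the molecule is enclosed in a van der Waals cavity
discretized into tesserae, and every tessera *j* carries a repulsive
Gaussian potential

    p_j * N_j * exp(-omega_j |r - r_j|^2),   N_j = (omega_j/pi)^(3/2)

whose exponent follows from the edge-halving condition
`omega_j = pi*ln2 / a_j` (area `a_j`). Each SCF cycle contracts the
density matrix with three-center overlap integrals into two per-tessera
vectors `g~_j` (value type) and `f~_j` (normal-derivative type); the
amplitudes follow from the force balance on each surface element,

    p_j = -p_inp * a_j / f~_j,

the pressure energy is `E_G = sum_j p_j g~_j` with conjugate volume
`V_eff = E_G / p_inp`, and the Fock contribution is the density
derivative `F_G = sum_j p_j [g_j - (g~_j/f~_j) f_j]`. Negative amplitudes
are a built-in diagnostic for ill-formed cavity regions (crevices); the
outer-cavity correction (vdW/OCC) removes them by taking switching
weights from a surface inflated by an extension radius. Everything is
evaluated integral-direct — no quantity of size `nbf^2 x n_tess` is ever
stored — with conservative batch screening, and the analytic nuclear
gradient of `E_G` (center-, exponent- and area-derivative parts) enables
geometry optimization under pressure.

Because no SCF engine exists in the R ecosystem, the package includes a
compact restricted Hartree-Fock engine (McMurchie-Davidson integrals
through *g* functions, DIIS, analytic gradients) with STO-3G shipped and
Gaussian94-format basis files accepted. It targets desk-scale studies of
the pressure model itself — its audience is method developers and
students of continuum pressure models, not production thermochemistry.

## A worked example

```r
library(hipres)
fx <- make_fixture("h2o")
run_scf(fx$mol, basis = "sto-3g", pressure = 10, cavity = "vdw_occ")
#> <hipres_scf> E = -74.9484297517 hartree (converged in 7 cycles)
#>   p = 10 GPa: E_G = 0.01449797 hartree, V_eff = 42.6545 bohr^3, 0 negative amplitude(s) on 184 tesserae
```

The total energy lies 0.0145 hartree above the gas phase
(−74.9629 hartree): compressing the electron density costs energy, and
the ratio of that cost to the applied pressure is the effective volume
(42.65 bohr³ here — the volume conjugate to the pressure, not the
geometric cavity volume). Zero negative amplitudes say the cavity is
well formed. Optimizing H2 under pressure shows the expected bond
compression:

```r
opt0  <- optimize_geometry(make_fixture("h2")$mol, pressure = 0,  cavity = "vdw_occ")
opt50 <- optimize_geometry(make_fixture("h2")$mol, pressure = 50, cavity = "vdw_occ")
#> bond length 0.7122 A at 0 GPa  ->  0.6993 A at 50 GPa
```

On the crevice-bearing wedge fixture (`make_fixture("benzene_dimer_crevice")`),
the plain vdW cavity produces negative amplitudes and erratic SCF
convergence at 10 GPa, while `cavity = "vdw_occ"` with
`r_ext = 0.25` converges cleanly with none — the cavity-quality
diagnostic the model is known for.

A command-line wrapper ships as `inst/cli/hipres`
(`hipres scf geom.xyz --pressure 10 --cavity vdw_occ --json out.json`,
plus `opt`, `bind` and `fixtures` subcommands).

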