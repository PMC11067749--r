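# aspherED

Aspherical-atom (TAAM) refinement machinery for 3D electron diffraction,
in R.

Conventional electron-diffraction structure refinement models the crystal
as a sum of spherical, neutral, independent atoms (IAM). At the data
quality modern 3D ED / microED experiments reach, that approximation is
the limiting error: bonding and intermolecular interactions redistribute
valence electrons, and the Mott–Bethe relation makes electron scattering
exquisitely sensitive to those redistributions at low scattering angle.
`aspherED` implements the full model stack needed to study this —
aspherical pseudoatom densities, their electron scattering factors,
kinematical and dynamical (multiple-scattering) intensities, and the
least-squares refinements that connect them to data — together with a
synthetic molecular-crystal generator (a planar N-methylated
pyrimidinedione in space group *Ibam*, emulating 1-methyluracil) so that
every algorithm can be validated end-to-end against known ground truth.

## The model

Each pseudoatom density follows the Hansen–Coppens multipole formalism

```
rho(r) = P_c rho_core(r) + P_val kappa^3 rho_val(kappa r)
       + sum_l kappa'^3 R_l(kappa' r) sum_m P_lm d_lm(theta, phi)
```

with Slater-type radial functions `R_l(r) ∝ r^(n_l) exp(-zeta r)` and
density-normalized real spherical harmonics `d_lm`
(`integral |d_lm| dOmega = 2` for `l > 0`). The analytic X-ray form
factor is

```
f_x(h) = P_c f_core(s) + P_val f_val(s/kappa)
       + sum_l 4 pi i^l <j_l>(s/kappa') sum_m P_lm d_lm(h_local)
```

with `s = sin(theta)/lambda` and `<j_l>` the closed-form Fourier–Bessel
transform of `R_l`. Electron scattering factors follow from the
Mott–Bethe formula `f_e(s) = (Z - f_x(s)) / (8 pi^2 a0 s^2)`. Kinematical
structure factors include site symmetry, local-frame rotation of the
deformation density and (an)isotropic Debye–Waller factors; dynamical
intensities come from the N-beam Bloch-wave eigenproblem
`A = diag(S_g) + U_(g-h)/(2K)` with `U_g = gamma F_e(g) / (pi V)`,
optionally averaged over a precession cone. Refinement is damped
Gauss–Newton least squares against `|F|` or `|F|^2` with the standard
`1/[sigma^2 + (aP)^2 + bP]` weighting, symmetry-derived special-position
constraints, and esds from the inverse normal matrix. Residual
electrostatic-potential maps (`e/Å` units) and their fractal-dimension
curves complete the analysis toolbox.

## Worked example

```r
library(aspherED)

st <- fixture_structure()
st
#> crystal structure: 14 sites in Ibam, V=1129.7 A^3

electron_wavelength(200)      # relativistic wavelength at 200 kV
#> 0.02508  (Angstrom)

# ME / RMSD of the packaged published X-H bond-length tables
xh_table_stats()
#>   table         model       ME    RMSD
#> 1   kin           IAM  0.01804 0.01976
#> 2   kin          TAAM -0.00266 0.00493
#> 3   kin molecule_TAAM  0.00184 0.00848
#> 4   kin  crystal_TAAM -0.00210 0.00852
#> 5   dyn           IAM  0.04738 0.06517
#> 6   dyn          TAAM -0.00522 0.02459
#> 7   dyn  crystal_TAAM  0.01438 0.02774

# electron structure factors: multipole (TAAM-like) vs spherical IAM
tm <- fixture_multipoles("databank")
H  <- rbind(c(1,1,0), c(2,0,0), c(0,2,0))
Mod(structure_factor(st, tm, H, "electron"))
#>  3.214 57.359 12.614
Mod(structure_factor(st, iam_models(st), H, "electron"))
#> 24.365 59.492  5.898
```

The kinematical table says IAM-refined X—H bonds are on average 0.018 Å
too long against the 15 K neutron reference while TAAM is within
uncertainties; the dynamical table shows the same contrast on
experimental-style data (0.047 Å vs −0.005 Å). The structure-factor
comparison shows why: the lowest-angle reflections (here 110, 200, 020)
react strongly to the valence redistribution, by far the most for 110.

A thin command-line front end over the same functions is provided in
`inst/cli/aspher.R` (subcommands `stats | simulate | refine | mm-refine |
dyncalc | map | fractal`, each writing a JSON run summary).

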