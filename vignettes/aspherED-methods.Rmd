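---
title: "Aspherical-atom electron diffraction refinement: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aspherical-atom electron diffraction refinement: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`aspherED` implements the model stack for transferable-aspherical-atom
(TAAM) refinement of 3D electron diffraction data: Hansen–Coppens
pseudoatom densities and their analytic form factors, Mott–Bethe
electron scattering factors, kinematical structure factors, weighted
least-squares refinement of structural and of multipole parameters,
N-beam Bloch-wave dynamical intensities with precession averaging and
thickness refinement, residual electrostatic-potential maps and
fractal-dimension analysis, and a synthetic-data generator that closes
the loop for validation. This vignette records the science, the
numerical choices, and the places where the design was genuinely open.

# The pseudoatom model

Each atom contributes a density

$$\rho(\mathbf r) = P_c\,\rho_{core}(r) + P_{val}\,\kappa^3\rho_{val}(\kappa r)
 + \sum_{l=1}^{l_{max}} \kappa'^3 R_l(\kappa' r)\sum_m P_{lm}\, d_{lm}(\hat{\mathbf r}),$$

with all radial functions single-zeta Slater densities
$R_{n,\zeta}(r) = N r^n e^{-\zeta r}$, normalized so
$\int R\,r^2\,dr = 1$ ($N = \zeta^{n+3}/(n+2)!$). The angular functions
$d_{lm}$ are real spherical harmonics under *density* normalization:
$\int |d_{lm}|\,d\Omega = 2$ for $l \ge 1$, so a population $P_{lm}$
moves one electron from the negative to the positive lobes, and
$d_{00} = 1/4\pi$. The normalization constants were generated once by a
48 000-point composite Gauss–Legendre quadrature and frozen as a table
in the source; the test suite re-derives them with an independent
separable quadrature to $10^{-6}$.

The analytic form factor uses the closed-form Fourier–Bessel transforms
$\langle j_l\rangle(s) = \int R(r) j_l(4\pi s r) r^2 dr$, evaluated
termwise through
$\int r^m e^{-\zeta r} e^{iKr} dr = m!/(\zeta - iK)^{m+1}$ on the
trigonometric expansion of $j_l$ (valid for $n \ge l$, which all shipped
radials satisfy). Below $K < 0.25\,\zeta$ the closed form cancels
catastrophically and a 30-term Taylor series in $K$ is used instead;
the crossover keeps at least ten significant digits on both sides.

Site symmetry restricts the allowed $(l, m)$: `"m"` (mirror = local
$xy$ plane) keeps $l + |m|$ even, `"3m"` keeps $m \in \{0, +3\}$,
`"cyl"` keeps only bond-directed $m = 0$ terms, `"1"` keeps all.
Forbidden populations are rejected at model construction, so they are
*exactly* zero throughout any fit. Local frames are built from two
reference atoms (first axis along the first reference, Gram–Schmidt for
the second, right-handed completion), and rotate rigidly with the
structure; the structure-factor engine therefore recomputes the frames
of every atom whose reference moved during refinement.

## Units and constants

All lengths are in Å, $s = \sin\theta/\lambda$ in Å$^{-1}$; Slater
exponents are stored in bohr$^{-1}$ in the packaged data file and
converted once at load. The Mott–Bethe constant is derived from the
Bohr radius, $C = 1/(8\pi^2 a_0) = 0.023934$, not hard-coded; the
relativistic wavelength and the interaction factor
$\gamma = 1 + eV/m_0c^2$ come from CODATA constants. The shipped
single-zeta shell exponents for H, C, N, O are generic
Clementi–Raimondi-like stand-ins (the data file says so); the hydrogen
valence radial is the *free-atom* value ($\zeta = 2.0$ bohr$^{-1}$)
because the independent-atom reference must be a free atom — bonded-H
contraction enters only through $\kappa$.

# Scattering and refinement

Kinematical structure factors sum over the explicit operator list of
the space group: for operator $(R, t)$ the effective index is
$h' = hR$, which simultaneously drives the Debye–Waller tensor, the
local-frame direction and the phase $e^{2\pi i(h\cdot t + h'\cdot x)}$;
sites are weighted by multiplicity/|ops| so special positions are exact.
Electron structure factors apply Mott–Bethe per atom (with the full
atomic number), which preserves Friedel symmetry and keeps
centrosymmetric electron structure factors real.

Refinement minimizes $\sum w (y_o - y_c)^2$, $y = |F|$ or $|F|^2$, by
damped Gauss–Newton (Levenberg-style multiplicative damping on the
normal-matrix diagonal, factor 10 up on rejection, 10 down on
acceptance). Derivatives are numerical central differences with
per-parameter steps ($10^{-5}$ fractional for coordinates, $10^{-5}$ Å²
for ADPs, $10^{-4}$ for populations and kappas); the per-atom column
structure of the structure-factor matrix is cached so a one-parameter
perturbation recomputes only the affected atoms. Convergence is
max|shift|/esd < 0.01 with a 100-cycle cap; esds come from the inverse
normal matrix (optionally goodness-of-fit scaled; the default is
unscaled so that doubling all sigmas doubles esds). Special-position
constraints are derived automatically by averaging over the site
stabilizer, both for coordinate shifts and for the U tensor in Voigt
space; the refinement parameterization spans only the eigenvalue-one
subspace of that projector. Parameters with no leverage in a given
cycle (e.g. $\kappa'$ while all deformation populations are still zero
in a from-spherical fit) are frozen for that cycle rather than
inverting a singular normal matrix; a refinement in which *no*
parameter has leverage is an error naming the null parameters.
Anisotropic tensors may pass through non-positive-definite trial points;
trial steps are accepted or rejected on the residual, and validity is
enforced at the container level.

The weighting scheme is
$w = 1/[\sigma^2(F_o^2) + (aP)^2 + bP]$, $P = \max(0, F_o^2)/3 +
2F_c^2/3$. The automatic $(a, b)$ selection is a coarse grid search
(8 × 6 values) minimizing the max/min ratio of the mean weighted squared
residual across ten intensity bins — a documented stand-in for the host
programs' proprietary recipes. This scheme matters scientifically: with
unit weights on $|F|^2$ the enormous low-resolution electron structure
factors (amplified by the $1/s^2$ in Mott–Bethe for charged pseudoatoms)
dominate the fit and drive unphysical compensations; the damped weights
reproduce the well-behaved refinement regime.

Multipole-parameter fitting mirrors databank construction: coordinates,
ADPs and scale frozen, phases constrained to the supplied values (the
target is the signed projection $\mathrm{Re}[F_c e^{-i\varphi_{obs}}]$),
unit weights, optional freezing of $\kappa'$ at input values.

## Comparison statistics

ME is the mean signed deviation; RMSD is implemented as
$\sqrt{\mathrm{mean}(d^2)}$ — the root of the mean square. Published
table footnotes sometimes print the algebraically different
$\{\sum d^2\}^{1/2}/N$, which does not reproduce the tabulated values;
the square-root-of-mean convention does, and is what this package uses
everywhere. $U_{eq}$ is one third of the trace of the Cartesianized
tensor. Bond-length esds are propagated from the full coordinate
covariance of the refinement.

# Dynamical diffraction

The Bloch-wave solver diagonalizes the Hermitian matrix
$A = \mathrm{diag}(S_g) + U_{g-h}/2K$ with excitation errors
$S_g = (K^2 - |\mathbf k_0 + \mathbf g|^2)/2K$ and potential
coefficients $U_g = \gamma F_e(g)/\pi V$ (Å$^{-2}$); intensities are
$I_g(t) = |\sum_j C_{gj} C^*_{0j} e^{2\pi i \gamma_j t}|^2$ and sum to
one at every thickness (no absorption in this version — the paper-scale
treatment of an imaginary potential is not documented anywhere we could
verify, so the matrix stays Hermitian). The two-beam pendellösung
$I_g = (U_g/K s_{eff})^2 \sin^2(\pi t s_{eff})$,
$s_{eff} = \sqrt{S_g^2 + (U_g/K)^2}$, is used as an independent oracle;
note the prefactor reaches 1 at exact Bragg, which fixes the
normalization unambiguously.

$RS_g$ is computed numerically as $|S_g(\text{central})| / \max_\alpha
|S_g(\alpha)|$ over a 720-point azimuth grid of the precession cone —
the defining software's closed form is not public, and the numerical
definition is unambiguous and testable. Beam selection applies the
resolution, $|S_g| \le S_{max}$ and $RS_g \le RS_{max}$ cuts (defaults
0.56 Å, 0.02 Å$^{-1}$, 0.75), orders beams by $|g|$ then
lexicographically, and caps the matrix at 500 beams. Precession
averaging is a uniform azimuth mean with the eigenproblems cached per
azimuth, so thickness refinement (golden-section search per crystal,
closed-form per-frame amplitude scales) reuses them at no extra cost.

# Maps and fractal analysis

Residual maps are Fourier syntheses with coefficients
$(|F_o|/k - |F_c|)e^{i\varphi_c}$, expanded over the space-group
operators with $F(hR) = F(h)e^{-2\pi i h\cdot t}$, on an FFT-friendly
grid with spacing at most $d_{min}/3$. The conversion
$\varphi_h = 2\pi a_0 F_e(h)/V$ gives electrostatic potential in
e Å$^{-1}$. Extrema are refined by per-axis parabolic interpolation
(position and value). The fractal-dimension curve is
$d_f(\rho_0) = \ln N(\rho_0)/\ln N_{tot}^{1/3}$ with $N$ counted in a
window of fixed width (1/100 of the value range), so the sampling
density only resamples the curve; at the default 100 samples the
windows tile the range and the whole-map count gives $d_f = 3$ exactly.
Maps are computed over the measured set only (no zero-filling of
unmeasured reflections); both CIF-subset structure files and X-PLOR
ASCII maps are plain text.

# The synthetic generator

`fixture_structure()` is a hand-built planar N-methylated
pyrimidinedione in *Ibam* (a = 13.3, b = 13.7, c = 6.2 Å; plausible
literature-like values, not measured data). Every atom except the
out-of-plane methyl hydrogen H7b sits on the z = 0 mirror; the ring was
closed by a small angular least-squares fit to standard bond lengths,
X—H distances carry standard neutron values, and the molecule is placed
so that N3—H3···O4 forms a linear 1.85 Å hydrogen bond across an
in-plane inversion centre — the motif that makes the crystal-field
polarization experiments meaningful. ADPs are plausible 100 K values.

`fixture_multipoles()` provides three neutral, internally consistent
parameter tiers ("databank", "tailored", "crystal") that differ only in
deformation populations, with the largest differences deliberately on
the hydrogen-bond actors H3 and O4 (bond-directed dipoles): tier
comparisons then probe exactly the sensitivity to intermolecular
polarization. Populations, kappas and deformation radials are
databank-plausible a-priori choices (e.g. carbonyl carbons electron
depleted, oxygens enriched, $\kappa_H = 1.15$).

`simulate_reflections()` emulates incomplete coverage by an
orientation-cone exclusion around c* plus seeded random thinning to a
target completeness (default experiments use 63%), and Gaussian noise
on intensities with $\sigma = \max(\sigma_{floor}, c\,F^2)$ — Gaussian,
not Poisson, to match the least-squares assumptions (a Poisson switch
would be a one-line change and is deliberately not the default).
`simulate_frames()` produces precession-averaged dynamical frames (one
[001] zone-axis orientation plus off-zone tilts by default) with
per-frame scales and noise, and records an intensity-weighted
kinematical-deviation statistic per frame; zone-axis frames are the
most dynamical by this measure, as expected from many-beam coupling.
Every generator is a pure function of its arguments and seed.

What the generator does *not* emulate: detector point-spread and dose
effects, crystal mosaicity and bending (the dominant residual in real
dynamical refinements), DFT-level electron densities (the "theory" side
here is itself a multipole model), and anharmonic motion. Passing the
closure tests therefore demonstrates the correctness of the algorithms,
not the accuracy of any particular parameter databank on real crystals.

# Problem sizes

The shipped tests and the acceptance script run the fixture at
reduced resolution so the whole suite stays desk-scale: structural
recovery at $d_{min} = 1.05$ Å (~290 reflections, 71 parameters),
multipole recovery at 0.9 Å (~460 reflections, 95 parameters), bias
trends at 0.8 Å (640 reflections), dynamical frames at
$d_{min} = 1.2$ Å with up to ~150 beams and 16 precession azimuths.
These sizes were chosen once as the smallest configurations that leave
the closures sharply determined (tens of reflections per parameter).

# Known limitations

* No absorption (imaginary potential), extinction, twinning, disorder
  or anomalous scattering; shells shipped for H, C, N, O only
  (user-extensible via the data-file format).
* One shared $\kappa'$ per atom (the common databank practice); per-$l$
  untying is not implemented.
* The qualitative refinement-bias experiments reproduce the established
  electron-diffraction trends — IAM-refined X—H bonds too long (and,
  as a cross-check, too short for X-rays: the classic ED/XRD contrast),
  non-hydrogen $U_{eq}$ too small, model-tier R ordering, low-resolution
  concentration of tier differences — but **not** the reported positive
  bias of IAM hydrogen ADPs: under every plausible single-zeta
  parameterization of this generator the IAM-refined hydrogen ADPs come
  out slightly *smaller* than truth. That sign evidently depends on
  density features beyond a single-zeta Hansen–Coppens emulation
  (exact Hartree–Fock free-atom curves, DFT valence detail), and the
  corresponding acceptance test is left failing rather than tuned.
* The automatic $(a,b)$ weighting search is a documented stand-in for
  unpublished vendor algorithms; absolute $(a,b)$ values are not
  comparable across programs, only the flattened-residual property is.
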