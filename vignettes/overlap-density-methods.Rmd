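---
title: "Overlap densities and topological bond descriptors: models, numerics, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap densities and topological bond descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A closed-shell molecular-orbital wavefunction expands each occupied
orbital over atom-centered contracted Gaussians,
$\psi_l = \sum_i c_{li}\,\phi_i$, and the one-particle density
$\rho = \sum_l n_l \psi_l^2$ then splits exactly into one-center terms
(both basis functions on the same atom) and signed two-center terms.  For
a pair of disjoint atomic fragments $A$ and $B$ the two-center slice

$$\rho^{OP}_{AB}(\mathbf r) \;=\; 2 \sum_l n_l \sum_{i\in A}\sum_{j\in B}
c_{li} c_{lj}\, \phi_i(\mathbf r)\,\phi_j(\mathbf r), \qquad
\text{restricted to } \rho^{OP} > 0,$$

is the *overlap density* of the bond between the fragments: the part of
the density produced by constructive interference of the two fragments'
orbitals.  Where the interference is destructive the two-center term is
negative (it removes one-center density); the overlap model clamps those
regions to zero, and the clamp applies to the **total pair sum per
point** — not per orbital or per primitive — because the positivity
restriction is stated on the field itself.  `opdensity` computes three
families of descriptors from this field:

* $\rho^{OP}$ (electrons): the grid integral of the clamped field — how
  much density the two fragments share.  The *signed* (unclamped)
  integral equals the analytic Mulliken overlap population
  $2\sum_l n_l \sum_{i\in A, j\in B} c_{li}c_{lj}S_{ij}$, which the
  package computes independently from Gaussian product integrals; the
  agreement of the two routes (1e-4 on toys) is the built-in check that
  the grid resolves the pair products.
* $J^{intra}$ (eV): the Coulomb repulsion of the clamped field with
  itself, $\int\!\!\int \rho^{OP}(\mathbf r_1) r_{12}^{-1}
  \rho^{OP}(\mathbf r_2)\,d\mathbf r_1 d\mathbf r_2$ — larger when the
  same shared charge is more concentrated.
* Topological descriptors: the in-bond stationary point of the pair field
  (overlap critical point, OCP — a local maximum, all three Hessian
  curvatures negative) with its value $\rho_{OCP}$ and Laplacian, and the
  conventional QTAIM (3,−1) bond critical point (BCP) of the *total*
  density with $\rho_{BCP}$, $\nabla^2\rho_{BCP}$ and the local energy
  density $H_{BCP}$.

Because every basis function is attributed to its center atom
(Mulliken-style), the decomposition is basis-set dependent in the same way
Mulliken populations are; trends within one basis set are the meaningful
output.  All fragment-pair quantities are invariant under linear
transformations *within* an atom's function set, so spherical vs cartesian
shell representations of the same wavefunction give identical fields.

## Energy densities

The local kinetic energy density uses the positive-definite form
$G = \tfrac12\sum_l n_l |\nabla\psi_l|^2 \ge 0$.  The potential energy
density is *defined* by the local virial relation
$V = \tfrac14\nabla^2\rho - 2G$, and $H = G + V$.  The source material
never writes these formulas; they are the universal convention in BCP
analysis and make $H$ computable from density derivatives alone.  The
tabulated eV/a0³ values are hartree/a0³ × 27.211386245988 (verified on
the water monomer: −0.688 hartree/a0³ → −18.7 eV/a0³).

## Numerics

**Basis evaluation.**  Every basis function — a cartesian component or a
real solid-harmonic component with $\ell \le 4$ — is compiled into a sum
of primitive monomial Gaussians $c\,x^a y^b z^c e^{-\alpha r^2}$.
Derivatives of monomial Gaussians are monomial Gaussians, so values,
gradients and Hessians share one analytic code path (C++); finite
differences appear only in tests.  Contracted functions are renormalized
to unit self-overlap on load, which absorbs the differing primitive
normalization conventions of SCF engines.

**Whole-space grid.**  Becke fuzzy-cell quadrature: per atom a 75-point
Gauss–Chebyshev (second kind) radial rule mapped by
$r = R_{BS}(1+x)/(1-x)$ with Bragg–Slater radii (H: 0.35 Å), times a
spherical rule, with Becke's iterated cutoff polynomial ($k=3$) and
heteronuclear size adjustment.  The angular rule is a Gauss–Legendre
(cos θ) × uniform (φ) **product grid** whose polynomial degree matches
the requested standard angular count (302 → degree 29): octahedral
(Lebedev) node tables are not available in the offline toolchain, and
exact integration of spherical harmonics up to the rule's degree — the
property quadrature accuracy rests on — is shared by the product rule at
~1.5× the points.  Electron counts integrate to ~2×10⁻⁶ on the shipped
fixtures; the requested grid spec is recorded in every output's
provenance.

**Coulomb double sum.**  $J$ is evaluated on a uniform bond-box grid
(default 0.15 bohr spacing, 5 bohr padding — the overlap density of a
bond is localized between its atoms, and boundary leakage is checked and
warned about).  The double sum runs over cells with $\rho^{OP}$ above a
1e-7 e/a0³ floor (the neglected charge is reported; its contribution is
bounded well below the discretization error).  The $r_{12}=0$ diagonal is
modeled as the interaction of each cell's charge with itself spread over
a uniform cube: $\rho_k^2 w_k^{5/3} \times 1.88231$.  The full cube
constant is used — the ordered double integral carries no ½, which an
earlier draft convention suggested — and this choice was validated
against the closed-form Gaussian self-repulsion
$J = \sqrt{2\alpha/\pi}$: −0.30% at 0.2 bohr spacing, −0.17% at the
0.15 default, converging as $O(h^2)$.  The self-term fraction is logged
and warned above 0.6%.

**Critical-point search.**  Damped Newton–Raphson with a 0.3-bohr trust
radius, step halving while the gradient norm grows, convergence at
$|\nabla\rho| < 10^{-10}$, classification by Hessian eigenvalues with a
relative degeneracy threshold of $10^{-12}\,\max|\lambda|$.  Convergence
into a vanishing-field region ($\max|\lambda| < 10^{-8}$) is an error,
not a critical point.  A singular Hessian switches to gradient-norm
minimization (flagged).  The OCP search runs on the *signed* pair field —
the clamp has gradient discontinuities at its zero boundary — and a
converged point outside the positive basin fails loudly.

**Hydrogen-bond seeds.**  Along an H-bond the pair field has, besides the
in-bond OCP, a larger clamped bump where the donor hydrogen's tails meet
the acceptor core, with a saddle between them; a midpoint seed can
converge to that saddle.  Seeds are therefore placed at the midpoint
*and* at the 40/60 split toward the hydrogen, and the pipeline selects
the converged point with all-negative curvatures as the OCP.

## The fixtures: what they emulate and what they do not

Toy two-center wavefunctions (single-primitive s shells, exact
$[2(1\pm S)]^{-1/2}$ orbital normalization) have closed forms for every
quantity the package computes and are generated in code; they are the
primary oracle surface.  The DFT fixtures are genuine ωB97X-D/def2-TZVP
SCF solutions for the water monomer, water dimer, methanol⋯water and
dimethyl ether⋯water, regenerated by the shipped pyscf driver
(`inst/scripts/make_fixture.py`) and stored as compact Molden files with
virtual orbitals removed (the density, and hence every descriptor here,
uses occupied orbitals only).  The exchange–correlation part comes from
libxc's ωB97X-D; the functional's empirical dispersion affects only
geometries and is implemented in the driver (Chai–Head-Gordon damping,
Grimme D2 parameters, s6 = 1, a = 6).

Two caveats a green test does **not** discharge: (i) geometries carry a
cross-engine uncertainty of a few thousandths of an Å — tight
optimization reproduces the reference dimer H⋯O distance (1.937 vs
1.939 Å) and passive O–H bonds (0.957 Å), but the reference water-monomer
bond length (0.960 Å) is 0.0024 Å longer than this engine's optimum, so
the monomer descriptor comparisons are made at the tabulated bond length
(shipped as the constrained `h2o_r0960` fixture) and the bond-length
criterion itself is left failing by design; (ii) descriptor magnitudes
are basis-set dependent (Mulliken-like partitioning) and the fixtures
probe a single basis set.

## Design choices made where the design was open

* **Internal units** are atomic everywhere; Å and eV appear only in
  reporting (the descriptor table mixes Å, e, eV, e/a0³, e/a0⁵, eV/a0³).
* **Open-shell** input is represented as separate spin orbitals with
  their own occupations, summed in density construction; all shipped
  systems are closed-shell.
* **ℓ > 4** basis functions raise an explicit unsupported-feature error
  rather than truncating silently.
* **Donor/passive labels** encode chemistry the tool cannot infer; bond
  labels come from the caller's configuration.
* **Spherical vs cartesian sensitivity** (an open question in the
  interface contract): fragment-pair fields are provably invariant under
  within-atom basis transformations, so the choice cannot move the
  descriptors; the tests exercise both representations.

## Known limitations

No analytic (integral-based) $J$; no three-center terms; no σ/π channel
decomposition of the overlap density; no exhaustive critical-point
inventory (bond-seeded searches only, no ring/cage points or
Poincaré–Hopf audit); no QTAIM basin integration; geometry optimization
and SCF are delegated to the external driver.  The $J$ double sum is
$O(N^2)$ in positive grid cells and warns above 2×10⁵ points; the default
bond box keeps $N \sim 10^5$ (≈ minutes single-core per bond).
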