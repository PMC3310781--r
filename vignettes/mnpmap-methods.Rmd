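---
title: "Methods: simulating and inverting magnetomotive displacement"
author: "mnpmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and inverting magnetomotive displacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Superparamagnetic nanoparticles delivered to a tissue region can be pulled
by an external magnetic field gradient; the particles drag the surrounding
tissue with them, and the resulting micrometre-scale displacement is
measurable by ultrasound elastography. If the applied gradient is uniform
over the region of interest, the magnetic body-force density is
proportional to the local particle density, so a map of the force is a map
of the particle deposit. `mnpmap` simulates that whole chain: the coil
magnetostatics, the elastic response of a tissue-mimicking phantom, and
the inverse step that turns axial displacement back into a force /
density map.

# Coil model

Two coaxial loop pairs share one axis and center: a Helmholtz pair
(co-directed currents, spacing $d=a$) magnetizes the particles with a
maximally uniform field, and a Maxwell pair (opposed currents,
$d=\sqrt3\,a$) supplies a maximally linear axial gradient. On the axis the
fields are closed-form; at the optimal spacings the center values are

$$B_z(0)=\left(\tfrac45\right)^{3/2}\frac{\mu_0 n_1 I_1}{a}\approx
0.716\,\frac{\mu_0 n_1 I_1}{a},\qquad
\frac{dB_z}{dz}(0)=\frac{3\sqrt3/2}{(7/4)^{5/2}}\frac{\mu_0 n_2 I_2}{a^2}
\approx 0.641\,\frac{\mu_0 n_2 I_2}{a^2}.$$

Off axis, each loop's field is evaluated with the complete-elliptic-integral
closed form (elliptic integrals from `pracma::ellipke`); axial gradients
off axis use central differences of that field with step $10^{-5}a$, since
the closed-form derivative only covers the axis. The quadrature oracle in
the test suite (midpoint Biot–Savart line integration, $10^4$ segments)
pins both paths to $<10^{-5}$ relative error.

**Saturation handling.** The moment model switches at a single flux
threshold (default 0.4 T): below it the specific moment is $\chi H$
(mass susceptibility, m³/kg), above it the saturation magnetization
(default 20 A·m²/kg, the low end of the 20–40 A·m²/kg range typical of
iron-oxide particles). No interpolation between regimes is attempted —
the imaging scenario drives the particles well into saturation, and the
design calculators (`required_helmholtz_ampere_turns`,
`required_maxwell_ampere_turns`) assume it.

**Force uniformity over the imaging volume.** The imaging region is the
cube of side $2a/3$ at the center. `imaging_volume_uniformity()` reports
two views deliberately. The *gradient-only* view differentiates the
Maxwell pair alone — the design idealization in which the Helmholtz coil
is a pure magnetizer — and is flat to about 3% along the axis of the cube.
The *full-pair* view differentiates the superposed field of all four
loops; because the Helmholtz pair's own axial gradient vanishes only
exactly at the center and its excitation is typically 10× the Maxwell
excitation (to reach saturation), the full-pair force deviates strongly
toward the cube faces, and its axial profile is not even in $z$. The
report is descriptive; no acceptance threshold is attached, because none
is physically canonical. All center-point quantities — the coefficients
above and the force coefficient $12.8\,w\,\mu_0 n_2 I_2/a^2$ at
20 A·m²/kg — are unaffected, since the Helmholtz gradient is zero there.

# Phantoms

Phantoms are regular node-centered grids over a centered domain. The 2D
phantom (default 10 cm × 10 cm, 201 × 201 nodes, $h=0.5$ mm) carries one
or more circular inclusions; the 3D phantom (default
10 cm × 10 cm × 6 cm, 51 × 51 × 31 nodes, $h=2$ mm) a centered sphere of
diameter 5–40 mm. A node belongs to an inclusion iff its center lies
inside the analytic shape — deterministic, first-order convergent, and
the total applied force is exactly force density × rasterized measure by
construction. The force density is uniform on the mask and exactly zero
off it: the inclusions are the particle-laden regions, the background is
clean tissue.

Material defaults mimic normal breast tissue: $E=10$ kPa (experiments
sweep 5–30 kPa), $\nu=0.495$, $\rho=1000$ kg/m³ ($\rho$ is carried but
unused — the solve is static). Inclusions and background share the same
stiffness; the data model permits per-voxel stiffness but no experiment
uses it.

The 2D grid resolves the 5 mm inclusion with 10 nodes across. The 3D
default of $h=2$ mm is a deliberate resolution choice: it resolves the
10–40 mm spheres the total-force experiments use while keeping a
quarter-million-DOF iterative solve at single-core desk scale (about
three minutes); `grid_n` raises it when finer maps are wanted.

Optional axial measurement noise (`add_measurement_noise`) adds seeded
zero-mean Gaussian noise to $u_z$ only, emulating the ~10 µm-class
precision of elastographic tracking. It is off by default — the reference
maps are noise-free.

# Forward solver

The static Navier equation with axial body force,
$$G\nabla^2 u + \frac{G}{1-2\nu}\nabla(\nabla\!\cdot\!u) + F = 0,$$
is discretized in the grad-grad + div-div weak form with bilinear quads
(2D, plane strain — the natural idealization of a long cylindrical
inclusion) and trilinear hexes (3D). At $\nu=0.495$ the div-div
coefficient is $100G$ and plain displacement elements lock; the volumetric
term is therefore underintegrated with the one-point rule (selective
reduced integration). The `mixed_u_p` option requests a condensed
Q1–P0 displacement–pressure element instead; on rectangular cells the
elementwise constant-pressure projection of a (bi/tri)linear divergence
equals its center-point value, so both options produce the same element
matrix — the enum records intent, not a different scheme.

Loads are lumped (nodal force density × tributary volume). Boundary
conditions: `bottom_fixed` (default) clamps the face the $+z$ body force
pushes away from and leaves all other faces traction-free — the phantom
resting against its support; `all_fixed` clamps every boundary node.
Either set can carry prescribed displacement values via
`boundary_values`, which the validation experiment uses (below). The
boundary condition is recorded in every field's provenance tag.

2D systems are solved by sparse Cholesky (`Matrix`/CHOLMOD); 3D systems
by a matrix-free Jacobi-preconditioned conjugate-gradient solver in C++,
exploiting that the uniform material and grid make one 24 × 24 element
stiffness serve every element. Default relative-residual tolerance is
$10^{-8}$; the solver errors out (with the residual) rather than return
an unconverged field.

**Validation.** The 3D solver is checked against the Kelvin solution
integrated over a uniformly loaded ball, for which the center displacement
has the closed form $u_z(0)=fR^2(5-6\nu)/(12G(1-\nu))$ and the exterior
field is the equivalent point force plus an $R^2/5$ finite-size
correction. Comparing a finite fixed-boundary box against an
infinite-medium solution would bury the discretization error under a
domain-truncation error of the same order, so the oracle experiment
prescribes the exact exterior solution as Dirichlet data on the box
boundary: what remains is pure discretization error, and the test demands
center agreement within 10%. The closed forms themselves are cross-checked
in the suite against brute-force grid quadrature of the Kelvin kernel.
Two further properties guard the element technology: no volumetric
locking (the $\nu=0.495$ solution matches the $\nu=0.45$ solution after
analytic $\nu$-rescaling within 15%) and mesh convergence (peak 2D
displacement moves under 2% when $h$ is halved from the default).

**Linearity shortcuts.** The operator is linear, so
`calibrate_force_for_peak_strain` (one unit solve, exact rescale to the
target peak strain — 0.1% by default, the sweet spot of elastographic
strain estimation) and `total_force_for_peak_displacement` (unit solve,
rescale to 10 µm peak displacement, multiply by inclusion volume) need no
iteration.

# Inverse mapping

With the inertial term dropped, the force map is minus the elastic
operator applied to the measured displacement:
$$F = -G\nabla^2 u - \frac{G}{1-2\nu}\nabla(\nabla\!\cdot\!u).$$
`full_force_map()` evaluates the axial component of this; the
axial-only approximation `laplacian_force_map()` keeps
$F_z=-G(\partial^2_y+\partial^2_z)u_z$, the form available when only the
axial component is measured and the elevational derivative is dropped.
$G$ and $\nu$ are taken as known and uniform; estimating them is
elastography's job, not this package's.

Second derivatives are 3-point central stencils; the boundary ring is
flagged `NA` rather than one-sided (one-sided second differences amplify
noise and the maps of interest are interior-focused).

**The divergence term is evaluated through a pressure filter.** Forming
$\nabla(\nabla\!\cdot\!u)$ by nested nodal central differences is
formally consistent but practically disastrous near the incompressible
limit: the $1/(1-2\nu)=100\times$ prefactor amplifies any
short-wavelength noise in the discrete divergence, and displacement data
from near-incompressible solids carry exactly such noise (for this
package's own elements, the well-known checkerboard pressure modes of
underintegrated volumetric terms). Measured on the standard 2D phantom,
nodal differencing turns these into ringing of the order of the applied
force itself around the inclusion boundary. The implementation therefore
computes the pseudo-pressure $p=\frac{G}{1-2\nu}\nabla\!\cdot\!u$ at cell
centers (midpoint-averaged forward differences — where an element-constant
pressure lives), averages it onto nodes (the standard Q1–P0 checkerboard
filter), and applies the axial central difference to the filtered $p$.
With this path the full inversion reproduces the applied force map to
well under the 5%-interior / 2%-background consistency bounds the tests
assert.

**What the Laplacian-only map can and cannot recover.** Dropping the
divergence term costs real amplitude, not just boundary artifacts. In the
incompressible limit the pressure field of a uniformly loaded disc has a
uniform interior gradient of $f/2$ (the 2D depolarization factor), so the
Laplacian-only interior plateau sits near
$f\,[1-\tfrac{1}{2(2-2\nu)}]\approx 0.505f$ at $\nu=0.495$ in plane
strain (a sphere in 3D gives $2f/3$). The package's tests assert this
factor rather than pretend it away. Two things survive the bias and make
the map useful regardless: the *shape* of the normalized map still marks
the particle-laden region (with a broad halo overshoot around the
boundary), and the interior mean remains exactly proportional to the
applied force — the linearity sweep demands $R^2\ge0.999$ with relative
intercept under 1% — so relative quantification across regions or time
points is preserved.

**Halo metric.** No standard quantitative halo definition exists; the
package uses max $|F_z|$ over the background shell within two inclusion
radii of the mask centroid, divided by the mean $|F_z|$ of the
one-voxel-eroded interior. It is zero for perfect recovery, invariant
under map normalization, and on every tested phantom orders the methods
as the physics demands: full inversion below Laplacian-only.
`mean_intensity_in_mask()` erodes the mask by one voxel by default to
keep the boundary overshoot out of the "interior" average; the full-mask
mean is available with `erode = FALSE`.

`density_from_force()` closes the loop: under a uniform gradient,
dividing the force map by $dB_z/dz$ gives the effective magnetization
density, and dividing by the specific saturated moment gives particle
mass density — the precise sense in which force map and density map are
interchangeable.

# Experiments and reproducibility

`run_experiment()` drives seven scripted pipelines (`coefficients`,
`single_inclusion_maps`, `double_inclusion_maps`, `divergence_comparison`, `linearity_sweep`,
`total_force_sweep`, `coil_currents`). Every run resolves its parameter
set, executes deterministically under its seed, and (optionally)
serializes parameters (YAML), metrics, tables (CSV) and maps (MHD/PNG).
Choices worth noting:

* The linearity sweep uses five force levels at 0.5–1.5× the calibrated
  0.1%-strain force, keeping all levels inside the usable strain window.
* The double-inclusion phantom places the 10 mm and 5 mm discs
  symmetrically, 2.5 cm apart — the in-plane layout is not otherwise
  constrained, and the choice is recorded in the run's sidecar.
* The 3D total-force sweep defaults to a reduced 35 × 35 × 21 grid; it
  exists to exhibit scaling behavior (force ∝ E at fixed geometry; force
  growing roughly linearly with diameter at fixed peak displacement),
  and those curves are frozen as implementation-derived regression
  values, not treated as external truth.

# What the synthetic data does not emulate

The phantoms are the idealized study conditions: uniform force inside
sharp-edged inclusions, homogeneous isotropic linear elasticity, known
$G$ and $\nu$, noise-free displacement with all components available on a
regular grid. Real magnetomotive data differ in every respect: speckle
tracking yields the axial component only, with correlated noise;
stiffness is heterogeneous and imperfectly known; particle distributions
are diffuse. Passing this suite therefore demonstrates the correctness of
the operators and the internal consistency of the forward–inverse pair —
not field performance. The optional axial-noise injector and the
susceptibility regime are the hooks for degrading the data toward
realism.

# Degenerate inputs and numerical edges

* $\nu=0.5$ is rejected everywhere the $1/(1-2\nu)$ factor appears.
* An unconstrained solve (no fixed boundary) errors as singular rather
  than returning a rigid-body-polluted field.
* Normalization of an all-zero map, empty masks, a zero-weight load in
  the current calculator, and evaluation of the loop field on the wire
  itself all raise explicit errors.
* The CG solver reports iterations and relative residual in the field's
  provenance and refuses to return unconverged results.

# Known limitations

* The solver handles uniform stiffness only; heterogeneous maps would
  need per-element matrices (the data model, but not the solver, already
  permits them).
* The inverse step is direct differentiation, as the method prescribes —
  no regularization, so heavy measurement noise must be smoothed before
  inversion.
* Coil engineering (inductance, heating, vibration) and ultrasound RF /
  speckle-tracking simulation are out of scope; displacement is taken as
  given.
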