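---
title: "The geometric route to standard binding free energies: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The geometric route to standard binding free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(geomroute)
```

## The problem and the model

Association of a ligand with a macromolecular host — the motivating case is
a minor-groove binder docking into AT-rich double-stranded B-DNA — involves
a large loss of configurational entropy that equilibrium sampling cannot
resolve: the unbound guest explores a solvent volume and the full rotation
group, while the bound guest is confined to a narrow basin.  The geometric
route solves this by bookkeeping.  Harmonic restraints are imposed
*sequentially* in the bound state on the conformation (an RMSD coordinate,
$u_c$), orientation (ZYZ Euler angles $\Theta,\Phi,\Psi$ from an optimal
superposition, $u_o$) and position (polar angles $\theta,\varphi$ of the
guest centre of mass in the host frame, $u_a$); the fully restrained guest
is then pulled to a reference separation $r^*$ along a rectilinear path;
finally the restraints are released in the bulk, where the reorientation
cost is an analytic integral over $SO(3)$ and the translational release is
the standard-state term.  Writing $w(\xi)$ for the PMF along coordinate
$\xi$ sampled with the previously imposed restraints active, each
imposition step costs

$$\Delta G_{\mathrm{impose}} = -\tfrac{1}{\beta}\ln
  \frac{\int e^{-\beta(w(\xi)+u(\xi))}J(\xi)\,d\xi}
       {\int e^{-\beta w(\xi)}J(\xi)\,d\xi},$$

with $J=\sin\xi$ for the polar-type angles $\theta$ and $\Theta$ and $J=1$
otherwise.  The nine terms add to $\Delta G^\circ_{\mathrm{bind}}$ and
$K_{eq}C^\circ = e^{-\beta\Delta G^\circ_{\mathrm{bind}}}$ holds by
construction (asserted to $10^{-10}$ in the composer).  Site terms enter as
releases (negative of imposition), bulk terms as impositions, and the
separation contributes $-\tfrac1\beta\ln(S^*I^*C^\circ)$ with

$$I^* = \int_{\mathrm{site}} e^{-\beta w(r)}\,dr \quad (w(r^*)=0), \qquad
  S^* = r^{*2}\iint e^{-\beta u_a(\theta,\varphi)}\sin\theta\,
        d\theta\,d\varphi, \qquad C^\circ = 1/V^\circ .$$

$S^*$ and $I^*$ are evaluated exactly in this form; the separation PMF is
used as sampled (its plateau carries the geometric $-2k_BT\ln r$ slope,
which is what makes the result insensitive to extending $r^*$ — the
$r^{*2}$ growth of $S^*$ cancels against the re-anchoring of $w$).

Because the cycle is an exact telescoping product of configurational
integrals, the composed total is invariant to the restraint force constants
as long as they are used consistently on both sides; the package tests this
by doubling all force constants and comparing against twice the propagated
two-block error, and it verifies the telescoping identity itself to
$10^{-6}$ relative with a common Monte-Carlo sample set
(`keq_cycle_identity()`).

## Toy systems instead of all-atom MD

The artifact deliberately replaces the solvated all-atom complex with
bead-and-spring guests in analytic host fields (sums of Gaussian wells, a
quartic double well, a harmonic trap): the method under test —
restraint/PMF bookkeeping — is agnostic to the origin of the forces, and
toy systems admit a brute-force oracle.  The host is an infinitely heavy
external field, so the "host conformational" terms of the cycle are
exercised on the *guest's* internal coordinates instead: the reference
three-bead complex (`toy_complex()`) carries a stiff bonded triangle whose
fitted-RMSD restraint plays the role of the flexible host's conformational
restraint.  No solvent, electrostatics or periodic boundaries are present.
Consequently, passing tests demonstrate the correctness of the route's
estimators and bookkeeping, not the adequacy of any force field, sampling
time, or collective-variable choice for a real complex.

The toy study conditions are fixed once: well depth 6 kcal/mol per bead
(σ = 1.2 Å) displaced 4 Å from the host origin so that every angular
coordinate sits far from its poles; bonds of 300 kcal/(mol Å²); temperature
300 K; friction 5 ps⁻¹; time step 2 fs.  The per-stage sampling budgets
(4×10⁵ steps for conformational stages, 5×10⁵ per angular stage, 1.2×10⁶
for the separation over three windows) give a propagated two-block error of
roughly 0.15 kcal/mol on the composed total and finish in a few minutes on
one CPU; they are the package defaults and the sizes used by the tests and
the acceptance script (`steps_scale` rescales them).

## Sampling machinery

**Integrator.**  A BAOAB-ordered splitting of Langevin dynamics: half-kick,
half-drift, Ornstein–Uhlenbeck velocity refresh, half-drift, half-kick.
At zero friction it reduces to velocity Verlet (the energy-conservation
test exploits this); no step-size sanity check is attempted — a too-large
`dt` surfaces as drift or a NaN error carrying the step index.  Units are
Å, ps, amu and kcal/mol throughout, with
$k_B = 0.0019872041$ kcal/(mol K); angles cross every interface in degrees
(so angular force constants are kcal/(mol deg²)), radians internally.

**eABF.**  Each biased coordinate is shadowed by a fictitious particle
$\lambda$ coupled by $\tfrac12 k_c(\lambda-\xi)^2$.  The default coupling
is $k_c = 4k_BT/\delta^2$ for bin width $\delta$ (RMS mismatch of half a
bin) and the fictitious mass is set for a $\lambda$ oscillation period of
50 time steps.  The adaptive bias is minus the running mean coupling force
in the current $\lambda$ bin, ramped linearly until a bin holds
`n_full = 200` samples.  $\lambda$ reflects at the window boundaries;
full-circle azimuthal coordinates ($\varphi,\Phi,\Psi$, dihedrals) are
instead treated periodically — the coupling uses the minimum-image
difference and $\lambda$ wraps — because a harmonic spring across the
branch cut would exert unphysical 360°-scale forces.  Windows therefore
never span a discontinuity: stratification applies to bounded coordinates,
and full circles are sampled as one periodic window.

**Estimators.**  The $\lambda$ histogram alone estimates the PMF convolved
with the coupling Gaussian (variance $k_BT/k_c$).  The CZAR estimator
removes the convolution using the sampled distribution of the physical
coordinate,
$A'(z) = -k_BT\,\partial_z\ln\tilde\rho(z) + k_c(\langle\lambda\rangle_z - z)$,
with central differences on the log-histogram; it is the package default.
At the default stiff coupling the convolution width is half a bin and the
naive mean-force integral is an equally faithful but *less noisy* estimate
(no log-histogram differentiation); the toy protocol therefore uses the
naive estimator, and the test suite verifies both against closed forms and
checks explicitly that naive and CZAR coincide in the stiff-coupling limit
while the naive curvature is the Gaussian-convolution value at moderate
coupling.  For the polar-type angles the geometric $-k_BT\ln\sin\xi$ term
is removed from the profile at estimation time, so the restraint quadrature
applies $\sin\xi$ explicitly and exactly once.

**Mean forces, merging, errors.**  Accumulators are per-bin sums (counts,
coupling-force sums, conditional $\lambda$ offsets), so estimates are
invariant to the time ordering of samples.  Consecutive windows are merged
by integrating the concatenated per-bin mean force (mean-force continuity
at the seams), then re-anchored to min = 0.  Every run keeps two
equal-time-block copies of its accumulators; a derived quantity's error is
half the absolute difference of its two block recomputations (generalized
to the standard error over blocks for more than two), and composed errors
add in quadrature, treating terms as independent.

## Numerical choices

* Quadrature over binned profiles is the midpoint rule on bin centres
  (every bin carries its full width); restraint quadrature refuses to
  proceed when the restrained integrand leaves more than $10^{-6}$ of its
  mass in the outermost bins, except at *closed* edges (RMSD = 0, periodic
  wraps) which are natural boundaries.
* Analytic one-dimensional integrals (bulk orientation, $S^*$) use adaptive
  quadrature to $10^{-10}$ relative.
* The ZYZ Euler convention is fixed and verified by a 500-rotation
  round-trip property; at gimbal lock ($\Theta = 0$ or $180^\circ$) only
  $\Phi\pm\Psi$ is defined and the convention $\Phi = 0$ is returned with a
  degeneracy flag rather than an error — degenerate geometries inside a
  trajectory must not abort it.  The same flag policy applies to the
  on-axis azimuth and to coincident points in the separation coordinate.
* The best-fit rotation is the quaternion (Horn) construction — therefore
  always a proper rotation, even for planar or reflection-contaminated
  inputs — diagonalized by a dedicated 4×4 Jacobi sweep; its gradient uses
  first-order eigenvector perturbation and is verified against central
  finite differences to $10^{-6}$, as is every other collective-variable
  gradient and force routine.
* "Distance RMSD" is ambiguous between a fitted RMSD and a
  distance-matrix RMSD; both are implemented, and the fitted form is the
  default restraint coordinate because rigid-body motion is already
  handled by the five angular coordinates — the conformational restraint
  should suppress internal deformation only.
* The bound basin for $I^*$ defaults to the contiguous region around the
  global minimum up to the highest intervening point toward $r^*$;
  profiles with a second pronounced minimum (e.g. a non-native
  electrostatically bound pose along the separation path) require an
  explicit interval, and the toy protocol passes its site boundary (7 Å)
  explicitly.  During the bound-state stages the site is bounded by a
  flat-bottom radial wall at the same radius; the wall sits ~10 kcal/mol
  above the basin floor, so the exponential weights make the difference
  between the smooth wall and the oracle's sharp site indicator negligible
  (relative weight below $10^{-7}$).
* The standard volume is $V^\circ = 1661$ Å³ (the 1 M number density
  $1/1661$ Å⁻³), configurable everywhere.
* Tie-breaking in conformer classification: a frame matching several modes
  goes to the nearest by max-coordinate periodic distance, with exact ties
  resolved by declaration order.

## Open parameters decided here

The simulation temperature is nowhere fixed by the method; 300 K is the
package default and every function takes a `thermo_state`.  The eABF
unbiasing estimator is likewise not prescribed; CZAR is the default with
the naive integral retained for the stiff-coupling regime (see above).
Restraint force constants default to 0.1 kcal/(mol deg²) for angles and
100 kcal/(mol Å²) for RMSD, and bin widths to 1° (angles), 0.05 Å (RMSD)
and 0.1 Å (separation) — the conventional working values for this protocol
family; the composed result must be, and is tested to be, independent of
the former.

## The dihedral-series generator

`generate_dihedral_series()` emulates a ligand exchanging rapidly between
conformers characterized by two scaffold dihedrals: a wrapped-Gaussian
mixture on the torus $(-180,180]^2$ plus a stated fraction of transition
frames.  Transition frames are drawn uniformly *outside* every mode's
classification box (at the 45° threshold by default): transitions are by
definition structures belonging to no conformer, and without the exclusion
roughly 44% of uniform draws would land inside a conformer box, making the
generating fractions unrecoverable by any threshold classifier.  The
generator reproduces mode weights and the transition fraction within
binomial error at $n = 5000$ frames (tested), but it does not emulate the
time correlation, the anisotropic mode shapes, or the sparsely populated
inter-mode ridges of a real trajectory — population recovery says nothing
about kinetics.  Mode centres may be auto-detected from the periodic 2D
histogram (`detect_modes()`): local maxima over a 3×3 periodic
neighbourhood, mass-weighted sub-bin refinement, merge radius 60°, and a
max/mean contrast requirement of 3 that rejects near-uniform series.

## Known limitations

* The oracle's exhaustive quadrature covers single-bead systems; the
  three-bead $K_{eq}$ uses seeded importance sampling (closed-form smeared
  shell and mixture proposals) and reports a delta-method standard error —
  deterministic given the seed, but a Monte-Carlo estimate nonetheless
  (~0.035 kcal/mol at 2×10⁶ samples for the reference toy).
* Harmonic restraints on azimuthal coordinates use minimum-image
  differences; centres should still be placed away from the branch cut,
  since the matching analytic integrals run over $(-180,180]$ around the
  centre.
* The square-well host is discontinuous and exists for quadrature checks
  only; it exerts no force and must not be used for dynamics.
* Angular eABF windows avoid the polar singularities by sampling
  $[10°,170°]$; the truncated $\sin\xi$ mass (<1%) biases the site terms
  by under 0.01 kcal/mol, far below the statistical error.
* Error propagation treats the nine terms as independent, which is exact
  here because every stage is an independent simulation.
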