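---
title: "Methods: GP force fields over atomic local frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GP force fields over atomic local frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the model, the numerical choices and the design
decisions behind `gprff`, in the spirit of a methods section: what is
computed, under which assumptions, and what the built-in validation does
and does not demonstrate.

## The force-field architecture

The package implements a force field in which machine-learned atomic
properties replace the bonded and intramolecular electrostatic terms of a
classical force field. Three ingredients combine:

1. **Per-atom Gaussian process models.** Each atom of a (monomer)
   topology owns one GP per property: its atomic energy, and each of the
   25 real spherical-tensor moment components Q_lm, l = 0..4. All models
   of one system share a training set of geometries ("per-system"
   training); the targets differ per atom.
2. **Intermolecular electrostatics** from the predicted multipoles, after
   rotation from each atom's local frame to the lab frame, summed over
   atom pairs in different molecules within a cutoff.
3. **Lennard-Jones** dispersion/repulsion with Lorentz–Berthelot
   combining, because monomeric models know nothing about exchange
   repulsion or dispersion between molecules.

Intramolecular electrostatics never appear explicitly: they are part of
the learned atomic energies.

## Featurization: atomic local frames

For atom A, two frame atoms are picked by priority — atomic number
descending, then extended connectivity (sum of the neighbours' atomic
numbers) descending, then atom index ascending. Full stereochemical
priority rules would add nothing for the small molecules this package
targets, and the index tie-break makes assignment deterministic;
symmetry-equivalent frame atoms (e.g. the two hydrogens of water) are
therefore ordered by index. Neighbours are atoms within 1.2 × the sum of
covalent radii, falling back to nearest atoms when an atom has fewer than
two bonded neighbours.

The 3N − 6 features are the two frame-atom distances, the frame angle,
and spherical coordinates (r, θ, φ) of every remaining atom in the frame.
The azimuth φ is measured from the x-axis in (−π, π] with the z-axis from
right-handed completion. Every third feature slot is flagged cyclic;
this includes the valence-angle slot, whose differences never exceed π,
so wrapping is the identity there and the flag is harmless.

Frames degenerate when the three frame atoms are collinear; construction
is rejected when |sin ∠(A_x, A, A_xy)| < 1e-6.

The feature Jacobian ∂f_k^A/∂α_i^B — needed to turn energy-model
gradients into forces, since atom A's features exert forces on every atom
they depend on — is computed analytically by forward-mode differentiation
through the frame construction, and is tested against central finite
differences (step 1e-6 Å, agreement to 1e-5 relative).

## The GP core

The kernel is an anisotropic RBF, `exp(-Σ_k θ_k d_k²)`, with the shortest
arc wrapped difference on cyclic slots — the minimal modification making
the kernel 2π-periodic there. One caveat is documented deliberately: the
wrapped-difference RBF is not positive definite for point sets blanketing
the whole circle. For molecular azimuths, which occupy clustered arcs,
Gram matrices are numerically PSD; if a covariance cannot be factorized
even after nugget escalation (δ from 1e-10 ×10 up to 1e-6), fitting stops
with an instruction to raise δ rather than silently regularizing.

The mean is fixed to the arithmetic mean of the targets, and the signal
variance is concentrated out analytically, leaving a profile
log-likelihood over θ alone:
`-n/2 log(σ̂²) - ½ log|R|`, `σ̂² = ỹᵀR⁻¹ỹ/n`. Hyperparameters are found
by multi-start (default 8) bounded L-BFGS-B on log θ, θ ∈ [1e-4, 1e3] in
feature-reciprocal units, with the analytic gradient. One start uses a
median-distance heuristic; the rest are uniform in log space.

Two numerical decisions deserve note:

* **Degenerate targets.** For constant y the concentrated variance
  underflows; the likelihood then returns a fixed constant so the surface
  is flat in θ rather than spuriously structured.
* **Degenerate likelihood shoulder.** On small, very smooth datasets the
  profile likelihood can develop a local maximum in a near-singular
  corner (θ → 0) where the model stops interpolating its own training
  data. Restart solutions within 2 log-likelihood units of the best are
  therefore screened for interpolation (residual δ·max|a| within
  max(1e-6, 10 δ‖y − μ‖)), and the best interpolating solution is
  preferred. A clearly better likelihood is never overridden.

The posterior variance `σ̂²(1 + δ − k*ᵀR⁻¹k*)` drives active learning.

## Training pipeline

A sampled pool splits into an initial training set of 36 points — the
per-feature minimum, maximum and nearest-to-mean geometries of a
reference atom (the first heavy atom), deduplicated and padded with
seeded random picks — a fixed validation set (default 500), and the
remaining sample pool. Each iteration fits the per-atom energy models,
records median and maximum validation error of the molecular (summed)
energy, and moves the `batch` pool points with the highest total posterior
variance into the training set. Hyperparameters are refit every
`refit_every` iterations (default every iteration), with weights-only
refreshes in between; the final model always gets a full refit. The
recovery harness refits at the start and the final size only — an
efficiency choice that leaves the sampling criterion untouched.

## Electrostatics

Moments follow the Racah-normalized real solid harmonic convention
(R_00 = 1, R_10 = z, R_11 = x, R_20 = (3z² − r²)/2, ...), in e·Åˡ. The
interaction tensor between components (l₁m₁) and (l₂m₂) is generated, not
transcribed: the regular solid harmonics are recovered as exact
polynomials (fitting the associated-Legendre spherical formula against
the homogeneous monomial basis), the potential of a unit multipole is the
irregular harmonic I_lm = R_lm/r^(2l+1), and applying the differential
operator R_{l₂m₂}(∇) — exact differentiation in the ring of
polynomial·r⁻ⁿ terms, normalized by the Fischer self-product
[R_lm(∇)R_lm](0) — yields every tensor at once. Correctness rests on the
test suite's independent oracle: point-charge arrays constrained to carry
a single pure moment each, whose Coulomb energies match the tensors to
0.1% at 10 Å, plus exact R^−(l₁+l₂+1) decay exponents. Rank-l rotation
(Wigner) matrices are likewise solved numerically from R_lm(Rot·s) in the
R_lm' basis, with a closed-form fast path at rank 1.

Truncation is **square**: a simulation at rank L′ includes *all* pairs
with l_A ≤ L′ and l_B ≤ L′, not the triangular l_A + l_B + 1 rule — so
L′ = 3 carries the octupole–octupole term. The Coulomb constant is
1389.35457 kJ·Å/(mol·e²); dipoles convert at 4.8032047 D per e·Å.

Summation is direct-space within a cutoff (12 Å default) in a large
non-periodic region (50 Å nominal box). No Ewald machinery is used: with
molecules a few Å apart and a 12 Å cutoff the real-space sum carries
essentially the full interaction, and periodic boundary effects are out
of scope.

## Simulation and the zero-Kelvin optimizer

`total_energy()` decomposes into per-molecule intramolecular energy
(GP-predicted in flexible mode; frozen in static mode, where local-frame
moments ride on the current frames — rigid multipoles without rigid-body
constraints), intermolecular multipole energy, and LJ. Forces are
analytic for the intramolecular part (chain rule through the kernel
gradient and feature Jacobian) and for LJ; the intermolecular multipole
force uses central finite differences (step 1e-5 Å) of the electrostatic
term including the geometry dependence of the predicted moments —
analytic gradients of rank-4 interaction tensors are high-risk
transcription, and the total force is independently verified against
finite differences of the total energy (relative 1e-4).

The optimizer is quasi-static MD: velocity-Verlet at 1 fs, then per atom
the velocity is zeroed if it opposes the current force and capped at the
10 K Maxwell–Boltzmann mean speed for its mass. (Whether a reference
implementation caps at the mean or most-probable speed is not specified
anywhere we could verify; the contract tested is monotone descent and the
closed-form two-particle LJ minimum, not a bit-match.) A thermostat would
be inert at this velocity-capped quasi-static limit and is omitted.
Convergence requires both: |E_N − E_{N−w}| / w ≤ 1e-4 kJ/mol per step,
and the RMSE of the window's energies about the straight line joining its
endpoints — sum of squared deviations over the window divided by w,
square-rooted — below 0.1 kJ/mol (window w = 1000 steps by default). The
optimized structure is the final step.

## The synthetic surrogate

The surrogate stands in for the quantum-chemistry stage so that the whole
pipeline is testable analytically. It is a formamide-like 6-atom molecule
(C central; 3N − 6 = 12 features) with Morse bonds, harmonic angles and
twofold cosine torsions, built so the equilibrium geometry and minimum
energy (zero) are known in closed form. Bond parameters (D_e 430–750
kJ/mol, a 1.8–2.2 Å⁻¹, r_e 1.01–1.36 Å) and force constants are chosen as
typical covalent magnitudes. Per-atom energies split each term equally
among its participants — arbitrary, but any smooth partition summing to
the total serves the pipeline. Charges come from electronegativity
equalization (smooth in geometry, summing exactly to zero; parameters
tuned once to give ±0.04–0.16 e). Atomic dipoles are bond-dipole vectors
rotated into each atom's ALF; quadrupoles and higher are small smooth
functions of the first two features. Everything is C¹ in coordinates and
rotation/translation covariant by construction.

`sample_pool()` emulates a room-temperature classical trajectory with
seeded Gaussian Cartesian distortions (0.04 Å per coordinate at
`temperature_scale = 1`) composed with random rigid motions, so
frame-invariance of the featurization is exercised by the data itself.
What the surrogate does **not** emulate: anharmonic mode coupling beyond
the chosen functional forms, charge transfer between molecules,
conformational transitions, and the error structure of real
electronic-structure data. Passing the recovery test therefore
demonstrates that the pipeline's machinery is correct and internally
consistent — not that a 400-point model reaches any particular accuracy
on real wavefunction data.

## Problem sizes and defaults

The shipped configuration trains on pools of 1500 geometries, 500-point
validation sets and 400-point final training sets with batches of 91
(initial 36 plus four adaptive rounds), 4 optimizer restarts — sizes at
which a full desk-scale run (training, optimization, dipole check)
completes in minutes while leaving the adaptive-sampling loop, the
validation analytics and the optimizer genuinely exercised. Production
use of this architecture would push the training set to the low
thousands and the sample pool to 10⁵; nothing in the code limits those
sizes.

With seed 1 the recovery harness reproduces the surrogate's equilibrium
bond lengths to 9e-4 Å, its molecular dipole to 5e-4 %, and yields a
validation S-curve with a 0.09 kJ/mol median molecular-energy error —
the desk-scale analogue of monomer validation against an electronic-
structure reference.

## Known limitations

* Wrapped-difference cyclic kernels are indefinite for full-circle
  azimuth spreads (see above); fitting errors out rather than silently
  regularizing.
* Intermolecular multipole forces are finite-difference, costing
  6N energy evaluations per force call; fine for dimers and the
  optimizer's step counts, slow for large assemblies.
* Static mode freezes moments in local frames but imposes no rigid-body
  constraint on the intramolecular geometry; comparisons with flexible
  mode are meaningful at the level of intermolecular geometry.
* Per-atom (as opposed to per-system) training sets, periodic boundary
  conditions/Ewald summation, and finite-temperature production MD are
  out of scope.
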