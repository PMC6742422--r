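---
title: "Mechanics of tubulin interfaces: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of tubulin interfaces: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tubemech)
```

# Scope

Microtubules are hollow polymers of αβ-tubulin heterodimers, usually 13
protofilaments wide, whose intermittent growth and shrinkage (dynamic
instability) is coupled to GTP hydrolysis on β-tubulin. A mechanistic
question behind much of microtubule biophysics is how the nucleotide
state changes the *shape* and the *mechanics* of the two kinds of
longitudinal contacts in a protofilament: the intra-dimer interface
(α–β within one dimer) and the inter-dimer interface (β–α between
successive dimers, which holds the exchangeable nucleotide site).

`tubemech` implements the analysis layer for that question:

1. a three-angle decomposition of the relative orientation of adjacent
   monomers, expressed in a microtubule-bound coordinate frame;
2. harmonic stiffness estimation for those angles from equilibrium
   fluctuations via the equipartition theorem;
3. essential-dynamics PCA of coordinate trajectories;
4. heterogeneous elastic-network models (ENM): construction, spring
   parametrization against pair-distance fluctuations, normal modes, and
   conversion of mode frequencies to beam-theory rigidities;
5. contact counting and nucleotide-based compaction metrics;
6. a synthetic-trajectory generator that produces every input with known
   ground truth, so each stage has a closed-loop test.

Running molecular dynamics itself is out of scope: the package analyzes
whatever trajectories it is given (multi-model PDB or DCD), and its own
studies run on the synthetic generator.

# The microtubule-bound frame and the angle decomposition

Every subunit site of a straight wall fragment carries an orthonormal
triad: **z** along the microtubule axis, **x** radial, **y** = **z** ×
**x** tangential. Internally **x** points *outward*, from the axis
toward the subunit; plotting functions flip the radial sign so that
"toward the axis" is positive, matching the usual presentation of
bending scatter plots. When the axis is not declared it is fit as the
least-squares cylinder axis through the subunit centroids
(`fit_cylinder_axis()`), initialized from all three principal axes of
the centroid cloud and refined by quasi-Newton iterations, which makes
the fit equivariant under rigid motion of the input.

For a monomer pair, the minus-end-proximal ("lower") monomer is
superposed onto its wall site (Kabsch, proper rotation enforced) and the
site triad is carried along; a second wall copy is aligned onto the
upper monomer, giving the triad **X**, **Y**, **Z**. The relative
rotation is decomposed as:

* bend magnitude θ = arccos(**z**·**Z**) ∈ [0°, 90°] in practice;
* bend direction φ = atan2(**Z**·**y**, **Z**·**x**) ∈ (−180°, 180°],
  so a strictly outward radial tilt has φ = 0;
* twist δ: the lower triad is rotated by θ about **P** = **z** × **Z**
  (Rodrigues), producing the auxiliary axis **x**′, and
  δ = arccos(**x**′·**X**) with the sign of the triple product
  det[**x**′, **X**, **Z**].

Two conventions were genuinely open and were fixed once:

* **The closed form of the φ equation.** The typeset source of the
  direction-angle formula is ambiguous, so φ is implemented from its
  stated contract (radial outward ⇒ φ = 0; signed azimuth) with the
  two-argument arctangent. The remaining freedom is the sign of the
  tangential direction; we take φ > 0 toward +**y**, i.e. right-handed
  about the axis. Validating the sign against deposited tubulin–MAP
  structures requires the corresponding PDB entries, which the package
  does not ship; `published_structure_angles()` performs that
  comparison when the files are supplied locally.
* **Degeneracy at θ ≈ 0.** The bend direction is undefined for an
  unbent interface; below 10⁻⁶ degrees φ is reported as 0 and the frame
  is flagged (`degenerate`). If ‖**z** × **Z**‖ < 10⁻¹², the auxiliary
  rotation is the identity.

The decomposition is verified three independent ways: an exact inverse
(`compose_interface_rotation()`, round trip < 10⁻⁸ degrees over 1000
random triples through the full superposition pipeline), a quaternion
swing–twist oracle written separately in the test suite, and invariance
properties (θ invariant under common rotations, δ antisymmetric under
twist reversal).

# Equipartition stiffness

At thermal equilibrium a harmonic angular degree of freedom satisfies
κ = k\_BT/σ², with σ² the variance of the angle in rad². Stiffness is
reported in thermal units (kBT/rad², numerically 1/σ²) and in J/rad².
Choices:

* **Window.** The estimator assumes equilibrated sampling; by default
  the second half of each run is used (the 500 ns cutoff of
  microsecond-scale runs scales to half-span for shorter synthetic
  series).
* **Pooling.** Variance is taken about the pooled mean of all runs
  (per-run centering is available via `per_run = TRUE`), with the 1/n
  normalization so pooling duplicated runs is exactly idempotent.
* **Uncertainty.** A block bootstrap over runs (1000 resamples, seeded).
  This is a reconstruction choice; it is not claimed to be how any
  particular published ± was obtained.
* **Circular data.** Fluctuations are far below 180°, so no circular
  correction is applied, but series near the ±180° branch (typical for
  the bend *direction* of weakly bent interfaces) are unwrapped about
  their circular mean before the variance.
* **Convergence.** `convergence_report()` splits the window into four
  equal blocks (the 4 × 125 ns convention) and reports per-block
  summaries plus a drift statistic, max |block mean − global mean| /
  SD.

The synthetic generator samples θ directly from a Gaussian of variance
1/κ\_θ (folded at zero) and the direction φ with the matched small-angle
SD σ\_θ/θ₀. An alternative parametrization samples the planar coordinate
(θ cos φ, θ sin φ) from an isotropic Gaussian; it avoids folding
entirely but gives the θ *magnitude* a Rice-type variance deficit of
order (σ/θ₀)²/4, about 6% at the softest condition studied (θ₀/σ ≈ 3).
Because the package's stiffness estimator operates on θ itself, the
angular parametrization is the default: its folding correction is below
0.5% at all study conditions, an order of magnitude smaller than the
planar bias. Both modes are exposed (`sampling =` "angular"/"planar").

Study conditions pair each stiffness with the equilibrium conformation
it was observed with (κ ∈ {350, 930, 1100, 1290} kBT/rad² with θ₀ ∈
{9.1, 9.4, 8.2, 5.2}° respectively); at n = 10⁵ frames the end-to-end
pipeline (generate → superpose → decompose → window → variance → κ)
recovers each κ within 3% (sampling SE of a variance at that n is
≈0.45%).

# Essential dynamics (PCA)

The bead model keeps one bead per retained Cα (superposition-core
residues: flexible loops and the last 10 C-terminal residues are
excluded by default, both overridable) and a coarse-grained nucleotide:
one bead per guanine ring, ribose, each phosphate group, and magnesium
when present, with bead masses equal to the summed atomic masses. GDP
yields one fewer phosphate bead and no Mg bead.

Frames are superposed onto a common reference (default: the first
frame) before the covariance C\_ij = ⟨(x\_i − ⟨x\_i⟩)(x\_j − ⟨x\_j⟩)⟩ is
built. The ⟨…⟩ average uses the 1/n normalization (switchable to n−1);
coordinates enter unweighted (a mass-weighting flag exists on the
alignment). Eigenvectors get a deterministic sign (largest-magnitude
component positive); eigenvalue ties within 10⁻¹⁰ × trace are flagged
as degenerate, and recovery claims are made for *subspaces* (cumulative
squared overlaps), never for individual vectors inside a degenerate
block. Projection variances reproduce the eigenvalues identically on the
data the PCA came from — this spectral identity is asserted to 10⁻⁸ in
the tests.

On ensembles sampled from a known ENM's Gaussian, the top-3 PC subspace
overlaps the three softest normal modes with cumulative squared overlap
> 0.99 at 2 × 10⁴ frames, which is the package's stand-in for the
"leading PCs describe most of the variance" behavior of real
trajectories. Published variance-explained percentages from
microsecond simulations are *not* reproduction targets: those
trajectories are not available, and the synthetic ensembles make no
attempt to mimic their anharmonicity.

# Heterogeneous elastic networks and beam theory

`build_network()` connects bead pairs closer than R\_cutoff = 0.8 nm
with harmonic springs at their current separations (the network is
built on a straight reference conformation). The Hessian is the
standard pairwise-spring block form; mass-weighting (masses in kg) makes
its eigenvalues squared angular frequencies, ω\_n = √λ\_n. Six
rigid-body modes are removed by a relative threshold of 10⁻⁸ × the
largest eigenvalue. All spring constants are in N/m and all beam
quantities in SI; Ångström inputs are converted explicitly.

**Parametrization.** Spring constants are fitted to pair-distance
fluctuations: initialization by Boltzmann inversion
(k\_ij = k\_BT/var d\_ij), then multiplicative updates
k ← k (var\_model/var\_target)^α with α = 0.5 until the maximum
relative deviation of predicted variances falls below 10⁻³ (both
configurable); springs whose target variance is ≈0 are pinned at a
configured maximum. Two details matter and are deliberate:

* **The model-side variance is computed exactly, not linearized.** For
  a bonded pair the relative displacement is Gaussian with a 3 × 3
  covariance S; E[d²] = |r₀|² + tr S is closed-form and E[d] is
  evaluated by Gauss–Hermite quadrature in the eigenframe of S (12³
  points, cached). A bond-parallel linearization has an exact but
  misleading property: for any network whose bond vectors are linearly
  independent, the linearized variances equal k\_BT/k\_ij *identically*,
  so Boltzmann inversion is a fixed point no matter how large the
  transverse fluctuations are, and fitting against sampled distance
  variances (which do contain the transverse contribution) converges to
  the wrong constants. The exact prediction compares like with like and
  restores the generate → fit closure.
* **Recovery error is sampling-noise-limited and redundancy-amplified.**
  The variance of a sampled variance is ≈ σ⁴·2/n; the inverse map from
  pair variances to spring constants amplifies that noise by a factor
  of ~2–3 when springs are redundant (more springs than internal
  degrees of freedom). At the study size (10-bead helical chain, 42
  springs, n = 2 × 10⁴ frames) the max-norm recovery error across
  springs is typically 4–10% with a median near 1–2%. The
  self-consistency property — the generating constants are a fixed
  point of the iteration — is therefore asserted against the ensemble's
  exact Gaussian pair variances (the n → ∞ limit of the targets), where
  the drift is < 2%.

The 10-bead "chain" fixture is a helix (rise 1 Å, 0.7 rad per bead,
radius 2.8 Å) rather than a straight line: a line of beads with pair
springs has no transverse stiffness at all, and even a sparse helix
connected only to nearest and next-nearest neighbors keeps soft
dihedral-like zero modes. The chosen geometry is generically rigid
(exactly 6 zero modes) and moderately over-constrained, which is the
regime where real Cα-level ENMs operate.

**Beam mapping.** A bending mode of frequency ω maps to a flexural
rigidity K\_bend = ρ\_l ω²/k⁴ and a torsional mode to
K\_twist = ρ\_v I ω²/k², with defaults ρ\_l = 1.95 × 10⁻¹⁴ kg/m,
ρ\_v = 1.3 × 10³ kg/m³, I = 3.42 × 10⁻³⁵ m⁴ (tubulin-filament values).
Wavenumbers assume a freely vibrating filament: bending kL ∈ {4.7300,
7.8532, …} (roots of cos kL cosh kL = 1) and torsion k = nπ/L; the
boundary-condition tag is explicit and the mode order must be supplied.
The filament length L is measured as the axial extent of the bead
model. Published absolute rigidities of tubulin tetramers are not
desk-reproducible (they require the original trajectories); the package
asserts the formulas (round trip through frequency exact to 10⁻⁶), the
qualitative ordering (softer inter-block springs ⇒ lower K), and a
continuum-limit check: for a discretized rod (4-strand square truss, 30
rings — slender enough that shear and rotary-inertia corrections fall
below 10%) the rigidity inferred from the first bending-mode frequency
agrees with the static cantilever rigidity F L³/(3δ) of the same
network to better than 10%. Statics and dynamics are independent routes
through continuum beam theory, which is what makes this a genuine
cross-check. A single-strand rod cannot serve here: with pair springs
only, it has no flexural rigidity.

**Mode classification** projects each mode onto ideal beam fields about
the filament axis — free-free Euler–Bernoulli bending shapes (two
orders, two transverse directions) and torsional fields (tangential
displacement with cos(nπs) axial profiles) — and labels the mode by the
dominant squared-projection fraction when it exceeds 0.6, else "other".
`beam_stiffness()` refuses "other" modes, since neither formula applies
to a mixed field.

# Contacts and compaction

A contact is a residue pair, one residue from each of two disjoint
selections, whose Cα–Cα distance is *strictly* below 8 Å. Counting is
done with a cell-list neighbor search validated against an all-pairs
double loop on 1000 random configurations (identical counts, exact
threshold behavior at 7.99/8.00/8.01 Å). Series over trajectories flag
lateral-bond rupture as the first frame at which the count reaches zero
and stays zero for a dwell of 10 sampled frames (configurable; rupture
is described only qualitatively in the literature, so the dwell is a
package choice to suppress single-frame flickers).

Compaction is the distance between the mass-weighted centers of the
ribose rings of the nucleotides in adjacent subunits. The ring atom set
is C1′, C2′, C3′, C4′, O4′ (configurable), chosen as the five-membered
furanose ring proper; missing atoms are reported by name. By the
analysis convention only the minus-end-proximal intra-dimer interface
of a tetramer is summarized, because plus-end nucleotides are more
mobile.

# The synthetic generator: what it does and does not emulate

The generator produces (i) idealized 13-protofilament wall fragments on
a 3-start helix (radius 12.5 nm; axial rise 4.2 nm per monomer, i.e. a
~8.4 nm dimer repeat), (ii) straight or prescribed-angle bent
protofilaments, (iii) rigid-interface trajectories with harmonic angle
fluctuations, and (iv) Gaussian ensembles of elastic networks (frames
drawn from k\_BT × H⁺). Subunits are fixed asymmetric 20-point clouds
(distinct α and β variants) — deliberately not tubulin-shaped, because
superposition and angle decomposition only require a well-conditioned
rigid body. All generators are deterministic under a seed, restore the
caller's RNG state, and return their ground truth with the data.

What passing tests on this data do show: the geometry, estimators,
fitting loops and unit conversions are correct, closed-loop, and
statistically calibrated at known noise levels. What they do not show:
anything about force fields, solvent, anharmonicity, rare transitions,
or the actual values of tubulin interface stiffness — those require the
original all-atom trajectories, which are not redistributable inputs.

# Problem sizes and runtime choices

The packaged analyses and tests use: 10⁵ frames per stiffness condition
(stiffness recovery), 2 × 10⁴ frames for ENM parametrization and PCA
ensembles, 10- and 20-bead helices, a 120-bead rod, and 1000-draw
property loops. These sizes keep every stage's statistical error well
inside its asserted tolerance while the whole suite runs in minutes on
one core.

# Known limitations

* The φ sign convention is fixed by contract, not yet calibrated
  against deposited curved-tubulin structures (no coordinate files are
  shipped); `published_structure_angles()` makes that calibration a
  one-liner when the entries are available.
* XTC trajectories are not read (no XDR reader among the package's
  dependencies); use DCD or multi-model PDB.
* The heterogeneous-ENM fit interpolates its targets; with redundant
  springs, per-spring constants inherit amplified sampling noise even
  when the fitted fluctuations match observation to 0.1%. Interpret
  individual spring constants accordingly and prefer n ≥ 2 × 10⁴
  frames.
* The equipartition estimator assumes a single harmonic basin over the
  analysis window; multi-minimum behavior (as suggested by
  run-to-run variability of inter-dimer bending directions) shows up in
  the block diagnostic rather than being modeled.
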