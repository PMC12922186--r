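---
title: "Models and methods in stacksas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in stacksas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

stacksas studies the self-assembly of *frustrated* triskelion amphiphiles:
molecules built on a rigid planar aromatic core whose six arms alternate
hydrophobic and charged hydrophilic groups, so that no clean core–shell
segregation is possible.  Such molecules associate into short face-to-face
π-stacks in water — consecutive molecules flipped so their inequivalent
chiral faces alternate up–down — and into larger prolate or oblate
aggregates when salt screens the sulfonate–sulfonate repulsion.  The
package provides the complete desk-scale analysis chain for this system:
a synthetic coarse-grained structure generator, aggregate and shape
analyses, a Debye-equation SAXS/SANS forward model, and Bayesian
(metainference-style) ensemble refinement against scattering curves.

This vignette explains the models, the tunable parameters with their units
and defaults, the numerical choices, and the limits of what the synthetic
generator can show about real data.

## The coarse-grained molecule

`build_template()` constructs one amphiphile at bead resolution:

* A rigid aromatic core of three *real* beads at the vertices of an
  equilateral triangle (edge `core_edge`, default 5 Å) plus three massless
  *virtual* sites.  Each virtual site is a fixed affine combination of the
  three real core beads, `v_k = (2 c_i + 2 c_j - c_k)/3`, which places it
  opposite bead *k* on the same circumcircle.  Because the rule is affine,
  virtual positions are reproduced exactly (to < 1e-6 Å, asserted on
  every configuration) under any rigid-body motion — this is how a planar
  polyaromatic core is kept rigid without bonded springs.
* Three hydrophilic arms (ether linker, alkyl, terminal sulfonate with
  charge −1) reaching `arm_hydrophilic` = 7 Å beyond the core edge, and
  three single-bead phenyl arms reaching `arm_hydrophobic` = 6 Å,
  alternating around the core.  Net molecular charge is −3.
* Arms carry a small azimuthal skew (default 10° per bead) and
  out-of-plane lift.  This makes the molecule *chiral*: its mirror image
  cannot be superimposed by any proper rotation (checked by a Kabsch
  alignment residual in the tests).  Chirality is what makes "up" and
  "down" faces physically distinct and drives the up–down alternation
  motif in stacks.

Bead radii, masses and scattering contrasts live in `bead_types()`.  The
radii follow small/tiny coarse-grained bead sizes (1.7–2.35 Å); the
contrast columns are *excess over displaced solvent* — effective electrons
for X-rays, summed nuclear scattering lengths (fm) for neutrons.  They are
nominal working values adequate for shape-level forward modelling and for
all internal consistency checks; for quantitative contrast-variation work
(e.g. D2O solvent, where the hydrogen-rich groups change sign) the columns
should be replaced by values computed for the actual chemistry.  The
neutron solvent convention is deliberately configuration, not a baked-in
default, because light- vs heavy-water contrast changes every number.
One deliberate widening of the type system: the `counterion` role covers
mobile ions of either sign (Na+ and Cl−), so screening-salt boxes are
representable.

## The synthetic ensemble generator

`build_ensemble()` realizes an `ensemble_recipe()` and stands in for the
molecular-dynamics sampling that would otherwise produce configurations.
Its defaults *are* the study conditions of the dilute aqueous system:

* 41 molecules in a cubic box sized for 25 mM (`molar_concentration()`
  gives 24.8 mM for the canonical 41-molecule, 14-nm box; exact
  neutralization of 41 trianionic molecules takes 123 monovalent
  counterions).
* `monomer_fraction = 0.2` — roughly a fifth of the molecules dissolved,
  the rest distributed over face-alternating stacks of 2–8 molecules with
  decreasing weights (sizes ≤ 4 dominant, > 6 rare).
* Stacking distance `d_stack = 4.5` Å.  The atomistic π-stacking repeat is
  ~3.4 Å while the coarse-grained centre-of-mass stacking peak sits near
  6.5 Å; coarse beads are fatter than atoms, and 4.5 Å is a deliberate
  intermediate default, exposed as a parameter.
* Up–down alternation is implemented as a 180° rotation about an in-plane
  axis (which preserves chirality) plus a 60° rotation about the stack
  axis so that the six arms of consecutive molecules interdigitate instead
  of clashing tip-to-tip; `twist_per_unit` adds any further twist.
* Placement is sequential random insertion with rejection: a fragment pose
  is accepted only if every bead stays at least `min_separation` (7 Å)
  from previously placed fragments; a fragment whose internal jitter
  produces a hard-core clash (bead–bead distance < 0.7 (r_i + r_j)) is
  re-drawn.  The 7 Å inter-fragment floor keeps independently placed
  aggregates resolvable by the 6 Å clustering cutoff, so generator
  composition is recoverable by the analyzer — a design choice that makes
  the generate → analyze loop a meaningful test.  No energies are
  computed anywhere: structures, not thermodynamics, are the deliverable.
* Larger aggregates mimicking the salted condition come in three shapes:
  plain stacks, sloppy columns (`prolate-cylinder`: larger jitter, random
  twist) and two-layer sunflower-spiral patches (`oblate-disc`).

The generator is a pure function of (recipe, seed): identical output for
identical inputs, which the tests assert bit-exactly.

What the generator does **not** emulate: thermal disorder beyond Gaussian
positional jitter, solvent and counterion structure around the aggregates,
inter-aggregate correlations (a structure factor), polydispersity of arm
conformations, or any energetics.  Tests that pass on synthetic ensembles
therefore validate the *analysis machinery* — clustering, shape
classification, scattering, refinement — not the realism of any particular
aggregate geometry.

## Aggregate analyses

**Clustering** (`cluster_molecules()`): single-linkage connected components
of the molecule contact graph, with contacts defined by minimum bead–bead
distance (default) or centre-of-mass distance under the minimum-image
convention.  The contact rule for the real system is genuinely unknown;
the default 6.0 Å cutoff sits between the potential-of-mean-force approach
threshold (~4.2 Å) and the centre-of-mass stacking peak (~6.5 Å), and both
criterion and cutoff are exposed because the size distribution moves with
them.  Cutoffs above half the shortest box edge are refused (minimum-image
violation).  Components are found by union–find; the test suite checks the
partition against an independent graph-components oracle on random
configurations, plus cutoff monotonicity and lattice-translation
invariance.

**Size distribution** (`size_distribution()`): mass-weighted by default —
`p(n) = n N_n / Σ m N_m`, the probability that a *molecule* belongs to an
n-aggregate (so clusters {4, 4, 2} of ten molecules give p(4) = 0.8) —
with a cluster-centric variant behind the `weighting` flag.
`monomer_fraction()` returns p(1), the dissolved fraction.

**SASA** (`sasa()`): Shrake–Rupley point sampling on a deterministic
Fibonacci sphere lattice (default 960 points, probe 1.4 Å); deterministic
by construction, no RNG.  Accuracy is verified against the analytic
sphere (4π(R+p)²) and the closed-form two-sphere lens subtraction at the
1% level.

**Shape classification** (`inertia_tensor()`, `classify_shape()`): the
mass-weighted inertia tensor about the centre of mass, eigenvalues sorted
I1 ≤ I2 ≤ I3 with a right-handed eigenframe.  The label rule, with
degeneracy threshold ε (default 0.25): near-spherical if I1/I3 ≥ 1 − ε;
otherwise prolate when the upper eigenvalue pair is the more degenerate
one ((I3−I2)/I3 < (I2−I1)/I2 — two large, one small, a rod) and oblate
otherwise.  The rule reproduces the rod and disc limits exactly and is
scale-invariant; ε is exposed because the published prolate/oblate split
for this system depends on a threshold that is not restated anywhere, so
fractions such as "~80% prolate" should be read as threshold-dependent.
Aggregates split across periodic images are rejected with an instruction
to unwrap (the package keeps molecules whole internally, wrapping only on
file output, precisely so this never happens in the native pipeline).

**Cylindrical distribution functions** (`cylindrical_distribution()`):
each selected aggregate is translated to its centre of mass and rotated so
its symmetry axis — the eigenvector of the most isolated inertia
eigenvalue (largest eigenvalue gap), sign fixed toward the positive
octant — is vertical; per-bead-type counts are accumulated in (r, |z|)
bins and divided by bin volume and aggregate count.  z is folded to |z| by
default because up–down alternating stacks are statistically mirror
symmetric (`signed_z` disables folding; bin volumes account for it either
way).  Mass conservation — Σ density × cell volume = mean beads per
aggregate — is asserted on every build at 1e-6 relative.
`perpendicular_rdf()` integrates the map along the axis by the trapezoid
rule over z-bin centres, giving the per-type perpendicular radial profile.
On generated stacks the core-bead density concentrates near the axis and
the sulfonate density peaks outside it — the core–shell-like segregation
signature.

## Scattering forward model

`debye_intensity()` evaluates the orientation-averaged Debye sum
`I(q) = Σ_i Σ_j f_i(q) f_j(q) sin(q r_ij)/(q r_ij)` over free
(non-periodic) bead distances — the dilute-limit single-cluster form
factor.  Bead amplitudes are homogeneous-sphere form factors,
`f(q) = contrast · 3[sin(qR) − qR cos(qR)]/(qR)³`, chosen over Gaussians
for their analytic zeros and exact forward limit `f(0) = contrast`; the
q→0 limit is series-expanded so there is no 0/0.  The implementation
computes the condensed distance set once and sums per q; tests pin it to a
brute-force double loop at 1e-10 relative and to analytic one-bead,
two-bead and dense-sphere limits (the last within 2% for qR ≤ π).
Inter-aggregate structure factors are deliberately *not* modelled: the
analysis targets the intermediate/high-q regime where single-aggregate
structure dominates, and the low-q suppression seen in charged-aggregate
solutions is out of scope.

`smear()` applies Gaussian resolution smearing with per-point width dq
(a 4σ-truncated kernel, trapezoid quadrature, renormalized per point) —
dq = 0 is the identity, constants are invariant, positivity is preserved;
grids too coarse for the requested width fall back to the unsmeared value
with a warning.  `fit_scale_offset()` solves the weighted least-squares
normal equations for intensity scale and offset in closed form
(model interpolated to the data grid linearly in log q–log I with a
positive floor).  `chi2()` is reduced by default (divided by the number of
points) with the raw sum behind `reduced = FALSE`; the choice is a
convention, stated here because published χ² values for this kind of
analysis rarely state theirs, and such values are not reproducible without
the original curves in any case.

## Metainference refinement

`refine()` implements desk-scale metainference: instead of biasing
molecular-dynamics replicas on the fly, the Bayesian machinery acts on the
*weights* of a fixed configuration library.  The posterior combines,
per data point i of each target curve,

E = Σ_i [ (s·⟨I_i⟩_w + c − d_i)² / (2σ_i²) + ln σ_i ]

with ⟨I_i⟩_w the weights-averaged model intensity, flat priors on scale s
and offset c, and each effective uncertainty σ_i confined to
[σ_min, σ_max].  The bounds follow the fractional rule of
`uncertainty_model()`: σ_max is 0.7% of the intensity at that point and
σ_min is 40% of σ_max.  The ln σ term (the Gaussian normalization) is what
stops σ from drifting to its upper bound trivially.  Twenty q points,
log-evenly spaced in a window around the q ≈ 0.1 Å⁻¹ feature, are used by
default (`select_q_points()`).  Multiple curves — SAXS and SANS
simultaneously — enter as a plain sum of per-curve energies with
independent (s, c, σ) blocks; simultaneous targets shrink the set of
configurations compatible with both contrasts.

Sampling is Metropolis Monte Carlo over four move classes: per-point σ
(uniform proposal scaled by the bound span, single-fold reflection at the
bounds — proposals still outside after one fold are rejected, which keeps
the proposal symmetric *and* keeps acceptance monotone in step size),
scale and offset (uniform proposals with constant reference spans, so
detailed balance holds), and pairwise weight transfer on the simplex
(Σw = 1 is preserved exactly, to 1e-12 over millions of moves).

Step sizes adapt during burn-in (default 40% of the run) toward ~50%
acceptance and are then frozen so the production chain is Markovian.  The
burn-in is staged: plain equilibration first, then tuning of the
scale/offset/weight steps, and only then tuning of the σ step under the
production move mix.  The staging matters: σ acceptance measured while the
other move classes are mistuned, or while σ moves are over-proposed, is
systematically biased, and a step frozen from such measurements misses the
50% target in production.  The controller multiplies the log step by a
high capped gain (the acceptance-versus-step response is shallow) with
Robbins–Monro decay.  On the standard two-population problem this lands
the post-burn-in σ acceptance at ~0.5 across seeds while recovering a
70/30 stack/monomer mixture to within a few hundredths.

Posterior means of weights, scale, offset and σ are reported together with
the reduced χ² at those means, per-class acceptance rates and a thinned
trace; `tidy()` returns per-configuration weights, `glance()` the run
summary.  Everything is bit-reproducible given the seed.

Problem sizes used throughout the tests — libraries of ~8 configurations,
60-point curves, 20–30 thousand MC steps, 10–20 generator seeds — were
chosen so each check exercises the full machinery with comfortable
statistical margins while a complete run of the suite stays a desk-scale
computation.

## Pipeline, formats and reproducibility

`run_pipeline()` chains generate → cluster → shapes → cdf → scatter
(→ refine when target curves are configured), writing tidy CSVs, curve
files and wrapped GRO snapshots into an output directory.  Every run is
stamped with the seed and a hash of the fully merged configuration;
reruns are byte-identical, and unknown configuration keys are rejected
with their location.  A single global seed expands into per-stage streams
by a counter scheme so stages are independently reproducible.

Coordinates are stored internally in Å with molecules whole; `GRO` (nm,
fixed columns), `PDB` (Å, CRYST1) and `XYZ` writers wrap molecules into
the box on output.  Scattering curves use the whitespace 2–4-column
dialect (q, I[, σ[, dq]]) with `#` comments and an explicit q-unit flag
(Å⁻¹ or nm⁻¹).  The package is used from R; the exported functions plus
`run_pipeline()` are the interface, and all stages are scriptable.

## Known limitations

* Contrast values are nominal; absolute-intensity calibration is out of
  scope, so scale factors against real curves are arbitrary.
* The cluster criterion/cutoff and the shape threshold ε are conventions;
  quantities downstream of them (size cap, prolate fraction) move when
  they move.
* The refinement library is fixed: configurations the generator cannot
  produce cannot be up-weighted into existence.
* No structure factor: the model is wrong at low q for concentrated,
  strongly charged samples.
* The generator's aggregates are geometric idealizations; they carry no
  force-field information.
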