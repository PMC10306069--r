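---
title: "Conformer assignment, restraints and density validation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer assignment, restraints and density validation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntckit)
```

## The problem and the model

Double-helical DNA refined against mid-resolution diffraction data (2.5–3 Å)
has a backbone that the map alone cannot determine: six backbone torsions,
the glycosidic torsion and the sugar pucker per nucleotide are strongly
correlated, so restraining them one at a time is ineffective.  The smallest
fragment whose backbone geometry clusters into well-defined classes is the
dinucleotide step, and `ntckit` operates entirely at that level: it
assigns each step to a named conformer class, scores the agreement, turns
confident assignments into refinement restraints, and validates the result
against electron density.

### The 22-parameter step descriptor

A step *i* → *i+1* is described by

* backbone torsions δ(i), ε(i), ζ(i), α(i+1), β(i+1), γ(i+1), δ(i+1);
* glycosidic χ of both nucleotides (O4′–C1′–N9–C4 for purines,
  O4′–C1′–N1–C2 for pyrimidines; for planar bases the two definitions give
  the same value, which keeps the descriptor comparable across sequences);
* the ten sugar ring torsions ν0–ν4 of both deoxyriboses;
* the pseudo-torsion N(i)–C1′(i)–C1′(i+1)–N(i+1);
* the pseudo-distances N(i)–N(i+1) and C1′(i)–C1′(i+1) in Å.

The pseudorotation phase P and amplitude τ~m~ (Altona–Sundaralingam:
tan P = ((ν4+ν1) − (ν3+ν0)) / (2ν2(sin 36° + sin 72°)), τ~m~ = ν2 / cos P)
are carried as derived summaries but are not part of the metric — the ν
torsions themselves are, and they are also what gets restrained, so no
information is lost.  All angles live in (−180°, 180°] and every comparison
uses circular differences; β and ζ routinely wrap near ±180° and raw
subtraction is never safe.

Dihedral signs follow the IUPAC convention (positive when, looking along
the central bond, the far bond is rotated clockwise from the near bond);
the unit test pins the convention with the four-point example
(0,0,0),(1,0,0),(1,1,0),(1,1,1) → +90°, cross-checked once against an
independent crystallographic implementation.

### Assignment and the NANT gate

The distance between a step and a class is

d(step, class) = sqrt( Σ_angles wrap(Δ)² + Σ_dists (K·Δ)² ),

with K = 20 °/Å so that a 0.1 Å pseudo-distance error weighs like a 2°
torsion error.  The step is assigned to the argmin class unless
d > 100° or any single angular deviation exceeds 72°, in which case it is
NANT.  Both thresholds are exposed as arguments.  A threshold gate was
chosen over a nearest-neighbour density gate because the built-in library
is small and the gate must behave predictably for user-supplied libraries
of any size.

Restraint *eligibility* is deliberately a separate, Cartesian criterion:
the r.m.s.d. of the step atoms against the class reference coordinates
after least-squares (Kabsch, proper rotation enforced) superposition must
be **≤ 0.5 Å**, boundary inclusive.  Torsion space decides *what* the step
is; Cartesian space decides *whether it is close enough to pull*.

### Confal-style scoring

Each parameter contributes s_k = exp(−Δ_k²/(2σ_k²)) with the class's σ_k;
the step score is round(100 · geometric mean of the 22 s_k).  The score is
100 exactly at the class geometry, 61 when every parameter is exactly one
sigma off (100·e^{−1/2}), and monotone non-increasing in every |Δ_k|.  The
structure score is the arithmetic mean over steps.  The published
percentile calibration of such scores against the PDB requires the full
archive and is not reproduced.

### Restraints

Eligible steps produce one record per parameter — 22 per step.  Targets
are always the class targets, never the model's current values: restraints
that chase the model would only entrench its errors.  Sigmas are the class
sigmas clamped to [8°, 25°] (distances [0.05, 0.3] Å) and divided by the
effective weight (global × per-step); the clamp keeps automatically derived
sigmas in a range that guides without freezing, and the "tighter" preset
(0.5×) reproduces a stricter protocol.  The ν torsions are restrained
individually rather than through a pucker pseudo-parameter, because both
output dialects speak plain torsion restraints.

The Phenix-style dialect writes, per parameter, an `ntc_delete` block
(remove the program's auto-generated torsion restraint on those atoms,
which would otherwise conflict) followed by an `ntc_change` block with atom
selection, target, sigma and period.  The REFMAC-style dialect writes
`exte tors` / `exte dist` lines.  Neither refinement program's exact
grammar is bit-reproduced (the patched engines are not publicly
verifiable); both dialects here are documented, deterministic (records
ordered by chain, residue, fixed parameter order) and mutually convertible,
with a parser that round-trips them and passes unknown lines through for
user editing.

Step selection (`--steps 1-7,12-18`) is residue-based and inclusive: a
step is restrained only when both its residues are selected, which leaves
a window such as residues 8–11 wholly unrestrained.

### Density validation

Model density is a sum of spherical Gaussians, variance B/(8π²) + blur²
(default blur 0.9 Å emulating finite resolution), amplitude normalized to
the atom's electron count times occupancy.  The per-step RSCC is the
unweighted mean over the step's atoms of the Pearson correlation between
observed and calculated density on grid points within 2.0 Å of the atom;
atoms with fewer than 8 mask points are excluded and counted.  The mask
radius and minimum are fixed documented defaults.  Steps are then placed
on the RSCC–r.m.s.d. plane and classified at RSCC = 0.8 and r.m.s.d. =
1.0 Å into good / over-refined / unique / poor, boundaries inclusive
toward the favourable class.  Observed maps are consumed as CCP4/MRC mode-2
grids; computing 2mFo−DFc coefficients from structure factors is out of
scope, so all shipped examples use model-generated and noise-perturbed
synthetic maps.  On real maps produced by a different density model, RSCC
values may differ in the second decimal.

### Crystal geometry

Symmetry expansion uses embedded operator tables (P1, P2, P2₁, C2,
P2₁2₁2₁, P4₁2₁2, P4₃2₁2; arbitrary x,y,z triplets are also parsed), with
group closure enforced by property tests.  A "unique" crystal contact is a
canonicalized atom-id pair (lexicographically smaller id first, an
operator identified with its inverse image) with distance strictly below
the cutoff; published contact counts depend on exactly such a convention,
so ours is documented and order-independent.  Intra-base-pair parameters
come from fitting embedded planar base templates to the observed ring
atoms, flipping the second base's frame (y, z) for antiparallel pairing,
and reading translations (shear, stretch, stagger) and the rotation-vector
components (buckle, propeller, opening) in the mid-frame.  Under strand
swap, shear and buckle flip sign and the other four parameters are
invariant, which the tests assert on distorted pairs.

## The synthetic generator: what it emulates and what it does not

`build_duplex()` constructs antiparallel Watson–Crick duplexes from a
rigid repeating unit per form:

| constant | A form | B form |
|---|---|---|
| twist (°/step) | 32.7 | 36.0 |
| rise (Å/step) | 2.56 | 3.38 |
| x-displacement (Å) | −2.5 | −0.7 |
| sugar P (°) / τ~m~ (°) | 18 / 38 | 162 / 36 |
| χ (°) | −157 | −102 |

The sugar ring is built from its pseudorotation state by natural-extension
placement with a small closure optimization; C5′, O3′ and the glycosidic
nitrogen are attached on the faces that make the ring a D-deoxyribose
(δ ≈ 90° for the A sugar, ≈ 148° for B).  The 5′ tail (O5′, P) is then
solved numerically so that O3′(i)–P(i+1) connectivity under the helical
step transform is a proper covalent bond; with the A-form x-displacement
at −2.5 Å the resulting backbone torsions sit nearest their canonical
ranges, which is why that value (rather than the ~−4.4 Å of fiber A-DNA
with inclined pairs) is the generator constant — the generator stacks
pairs without inclination for simplicity.  Base templates are idealized
planar geometries in the pair reference frame, rigidly snapped to a
canonical glycosidic anchor so the sugar-phosphate frame is exactly
sequence-independent; an ideal pair therefore has C1′–C1′ = 10.5 Å and
identically zero base-pair parameters.

These are **generator constants, not measurements**: the fixtures and the
built-in "mini" library (AA00 and BB00 from the pure forms, AB01/BA05
bridges rebuilt from mixed torsion vectors; σ = 12° / 0.15 Å throughout)
form a closed, self-consistent ground truth.  Passing tests demonstrate
that the pipeline is internally correct — assignment recovers planted
classes, restraint targets equal class geometry, RSCC degrades with noise
— not that the mini library reproduces the class boundaries of the curated
experimental golden set.  Swapping in a golden-set export via the JSON
schema changes no code paths.

Noise: coordinate noise is i.i.d. Gaussian per coordinate; torsion noise
rotates about backbone bonds (α, β, γ, ε per residue) with the rotation
propagated to all atoms 3′-ward, emulating correlated backbone deformation
without breaking bonds, and records per-bond truth metadata.  All
randomness flows from the single spec seed.

## Numerical choices and degenerate inputs

* Ring rebuilds from arbitrary ν targets first project onto the nearest
  consistent pseudorotation state (closed-form least squares in the
  (τ~m~cos P, τ~m~sin P) plane); unconstrained ν combinations need not be
  realizable by a closed five-ring and previously drove the closure
  optimizer into collinear geometries.
* Superposition refuses n < 3 or collinear point sets; dihedrals refuse
  coincident or collinear points with a named error.
* Alternate conformers: highest occupancy wins, ties break to the
  alphabetically first alt-loc id (a deterministic repository convention;
  how the original analyses handled alt-locs is not documented anywhere).
* Steps exist only between residues with consecutive author numbers *and*
  O3′–P < 2.5 Å, guarding against chain breaks and numbering gaps.
* The step-atom subset used for torsions and Cartesian comparison is the
  documented ordered list in `ntckit:::STEP_ATOMS_NT1/NT2` (20 atoms, 21
  with the optional nt1 O5′); Cartesian r.m.s.d. uses the atoms common to
  the step and the class reference, so rebuilt steps without a 5′ tail
  compare cleanly.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
fixtures: 18-mer duplexes (36 nucleotides, ~730 atoms) for assignment and
restraints, 6-mer duplexes for density work (0.8 Å grids), 200 noisy
replicates per class for recovery, and 10 random 5-point sets for the
superposition oracle.  These sizes were chosen so the whole suite
completes in a few minutes on one core while every statistic is still
stable to well inside its test tolerance.

## Known limitations

* The mini library has 4 classes; real assignments need the full curated
  library, supplied as JSON.
* The Gaussian density model ignores atomic form-factor differences beyond
  electron count and B; absolute RSCC values on experimental maps will
  differ slightly from engine-computed ones.
* Only orthogonal-axis CCP4/MRC mode-2 maps are read; symmetry-expanded
  map handling is not implemented.
* Base-pair parameters use a rotation-vector decomposition, which matches
  the standard convention exactly at small angles and to first order
  beyond; heavily buckled pairs may differ by fractions of a degree from
  implementations using other decompositions.
* Crystal contacts enumerate ±1 lattice translations around each
  operator, sufficient for molecular crystals whose asymmetric unit fits
  the cell; exotic packings with longer reach would need a wider search.
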