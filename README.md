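# ntckit

Conformation-based refinement support and validation for DNA crystal
structures in R.

Mid- and low-resolution DNA refinement is unstable because the
sugar-phosphate backbone has many correlated torsions that diffraction data
alone cannot pin down.  Restraining one torsion at a time is
counterproductive; the natural restraint unit is the **dinucleotide step**,
whose backbone geometries cluster into named conformer (NtC) classes (AA00
for the canonical A-form step, BB00 for B-form, bridge classes between
them, and NANT for "not assigned").  `ntckit` implements that workflow for
crystallographers and nucleic-acid modellers:

* **Assignment.**  Each step's 22 torsional/pseudo-bond parameters
  (backbone torsions δ ε ζ α β γ δ, glycosidic χ of both nucleotides, the
  ten sugar ring torsions ν0–ν4, the N–C1′–C1′–N pseudo-torsion, and the
  N–N / C1′–C1′ pseudo-distances) are compared with every class in a
  reference library under a circular-Euclidean metric; a step is assigned
  to the nearest class unless the distance exceeds 100° or any single
  angular deviation exceeds 72°, in which case it is NANT.
* **Confal-style scoring.**  Per-parameter agreement s_k =
  exp(−Δ_k²/2σ_k²); the step score is 100 × the geometric mean over the 22
  parameters, and the structure score is the mean over steps.
* **Restraints.**  Steps whose Cartesian r.m.s.d. (Kabsch superposition)
  to the nearest class reference is within 0.5 Å are eligible; each
  eligible step yields 22 records whose targets are the *class* values —
  never the model's own torsions — rendered either as
  `ntc_delete`/`ntc_change` blocks (Phenix-style: delete the program's
  auto-generated torsion restraint, then set the class target) or as
  `exte tors`/`exte dist` lines (REFMAC-style).  Sigmas are clamped to
  [8°, 25°] (distances [0.05, 0.3] Å) and divided by global and per-step
  weights; a `--tighter` preset halves them.
* **Validation.**  Per-step real-space correlation (RSCC: mean over atoms
  of the Pearson correlation between observed and model Gaussian density
  within a 2 Å mask) is plotted against the step's r.m.s.d. to the nearest
  class, and classified into quadrants split at RSCC = 0.8 and r.m.s.d. =
  1.0 Å: *good*, *over-refined*, *unique*, *poor*.
* **Crystal geometry.**  Symmetry-expanded DNA–DNA contacts, cross-strand
  C1′–C1′ distances (second chain or closest symmetry mate), the six
  intra-base-pair parameters (shear, stretch, stagger, buckle, propeller,
  opening), and cation coordination distances.
* **Fixtures.**  A fiber-style duplex generator (ideal A and B forms, with
  seeded torsion/coordinate noise and truth metadata), a built-in mini
  conformer library derived from it, and synthetic density maps, so the
  whole pipeline runs without any external data.

## Worked example

```r
library(ntckit)

s   <- build_duplex(fixture_spec())     # ideal A-form 18-mer duplex
lib <- load_library("mini")
a   <- assign_structure(s, lib)
head(a[, 1:6], 3)
#>   step_label  ntc torsion_distance cartesian_rmsd confal eligible
#> 1  A.DG1_DG2 AA00     4.264591e-13   2.885639e-15    100     TRUE
#> 2  A.DG2_DT3 AA00     4.115278e-13   3.861949e-02    100     TRUE
#> 3  A.DT3_DG4 AA00     3.061567e-13   3.926679e-02    100     TRUE
structure_confal(a)
#> [1] 100
```

Every step of the ideal fixture is assigned to AA00 at zero torsion
distance, scores a confal of 100, and is eligible for restraints (the
sub-0.1 Å r.m.s.d. values on mixed-sequence steps come from the
base-specific χ-reference atom).  Restraints for the selective protocol
that leaves the central base pairs free:

```r
rs <- build_restraints(a, lib, s,
                       include_residues = parse_step_selection("1-7,12-18"))
cat(substr(render_restraints(rs, "refmac_style"), 1, 180))
#> # NtC restraints | library ntckit-mini-1 | global_weight 1
#> exte tors first chain A resi 1 atom C5' next chain A resi 1 atom C4' ...
```

The same set renders to the Phenix-style dialect, and both parse back to
identical (parameter, target, sigma) content.  Validation against a map:

```r
m   <- synthetic_map(s, noise_sigma = 0.05, seed = 7)
tab <- scattergram_table(s, m, lib)
table(tab$quadrant)
#> good
#>   34
```

The command-line interface mirrors the workflow:

```sh
ntc-kit fixture  --sequence GGTGGGGCATGCCCCACC -o model.cif --map map.ccp4
ntc-kit assign   model.cif -o assignments.tsv
ntc-kit restrain model.cif --steps 1-7,12-18 --dialect phenix_style -o ntc.params
ntc-kit validate model.cif --map map.ccp4 -o scattergram.tsv
```

## Scope notes

Map-coefficient synthesis (2mFo−DFc), the refinement engines themselves,
and Saenger/Leontis–Westhof pair-class assignment are out of scope: the
package generates refinement *inputs* and consumes maps as grids.  The
built-in "mini" library is derived from the package's own ideal fiber-style
geometry, not from a curated experimental ensemble; a user-supplied library
in the documented JSON schema (label, 22 targets, 22 sigmas, reference
coordinate block) is a drop-in replacement.
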