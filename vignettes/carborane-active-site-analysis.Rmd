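---
title: "Analysing carborane-sulfamide binding sites: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing carborane-sulfamide binding sites: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbscan)
```

## The problem

Icosahedral carboranes (12-vertex *closo* C~2~B~10~ cages) are bulky,
hydrophobic pharmacophores. Attached to a sulfamide zinc-binding group
they inhibit carbonic anhydrases, and differences between the
ubiquitous isoenzyme II and the tumour-associated isoenzyme IX are the
basis for selectivity engineering. The analyses a structural biologist
runs on such a complex are the subject of this package:

* superposing crystal forms and quantifying backbone and ligand
  displacements (Kabsch least-squares fit, RMSD, per-residue deviation
  maps);
* enumerating protein–ligand and zinc–ligand contacts at a distance
  cutoff and classifying them (metal coordination, polar, van der
  Waals);
* detecting dihydrogen bonds, the B–H^δ−^···^δ+^H–X interaction unique
  to hydridic boron clusters;
* modeling the complex of a homologous isoenzyme by grafting the ligand
  from a solved template, relaxing the binding site, and
* quantifying per-residue side-chain contributions to binding by a
  virtual glycine scan.

## Structure model and I/O

Structures are flat atom tables grouped into residues by
`(chain, author residue number, insertion code)`. PDB and mmCIF files
are parsed through bio3d; writing uses bio3d for PDB and a minimal
`atom_site` loop for mmCIF. Alternate locations are kept on input; all
geometric analyses run on a single position per atom, chosen per atom
name as the altloc with the highest occupancy (ties alphabetically).
The `adp` column is the isotropic-equivalent displacement parameter as
deposited in the ATOM records; mean ADPs are unweighted arithmetic
means over the selected atoms.

## Contact analysis

`enumerate_contacts()` lists every heavy-atom pair (protein or metal
versus ligand) within 4.0 Å, the cutoff used by crystallographic
contact tables for this system; the boundary is inclusive and distances
are reported to 2 decimals. Classification is a pure function of
(element pair, distance, metal flag):

* **metal coordination**: protein-side atom is a metal ion and the
  distance is ≤ 2.5 Å. This keeps the Zn–sulfamide coordination bond
  (1.87 Å in the crystal) and rejects the longer Zn···S/O approaches
  (≥ 3.0 Å).
* **polar**: both atoms are N/O/S and the distance is ≤ 3.1 Å. The
  crystal table's highlighted hydrogen-bond rows all fall at ≤ 3.02 Å
  and its non-highlighted N/O pairs at ≥ 3.14 Å, so 3.1 Å separates the
  two populations exactly; the published table states no criterion of
  its own.
* **van der Waals** otherwise.

The bundled `reported_contacts()` tables (the published crystal table
for the isoenzyme-II complex, 39 rows including three zinc rows, and
the published model table for isoenzyme IX) are *inputs*: the tests ask
whether the distance-only classifier reproduces their polar/bold
highlighting, and it does, 39/39 rows.

Dihydrogen bonds use standard crystallographic criteria: an H···H
distance ≤ 2.4 Å between a protic hydrogen (on N, O, S or an aromatic
carbon) and a hydridic hydrogen (on boron), with both X–H···H angles
≥ 90°. Hydrogens must be present (`add_hydrogens()`).

## Hydrogen placement

Hydrogens are placed by ideal geometry: sp^3^/sp^2^ rules with standard
bond lengths (C–H 1.09, N–H 1.01, O–H 0.96, S–H 1.34 Å). Cage vertices
get one exo hydrogen each on the centroid–vertex axis at 1.19 Å, the
defining geometry of a *closo* cluster. Existing hydrogens and heavy
atoms are never moved. Underdetermined torsions (rotatable O–H, N–H~2~,
N–H~3~) are fixed deterministically; around metal ions the torsion is
chosen to keep polar hydrogens away from the cation, standing in for
the lone-pair-toward-metal orientation of a real coordination bond.
Histidine is built as the single neutral N^ε2^–H tautomer; a
per-instance tautomer choice would require per-instance charges, which
the fixed-charge tables below do not support, and none of the shipped
analyses depend on the distinction.

## The energy surrogate

The interaction energy ΔG′~int~ of the ligand with its environment is a
classical fixed-charge model,

$$E = \sum_{i \in \mathrm{lig}} \sum_{j \in \mathrm{env}}
  \frac{332.0637\,q_i q_j}{\varepsilon(r_{ij})\, r_{ij}}
  + 4\epsilon_{ij}\!\left[\left(\frac{\sigma_{ij}}{r_{ij}}\right)^{12} -
  \left(\frac{\sigma_{ij}}{r_{ij}}\right)^{6}\right]$$

with Lorentz–Berthelot combination and a distance-dependent dielectric
ε(r) = 4r as the default solvent screening (a constant-dielectric mode
exists for closed-form checks). Units are kcal/mol, Å and elementary
charges throughout. There is no cutoff and no periodicity: systems are
active-site-scale. This surrogate replaces the quantum-chemical
treatment that a publication-grade study of boron clusters would use;
it supports rank-level and property-based conclusions, not quantitative
binding free energies, and the package deliberately makes no K~i~
claims.

The parameter table is the package's own minimal set, shipped as
plain-text data (`inst/extdata/ff_*.tsv`): group-style charges on polar
atoms (amide, hydroxyl, imidazole, carboxylate, guanidinium groups with
integer residue sums asserted in tests), zero charge on aliphatic and
aromatic carbons and their hydrogens, whose sterics are folded into the
parent atom's σ. Hydridic cage hydrogens carry −0.08 e against +0.08 e
on boron, giving dihydrogen contacts their electrostatic signature, and
keep a small LJ well so they have volume. Zinc is a bare +2 ion with a
small, tight LJ well; the sulfamide anchor nitrogen at −0.8 e then
binds it at ≈ 2.1–2.3 Å by electrostatics alone, without a bonded term.
One consequence of zeroing nonpolar-H charges is exact bookkeeping in
the glycine scan: mutant glycines share every backbone parameter with
the wild type, so a rigid-mode ΔΔG is *exactly* the side-chain–ligand
pairwise sum, which the tests exploit as an oracle.

## FIRE relaxation

Binding-site relaxation minimises the nonbonded energy of the movable
atoms (chosen residues plus the ligand) in the field of the frozen
remainder, using the Fast Inertial Relaxation Engine with the original
parameter scheme (α~start~ = 0.1, f~α~ = 0.99, f~inc~ = 1.1,
f~dec~ = 0.5, N~min~ = 5). Because the energy model is nonbonded-only,
covalent geometry is maintained by harmonic restraints on bond lengths
(k = 300 kcal/mol/Å²) and 1–3 distances (k = 60) at their input values;
1–2 and 1–3 pairs are excluded from the nonbonded sum. Two numerical
safeguards matter on grafted starts, which can be severely strained: a
deterministic pre-separation sweep pushes hard overlaps (< 1.7 Å) apart
before dynamics begin, and each FIRE step caps the per-coordinate
displacement at 0.2 Å. Convergence is a maximum force component
≤ 0.05 kcal/mol/Å or the iteration cap, whichever first (the trajectory
summary reports which); the returned configuration is the best visited
point and never has higher energy than the start. Frozen atoms are
bit-identical on return. Thermal annealing after minimisation is out of
scope; this is a minimisation-only protocol.

## Virtual glycine scan

Each scanned residue is truncated to glycine — side chain removed
beyond C^α^, an H^α2^ added along the old C^α^–C^β^ direction — and the
interaction energy recomputed; the wild type is restored between
mutations, so results are independent of scan order. The report is

$$\Delta\Delta G = \Delta G'_{\mathrm{int}}(\mathrm{Gly\ mutant}) -
  \Delta G'_{\mathrm{int}}(\mathrm{wild\ type}),$$

so a **positive value means the side chain favours binding**. (The two
orderings of this difference are both in circulation; this one makes
the sign of a bar chart match the intuition "contribution to
binding".) The default rigid mode performs no re-relaxation and costs
n + 1 energy evaluations for n residues; an opt-in relaxed mode
re-relaxes the movable set for the wild type and every mutant.

## Template-based modeling of the homolog complex

`graft_ligand()` superposes the solved template complex onto the target
protein over a C^α^ selection (pairing by chain/number/atom name),
carries the ligand, the metal (if the target lacks one) and named
bridging waters into the target frame, and reports — but does not
repair — steric clashes, which the subsequent relaxation resolves.
Binding-site substitutions between the two proteins are listed by
spatial pairing (nearest C^α^ within 2.5 Å after the fit), not by
author numbering, because numbering schemes need not align between
isoenzymes. The pipeline (`run_caix_pipeline()`) then relaxes the
contact residues plus ligand, and reports the model's contact table,
the ligand displacement between grafted and relaxed pose (overall RMSD
and at the cage vertex B12, the atom conventionally used to express the
cage shift), the metal–anchor distance, and glycine scans of template
and model side by side.

## The synthetic test systems

Real deposited structures cannot ship with the package, so every stage
is validated on constructed systems with known ground truth
(`make_toy_complex()`, `make_homolog_pair()`):

* the ligand is built at its idealised template geometry (cage edge
  1.78 Å) at the origin;
* residues are placed so that one named atom sits at an exact
  engineered distance from one named ligand atom, facing it, with a
  seeded search over orientations that keeps everything else clear of
  the ligand (including its exo-hydrogen shell) and of other residues;
* the default layout is an isoenzyme-II-like site: the residue
  identities and contact distances follow the published crystal-contact
  table (shortest contact per residue — e.g. Thr199 O^γ1^ 2.74 Å from
  the anchor nitrogen, Gln92 O^ε1^ 3.47 Å from B6), the zinc ion sits
  2.0 Å from the anchor nitrogen on a tetrahedral lone-pair direction,
  and the remaining comparison residues sit just outside contact range;
* the homolog applies the six binding-site substitutions that
  distinguish the IX-like site (67 Asn→Gln, 91 Ile→Leu, 123 Trp→Leu,
  131 Phe→Val, 135 Val→Leu, 204 Leu→Ala) onto identical backbones,
  deletes ligand and waters, and moves everything by a seeded random
  rigid transform that is returned as the superposition oracle;
* ground truth (all pairwise distances, contact sets at any cutoff,
  closed-form Coulomb energies for a point-charge probe) is recomputed
  from the final coordinates with plain double loops, independent of
  the vectorised package paths.

What these fixtures do *not* emulate: a folded chain (residues are
disconnected fragments, so packing is looser and a handful of
residue–residue approaches sit near 1.5–2 Å until relaxed), rotamer
statistics, crystallographic disorder and solvent beyond one bridging
water. Passing tests therefore demonstrate correctness of the
computational machinery and of the engineered geometric facts, not
predictive accuracy on real proteins.

## Numerical choices and conventions

* Coordinates in Å; author residue numbering everywhere; residue-number
  ranges inclusive.
* Contact distances reported to 2 decimals; test comparisons use
  0.01 Å.
* Kabsch via SVD with determinant correction; rank-deficient
  (collinear) point sets are an error, reflections are impossible by
  construction.
* Superposition pairing drops atoms present on one side only, with a
  message; duplicate keys (unresolved altlocs) are an error.
* Waters are excluded from contact tables by default, included in
  energy evaluations.
* Deposited ligand atom names may differ from the template's canonical
  names; the template carries an explicit alias column (currently the
  identity mapping) so a deposition-specific naming can be dropped in
  as data.

## Problem sizes

The shipped analyses run on one CPU in well under a minute per script:
the synthetic site has 18 residues (≈ 350 atoms once protonated), FIRE
runs are capped at 500–800 iterations, and the brute-force oracles use
10,000 random rotations and 100 random fixtures. These sizes were
chosen so the whole battery — including the end-to-end modeling
pipeline — stays interactive while still exercising every code path at
meaningful scale.

## Known limitations

* The energy model is a fixed-charge surrogate: no polarisation, no
  charge transfer, no quantum effects — all of which matter
  quantitatively for boron clusters and zinc. Magnitudes of ΔΔG are
  model-specific; only signs and ranks are meaningful, and only within
  the model.
* Glycine truncation keeps the backbone fixed; rigid-mode scans ignore
  side-chain relaxation of the mutant.
* The His tautomer is fixed; protonation states are standard
  (Asp/Glu^−^, Lys/Arg^+^).
* Sequence-based alignment is out of scope: cross-isoenzyme pairing is
  purely spatial.
* The mmCIF writer emits a single `atom_site` loop — sufficient for
  round-tripping coordinates, not a general mmCIF serialiser.

## A worked example

```{r example, eval = FALSE}
library(carbscan)
toy <- make_toy_complex(fixture_spec(seed = 1, water = 272L))
contacts <- classify_contacts(
  enumerate_contacts(toy$structure, atom_selection(resname = "CB1")))
table(contacts$contact_class)

s <- assign_parameters(add_hydrogens(toy$structure))
scan <- glycine_scan(s, list(residue_id("A", 199L), residue_id("A", 5L)),
                     atom_selection(resname = "CB1"))
scan[, c("resno", "resname", "ddg")]
```

The `analysis/` directory runs the full study — fixture construction,
contact analysis, superposition, homolog modeling, glycine scan — as
five numbered scripts writing their tables under `results/`.
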