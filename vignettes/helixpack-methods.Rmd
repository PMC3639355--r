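---
title: "helixpack: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{helixpack: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
knobs matter, and where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model

A receptor's transmembrane region is represented as seven rigid helical
segments (`BundleState`). Each helix carries an immutable body template
(its internal coordinates, fixed at extraction) and six placement
variables in a fixed bundle frame:

| variable | meaning | units |
|---|---|---|
| `r`, `azimuth` | position of the helix center in the membrane plane | Å, ° |
| `z` | offset along the bundle axis | Å |
| `tilt`, `tilt_azimuth` | direction of the helix axis relative to the bundle axis | ° |
| `spin` | rotation about the helix's own axis | ° |

The bundle frame is fixed when the bundle is constructed (z = bundle axis,
origin = residue-count-weighted mean of helix centers); the derived
`bundle_center`/`bundle_axis` fields are recomputed after every move, but
the frame is not, so the variables of an unmoved helix never drift. This
parameterization is one of several equivalent six-variable charts; it is a
ZYZ Euler factorization, with the usual chart degeneracy at tilt exactly 0°
or 180° (the tilt azimuth is then undefined and set to 0 by convention).
Round-tripping variables → coordinates → variables reproduces the input to
1e-6, which the test suite checks over 1000 random variable sets.

The bundle axis is the residue-count-weighted mean of the sign-aligned
per-helix axes, after single-link clustering at a 30° cutoff with up to
`floor(0.10 N)` off-cluster vectors excluded. The conservative reading of
"up to 10 %" means a 7-helix bundle never excludes any (`floor(0.7) = 0`);
exclusion first becomes possible at N = 10. Helix axes come from the first
principal component of the Cα trace, oriented N→C.

Kinks are detected from carbonyl-oxygen i→i+4 distances: the ideal-geometry
builder gives 6.35 Å for a straight α-helix (φ = −57°, ψ = −47°), and a
helix is split where the observed distance deviates by more than 1.0 Å
(configurable; no published value exists for this tolerance). Segments are
kept at ≥ 4 residues by merging short remainders.

## The surrogate energy model

The original method ran inside a proprietary internal-coordinate force
field that cannot be reproduced; what the method actually contributes — the
staging, restraints, sampling weights and scoring — is force-field-agnostic.
The surrogate:

* **van der Waals**: Lennard-Jones 6–12 with per-element parameters
  (Lorentz–Berthelot combining) and 1-2/1-3/1-4 exclusions. The soft-core
  form is `E/(1 + λE/cap)` on the repulsive branch, so at stage-1 softness
  (λ = 1) the per-pair repulsion is capped at `vdw_cap` = 2.0 kcal/mol — the
  one numeric the original protocol states — and λ = 0 is plain LJ. For any
  clashing pair the energy is monotone non-decreasing as λ → 0, which makes
  the stage-wise hardening well behaved.
* **Electrostatics**: Coulomb with the distance-dependent dielectric
  ε(r) = 4r (the standard implicit-membrane reading of "a distance-dependent
  dielectric constant of 4"), conversion 332.06 kcal·Å/(mol·e²), so
  E = 332.06·q₁q₂/(4r²). A constant-4 alternative is a config switch.
  Charges are fixed template values for protein polar groups and
  Gasteiger charges for RDKit-embedded ligands.
* **Hydrogen bonds**: well depth (default 2.0 kcal/mol) × a distance switch
  on H···acceptor (full ≤ 2.5 Å, fading linearly to zero at 3.2 Å) ×
  cos²(θ) of the donor–H···acceptor angle for θ > 90°, else 0. The original
  names this term but not its form; this 10–12-like radial × angular shape
  is conventional and always ≤ 0.
* **Tethers**: Σ k·scale·d² over conserved-residue Cα atoms with target
  0 Å; the per-stage scale ramps 1 → 0.5 → (0.25 → 0) so the final stage
  ends tether-free.
* **Anchors**: flat-bottom quadratic, zero inside [target − w, target + w]
  and k·(excess)² outside; C¹-continuous at the window edges. The shipped
  windows are the printed ones: 12 ± 2 Å (D2-like) and 9.5 ± 1.5 Å
  (beta1AR-like).

Because the energy scale is surrogate-referenced, the pose acceptance
thresholds (−0.2/−0.2/−0.3 kcal/mol) are defaults exposed in config rather
than transferable constants.

## The Monte Carlo protocol

Four stages with monotonically growing degree-of-freedom classes: (1) rigid
helices + rigid ligand; (2) + ligand torsions and pocket side chains;
(3) + all side chains; (4) + backbone torsions, tethers ramped off.
Defaults that the source material does not fix, chosen once:

* **Temperature**: geometric cooling 600 K → 300 K within each stage.
* **Step budgets**: 2000/5000/10000/20000 proposals (desk scale); the test
  suite scales these down further (200–1500) to fit its time budget —
  scaling budgets, never thresholds.
* **Move magnitudes**: rigid moves N(0, 0.5 Å) translation and N(0, 3°)
  rotation; torsions N(0, 15°).
* **Pocket redefinition**: every 250 accepted moves ("regularly" is
  unquantified).
* **Checkpoints**: percentile-based (keep the best 15 % after stage 1, 25 %
  after stage 3). The original uses absolute score thresholds on its own
  scale; percentiles reproduce the funnel shape (hundreds → dozens → ~10)
  without that scale.
* **Variable-release order**: side chains before backbone; the original
  says only that torsion sets were "gradually" freed.

Move classes are drawn with weights 100:50:20:2
(ligand : pocket : helix-positional : rest), the concrete encoding of
"twice as often as the pocket, five times more than helix positional
variables, 50 times more than the remaining residues". Energies are
delta-evaluated (only interactions involving moved atoms are recomputed)
and the running total is re-anchored by a full evaluation at stage end.

## Scoring

Per-term weights were fitted by the original authors on a private
set of membrane-protein structures and never published. Two modes are
provided: raw unit weights (`score_report`, useful for single models and
for tests where directionality is what matters) and per-term z-score
normalization over the current ensemble (`score_ensemble`, used at the
checkpoints) with unit top-level weights. Lower is better throughout.
Penalty constants `k_tilt`, `k_elev`, `k_loop` default to 1 per °, Å, Å²
respectively — the proportionality constants are likewise unpublished.

Pocket detection is voxel-based (0.8 Å grid): empty voxels not covered by
bulk solvent (bulk = probe-accessible region flood-filled from the box
boundary, dilated by the 1.4 Å probe) are clustered; clusters with no
contact with bulk solvent are *buried* cavities (the packing-defect
signal), clusters touching it are surface concavities, which the original
authors note add noise — hence only buried pockets enter the packing terms.

Hydrophilic exposure evaluates only the membrane-embedded mid-third of the
bundle (by Cα projection onto the bundle axis), with per-residue reference
areas computed on an extended Gly-X-Gly tripeptide by the same
Shrake–Rupley routine — self-consistent rather than tabulated. Both stated
variants (groups ≥ 25 % exposed; all polar groups) are computed and
independently weighted, resolving the spec's open question by inclusion.

For the serine hydrogen-bond criterion ("S5.42 and/or S5.46"), the filter
uses the best single-serine energy against the −0.2 kcal/mol threshold —
the "and/or" phrasing makes a combined sum unnecessary, and per-residue
energies are the more conservative reading.

## Docking and selection

`dock_ligand` is a minimal grid-map docker: four receptor maps (vdW with a
carbon probe, electrostatic potential under ε(r) = 4r, hydrogen-bond and
hydrophobic wells) at 0.5 Å spacing, restarted ligand MC against them, and
1 Å heavy-atom RMSD deduplication of the stored stack (~30–40 poses
typical). It exists to exercise the selection logic end to end — pose
evaluation, the three-criterion filter, unique-agonist ranking with
enantiomer collapsing — which is the contribution being reproduced; it is
not a production docking engine.

APF grids use a Gaussian kernel of half-width 1.0 Å at 0.5 Å spacing
(unspecified in the source); donor density is placed on polar hydrogens
(the donated proton), acceptor/charge/size/electronegativity on heavy
atoms, with standard Pauling electronegativities and vdW radii as the
atomic tables.

## What the synthetic fixtures do and do not establish

`make_ideal_bundle` builds mathematically ideal α-helices on a ring
(default radius 11.5 Å, giving ~10 Å nearest-neighbour axis separations as
in real 7TM bundles), antiparallel alternation, no clashes below 3.0 Å.
It scores zero on every orientation penalty and has no buried pockets — the
null reference the scoring tests lean on. `make_pocket_bundle` spins three
helices so an aspartate, two serines (i, i+4) and two phenylalanines face
the interior, emulating the D3.32/S5.42+S5.46/F6.51+F6.52 motif; its
aspartate-to-serine distance falls inside the 12 ± 2 Å anchor window by
construction. `make_decoy_set` applies the stated randomization at graded
fractions of the full amplitudes.

What these fixtures do **not** have: sequence diversity (poly-Ala bodies),
loops, kinks and bulges, lipids and water, or crystallographic detail. A
green recovery or funnel test therefore establishes that the optimizer,
restraints and filters behave as specified on a well-posed instance — not
that the pipeline predicts real receptor structures at the accuracy the
original study reports against crystal structures; those comparisons need
external PDB inputs and multi-day sampling, both outside this package's
test scale.

The (R)-NPA and (S)-cyanopindolol fixtures are built from packaged SMILES
at run time (RDKit ETKDGv3, fixed seed 42, lowest MMFF energy of 10
embeddings — the multi-embedding selection makes the conformer stable
across seeds). The 8 Å catechol-O-to-amine-N span of (R)-NPA is the one
ligand geometry the acceptance report checks.

## Numerical choices and degenerate inputs

* Grid volume/area: voxel-center counting at 0.5 Å (0.8 Å in ensemble
  scoring for speed); the single-sphere oracle is reproduced within 2 %.
  Duplicate-coordinate atoms are tolerated (they simply co-occupy voxels).
* SASA: Shrake–Rupley with 240 sphere points (480 for the Gly-X-Gly
  references).
* Superposition: Kabsch with reflection excluded; checked against an
  independent quaternion (Horn) implementation at 1e-8.
* Ties: checkpoint survivors and accepted poses break ties by index;
  `rank_models` breaks agonist-count ties by total score.
* Zero-length loops, empty pockets, ligand-free states and empty tether
  lists all degrade to zero-valued terms or explicit warnings rather than
  errors; a missing anchor residue or tether residue is a hard error
  naming the residue.

## Known limitations

* The surrogate force field reproduces the *logic*, not the energies, of
  the original protocol; absolute scores and thresholds do not transfer.
* Backbone moves in stage 4 rotate the chain tail within one helix, which
  is a crude torsion-space move set; helix ends are kept anchored.
* Residue templates cover Ala/Gly/Ser/Asp/Phe/Lys — enough for the
  synthetic pocket motif, not for arbitrary sequences.
* Single-chain receptors only; loops are scored by proxy (the 3.2 Å per
  residue span rule), never built.
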