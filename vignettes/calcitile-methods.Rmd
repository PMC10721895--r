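---
title: "Methods: designing and scoring protein templates for CaCO3 nucleation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing and scoring protein templates for CaCO3 nucleation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcitile)
```

`calcitile` models the computational workflow behind protein-templated
calcium carbonate nucleation: building flat helical-repeat protein
templates, characterizing their carboxylate surface lattices, matching
those lattices against mineral surface nets, docking templates onto slabs,
and evaluating the solution thermodynamics that set the nucleation driving
force. This vignette explains the models, the parameters that matter, and
the design choices made where the methodology was genuinely open.

## Idealized repeat-protein backbones

A designed helical repeat (DHR) protein is a tandem array of
helix-turn-helix units. The builder places each helix with ideal
α-helical geometry — 1.5 Å rise and 100° twist per residue, with N, Cα, C
and O on fixed cylindrical offsets — and relates successive repeats by a
*pure translation* of magnitude `d_rep` (the inter-repeat distance, 5–20 Å
supported; helix lengths sample the 16–30 residue range). The two helices
of a repeat occupy two layers 10 Å apart; loops are straight-line
placeholders bowed past the helix ends, carried for completeness but
excluded from scoring. A hard-sphere check (3.0 Å between non-bonded Cα
atoms) rejects self-clashing geometries and names the offending residue
pair.

Because the repeat transform is a translation, the backbone is flat by
construction: the superhelical radius is effectively infinite (500 nm bias
target), rise and curvature per repeat are zero. `measure_repeat_spacing()`
fits a least-squares axis through each helix's Cα atoms and reports the
mean perpendicular distance between corresponding axes of adjacent repeats;
the reported "spacing" of a template is this axis-to-axis distance.
The measurement convention is a package decision — the alternative
(Cα-lattice spacing) differs only in its sensitivity to helix phase.

## The flattening protocol

Real design pipelines relax a repeat protein to a perfectly flat, periodic
idealization before surface matching. `flatten_model()` evaluates a grid of
candidate inter-repeat distances (default 8–15 Å in 0.1 Å steps, i.e. 71
candidates) and, for each, relaxes the repeat unit by seeded Metropolis
Monte-Carlo over torsion-like moves — a rotation of all downstream atoms
about a Cα–Cα axis, applied identically in every repeat so repeat symmetry
is explicit. The score combines:

* harmonic distance restraints holding adjacent-repeat Cα distances at the
  candidate target (weight 10),
* internal strain: intra-repeat Cα pair distances restrained at their input
  values (weight 1),
* interface strain: adjacent-repeat Cα contacts restrained at the distances
  implied by the input's *straightened* repeat transform (weight 1), and
* a soft-sphere Cα repulsion below 3.5 Å (weight 5).

The straightened reference spacing is the centroid-to-centroid chord of
adjacent repeats, which is what a bent input's repeat transform preserves;
restraining to it makes the grid minimum recover the generative spacing of
a synthetic bent input to well within 0.2 Å, while curvature and twist are
removed exactly because candidates are constructed by pure-translation
propagation. The 180° first/middle/last angle and 0° first-to-last dihedral
constraints are therefore satisfied identically (they are still measured
and reported per candidate, and a convergence warning fires if they ever
exceed 1°). The flatness constraints mirror the constrained-minimization
formulation of the original design protocol; the score here is a
geometric/steric surrogate, so the specific optima that an all-atom energy
function would select for real designs (e.g. 8.7/10.6/11.4 Å for the
packaged designs) are inputs taken from the published protocol, not
quantities this package re-derives.

The Monte-Carlo temperature schedule is geometric from 1.0 to 0.01 over the
step budget (configurable; at zero temperature acceptance is strictly
downhill and the accepted-score trajectory is non-increasing). Identical
seeds give bit-identical results. Selected models "within 1 Å" of the
optimum (`selection_window = 1.0`) are the ones carried into docking,
matching how flattened ensembles are used in practice.

## Surface arrays, fixtures and recoding

A template's business end is its carboxylate array. `extract_surface_array()`
takes one anchor per *slot* per repeat: the slot Cα projected 1.5 Å along
the surface normal, a coarse Cβ proxy (side-chain rotamers are handled
separately in docking). Packaged face specifications pin the slot counts
that reproduce the published design totals: 6 slots/repeat for FD31 (36
carboxylates at 6 repeats, 18 at 3, 54 at 9), 7 for DHR49-Neg (42 positions
= 24 Asp + 18 Glu), and 4 notional slots for FD15 — FD15's true slot count
is not published, so its totals are flagged `verified = FALSE` and only its
0.9 nm spacing is treated as a design fact.

The recoding variants substitute positions of the FD31 array: half to
glutamine (18, checkerboard parity), 24 to aspartate (the first four slots
of every repeat), and 13 to lysine (an explicit spread pattern). Which
specific positions were substituted is not published; the packaged maps are
explicit `(repeat, slot)` tables chosen to reproduce the published counts
exactly, so composition arithmetic (e.g. net charge −36 + 2·13 = −10 for
the Lys variant) is independent of the pattern choice.

`array_geometry()` reports the interface extents as the anchor bounding box
along the repeat axis and the helix axis plus a 1.0 nm margin per side —
roughly a glutamate side-chain reach plus a van der Waals radius — rounded
to 1 nm. With the packaged slot geometry this reproduces the published
5 × 8 nm (6 repeats), 5 × 5 nm (3) and 5 × 11 nm (9) interfaces. Row
spacing is the measured repeat spacing in nm; note that the DHR49-Neg
idealized spacing of 10.6 Å rounds to 1.1 nm at this precision although it
is conventionally quoted as ~1.0 nm.

## Mineral surfaces

The bundled calcite cell is the standard 25 °C hexagonal setting of R-3c
(a = 4.988 Å, c = 17.061 Å) with all 30 sites listed explicitly. The
hexagonal cell is a *triple* cell of the rhombohedral lattice, so slab
construction works in the primitive lattice (the R-centering translations
are honoured); this matters — it is what produces the familiar 4.99 × 8.10 Å
(104) surface cell rather than a spuriously long second vector. Vaterite is
structurally ambiguous in the literature; the bundled `vaterite_cell_synthetic()`
is a synthetic orthorhombic approximant, labelled as such, intended only to
expose a {010}-type ion net and replaceable by any user-supplied cell.
Carbonate groups are planar C + 3 O rigid units; point charges are Ca +2,
carbonate O −2/3 (carbonate −2 in total), keeping every cell neutral.

`build_slab()` cuts a Miller-indexed slab with the outward normal along +z
and the topmost layer at z = 0. Indices are gcd-reduced on construction (so
{202} reduces to the {101} plane family, as in the 3-index hexagonal
convention). The termination is the densest single layer of the stacking
period, tie-broken towards a Ca-containing layer; if a cut leaves more than
one formula unit of net charge (|q| > 2), bottom layers are trimmed.
`extract_net()` reduces the in-plane cell to the Lagrange–Gauss shortest
basis and keeps the ions within a tolerance of the surface as the motif.
Surface relaxation, reconstruction and hydration layering are out of scope.

## Epitaxy scoring

Lattice matching is made explicit rather than left implicit in docking
energetics. `row_mismatch()` minimizes the supercell strain
ε = |m·s_array − n·s_net|/(n·s_net) over 1 ≤ m, n ≤ 4 (default) for every
row family of the net (coprime directions up to index 3);
`scan_orientations()` rotates the template (1° default step; coarser in
test settings), optimizes the in-plane translation on a 1/10-cell grid with
local refinement, and reports the fraction of anchors within a 0.1 nm
capture radius of a net site. Templates are projected to 2D using a basis
built from the global axes projected onto the template plane, so the
template's in-plane orientation is preserved and jointly rotating template
and surface leaves results unchanged. `rank_surfaces()` orders candidate
nets by matched fraction, tie-broken by lower strain and then stable input
order. The continuous translation optimum is not pursued: at 0.1 nm capture
radii the grid-plus-refinement search is already below the anchor
positional noise of real models.

## Docking and the binding score

`mc_dock()` is Metropolis Monte-Carlo over rigid-body poses: translation
moves of 0.5 Å, in-plane rotation moves of 5°, tilt moves of 1° bounded at
±10°, geometric temperature schedule, best pose retained. Each trajectory
starts from a random in-plane rotation at contact height. The interface
score is a deliberate coarse-grained simplification — screened Coulomb
(Debye length 8 Å, appropriate for ~10 mM ionic strength) plus a soft
Lennard-Jones term, evaluated over anchor–ion pairs within a 15 Å cutoff by
a cell-list neighbor search; pairs below hard-sphere contact are clamped
and flagged rather than raised as errors. Its absolute values are not
comparable to all-atom energies; only pose ranking and the baseline
subtraction below are meaningful.

Side-chain flexibility is reduced to a discrete anchor-offset library
(default 5 offsets mimicking a carboxylate rotamer sweep), with one state
chosen per within-repeat slot and applied at every repeat — repeat symmetry
by construction. Selection is greedy in a seeded random slot order; for
well-separated slots this is exact (and is tested against exhaustive
enumeration in that regime).

The binding score subtracts the median energy of an ensemble of separated
configurations: 15 poses (count configurable, forced odd) at 10 nm
separation under random in-plane rotations. A trajectory that never
approaches the surface therefore scores exactly zero. The published
protocol does not state its ensemble size; 15 is the package default.

## Nucleation thermodynamics

`speciate()` solves the closed-system carbonate equilibria for the mixed
solution (defaults: 5 mM CaCl₂ + 5 mM NaHCO₃, the standard templating
condition), with Na⁺ and Cl⁻ carried from the salts, pH from the full
charge balance by root bracketing, Davies activity coefficients iterated to
self-consistency (valid to ~0.1 M, ample for mM solutions), and ion pairing
neglected. CO₂ exchange with the atmosphere is neglected over experiment
timescales. The bundled constants (pK1 6.352, pK2 10.329, pKw 13.997; pKsp:
calcite 8.48, aragonite 8.336, vaterite 7.913, ACC 6.40) are standard 25 °C
literature values with source annotations. Under the default condition the
computed pH is ≈ 8.2 and the saturation indices order as
SI(calcite) > SI(aragonite) > SI(vaterite) > 0 > SI(ACC): supersaturated
with respect to all three crystalline polymorphs, undersaturated with
respect to amorphous CaCO₃.

`cnt_barrier()` implements classical nucleation theory,
ΔG(r) = −(4/3)πr³·kT ln S/v + 4πr²γ, with r* = 2γv/(kT ln S) and
ΔG* = 16πγ³v²/(3(kT ln S)²), and the spherical-cap heterogeneous factor
f(θ) = (2 + cos θ)(1 − cos θ)²/4. One caveat the schematic language of
"reducing the critical radius" glosses over: in spherical-cap CNT the
critical *radius of curvature* is unchanged by the template while the cap
*volume* shrinks by f(θ) — the result object reports both rather than
conflating them.

## Analysis formulas

`number_density()` converts molarity to particles/mL (c·N_A/1000;
1.08 µM → 6.5 × 10¹⁴/mL). `mre_convert()` divides the raw CD signal by
N·C·L·10. `particle_stats()` reports mean ± sample SD (n − 1) to 0.1 nm.
`scaling_fit()` regresses 1/(πS²) — the surface area of a sphere of
diameter S; the plain S² convention is available since the published
convention is not stated — against template interface area.
`template_size_series()` packages the published summary statistics
(n = 172/150/147; S = 9.1 ± 2.9, 5.5 ± 0.9, 4.7 ± 0.8 nm for the 3/6/9
repeat templates); raw per-particle measurements are not available and are
not synthesized as if they were.

## Problem sizes, determinism and limitations

The test suite exercises the protocols at deliberately modest sizes: toy
topologies with 16-residue helices and 3–4 repeats for flattening
(constraint satisfaction and spacing recovery over the full 71-candidate
grid on 20 random bent inputs), 3-repeat arrays and ~2–4 nm slabs for
docking, and rectangular synthetic nets for epitaxy oracles. These sizes
are chosen so each property is tested at full protocol fidelity while the
suite stays quick; the protocols scale to full-size designs (6–9 repeats,
10 nm slabs) with proportional cost.

All stochastic operations take explicit integer seeds and are
bit-reproducible under a fixed seed on a fixed platform. The synthetic
inputs emulate geometric features of real designs — spacing, curvature,
lattice composition — but not side-chain chemistry, solvent structure or
all-atom energetics, so passing tests demonstrate correctness of the
geometry, search and bookkeeping, not predictive accuracy for real
nucleation outcomes. Known limitations: the interface energy model is
coarse-grained; vaterite is an approximant; loop placeholders are not
chemically realistic; and experimental observables (polymorph selection,
particle sizes, TEM number densities) enter only as packaged summary data
for the analysis module, never as quantities the simulations claim to
reproduce.
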