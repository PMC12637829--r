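---
title: "Quantifying amyloid fibril geometry, stability and mechanical unfolding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amyloid fibril geometry, stability and mechanical unfolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibriltools)
```

Amyloid fibrils are helical stacks of identical protein chains.  The
same sequence can fold into several distinct fibril polymorphs, and for
prion proteins such as yeast Sup35 the polymorph determines the
heritable strain phenotype: how stable the fibril is, how easily
chaperones fragment it into new seeds, and therefore how strongly the
prion propagates.  `fibriltools` implements the quantitative analyses
this picture rests on — helical geometry, layer planarity, a
solvation-based stabilization free energy, chaperone-site
accessibility, and worm-like-chain analysis of single-molecule pulling
experiments — together with seeded generators of synthetic inputs whose
ground truth is known exactly.

## Fibril models and layer ordering

A `fibril_model` is a flat atom table plus a layer ordering.  Layers
are chains; `order_layers()` sorts them by the projection of their
C-alpha centroids on the fibril axis and records the central layer
(even stacks take the lower of the two middle chains, a stated
tie-break so results are reproducible).  Author residue numbering is
kept throughout because core regions are quoted by sequence position
(e.g. a core spanning residues 69–132).  Van der Waals radii are
assigned from a fixed Chothia-style table (C 1.87, N 1.50, O 1.40,
S 1.85 Å) rather than read from files, so surface areas are a function
of coordinates alone.

mmCIF is parsed with a column-order-tolerant `_atom_site` reader
(author numbering preferred over label numbering); PDB files go through
`bio3d`.  Altlocs keep the highest-occupancy conformer; insertion codes
are rejected — fibril depositions do not use them, and silently
renumbering would corrupt span arithmetic.

## Helical geometry

`estimate_axis()` fits a least-squares line through per-layer
centroids.  `measure_rise_twist()` computes the optimal rigid transform
between consecutive layers (Kabsch superposition) and decomposes it as
a screw motion: the rise is the translation along the screw axis, the
twist the signed rotation about it, averaged over layer pairs with the
spread reported as a quality metric.  The sign convention is the
right-hand rule about the axis oriented from the first to the last
layer; a fibril with +3.95° twist per layer is right-handed.  The
crossover distance — the length over which a twisted fibril completes a
half turn, the quantity measured from fibril images — is
`rise * 180 / |twist|`.

Layer planarity ("warping") is summarized by two RMSDs over the core
C-alpha atoms of one layer: distance from the plane normal to the
fibril axis through their centroid, and distance from the
orthogonal-least-squares best-fit plane.  The central chain is used by
default because edge chains lack neighbours on one side; the residue
spans are an explicit argument, since published values do not always
state whether a trimmed core was used.  Optimality of the least-squares
plane guarantees best-fit ≤ normal-plane, which the tests assert as an
invariant.

One geometric subtlety is worth recording.  For a sinusoidal
out-of-plane displacement the RMS about the axis-normal plane is
exactly `amplitude / sqrt(2)`.  The best-fit plane, however, tilts
toward any component of the displacement field that is correlated with
the in-plane coordinates; for a full-period sinusoid along a
U-shaped backbone path this correlation is substantial and the best-fit
RMSD drops well below `amplitude / sqrt(2)`.  A half-chain-period
sinusoid on the U-bend template is orthogonal to both in-plane
coordinates, so the tests pin the `amplitude / sqrt(2)` identity on
that construction and treat the tilted full-period case through the
invariant only.

## Stabilization free energy

The per-layer stabilization energy uses the classic atomic solvation
parameter (ASP) model: the free energy of transferring surface area
between solvent and buried states,

    dG_stab(chain) = sum_atoms ASP(class) * (A_fibril - A_reference)

with areas in Å² and ASPs in kcal/(mol·Å²).  Burying apolar carbon is
favourable, burying charged nitrogen or oxygen costly.  The default
parameters are the Eisenberg–McLachlan transfer values (+0.016 apolar
C, −0.006 uncharged N/O, −0.024 carboxylate O, −0.050 charged N,
+0.021 S); they live in an editable, JSON-serializable
`solvation_params` object, and `calibrate_solvation_params()` can
rescale the whole set against a user-supplied table of reference
energies, because legacy implementations of this model differ in their
exact parameterization.  Negative values are stabilizing; chains are
scored in a ≥5-layer context (extended by helical symmetry when the
input stack is shorter) so that both axial neighbours are present.

SASA is computed with a deterministic sphere-sampling algorithm: 960
Fibonacci-lattice points per atom, probe 1.4 Å, hydrogens excluded.
There is no RNG anywhere in the surface code, so energies are exactly
reproducible; the lattice does not rotate with the molecule, so areas
are rotation-invariant only to quadrature precision (about 0.5 %,
verified against closed-form one- and two-sphere areas in the tests).

The reference state is the package's main open design decision.  The
default `extended_chain` rebuilds the scored chain with extended
backbone dihedrals (phi −140°, psi 135°, omega 180°; ideal bond
geometry) and transplants everything beyond the backbone rigidly in
each residue's local N–CA–C frame.  This keeps a one-to-one atom
correspondence (required for the per-atom area difference), counts both
intra-layer side-chain packing and inter-layer burial as stabilizing —
necessary, because a polymorph can owe its instability specifically to
missing intra-layer contacts — and avoids a rotamer library, at the
cost of retaining the deposited rotamers in the reference.  An
`isolated_chain` mode (deposited conformation, neighbours deleted)
isolates the inter-chain contribution alone.

`subunit_decomposition()` splits the per-layer energy over residue
spans either additively (`in_context`, summing per-residue terms, which
exactly partitions the chain total) or by rebuilding the fibril with
only one subunit present in every layer (`alone`), which measures what
a subunit would contribute without its partner.  Per-residue energies
feed `energy_map_values()`, clipped to ±2.5 kcal/mol, the conventional
rendering scale of stability maps.

## Chaperone accessibility

Fibril fragmentation by the Hsp104/Ssa1/Sis1 machinery starts with
Ssa1/Sis1 binding a specific Sup35 region (residues 143–164 by
default).  `chaperone_sequence_distance()` measures how far the ordered
core ends from that site in sequence — zero iff they overlap, otherwise
the count of residues strictly between the nearest boundaries.
Sequence separation (not 3D distance) is the axis used in
structure–phenotype landscapes, because the intervening residues are
disordered and their spatial position is not defined; a 3D variant
(`site_min_distance()`) is provided for completeness.
`strain_landscape_table()` assembles polymorph records (energy,
distance, population fraction) into a deterministic coordinate table
and validates that fractions within one fibril preparation sum to at
most 1.  No phenotype is predicted — the table holds coordinates only.

## Worm-like-chain force spectroscopy

In the pulling experiment a single protein is tethered between two
2,000 bp dsDNA handles and stretched quasi-statically between about 2
and 35 pN.  Both elastic elements are Marko–Siggia worm-like chains;
elements in series add extension at equal force.  Defaults, all
user-configurable with units: handle persistence length 45 nm and
0.338 nm/bp (total handle contour 1352 nm), unfolded-polypeptide
persistence length 0.65 nm and 0.365 nm of contour per residue,
temperature 298 K (kT = 4.114 pN·nm), and no folded-offset correction —
the folded end-to-end distance of an intrinsically disordered protein
is not well defined, so the conversion from contour-length gain to
residue count deliberately omits it.  These are standard values for
this instrument class; published pulling datasets rarely state their
exact conversion constants, so these are documented package defaults,
not inferred quantities.

An unfolding rip is an abrupt force drop while the trap position keeps
increasing.  Detection uses a slope-corrected step filter: at each
sample a line is fitted to the preceding 15 points and the mean
shortfall of the next 5 points below its extrapolation is compared
against `max(4 * sigma, 0.5 pN)`.  The slope correction matters because
near rupture the loading curve is steep, and a plain smoothed
difference dilutes the drop by the loading slope.  Each inter-rip
branch is then fitted with the tether model with a single free
parameter, the unfolded protein contour length, by least squares in
force space — extension is the clean trap coordinate and the noise
lives in force, so fitting in extension space would push low-force
points (with compliances of tens of nm/pN) to dominate and bias the
estimate.  The branch estimates are deliberately not clamped at zero:
the folded branch's true contour parameter is zero, and truncating the
noise distribution there would bias every contour-length difference.
The rip size is the contour gain between adjacent branches divided by
0.365 nm/residue; the rupture force is the fitted pre-rip branch force
at the last sample that still tracks that branch.

Detectability has a physical boundary: the force drop at a rip is the
released extension times the local tether stiffness, so small segments
rupturing at low force produce drops below the noise floor.  A
20-residue rip is resolvable above ~12 pN, while 100+-residue rips are
visible down to ~6 pN.  The recovery tests sample their cohort inside
this resolvable regime (20–200 residues, matching the range seen in
Sup35 pulling data) and verify sizes within ±2 residues and rupture
forces within ±0.5 pN over 100 seeded pulls.

## Synthetic data

`make_ideal_fibril()` builds idealized cross-beta stacks: C-alpha atoms
at 3.8 Å spacing along a linear, U-bend or S-fold in-plane path (or any
user path), N/C/O/C-beta placed by idealized local geometry with
backbone carbonyls along the stacking axis and side chains alternating
above and below the sheet, an optional sinusoidal out-of-plane warp,
helical stacking at a chosen rise and twist, and seeded Gaussian
coordinate noise.  The ground-truth record carries the exact rise,
twist and warp displacement field, and every downstream test compares
against that record rather than against copied numbers.

`simulate_fec()` produces quasi-static stretch/relax pairs of the
dual-handle tether: each programmed segment joins the unfolded contour
when the force first crosses its rupture force, force noise is seeded
Gaussian, and the default sampling of 10 points/nm corresponds to a
kHz-class instrument pulling at 100 nm/s.  There are no Bell–Evans
kinetics: rupture forces are programmed, not drawn from a
loading-rate-dependent distribution, which is sufficient to exercise
rip detection and the size/force scatter but does not emulate the
stochastic spread of repeated pulls of a real molecule.  Refolding on
the relax branch is likewise absent: refolding rips are rare for
intrinsically disordered proteins, and the analysis pipeline consumes
stretch branches only.

What passing these tests shows — and does not show.  The synthetic
fibrils have ideal stoichiometry, no missing atoms, no alternate
conformations and poly-alanine side chains; real deposited models have
full side chains, occasional gaps, and coordinate error of refinement.
The energy machinery is therefore verified for correctness of its
arithmetic (closed-form SASA oracles, hand-computable burial, exact
additivity), not for agreement with any published per-polymorph value,
which requires the deposited coordinates as input.

## Numerical choices

* Sphere sampling: 960 points; single-sphere quadrature error ~1e-16
  by symmetry, two-sphere caps within 1 %.
* WLC inversion: bracketed root-finding to 1e-14 relative; the
  simulator and branch fits use a cached 4001-knot monotone spline of
  the unit-contour inverse (error well below instrument noise), while
  `wlc_extension()` itself stays exact.
* Best-fit planes: SVD of the centered cloud; collinear clouds (second
  singular value below 1e-9 of the first) are rejected as degenerate.
* Screw decomposition: rotations near 180° take the axis from the
  dominant column of R + I; pure translations report zero twist.
* Degenerate inputs: duplicate atom coordinates abort SASA; overlapping
  residue spans abort counting; fractions above 1 per preparation abort
  the landscape table.

Problem sizes in the shipped tests were chosen to keep the full suite
around a quarter of a minute on one core: layers of 10–64 residues,
stacks of up to 7 layers (100 for the rotation-composition check), and
100-curve pulling cohorts at 10 samples/nm.

## Known limitations

* The ASP parameter set is a documented default, not the (unpublished)
  parameterization of legacy fibril-energy programs; absolute energies
  for deposited structures should be interpreted after calibration
  against a reference table.
* Only single-start helices are modeled; multi-protofilament fibrils
  are handled as stacked chains, with no interface classification.
* The extended reference keeps deposited rotamers; a rotamer-library
  reference would change absolute (not relative) energies.
* Rip detection assumes quasi-static pulls with monotone trap motion;
  hopping between states within one branch is not modeled.
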