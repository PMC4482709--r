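---
title: "Methods: trajectory superposition, correlated motions, hydration and grafting in poretraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory superposition, correlated motions, hydration and grafting in poretraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

poretraj implements the desk-scale analysis suite used to characterise early
channel-opening events in microbial rhodopsin channels such as the C1C2
channelrhodopsin chimera: how a trajectory is superposed on a crystal
reference, how coupled helix motions are quantified, how constriction
contacts and pore hydration are monitored, and how a 13-cis retinal
chromophore is modelled into an all-trans binding site. This vignette
documents the models, their assumptions, the tunable parameters, and the
numerical choices, in the package's own terms.

## Structures, trajectories and selections

A `mol_structure` is an ordered atom table (PDB-style identities plus
coordinates in Ångström); a `mol_trajectory` adds a fixed topology, an
`n_atoms x 3 x n_frames` coordinate array, and a frame interval in
nanoseconds. Multi-model PDB is the canonical trajectory format: it is
plain text, viewable in any molecular viewer, and forces the topology
consistency the analyses assume. Binary formats (DCD/XTC), periodic-boundary
unwrapping, and mmCIF are out of scope; trajectories are assumed wrapped
with the channel contiguous.

Atom selections are disjunctions of conjunctive clauses over chain, residue
number (1-based, ranges inclusive on both ends, following PDB convention),
residue name, and atom name. Resolution is deterministic and ordered by
atom index. A clause naming an unknown chain warns and matches nothing,
rather than failing a whole analysis over a typo. Waters are recognised
under the HOH/TIP3/WAT/SOL dialects; alternate-location conformers other
than blank/"A" are dropped at parse time (single-conformer analysis, the
usual starting point of an MD setup). Since transmembrane helix boundaries
are rarely published alongside a structure, every fit/measure/region helix
range is user-supplied configuration, never hard-coded.

## Superposition and RMSD

`kabsch_fit()` solves the weighted least-squares rigid superposition by
singular value decomposition of the 3x3 cross-covariance, with the smallest
singular vector sign-corrected so the rotation determinant is +1 —
reflections are never returned, even for nearly planar point clouds.
Degenerate inputs (fewer than 3 pairs, collinear clouds) are errors:
the rotation about a line is undetermined. Weights default to uniform;
for the C-alpha-only selections used throughout, mass weighting would be
immaterial anyway.

`superpose_trajectory()` fits each frame independently onto a reference
selection and applies that frame's transform to all atoms. Fit and measure
selections are deliberately independent parameters: one typically fits on
all transmembrane helices for RMSD work but on a stable helix subset
(e.g. TM3–5) before correlation analysis, and the package does not conflate
the two. `rmsd_series()` assumes — and documents — that superposition has
already been applied; it never re-fits. "Residue-averaged RMSD" is read as
a per-residue, time-pooled RMSD profile along the sequence (root of the
mean squared deviation over frames and the residue's selected atoms); the
other reading, a per-frame RMSD averaged over atoms, is exactly what
`rmsd_series()` returns, so both interpretations are available.

A point worth knowing when fitting on fluctuating atoms: per-frame fitting
subtracts the fit selection's own mean displacement from every atom, which
biases displacement correlations among the remaining atoms. This is a
property of trajectory fitting, not of any implementation. It is why the
demo keeps its fit helices quasi-static (the analogue of fitting on the
structurally stable core) and why correlation-recovery checks are run
without rigid-body noise and without fitting.

## Dynamic cross-correlation (DCCM)

`dccm()` computes the standard normalised covariance of C-alpha
displacement vectors,

$$C_{ij} = \frac{\langle \Delta\mathbf{r}_i \cdot \Delta\mathbf{r}_j \rangle}
{\sqrt{\langle |\Delta\mathbf{r}_i|^2\rangle\,\langle |\Delta\mathbf{r}_j|^2\rangle}},$$

with displacements relative to the trajectory-mean position by default
(the crystal-referenced variant is available through the `reference`
argument). The matrix is symmetric with unit diagonal and entries clamped
to [-1, 1]; atoms with zero displacement variance get NA rows/columns and
a warning. `region_pair_report()` lists residue pairs between two regions
at or above a high threshold (0.7 is the conventional strong-coupling
bound) and strictly below a low threshold (0 by default: anticorrelated
pairs), the tabular counterpart of circling coupled helix blocks on a
correlation map. "Cytoplasmic half" of a helix is whatever residue
sub-range the user supplies — the package does not guess membrane topology.
`correlation_to_structure()` paints one matrix row into the B-factor column
for viewer-based colouring, at PDB's two-decimal precision.

## Contacts and hydrogen-bond events

Constriction interactions (e.g. Glu121–Arg307, Glu122–His173,
Glu129–Asn297 in C1C2 numbering) are tracked as per-frame distances:
either a named atom pair or the minimum heavy-atom distance between two
groups, the robust standard when a figure plots "the distance" between two
residues without naming atoms. Default side-chain groups follow the field's
convention (carboxylate OE/OD oxygens against guanidinium/amine/imidazole
nitrogens).

`contact_states()` converts a distance series into formed/broken states
with hysteresis: formed breaks above `break_cutoff`, broken reforms at or
below `formed_cutoff`. Defaults are 3.5/4.5 Å for hydrogen bonds and
4.0/5.0 Å recommended for salt bridges; the band suppresses cutoff chatter
so that "disrupted and reformed" events are countable rather than numbering
in the hundreds. Ties at a cutoff count as formed (the ≤ convention, tested
explicitly). The initial state is formed iff the first distance is at or
below `formed_cutoff`; this choice keeps occupancy monotone in both
cutoffs. Event lists alternate by construction and replay exactly to the
per-frame state vector.

## Water density, wires, and pore radii

`water_density()` bins water-oxygen positions into an axis-aligned grid
(default 1.0 Å voxels) and normalises counts as
`count / (voxel volume x n_frames x frame_interval_ns)`, i.e.
molecules Å⁻³ ns⁻¹ — the probability-density unit channel hydration maps
are contoured in, with 0.0015 as the conventional level. This normalisation
is dimensionally the printed unit and keeps an exact conservation identity:
`sum(values) x voxel volume x total ns` equals the integer count of in-grid
water observations. A per-frame-average variant (VolMap-style occupancy
density) is available behind a flag. Waters outside the grid are tallied,
not silently dropped. Maps serialise to OpenDX with the z-fastest data
ordering standard viewers expect.

The "water channel formed" criterion is operationalised as graph
connectivity: nodes are water oxygens (optionally plus protein polar heavy
atoms), edges join pairs within the hydrogen-bond heavy-atom cutoff
(3.5 Å), and a frame is *spanning* when any node in the lower z-slab is
connected to any node in the upper z-slab. The two slabs are user-configured
z-intervals standing for the intra- and extracellular membrane boundaries
— membrane placement is system-specific. The reported path is a
breadth-first shortest path with ties broken towards smaller atom ids.
This is a stated operationalization of the qualitative "water-mediated
hydrogen-bond network connecting the two sides" criterion, not a published
exact rule; spanning is monotone in the cutoff and under adding waters,
which the tests assert. Hydrogens are not modelled anywhere in the
hydration analysis — the criterion is heavy-atom distance throughout.

`pore_radius_profile()` reports, per z-slice, the largest sphere centred
on a vertical axis that clears every atom by its Bondi van der Waals
radius. With the centre pinned to the axis this maximum has the exact
closed form `min_i(|p - x_i| - vdw_i)`, so no iterative search is needed;
an independent dense radial scan backs this in the tests. Slices
unconstrained within the search radius (default 10 Å) are reported at the
bound and flagged. This is a HOLE-style surrogate profile along a fixed
axis, not a full steepest-ascent pore walker.

## Chromophore grafting

`graft_fragment()` reproduces the standard isomer-replacement modelling
move: superimpose a donor fragment (a Lys–13-cis-retinal) onto the bound
acceptor fragment (Lys–all-trans-retinal) over name-defined anchor pairs —
main-chain C, O, N, CA plus the β-ionone ring atoms — then transplant the
whole donor rigidly. Correspondence is by atom name, because that is how
the anchor set is defined; ring atoms are an explicit user-supplied list
(donor and acceptor naming dialects differ between structures), weighted
equally with the main-chain atoms by default. Rigidity guarantees every
donor internal distance and torsion is preserved (the 13-cis tail dihedral
survives the graft exactly), and the result is independent of the donor's
starting pose. An anchor RMSD above 2.0 Å warns but does not fail — a cis
fragment anchored on a trans one legitimately fits imperfectly. The
force-field energy minimisation that follows such a replacement in an MD
workflow is out of scope; `clash_check()` reports heavy-atom contacts
below 2.0 Å (excluding pairs bonded through the anchor junction) as the
desk-scale surrogate.

## Synthetic scenes and what they do (not) show

The generators plant the exact statistical structure each analysis assumes,
so every stage is tested closed-loop:

* `make_helical_bundle()` builds ideal C-alpha helices (rise 1.5 Å,
  100°/residue, C-alpha radius 2.3 Å) on a circle — a toy stand-in for a
  seven-transmembrane fold.
* `simulate_correlated_trajectory()` draws, per frame and Cartesian
  component, one latent Gaussian factor per helix; the factors carry the
  planted inter-helix correlations and all residues of a helix share their
  factor. A flat residue-level matrix with constant off-diagonal blocks
  and independent residues is not positive semi-definite, which is why the
  factor construction is used; it also makes the planted correlation the
  *exact* theoretical DCCM entry (the same rho applies isotropically to
  x, y, z), giving an analytic recovery target. The helix-level matrix is
  eigen-checked for positive semi-definiteness before sampling. Optional
  per-frame rigid-body noise (uniform random axis, uniform angle up to a
  bound; uniform direction and magnitude for translation) exercises the
  requirement that superposition precede RMSD and DCCM. A per-helix
  fluctuation scale lets some helices be quasi-static, emulating the
  stable core used as fit selection.
* `make_water_scene()` draws Poisson background waters uniformly per frame
  and adds an optional fixed chain of ≤3.5 Å-spaced points linking the two
  slabs in chosen frames, returning the planted per-frame spanning labels.
  Because the trajectory container requires a fixed topology, unused water
  slots are parked at a remote point far outside any grid or slab.
* `simulate_two_state_distance()` is a symmetric two-state Markov chain
  (persistence probability `p_stay` per frame, default 0.98 at a 0.1 ns
  frame interval) emitting formed/broken mean distances (2.8/8.0 Å) with
  0.2 Å Gaussian noise — the statistical skeleton of a hydrogen bond that
  breaks and reforms during a run.
* `make_toy_retinal()` builds a planar lysine-retinal stand-in with named
  main-chain anchors, a six-membered ring, and a polyene tail whose
  C12–C13–C14–C15 torsion is exactly 180° (trans) or 0° (cis); all bond
  lengths lie in 1.4–1.6 Å.

All generators are pure functions of their arguments and seed (the RNG
state is restored afterwards), so identical inputs give bit-identical
output.

What passing these tests does *not* show: the generators have no force
field, no solvent structure, no secondary-structure relaxation, no
anisotropic or time-correlated fluctuations, and no periodic boundaries.
They validate the *estimators* — that the DCCM recovers a known
correlation, that the wire detector equals exact connectivity, that
density bookkeeping is conservative — not that any particular protein
behaves a particular way. Conclusions about real channels still require
real trajectories.

## Problem sizes, defaults and numerics

Recovery checks run at the sizes at which their sampling error is well
inside the asserted tolerances: 10,000 frames and 140 C-alpha atoms for
DCCM and contact-occupancy recovery (correlation standard error well below
the ±0.05 band; binomial error below ±0.02), 100 random scenes for the
wire/connectivity oracle, 50 random 10-point instances against a 10°
axis-angle rotation-grid oracle for the Kabsch fit, 20 scenes for exact
density conservation. The two-scene demo uses 1200 frames at 0.125 ns
(a 150 ns-scale run) with a 7x20-residue bundle, ~48 background waters per
frame in a 40x40x60 Å box, and a 2.7 Å-spaced planted wire. These sizes
are the package's chosen test conditions and are also what
`scripts/acceptance.R` re-runs.

Numerical conventions worth restating: rotations are validated orthonormal
with determinant +1 to 1e-8; collinearity is detected via the second
singular value of the centred cloud; PDB coordinates must lie in
(-1000, 10000) to fit the fixed 8.3 columns (slightly tighter than the
format's nominal range, on the negative side, because "-1000.000" is nine
characters); DX round trips preserve voxel values to 1e-6; correlation
entries are clamped to [-1, 1] after the floating-point division; ties at
contact cutoffs count as formed; the BFS path tie-break is the smallest
atom-id sequence at equal path length.

## Known limitations

No periodic-boundary handling in distances or connectivity; no hydrogen
placement or angle-resolved hydrogen bonds (the angle criterion exists but
needs user-supplied hydrogen coordinates); element inference from atom
names does not resolve two-letter metals; the pore profile follows a fixed
vertical axis rather than a curved pore centreline; water identities are
slot-based in synthetic scenes, so per-molecule residence times are not
meaningful there.
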