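---
title: "Methods: landscape-guided pocket reshaping analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape-guided pocket reshaping analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketshaper)
```

This vignette is the package's own account of the models and numerical
choices behind each analysis stage: what is computed, under which
assumptions, which parameters matter, and what the synthetic validation
system does and does not establish about real data.

## The scientific setting

Family-1 glycosyltransferases (GT-B fold) transfer glucose from
UDP-glucose to an acceptor hydroxyl via an S~N~2-like mechanism: a
catalytic histidine deprotonates the acceptor oxygen, which then
attacks the anomeric carbon of the sugar donor. Acceptors with several
hydroxyls (tyrosol has a phenolic C4-OH and an alcoholic C8-OH) can be
glycosylated at either position when the binding pocket tolerates more
than one substrate orientation, producing regio-isomer mixtures.
Engineering campaigns that fix this work from conformational-ensemble
evidence: which residues hold the substrate in each orientation, how
often the reactive geometry is visited, and how easily product leaves
through the access tunnels. `pocketshaper` implements that evidence
chain as reusable, tested code, with a synthetic-ensemble generator
standing in for molecular-dynamics trajectories.

## Ensembles and geometric primitives

An ensemble is a topology table (atom name, element, residue number and
name, chain) plus an ordered list of N×3 coordinate frames in Å —
exactly the content of a multi-model PDB file, which is the package's
interchange format (read and written through bio3d, with validation of
per-model atom counts and coordinate fields). Coordinates are always Å;
no unit autodetection is attempted. Residue identity is keyed on
(chain, residue number); residue names are display/selection sugar.

Atom selections use a small expression language (`chain`, `resnum`,
`resname`, `name`, `element`, combined with `and`/`or` and
parentheses, `and` binding tighter). The special atoms of the
glycosylation problem — the acceptor hydroxyl oxygens, the donor
anomeric carbon, the catalytic histidine nitrogen — are always supplied
by the user as named selections; the package never infers them from
connectivity.

RMSD uses the Kabsch superposition: the optimal proper rotation from
the SVD of the cross-covariance, with the determinant-sign correction
so reflections are never applied (without that correction the optimal
alignment of mirror-related point sets is wrong — the two-atom example
in the test suite fails by a factor of about 3). Fewer than three atoms
or collinear geometry still yield a defined value but are flagged
degenerate. The radius of gyration is the mass-weighted RMS distance
from the centre of mass; masses default to uniform, which for Cα-only
selections is also the physically sensible choice.

`equilibration_window()` decides how much of a series to discard: the
earliest window start from which every sliding-window mean stays within
a tolerance of the final window's mean. The final window satisfies this
trivially, so the rule additionally requires the plateau to begin at
least one window before the end — otherwise a monotone drift would
always "equilibrate" in its last window. A drifting series is therefore
reported as not equilibrated rather than given a misleading start
index.

## Free-energy landscapes

The landscape is a Boltzmann inversion of a 2D histogram over two
reaction coordinates, by default Cα RMSD against a reference frame and
radius of gyration:

$$\Delta G_{ij} = -k_B T \,\ln\frac{P_{ij}}{P_{\max}},$$

with $k_B = 0.0019872$ kcal·mol⁻¹·K⁻¹ and $T$ defaulting to 300 K
(exposed as a parameter; reported ΔG scales linearly with it). Empty
bins are *unreachable* (`NA`), never assigned a finite ΔG — the
alternative (a large finite value) would create spurious minima at the
data boundary. The default grid is 40×40 with explicit edges
overridable; the last bin is right-closed so the maximum datum is
counted. Principal components are offered as alternative coordinates
(frames are superposed on the ensemble mean before the covariance is
taken, and the sign convention makes the largest-magnitude loading
positive), but RMSD/Rg remains the default pair.

Minima are occupied bins strictly below all occupied 8-neighbours;
candidates closer than a Chebyshev separation (default 2 bins) merge
into the deeper one, ties breaking lexicographically on the bin index.
The deepest basin is "global", the rest "local". A basin's
representative frame minimises the Euclidean distance to the bin centre
in per-axis z-scored coordinates — z-scoring because RMSD and Rg spans
differ and no metric is canonical; ties go to the lowest frame index.

Two estimates of the gap between basins are available. The peak-bin
difference `basin_ddg()` is the textbook reading of the surface but
inherits single-bin discretisation noise: when a basin's spread
straddles a bin edge its peak count drops and the gap shifts by up to a
few tenths of kcal·mol⁻¹. `basin_population_ddg()` instead integrates
counts over the (2r+1)² neighbourhood of each minimum (default r = 1)
and applies $k_BT\ln(N_a/N_b)$ — the well-population estimate, which on
generated two-basin systems recovers the planted occupancy ratio to
better than 0.01 kcal·mol⁻¹ independent of where the bin edges fall.
Validation binning is 12×12 for the 2000-frame synthetic systems so a
basin's jitter spread (σ ≈ 0.03 Å on each coordinate) sits well inside
one bin; the 40×40 default is appropriate for the broader, rugged
surfaces of real trajectories.

## Interaction fingerprints and hotspots

Interactions are detected geometrically, per frame:

| type | criterion | defaults |
|---|---|---|
| hydrogen bond | D–A heavy distance, D–H···A angle | ≤ 3.5 Å, ≥ 120° |
| hydrophobic | apolar C – apolar C distance | ≤ 4.0 Å |
| π–π stacking | centroid distance, interplanar angle | ≤ 5.5 Å, ≤ 30° |
| π–ion | centroid–ion distance, axis angle | ≤ 5.0 Å, ≤ 30° |

No published criterion accompanies the workflow this package
implements, so the defaults follow common interaction-fingerprint
practice and every cutoff is serialised into the outputs. When donors
carry no explicit hydrogens (the usual case for heavy-atom ensembles)
hydrogen bonds fall back to the distance criterion alone and events are
flagged `heavy_only`. Apolarity uses a distance heuristic — a carbon
within 1.8 Å of N/O/S counts as bonded to it and polar — because no
bond topology is perceived. Ring planes come from least-squares
normals; ring membership is supplied by named selections (no
aromaticity perception). The π-stacking rule is parallel-only:
T-shaped geometries are deliberately not counted.

A fingerprint is the per-residue, per-type fraction of frames with at
least one event — presence/absence per frame, not event counts, which
keeps frequencies in [0, 1] and makes them comparable across residues
with different atom counts. Hotspots are residues whose best-type
frequency reaches a persistence threshold (default 0.5) in **every**
basin of the landscape; the threshold is a package decision, not an
inference from any published value, and is exposed as a parameter.
Ranking is by mean frequency across basins, ties broken by residue
number.

## Pre-reaction-state statistics

The pre-reaction state of an inverting GT is operationalised as both
key distances strictly below a threshold (default 3.5 Å): acceptor
oxygen to anomeric carbon, and acceptor oxygen to catalytic nitrogen.
The population is the fraction of frames satisfying the conjunction;
it is therefore bounded above by each single-distance "attack
frequency", which this package defines as the fraction of frames with
that pair strictly below the same threshold. That operational
definition is a package convention (flagged in every report); frames
exactly at the threshold are excluded by the strict inequality and
counted in a boundary diagnostic. Distance summaries in comparisons use
the median, which is robust to the long tails produced by unbound
excursions.

## Tunnels and pockets

A tunnel profile is an ordered list of centerline spheres (centre +
radius, with radius meaning distance to the nearest atom van-der-Waals
surface, the CAVER convention). Derived metrics:

* length — sum of segment lengths;
* curvature — length over endpoint chord, dimensionless and ≥ 1
  (published tunnel tables sometimes attach Å to this quantity; the
  package treats it as a pure ratio);
* bottleneck — minimum radius;
* cost — $\sum_i \ell_i / r_i^2$ times `cost_scale`, penalising narrow
  segments; throughput — $e^{-\mathrm{cost}}$, in (0, 1], higher for
  shorter, wider, straighter tunnels.

The absolute `cost_scale` in published throughput values is not
recoverable without the original structures, so it is an explicit
parameter (default 1) and the package makes no claim of matching any
specific printed throughput; the monotone directions (shorter, wider,
straighter ⇒ higher throughput) are property-tested instead.

The grid tunnel search voxelises space over the padded atom bounding
box (default 0.5 Å), marks a voxel free when no atom surface comes
within the probe radius (default 1.4 Å, water; per-element radii C 1.7,
N 1.55, O 1.52, S 1.8, H 1.2, unknown → C), and finds the
bottleneck-optimal escape: binary search over candidate clearances,
each step a 6-neighbour flood fill, then a breadth-first shortest path
on the admissible subgraph with ascending-index tie-breaks so results
are reproducible. A buried start with no exit is a "no tunnel" result,
not an error. Note the lattice resolution bounds what the search can
see: a channel whose free radius is smaller than about one voxel
diagonal may be reported as closed; validation fixtures keep channels
at least two voxels wide.

Pocket metrics flood-fill connected free voxels from a seed:
volume = voxel count × spacing³; surface area counts exposed voxel
faces × spacing² with a 2/3 correction for the staircase bias of face
counting on smooth boundaries (an axis-aligned plane is counted
exactly; a sphere's face count overestimates by ×1.5, hence the
correction — on the r = 5 Å sphere fixture the corrected estimate lands
within 0.1% of 4πr²). A fill that reaches the bounding box is flagged
unbounded rather than silently capped.

## Kinetics and library design

Initial-rate data are fitted to $v = V_{\max}S/(K_m+S)$ by
Levenberg–Marquardt least squares, initialised from the Hanes–Woolf
linearisation ($S/v$ on $S$), unweighted by default with an optional
relative-weighting flag. $k_{cat} = V_{\max}/[E]$; standard errors come
from the local curvature. A warning fires when
$S_{\max} < 2K_m$ (poorly constrained $V_{\max}$) — the 0–7 mM assay
grid with a wild-type $K_m$ of 4.32 mM sits exactly in this regime,
which is worth knowing when interpreting such fits.

Efficiency reporting mirrors bench conventions: $k_{cat}/K_m$ both raw
and rounded half-up to two decimals (base R's round-half-even does not
reproduce table rounding), and fold changes computed from the rounded
efficiencies at one decimal, because published fold values are
generally reproducible only from the rounded table entries. The raw
ratio is always emitted alongside, since at least one published row is
only consistent with an unrounded calculation.

NNK library arithmetic distinguishes two questions. How many
transformants per site does the community rule of thumb prescribe?
`oversampling_clones()` gives $-V\ln(1-F)$ for $V$ equiprobable codons
(95.9 → 96 for NNK at 95%, conventionally quoted as ≈94–96). How many
clones until every amino acid has actually been observed?
`nnk_coverage_clones()` solves the exact unequal-probability
coupon-collector by inclusion–exclusion grouped over the NNK
multiplicity classes (3 amino acids × 3 codons, 5 × 2, 12 × 1, 1 stop
out of 32), giving 173 at 95% — substantially more than the
oversampling rule, because the twelve single-codon amino acids each
appear with probability 1/32. Both are reported; a seeded Monte-Carlo
estimator cross-checks the exact model in the test suite.

## The synthetic validation system

The generator emulates the statistical structure of a
glycosyltransferase–ligand trajectory, not its physics. The toy system
is 24 four-atom pseudo-residues on a ring (the pocket), residue 16
being the catalytic histidine with an NE2 nitrogen; a central 8-atom
ligand with a planar six-carbon ring and para hydroxyl oxygens playing
the C4-OH/C8-OH roles; and a three-atom donor fragment with a labelled
anomeric carbon. Basins are alternative ring radii (8 and 9.2 Å by
default, separating cleanly in both RMSD and Rg); frames get isotropic
Gaussian jitter (σ = 0.1 Å by default — small against the planting
margins, and a warning fires above 0.3 Å).

Everything statistical is planted by exact counts: basin labels by
largest-remainder allocation of the occupancies followed by a seeded
shuffle, contact and pre-reaction-state labels by seeded selection of
exactly the rounded fraction of each basin's frames. Planted geometry
is written after the jitter, so the planted labels hold exactly:
contact atoms are placed at 2.9 Å (hydrogen bond) or 3.4 Å
(hydrophobic) from their ligand anchor — hbond oxygens above the ligand
plane, hydrophobic carbons below, and the catalytic nitrogen on an
off-axis approach, a layout chosen so planted atoms of different kinds
never stray into each other's polarity heuristic radius. Non-planted
frames keep their reference geometry, 2 Å or more outside every
criterion. Each generator is a pure function of its spec, with
independent sub-streams per purpose derived from the master seed.

Because planting is exact, downstream recovery tests have zero sampling
slack: fingerprints must return the planted frequency to the digit, the
PRS population must equal the planted rate, and hotspot selection must
achieve precision = recall = 1 against decoys with a 0.15 frequency
margin. What passing these tests shows is that the *bookkeeping* —
detection geometry, per-frame deduplication, basin conditioning,
thresholds and tie-breaks — is correct. What they cannot show is
robustness to features of real trajectories the toy lacks: correlated
motions, partial occupancy of contact geometry near the cutoffs,
solvent-mediated interactions, and force-field-scale noise. One planted
artefact is worth knowing: in frames with compliant pre-reaction-state
geometry the catalytic nitrogen necessarily sits within hydrogen-bond
distance of the acceptor oxygen, so the catalytic residue shows a
corresponding hbond frequency — real geometry, excluded from hotspot
scoring in the validation workflows.

## Problem sizes and determinism

The validation suite runs two-basin systems of 200–2000 frames
(107-atom topology), pocket and tunnel grids of roughly 30³–70³ voxels
at 0.5–1.2 Å spacing, 200 replicate kinetic fits, and a 10⁶-trial
Monte-Carlo check of the NNK coverage model — sizes chosen so each
stage's statistical question is answered with margin on a single CPU.
All randomness flows from explicit seeds; the workflow report carries a
config hash and a content hash, and identical config + seed reproduces
results exactly.

## Known limitations

* No trajectory formats beyond multi-model PDB (DCD/XTC are an
  extension point); no solvent handling or periodic-boundary imaging.
* No kinetic analysis of basin transitions (no Markov-state modelling)
  and no reweighting of biased sampling.
* Interaction detection perceives no topology: donors/acceptors,
  rings and charged groups are named selections, and apolarity is a
  distance heuristic.
* Tunnel search is a voxel approximation, not a Voronoi construction;
  absolute throughput values depend on an arbitrary `cost_scale`.
* The Michaelis–Menten module fits single-substrate saturation only —
  no inhibition terms, no global multi-enzyme fits.
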