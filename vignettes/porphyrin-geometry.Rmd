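---
title: "Macrocycle geometry, aromaticity and nonplanarity: models and conventions"
author: "porphgeom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macrocycle geometry, aromaticity and nonplanarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porphgeom)
```

`porphgeom` measures two geometric properties of the porphyrin macrocycle —
structural aromaticity and out-of-plane distortion — and relates them to
substituent sterics with interpretable models. This vignette is the
package's account of the underlying models, the conventions and numerical
choices baked into the defaults, and what the synthetic validation does and
does not demonstrate.

## Curation model

Crystal structures arrive as CIF (symmetry-folded asymmetric units with
occupancies) or XYZ. Parsing expands all symmetry images, merges coincident
sites, and grows bonded molecules outward through neighboring lattice
translations so each molecule is chemically complete. Disordered sites are
resolved per disorder assembly: the alternative group with strictly highest
mean occupancy is kept; a tie at the maximum (within 1e-6) means there is
no dominant conformation and the whole structure is *rejected* — a verdict,
not an error.

Bonds are perceived by the covalent-radius rule `d ≤ s·(r_i + r_j)` with a
Cordero-type radius table and scale `s = 1.15` (configurable). Low-spin
radii are used for Mn/Fe/Co, appropriate for most metalloporphyrins.
Formal charges absent from a file default to zero, so electron parity
depends only on elemental composition; this matches the curation goal of
keeping uncharged molecules.

The seven filters are pure predicates, so their verdicts are
order-independent and survivor counts along the sequence are monotone
non-increasing. Two interpretation choices were genuinely open:

* *Connected molecule* (filter 2) is evaluated against the source file's
  molecule labels: every atom labeled as part of the porphyrin-bearing
  molecule must lie in one bonded component. Structures without labels
  (plain XYZ) treat each bonded component as its own molecule and pass
  vacuously.
* *Central ion* (filter 1) means any atom bonded to all four pyrrole N —
  no element whitelist, so metalloid centers count.

Hydrogens are never added to a structure that lacks them: the saturation
filter counts declared connections only, which deliberately rejects
H-depleted models rather than inventing geometry. The macrocycle itself is
found by graph substructure only (four N-containing five-rings bridged by
four single-carbon bridges into a 16-ring), so arbitrarily distorted
macrocycles — the subject of study — are detected, while corroles
(a direct pyrrole–pyrrole bond) and chlorin-like rings (which fail the
saturation pattern) are excluded.

## HOMA, EN, GEO and the calibration

For a circuit of `n` bonds with lengths `R_i`, mean `R̄`, optimum `R_opt`
and normalization `α`:

$$\mathrm{HOMA} = 1 - \underbrace{\alpha\,(R_\mathrm{opt}-\bar R)^2}_{\mathrm{EN}}
               - \underbrace{\tfrac{\alpha}{n}\sum_i (\bar R - R_i)^2}_{\mathrm{GEO}}$$

EN penalizes a mean bond length away from the aromatic optimum (bond
*elongation*), GEO penalizes bond *alternation*. The identity
`HOMA = 1 − EN − GEO` is exact in the implementation and asserted to 1e-10
throughout the tests. C–N bonds are mapped onto the C–C scale before
pooling: with single/double reference lengths (C–C 1.467/1.349, C–N
1.465/1.269 Å) the Pauling bond number of a C–N bond of length `R` is
`exp[(R₁−R)/c]` with `c = (R₁−R₂)/ln 2`, and the effective length is the
C–C length of the same bond number. Literature C–C defaults are
`R_opt = 1.388 Å`, `α = 257.7 Å⁻²`; everything is configurable through
`homa_params()`.

Two circuits matter for metalated porphyrins: the 16-membered *inner
cross* (4 N + 8 Cα + 4 Cmeso) carrying the dominant aromatic pathway, and
the four pyrroles measuring local aromaticity. The free-base 18-π
bridged-annulene pathway is out of scope.

**Calibration.** The contract is that a planar, unsubstituted porphine
scores 1. Requiring this with a *fixed* literature `R_opt` and a nonzero
deviation sum would force `α = 0`, so the requirement is mathematically
incompatible with per-system α alone. Two defensible mechanisms are
implemented and tagged in the parameters:

* `reference_ropt` (default): `R_opt` per circuit type is set to the mean
  effective bond length of that circuit on the packaged reference, making
  EN vanish on the reference. The packaged reference geometry is designed
  on the *aromatic-equivalence* principle — every inner-cross bond carries
  the same Pauling bond order (C–C 1.395 Å, N–Cα its C–N equivalent,
  ≈1.345 Å) — so the inner circuit's GEO also vanishes and its calibrated
  score is exactly 1 (asserted to 1e-12). Pyrrole-only bonds take typical
  crystallographic values (Cα–Cβ 1.440, Cβ–Cβ 1.355 Å), so the planar
  pyrrole scores below 1 (≈0.73), dominated by GEO — consistent with the
  empirical pattern that metalated porphyrins are globally more aromatic
  than locally.
* `rescale`: literature `R_opt` everywhere, with every score divided by
  the reference's raw score of the same circuit type. Because rescaled
  scores can exceed 1, EN and GEO are rescaled proportionally to preserve
  the decomposition identity; they can then be negative, which is why this
  is not the default.

Scores are never clamped to [0, 1]: strongly distorted geometries
legitimately score negative, and clamping would hide calibration errors
(a warning is logged once per session instead).

## Normal-coordinate structural decomposition

The out-of-plane state of the macrocycle is described by projecting the
24-atom displacement vector `z` (relative to the planar reference) onto
six orthonormal symmetry-adapted modes: saddling (B2u), ruffling (B1u),
doming (A2u), waving x/y (Eg) and propellering (A1u). The mode shapes are
constructed geometrically on the packaged reference rather than taken from
a force field:

* *ruffling*: linearized rigid counter-rotation of the four pyrroles about
  their radial axes; the meso carbons follow the extended pyrrole planes
  (both flanking planes predict the same meso displacement, which makes
  the construction parameter-free);
* *saddling*: alternating pyrrole tilts about the tangential axes through
  each N (N and meso stay in plane);
* *doming*: a mean-free radial cone (inner atoms up, outer down);
* *propellering*: same-sense pyrrole rotation;
* *waving*: a step-like tilt of one opposite pyrrole pair.

Each raw shape is purged of rigid-body content (net z-translation and the
two global tilts) and the set is Gram–Schmidt orthonormalized in a fixed
order; orthonormality holds to machine precision. Because every mode is
mean-free and tilt-free, amplitudes are invariant to where the fitted
plane puts its offset.

**Frame.** Projections are meaningless without a common frame, and
re-fitting a plane to the distorted N4 would tilt the frame (waving moves
the N atoms) and spoil exactness. `nsd_decompose()` therefore aligns the
geometry to the *reference* by minimizing the in-plane (x, y) mismatch
over proper rotations — Gauss–Newton on the rotation manifold, started
from the principal-plane fit with both normal orientations. For any pure
out-of-plane displacement of the reference this recovers the reference
frame exactly, which is why the impose→decompose round trip recovers all
six amplitudes to better than 1e-8 for amplitudes up to 3 Å (tested on
1000 random vectors), and why decomposition is rigid-motion invariant.
Canonical atom ordering (below) breaks the D4h degeneracy of the in-plane
match, so the frame is unique.

Conventions: amplitudes are signed (a mirror image flips the ruffling
sign); the total out-of-plane is the Euclidean norm `D_oop = ‖z‖`
(`Σ amplitudes² + residual² = ‖z‖²` exactly); the per-atom deviation is
`D_oop / 24` — the convention under which a total of 0.6 Å equals 0.025 Å
per atom. `fit_reference_plane()` exposes the N4 (default) and all-atom
least-squares planes with the normal oriented toward the metal's axial
hemisphere. Doming is computed and reported but excluded from the default
model targets, since domed structures are too rare to predict.

`impose_distortion()` inverts the decomposition: reference plus a mode
combination, displaced strictly along the plane normal with in-plane
coordinates fixed. Bonds therefore elongate geometrically
(`d' = √(d² + Δz²)`) — a deliberate minimal model with no force-field
relaxation. Under it, pure ruffling stretches the short Cβ–Cβ bond
fastest, which *equalizes* the pyrrole bonds: GEO falls before EN's
elongation penalty takes over, so mean pyrrole HOMA rises to an interior
maximum and then falls, while saddling (which leaves Cβ–Cβ untouched and
stretches the already-long bonds) only lowers it. The packaged scan places
that ruffling maximum near 1.5 Å of total out-of-plane displacement; its
exact location is sensitive to the meso-vs-pyrrole weighting of the
ruffling eigenvector and to the template's pyrrole bond lengths, neither
of which has a unique literature-fixed value, so the qualitative
crossover — not its precise abscissa — is the robust prediction. Along the
ruffling scan the EN range dominates the GEO range in both circuits,
i.e. distortion acts on aromaticity mainly through bond elongation.

## Canonical ordering and substituent identity

A substitution pattern can be written in 8 symmetry-equivalent walk orders
(4 rotations × 2 directions). `canonical_atom_ordering()` picks the image
with the lexicographically smallest substituent-pattern encoding (ties —
fully symmetric patterns — broken by atom index, harmless because the
descriptors are means over positions). Descriptor vectors are therefore
identical across all 8 images, removing ordering bias. Substituent
*identity* (for the train/test protocol) is a Morgan-style iterative
refinement hash of the substituent's atoms and bonds, seeded with element
symbols plus any declared vdW override, so two steric probes of different
bulk are different identities.

## Steric descriptors

**Cone angles.** The maximal coning angle of a substituent is the full
apex angle of the smallest cone, anchored at the attachment atom (ring
atom for beta/meso, metal for axial), containing the substituent:
`2·min_u max_i [∠(u, v_i) + asin(r_i/|v_i|)]`. A single atom has the
closed form `2·asin(r/d)`; the general case is solved by deterministic
multistart Nelder–Mead (atom directions, their mean, and the best points
of a coarse 600-direction sphere scan, each refined twice), verified
against dense two-stage grid search to 0.5° in the tests. The radius
convention needed a decision: Bondi spheres of atoms *directly bonded* to
the apex always contain the apex (r_vdW exceeds the bond length for C–H,
C–C, C–F alike), making the enclosing cone degenerate for every real
substituent. The default (`radii = "declared"`) therefore treats ordinary
atoms as points and uses declared radii only for the parameterized steric
probes, for which the cone is exact and continuously tunable; a full-Bondi
mode exists and errors on degenerate atoms, as does the primitive
`cone_angle()` itself.

**Crowding distances.** Cone angles do not express crowding between
neighboring substituents, so the second representation measures the
minimal inter-atomic distance between neighboring substituents after
rigidly transplanting each (in its observed conformation) onto a fixed
*surrogate frame* — two attachment sites with idealized positions and
outward bond vectors, taken once from the packaged planar reference for
the beta–beta and meso–beta site classes. Transplanting carries no
per-structure macrocycle information into the descriptor. The rotational
degree of freedom about the bond axis is completed deterministically from
the substituent's second atom (global z as fallback).

**Feature vectors.** Both representations share metal radius (covalent
table — the choice between covalent and ionic was open; covalent needs no
oxidation-state assignment, which curation deliberately avoids),
coordination number (4 + axial ligands) and mean axial cone angle, fixed
to −1 when the coordination number is 4 (a sentinel that intentionally
correlates with coordination number, as in the reference protocol). The
cone variant adds mean meso and mean beta cone angles (H included); the
distance variant adds mean beta–beta and meso–beta surrogate distances
over all adjacent pairs of the canonical layout.

## Models and evaluation

LASSO is fitted on z-scored features (training statistics), with the L1
penalty chosen on a 50-point logarithmic grid (from the data's maximal
absolute gradient down four decades) by 5-fold cross-validation minimizing
MAE; folds are shuffled by the run seed. Standardization was an open point
in the reference protocol; it is applied here so coefficient magnitudes
are comparable across features, which heatmap-style interpretation needs.
Coefficients are reported on the standardized scale. Random forests run
with permutation importances and a fixed seed.

The train/test split holds out whole substituent identities: a seeded
greedy search (with restarts and an exact-size fill step) picks identities
whose covering structures total the requested test count, so every test
structure provably contains a substituent absent from training; the
predicate is re-verified exhaustively before returning, and an
unsatisfiable constraint (all structures sharing one identity set) raises
an explicit infeasibility error. Published protocols sometimes quote exact
counts that differ from their nominal fraction (e.g. 30 test structures
out of 425 at "10%"), so the function accepts an exact `test_size`
override alongside the fraction.

"10 bootstrap experiments" is read as 10 independent re-draws of the
split (each with its own derived seed), the default; row-resampling with
out-of-bag testing is available via `resample = "rows"`. Reported metrics
are means with percentile 95% confidence intervals. Models predicting
HOMA scores are excluded from the default interpretation table — their
relative error is higher — unless explicitly requested.

## The synthetic generator as study conditions

`generate_population()` stands in for the proprietary curated set. Its
defaults *are* the study conditions and were fixed once:

* metals Ni/Zn/Mg/Ru/Pd/Sn (covalent radii 1.22–1.46 Å, all even-electron);
* 0/1/2 axial ligands with probabilities 0.35/0.44/0.21, matching the
  coordination-number mix reported for curated metalloporphyrin sets;
* substituent bulk drawn from steric probes on distinct radius grids per
  position class (meso 0.90–1.70, beta 0.85–1.65 plus H at 40%, axial
  1.00–2.10 Å), giving a ~30-identity pool for the unseen-substituent
  protocol;
* planted standardized coefficients with the signs the porphyrin
  literature expects — ring bulk increases distortion, larger metals and
  axial spheres planarize, ruffling more metal/axial-sensitive and
  saddling more ring-substituent-sensitive — at magnitudes giving
  amplitudes in the 0.5–2 Å range typical of nonplanar porphyrins;
* noise σ derived so the planted law explains ≈70% of amplitude variance.

Geometries are built by imposing the planted saddling/ruffling amplitudes
on the substituted template, so re-measuring the structures reproduces the
planted targets exactly at σ = 0 (asserted to 1e-8) — the population is a
closed loop through the package's own geometry engine, not a table of
numbers. What it does *not* emulate: crystal packing, force-field
relaxation of distorted geometries, real metal-abundance bias, charged or
disordered structures, or correlated substitution patterns. Passing the
recovery tests therefore demonstrates that the pipeline measures what it
builds and that the models recover a linear steric law under realistic
noise — not that real crystal data obey that law.

## Problem sizes and numerical defaults

The test-suite and acceptance computations use: populations of 400
structures (sign recovery; R² ≈ 0.7; 10 bootstrap replicates) and 425
(split shape); 1000 random amplitude vectors for the round-trip property;
distortion grids of 0–4 Å in 0.1 Å steps; 200-replicate and 20-replicate
property loops elsewhere. Defaults worth knowing: bond cutoff scale 1.15;
disorder tie tolerance 1e-6; cone-optimizer restarts as described, with
the 0.5° grid-agreement contract; Gauss–Newton alignment to relative
objective change 1e-15 (at most 60 iterations); canonicalization
tie-break by atom index; all stochastic steps take explicit seeds and the
derived per-replicate seeds stay within 32-bit integer range.

## Known limitations

* The rigid out-of-plane displacement model exaggerates bond elongation at
  large amplitudes (beyond ~3 Å the implied stretches exceed anything
  physical); scan behavior there is a property of the model, not of
  porphyrins. On the saddling scan the pyrrole GEO range can exceed the EN
  range in that regime.
* The NSD basis is the minimal one vector per symmetry; extended
  multi-vector bases and in-plane distortion analysis are out of scope, and
  agreement with other NSD software is structural, not bit-exact.
* The CIF reader covers the core dictionary subset needed for curation
  (cell, symmetry operations, atom sites, occupancies, disorder tags); it
  is not a general CIF implementation.
* Electronic substituent effects (Hammett-type), buried volumes and
  conformer ensembles are outside the descriptor set.
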