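---
title: "Spherical featurization and graph convolutional analysis of binding pockets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spherical featurization and graph convolutional analysis of binding pockets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketsphere)
```

## The problem

Two proteins with unrelated folds can present chemically similar binding
pockets, and the same pocket looks different in every crystal because
proteins have no canonical orientation. `pocketsphere` represents a binding
pocket by the *negative imprint* of its cavity — a cluster of spheres filling
the empty space — projects the imprint's surface onto a sphere, and learns
either ligand-class labels or a 256-dimensional descriptor whose Euclidean
distances measure pocket similarity. Because the learning operates on a
spherical pixelization through graph convolutions and ends in global average
pooling, the descriptor is approximately invariant to rigid rotations of the
input structure.

## Pocket location and filtering

Gap spheres are seeded at the midpoint of every pair of protein heavy atoms
whose inter-surface gap admits a sphere of radius at least `r_min` (1 Å),
with initial radius equal to half that gap, capped at `r_max` (4 Å). Each
candidate is then iteratively shrunk and recentred against its nearest
intruding atom — each step moves the centre directly away from the intruder
by half the violation and shrinks the radius by the same amount, leaving the
sphere tangent to that atom — for at most 10 iterations, after which a
brute-force clearance check discards anything still penetrating a van der
Waals surface. Near-duplicate spheres are collapsed on a 0.5 Å grid
(largest radius wins) and survivors are clustered by overlap.

Sphere placement alone overestimates pockets, so the cluster is filtered
against the ligand: protein atoms within `r = 6` Å of any ligand heavy atom
(unioned over an ensemble of poses when several are supplied) define a
convex hull, and only spheres whose *centre* lies inside or on that hull are
kept. The closed-hull convention and the centre-only test are deliberate:
no partial-overlap rule is defined for hull membership, and testing centres
makes the filter invariant under rigid motion exactly. Without a ligand, a
pluggable predictor supplies probe points; the built-in default uses the
centres of the largest sphere cluster.

## Surface extraction

The imprint surface is the solvent-excluded surface of the sphere union for
a probe of 1.5 Å: morphologically, dilate the union by the probe radius and
erode it back. We voxelize the dilated union on a grid whose spacing is
derived from the requested vertex density (3 vertices/Å² by default; the
tetrahedral contouring below yields about 4.7 vertices per `h²` of surface,
so `h = sqrt(4.7 / density)` ≈ 1.25 Å), measure interior depth with an
exact separable Euclidean distance transform, and contour the signed field
at depth = probe radius.

Two numerical choices matter here. First, the interior depth estimate is
`max(-f1, EDT - (sqrt(3)/2) h)`, where `f1` is the minimum signed distance
to any inflated sphere: `-f1` is exact wherever one sphere dominates (so an
isolated sphere reproduces its analytic area to a few percent), while the
distance transform improves the estimate inside crevices; subtracting the
maximal voxel-centre excess guarantees the combination never overshoots,
which keeps convex regions exact at the cost of slightly under-eroded
crevices. Second, contouring uses marching *tetrahedra* on the 6-tetrahedron
cube decomposition rather than marching cubes: it needs no case tables, has
no ambiguous configurations, and always produces a closed manifold, which
the test suite checks through the Euler characteristic V − E + F = 2. Face
orientation is fixed by the trilinear gradient of the field, so normals
point outward.

Cleanup removes non-finite vertices, zero-area and duplicate faces, and
unreferenced vertices (preserving vertex order), and is idempotent. Four
iterations of uniform (umbrella-weight) Laplacian smoothing follow; uniform
weights are the simplest choice consistent with "replace each vertex by the
mean of its 1-ring", and smoothing demonstrably never increases the area of
a noisy closed surface.

## Vertex properties

Each surface vertex carries seven numbers: four binary pseudocenter
channels, a hydrophobicity and an electrostatic potential.

**Pseudocenters** summarize the interaction capability of pocket-lining
residues: hydrogen-bond donors (DON), acceptors (ACC), mixed
donor/acceptors (DAC, e.g. histidine ND1/NE2), aliphatic (ALI) and
aromatic/π (ARO) groups. The residue template table ships as an editable
TSV (`inst/extdata/pseudocenter_templates.tsv`); each row names the atoms
that define a centre and the rule orienting its interaction direction `v`
(along a bond, opposite a bond-angle bisector for the backbone N-H, away
from a ring centroid, or the ring plane normal). A centre's surface
exposure is the normalized sum `r` of vectors to all mesh vertices within
3 Å; directional centres are kept only when the angle between `v` and `r`
is at most 100° (DON, ACC, ARO) or 120° (DAC). Ring normals have no
preferred sign, so ARO angles are compared axially (the smaller of the
angles to ±v). ALI centres are isotropic and never filtered. Vertices take
the channels of their single nearest surviving centre within 3 Å — DAC
sets both DON and ACC — and are NULL (all-zero) otherwise, which makes the
open mouth of a pocket read as featureless.

**Hydrophobicity** binarizes atoms by partial-charge magnitude — nonpolar
(|q| ≤ 0.25 e) scores −1, polar (|q| > 0.25 e) scores +1 — and averages
over atoms within 4.5 Å with inverse-distance weights floored at 0.5 Å.
The floor bounds the weights so the result is a convex combination of ±1;
any weighting decreasing with distance would do, and inverse distance is
the least-committed such choice. The magnitude convention resolves the
ambiguity of applying a charge interval to signed charges.

**Electrostatics** come either from an external scalar grid (OpenDX
dialect, trilinearly interpolated; an error names any axis on which the
grid fails to cover the mesh) or from a built-in screened-Coulomb model,
φ(x) = Σᵢ qᵢ e^(−κdᵢ)/(εᵣ dᵢ) in kT/e with κ = 0.1 Å⁻¹ and εᵣ = 4 —
a standard Debye-screened approximation that keeps the package free of an
external Poisson-Boltzmann solver. Potentials are capped at ±30 (kT/e,
the conventional unit at which such a cap is meaningful) and scaled to
[−1, 1].

## Spherical projection

The attributed mesh is translated to its centroid and scaled so the
farthest vertex sits at radius 0.99 — not 1.0, so rays never start exactly
on the surface. From each pixel of a HEALPix pixelization (nested
ordering, `N_side = 16`, `N_pix = 12·16² = 3072`) a ray is cast toward the
origin and the first triangle hit is recorded. Nine channels result: depth
(distance traveled from the sphere before the hit, 0 at the sphere and →1
near the origin), cos θ and sin θ of the angle between the outward face
normal and the hit-to-pixel direction (a concentric sphere reads cos θ = 1
everywhere; sin θ ≥ 0 makes the pair redundant but both normal maps are
kept), mean charge and hydrophobicity of the hit face's vertices, and the
OR of the face's DON/ACC/ALI/ARO bits. Missed pixels (possible only for
non-star-shaped imprints or open mouths) carry depth 0, angle 0 and zero
properties, with a recorded miss mask — "far and featureless", matching
the NULL-vertex convention.

HEALPix is implemented from the canonical nested-ordering algorithms and
verified against the analytic 12-pixel base layout, exact
pixel-centre/index round trips, and the 4:1 parent-child containment that
pooling relies on.

## The spherical graph network

Pixels become vertices of a k-nearest-neighbour graph (k = 20, chordal
distances, Gaussian weights exp(−d²/4t), union-symmetrized;
neighbourhoods are tie-inclusive so the symmetric grid never depends on
floating-point tie order). The kernel width defaults to the mean squared
distance to the k-th neighbour divided by 4. Convolutions are polynomials
in the combinatorial Laplacian L = D − W: y = Σ_{k=0..K} Lᵏ x aₖ with
K = 3, computed by recursive sparse application of L. The monomial basis
in the unscaled L is used as stated; because ‖L‖ grows with the weighted
degree, initialization scales the k-th order coefficients by an estimate
of ‖L‖⁻ᵏ so activations are finite at the start (a Chebyshev
reparameterization would achieve the same end but changes the filter
parameterization itself).

The trunk is four blocks of [graph convolution → batch normalization →
ReLU → 4:1 max pooling] with 32/64/128/256 channels, taking `n_side`
16 → 8 → 4 → 2 → 1; a fresh graph is built at each pooled resolution with
the same k (capped on tiny grids). Global average pooling over the final
12 pixels yields a 256-vector; the classifier head applies a linear map to
`n_classes` logits and softmax, the embedder head a linear map to 256 with
no activation. Batch normalization keeps running statistics with momentum
0.9; `calibrate_network()` sets them from a reference batch, which is how
an untrained or freshly loaded network is prepared for inference. Average
pooling is available as a configuration option (`pool = "average"`), but
the default follows the stated architecture (max).

Backpropagation and the Adam optimizer are implemented directly on R
matrices; every gradient path is validated against central finite
differences in the test suite.

## Training objectives

*Classification*: softmax cross-entropy, Adam at learning rate 0.05
(weight decay 0, β = 0.9/0.999), decayed ×0.1 every 25 epochs, batch 32,
stratified k-fold cross-validation, per-sample rotation augmentation
(maps are resampled at rotated pixel positions by nearest pixel lookup).

*Metric learning*: the embedder minimizes the contrastive margin loss
y·d² + (1−y)·max(0, m−d)² with m = 1 at learning rate 0.0005, batch 128,
up to 25,000 pairs per epoch subsampled without replacement (reseeded per
epoch from the master seed), rotations applied to both members of each
pair. Pairs that straddle the train/test split are excluded and counted.
Leakage control follows sequence identity: structures sharing more than
30% identity join the same single-linkage cluster, and whole clusters are
randomly assigned to one side of the split. Identities are normally a
precomputed matrix; an alignment-free k-mer (k = 3) fallback lets the
package run without an external aligner.

Evaluation reports ROC curves and AUC; the AUC is computed from rank sums
(Mann-Whitney with half-credit ties), which the tests pin to an exhaustive
pair-counting oracle, and descriptor analysis uses plain Euclidean
distance matrices and average-linkage hierarchical clustering.

## The synthetic fixtures

`make_toy_protein()` builds a concave pocket a few hundred atoms in size:
pseudo-residue fragments (Lys-like donors, Asp-like acceptors, Phe-like
rings, Ala-like aliphatics, Arg/Glu-like charged groups) are placed on a
spherical-cap shell at the requested cavity radius with their functional
groups pointing inward, a 4-atom dummy ligand sits at the centre, and
Gaussian positional noise (default 0.05 Å) is added. The defaults
(cavity radius 5 Å, mouth angle 60°, mixed lining) describe a small,
enclosed, druggable-looking cavity; every generated protein passes the
full pipeline and yields finite, in-range maps. What these fixtures do
*not* emulate: real rotamer geometry, backbone connectivity, B-factors,
crystal contacts or solvent — so green tests demonstrate algorithmic
correctness, not biological accuracy.

`make_map_dataset()` skips the geometry entirely and draws labeled
spherical maps directly: each class is a combination of smooth
spherical-cap motifs on specific channels, each sample is a uniformly
random rotation of its class template plus channel noise (0.05, chosen
so that two samples of a class stay histogram-close while remaining
visibly noisy). Class identity is therefore orientation-free by
construction, which is exactly the property the learning heads are
supposed to exploit.

## Problem sizes and what the checks show

The learning-sanity demonstrations train on synthetic map datasets with an
Adam learning rate of 0.01 rather than the 0.05 default: the default is
calibrated for datasets three orders of magnitude larger, and oscillates on
a few dozen samples. The package defaults are unchanged; the sanity runs
pass the override explicitly.


The shipped tests and the acceptance script run at desk scale: toy
pockets of ~100–300 atoms, map datasets of 30–60 samples, training runs
of 12–30 epochs, oracle comparisons at `n_side` = 2–4. These sizes
exercise every code path and all documented contracts; they do not
approach the data volumes at which the reference results for real
benchmark collections were obtained, and no claim about performance on
real protein data follows from them.

One property deserves an honest caveat: rotation invariance of the
descriptor. Global average pooling makes the *final* aggregation exactly
invariant, and input-level statistics of our projections are stable under
rotation to well below 1%. But each max-pooling stage aggregates fixed
4-pixel blocks, and a rotation moves signal across block boundaries;
with an untrained network the median relative descriptor change under
rotation is roughly 10-20% (8% with the average-pooling option), and
desk-scale contrastive training (tens of epochs on tens of pockets)
reduces it only partially. Tight rotation invariance (a few percent) is a property of
long rotation-augmented training at scale, not of the untrained
architecture; the acceptance script therefore measures and reports the
median relative change as an honest number rather than asserting a small
bound.

## Limitations

- The built-in electrostatics is a screened-Coulomb model, not a
  Poisson-Boltzmann solution; supply an OpenDX grid for fidelity.
- Ray casting records only the first intersection, so deeply non-convex
  pockets lose information (an inherent property of the projection).
- The pseudocenter templates use heavy-atom geometry only; no hydrogens
  are placed and no protonation states are enumerated.
- Only the first model of multi-model structure files is read, and no
  symmetry mates are generated.
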