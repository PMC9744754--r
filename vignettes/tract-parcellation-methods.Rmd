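---
title: "Morphometry-driven parcellation of spinal white matter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry-driven parcellation of spinal white matter: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordparc)
```

## The problem

Spinal white matter is organized into tracts (funiculi): bundles of axons
with a shared origin and destination, and — to a useful approximation — a
shared *morphometric signature*: a characteristic joint distribution of axon
density, axon diameter, axon volume fraction, g-ratio and myelin thickness.
`cordparc` asks how far that signature alone can take you: given pixelwise
morphometry maps on a 50 μm grid (the kind produced by automatic axon/myelin
segmentation of electron-microscopy sections), can an unsupervised,
spatially constrained clustering recover the known tract topology?

The package provides the full analysis chain — synthetic data generation,
slice-to-slice registration, template building, connectivity-constrained
Ward clustering, and overlap-based validation against a reference tract
atlas — as composable R functions plus a staged pipeline driver.

## The clustering model

Each white-matter pixel is a feature vector of the five morphometric
channels, min–max normalized to $[0,1]$ per slice over masked pixels only
(`normalize_metrics()`; a constant channel collapses to zero with a
warning).  Clustering is agglomerative with the Ward criterion: merge the
pair of clusters $(i, j)$ that minimally increases total within-cluster
variance,

$$\Delta(i,j) \;=\; \frac{n_i\,n_j}{n_i+n_j}\,\lVert \mu_i - \mu_j \rVert^2 ,$$

restricted to pairs that share at least one edge of the pixel adjacency
graph (4- or 8-neighbourhood in the axial plane, `build_connectivity()`).
The constraint guarantees spatially connected parcels — the defining
property of a tract candidate.

Implementation notes (`ward_cluster()`):

* Costs are computed directly from maintained centroids and sizes.  This is
  algebraically identical to propagating them with the Lance–Williams Ward
  recurrence, but needs no special-casing for cluster pairs that only become
  adjacent after a merge.
* Candidate merges live in a lazily deleted queue: entries that reference an
  absorbed cluster are discarded when popped.  Correctness, not speed, is
  the contract; the engine is validated against a brute-force oracle that
  recomputes all pairwise costs from scratch at every step, and against
  `hclust(method = "ward.D2")` partitions on unconstrained instances.
* Ties on merge cost break to the lexicographically smallest cluster-id
  pair, making results bit-reproducible.
* A disconnected mask is clustered per component, with the requested cluster
  count apportioned by component pixel share (largest remainder, at least
  one per component).  The effective cluster count is therefore
  `max(n_clusters, n_components)`.
* Merge costs are monotone non-decreasing for unconstrained Ward; under a
  sparse connectivity constraint, a merge can expose a newly adjacent pair
  cheaper than the current minimum, so monotonicity is only asserted on
  complete graphs.

Two drivers apply the engine the way the study design does:
`cluster_slicewise()` runs one independent clustering per spinal level
(31 levels C1–S4), `cluster_regionwise()` runs one per region (cervical,
thoracic, lumbar, sacral) on registration-aggregated inputs.

## Registration and aggregation

Region-wise aggregation needs adjacent slices in a common space.  The
engine (`estimate_nonrigid()`) is a B-spline free-form deformation: the
displacement field is parameterized by control-point displacements on a
coarse grid (cubic B-spline tensor basis), optimized by gradient descent on
the masked sum of squared differences with backtracking line search, so the
objective never increases across accepted iterations.  A roughness penalty
(squared first differences of control displacements, averaged per control
point; weight `smooth_weight`, default 0.01) keeps the field smooth.
Coarse-to-fine continuation halves the control spacing per level (default 3
levels ending at 8 px) and folds increments in by field composition.  A
full diffeomorphic (SyN-style) model is deliberately out of scope: the
contract downstream stages rely on — SSD decrease and a smooth field — is
what is implemented and tested.

`estimate_affine()` provides the global stage: centroid/second-moment
initialization refined by Nelder–Mead on the same masked SSD, returning the
identity whenever no candidate beats it.

Slices are never registered directly to a distant reference.  Instead
`stepwise_chain()` registers each slice only to its neighbour and
concatenates the pairwise transforms outward from the reference slice (the
region mid-slice; the lower median index for even counts, a deterministic
reading of "center slice").  Field composition
(`compose_fields()`) is defined so that applying the composed field is
equivalent to applying the inner then the outer field, and is validated
against sequential application.  The pairwise direction — neighbour as
moving image, registered onto the reference-side slice — is a convention
choice (the chained wording is direction-ambiguous); the inverse convention
is selectable in `registration_config()`.

`aggregate_region()` drives the chain on the axon-density channel only,
applies each composed field to all five metric channels (linear
interpolation) and to one-hot tract-label channels (also linear — this is
what turns discrete labels into per-tract partial volumes in $[0,1]$), then
averages along the superior–inferior axis.  A 3D stack with through-plane
edges is a conceivable alternative to averaging; the 2D-average path is the
default and the only one implemented here.

`build_template()` assembles the across-subject average at one level:
subjects are co-registered (affine then nonrigid, driven by the
white-matter masks) to the first subject's slice as a provisional common
space, resampled, averaged pixelwise over defined values, and right–left
symmetrized (`symmetrize()`: the average of the image and its mirror,
idempotent by construction).

## The synthetic cord generator

No microscopy data ship with the package; `toy_atlas_spec()` +
`build_reference_atlas()` + `sample_subject()` generate everything the
pipeline consumes, with known ground truth.

**Geometry.**  A parametric cross-section on a 64 × 64 grid of 50 μm
pixels: an elliptical cord, a gray-matter "butterfly" (central commissure
plus dorsal and ventral horn ellipses), and a 9-tract partition of the
white matter placed to mimic the usual rat topology — fasciculus gracilis
(FG), postsynaptic dorsal column (PSdc) and fasciculus cuneatus (FC) in the
dorsal column, the dorsal corticospinal tract (dCST) at its base, lateral
cervical nucleus (LatC) and lateral spinal nucleus (LSp) on the
dorsolateral rim with the rubrospinal tract (RST) deep to them, and the
lateral and ventral funiculi (LF, VF).  All geometry is computed from the
absolute left–right offset, so symmetric atlases are exactly
mirror-symmetric.  `merge_lfvf = TRUE` collapses LF and VF into one
ventrolateral label, giving the 8-tract reference convention used for
cluster-count comparisons.  A smooth per-level scale factor emulates the
cervical and lumbar enlargements and the sacral taper across the 31 levels
(8 cervical, 13 thoracic, 6 lumbar, 4 sacral).

**Signatures.**  Default per-tract means anchor on reported template
statistics: axon density from 78,000 axons/mm² (FG) to 168,800 axons/mm²
(dCST); mean axon diameter 1.1 μm (dCST) and 1.35 μm for the ascending
dorsal column (FG, PSdc, FC — the value is shared so the union-mask mean is
exact); tract-mean myelin thickness spanning 0.35–0.5 μm; g-ratio
approximately flat at 0.7.  Myelin volume fraction is not a stored channel;
it derives from the axon volume fraction and g-ratio under circular
cross-sections, $\mathrm{mvf} = \mathrm{avf}\,(1/g^2 - 1)$
(`myelin_vf()`), and the default axon-volume-fraction means are chosen so
the derived tract means span exactly 15–30%.  Values not individually
reported are interpolations inside those ranges and live in
`default_signatures()` as configuration, not as measurements.  Standard
deviations are sized so per-tract pixel distributions overlap substantially
— except the dCST density, which stays well separated — matching published
per-tract violin distributions at C1.  Signatures are held constant across
levels; per-level signature variation is unreported and therefore not
modelled.

**Noise model.**  Each pixel draws every metric from a truncated normal
(truncation at 0, and at 1 for fractions and the g-ratio) with the tract
mean and `sd × noise_scale`.  Truncated normals respect the positive,
bounded nature of the metrics; at the default means the truncation bias is
negligible (bounds ≥ 3.5 SD away).  `noise_scale = 1` reproduces the
configured pixelwise spread (at 50 μm, one pixel aggregates only a few
hundred axons, so pixel noise is of the same order as the axon-population
spread); `noise_scale = 0` is the degenerate exact draw used for recovery
tests.

**Deformations.**  Inter-subject anatomical variability is a smooth random
displacement field: iid normal control-point displacements on a coarse grid
upsampled through the cubic B-spline basis.  The control amplitude bounds
the displacement gradient, keeping small-amplitude fields invertible.  The
same field warps metrics (linear) and labels (nearest neighbour), so ground
truth stays aligned with the data.  Outside the mask, channels carry `NA` —
never 0, which is a legal metric value.

**What the generator does not emulate:** raw electron microscopy,
individual axons, segmentation failure modes (false merges/splits, missed
small axons), staining artifacts, or spatially correlated noise.  Passing
recovery tests on this phantom therefore demonstrates that the pipeline's
machinery is correct under its own assumptions — not that real tissue
satisfies those assumptions.

## Evaluation

`overlap_matrix()` tabulates cluster-by-tract co-occurrence (pixel counts
against discrete labels, summed partial volume against a soft atlas).
Matching is per-cluster argmax — several clusters may share a tract and a
tract may go unclaimed — because a one-to-one assignment would force
arbitrary pairings exactly where parcellations split tracts.
`match_and_color()` reproduces the figure convention: a cluster inherits
the hue of its best tract; clusters sharing a tract are spread over
intensities $0.2 + 0.8\,f/f_{\max}$, where $f$ is the fraction of the tract
the cluster covers (only the range and the "scaled with overlap" behaviour
are prescribed; the linear form is this package's choice).  Equal fractions
rank by cluster size, then id.  `render_hemisection()` writes the
clusters-left / atlas-right PNG at a constant spatial scale.

Because the synthetic ground truth removes the headline obstacle to
quantitative validation (not knowing which cluster "is" which tract), the
package adds the Adjusted Rand Index (`ari()`, chance-corrected agreement
over mask-and-atlas-covered pixels) and per-tract best-cluster recall
(`tract_recall()`).

### Bilateral symmetry and exact recovery

One subtlety is worth spelling out.  On a bilaterally symmetric atlas, a
lateral tract consists of two disconnected mirror blobs that share a label.
A connectivity-constrained clustering with `n_clusters` = tract count
cannot reproduce that partition: at zero noise the mask contains ~17
connected single-signature blobs, and parcels must stay connected.  Exact
recovery is therefore asserted on a *hemisection* (`hemisection_mask()`),
where every tract is one connected region — the same reasoning that
motivates right–left symmetrization of bilateral data in the first place.
On a noise-free hemisection the engine provably stops after exhausting the
zero-cost merges, and the recovered parcellation attains ARI = 1.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `pixel_size` | 50 | μm | resolution of the emulated metric maps |
| `noise_scale` | 1 | × signature SD | 0 = noise-free recovery setting |
| `deform_amplitude` | 1.5 | px | smooth inter-subject deformation |
| `n_clusters` | 8 | – | the reference tract count; sweeps supported |
| connectivity `scheme` | `axial4` | – | conservative; `axial8` selectable |
| `spacing` | 8 | px | B-spline control spacing at finest level |
| `smooth_weight` | 0.01 | – | roughness penalty weight |
| `max_iter`, `tol` | 200, 1e-4 | – | per-level descent budget / relative SSD stop |

Feature vectors use all five normalized metrics with equal weight by
default; `metrics = c("axon_density", "axon_volume_fraction")` reproduces
the two-metric variant.

## Problem sizes and reproducibility

All shipped analyses run at desk scale: 64 × 64 grids (about 1,500
white-matter pixels per slice; ~600–750 on a hemisection), 5 subjects × 31
levels for cohort counting, and reduced slice counts per region for
registration-heavy aggregation checks.  The test suite and the acceptance
script regenerate every input programmatically from seeds; all randomness
flows from a single master seed (per-sample seeds are drawn once and
recorded in the manifest), and clustering itself is deterministic by the
tie-break rule.

## Known limitations

* The nonrigid engine is a small-deformation FFD, not a diffeomorphic
  model; large or folding deformations are out of contract.
* The toy atlas is a topological stand-in, not a digitization of any
  published drawing; real tract shapes, inter-tract gaps and missing-tract
  caveats of reference atlases are not modelled.
* Region-wise aggregation assumes slowly varying tract topology within a
  region — an oversimplification for small tracts, inherited knowingly from
  the study design it mirrors.
* Morphometric distributions overlap across tracts by construction; with
  realistic noise, only tracts with well-separated signatures (notably the
  dCST) are reliably recovered as single clusters.  That is the scientific
  point, not a defect.
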