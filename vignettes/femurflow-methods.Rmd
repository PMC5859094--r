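---
title: "Conformal parametrisation and statistical mapping of proximal femur surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformal parametrisation and statistical mapping of proximal femur surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Comparing cortical bone morphology across a cohort requires a dense,
consistent correspondence between subjects' periosteal surfaces. Proximal
femur surface meshes segmented from tomographic images are open surfaces
(genus 0 with a single distal boundary) whose distal extent varies with the
imaging field of view, so the boundary itself is useless as a registration
reference, and reliably detectable anatomical landmarks are few. `femurflow`
implements a registration chain that sidesteps both problems by flattening
each surface conformally and matching subjects in the 2D parametric domain,
where rigid motion, scale and isometric bending of the 3D anatomy have no
effect.

The chain is: discrete Ricci flow to a flat metric -> planar embedding ->
automatic detection of the femoral head (FH), greater trochanter (GT) and
lesser trochanter (LT) from conformal-factor peaks -> slitting and
normalisation into a common strip/annulus frame -> template registration
with compactly supported radial-basis corrections -> per-node feature maps
(cortical thickness, surface principal strains) -> node-wise linear models
with cluster-level multiple-comparison correction.

# Discrete Ricci flow

A triangle mesh carries a discrete metric: one length per edge. We deform
it conformally by per-vertex log factors `u`,

    l_ij  =  l0_ij * exp((u_i + u_j) / 2),

the discrete conformal (vertex-scaling) metric. The discrete Gaussian
curvature at a vertex is the angle deficit (`2*pi` minus incident corner
angles at interior vertices; `pi` minus the sum at boundary vertices, so
the total always equals `2*pi*chi` by the combinatorial Gauss-Bonnet
identity). Ricci flow drives the curvature to a prescribed target; the
target determines the parametrisation:

* **Disk step** (`disk_free_boundary`): target curvature 0 at every
  interior vertex and the boundary metric left unchanged, realised as
  `u = 0` on boundary vertices. The flat metric develops into a planar
  disk-like domain.
* **Annulus step** (`annulus_zero`): after the inter-feature slit the
  surface has `chi = 0` and two boundaries; target curvature 0 at *every*
  vertex (boundaries included) yields a flat cylinder whose development is
  a straight strip and whose exponential image is a circular annulus.

The curvature map is solved by Newton's method: its Jacobian with respect
to `u` is the half-cotangent-weighted Laplacian of the current metric, a
convex-energy structure that converges quadratically (three to five
iterations to `1e-10` on ~1k-vertex meshes). A step-halving line search
guards the triangle inequalities and enforces a monotone curvature
residual; in the annulus step the additive gauge freedom of `u` is pinned
at one vertex, whose curvature then vanishes automatically by
Gauss-Bonnet. We use vertex scaling rather than inversive-distance circle
packing because it needs no auxiliary radii/angle structure, has the same
convex Newton energy, and its conformal classes are well understood; the
two give the same flat metrics in practice up to solver tolerance.

Defaults: `tolerance = 1e-8` on `max|K - Kbar|` (radians), `max_iter = 50`.

The flat metric is developed into the plane by breadth-first face
propagation from a reproducible seed face (the lowest-index face, or the
lowest-index face touching the slit boundary for the fundamental domain).
Because the metric is flat to solver tolerance, placement is
path-independent: embedded edge lengths match the metric to ~1e-12
relative, and face orientations are checked to exclude fold-overs.

# Feature detection

The conformal factor (stored as `-u`, larger where the flattening
compresses the surface) concentrates at protruding processes. FH and GT are
the two most prominent interior local maxima of the disk parametrisation's
conformal factor; prominence is computed by watershed flooding (descending
sweep with union-find merging), which is deterministic and scale-free.
FH is the peak with the *higher* conformal factor: the head is the largest
protrusion and is compressed the most. (The planar footprint of the fitted
feature regions is not a reliable discriminator, because stronger
compression shrinks the larger feature's planar image; on perturbed
synthetic cohorts a footprint rule mislabels a few percent of subjects.)

LT does not separate from the FH/GT processes in the disk parametrisation;
it is detected on the strip (annulus metric) after excluding the
neighbourhoods of FH and GT. Each feature's *region* is a 2D Gaussian
(centre, covariance, amplitude) fitted by Levenberg-Marquardt to the
conformal factor over the peak's watershed basin, capped at the basin's
highest exit level so only the local dome is fitted. Two numerical choices
matter here:

* the fit's constant offset is pinned at the basin minimum: a free offset
  trades off against amplitude and width and leaves the least-squares
  problem unidentified (the optimiser wanders a flat valley);
* LT exclusion uses a 3-sigma Mahalanobis neighbourhood of the FH/GT
  Gaussians (`exclusion_sigma = 3`), because the processes extend well past
  their 1-sigma support and their shoulders otherwise out-rank the weaker
  LT peak.

Prominence thresholds are in log-conformal-factor units and therefore
scale-invariant: 0.1 for the disk peaks, 0.02 for LT (the annulus-metric
factor varies on a smaller scale). The support of a region is every vertex
within Mahalanobis distance 1 of the fitted centre.

# Slitting and the common frame

The straight segment between the FH and GT positions in the disk is traced
through the triangulation (snapping to vertices within a relative
tolerance of 1e-6 of the segment length, splitting crossed edges
otherwise) and the mesh is slit along it: interior path vertices are
duplicated and the faces strictly right of the oriented path reassigned.
This turns the disk into a `chi = 0` surface with two boundaries. After
the annulus flow, a shortest edge path (Dijkstra on 3D edge lengths,
avoiding boundaries) from GT to the distal boundary is slit the same way
— here endpoints on boundaries are duplicated too, so the annulus opens
into a disk-type fundamental domain.

The development of this domain is normalised by a similarity transform
(never a reflection): the inter-feature chain is mapped onto the imaginary
axis spanning exactly `[0, 2*pi]`, with the surface in the left
half-plane and the distal boundary parallel to the axis. `z -> exp(z)`
then produces the annulus with the slit on the unit circle. The two GT
copies land at 0 and `2*pi`; the FH vertex lands at the imaginary
coordinate that splits the chain by conformal length. It sits at `pi`
exactly when the two slit sides have equal developed length — true by
construction for the mirror-symmetric synthetic femora used in the tests,
and reported (not enforced) for general input.

# Template correspondence

The canonical template is the normalised strip of a designated reference
subject (the first, by default), cropped at 95% of the cohort's minimum
distal extent so it stays inside every subject's domain. For each target:

1. an RBF deformation is built from the FH and LT region pairs: control
   points are each template region's centre plus eight points on its
   1-sigma ellipse, displaced onto the target region by translation plus
   the symmetric (rotation-free) scaling `St^(1/2) ST^(-1/2)` — the strip
   frame already fixes orientation, so no rotation is fitted (a documented
   limitation);
2. the Wendland C2 kernel `(1 - r/rho)^4 (4r/rho + 1)` interpolates the
   control displacements exactly and vanishes identically beyond the
   support radius `rho` (default: twice the largest template region
   sigma), so the correction is local by construction;
3. each deformed template node is located in a target face (lowest-index
   face on ties) with barycentric weights; nodes outside the target domain
   are clamped to the nearest boundary point and flagged (clamped nodes are
   excluded from statistics rather than extrapolated);
4. target 3D coordinates and per-node scalar fields are interpolated
   barycentrically — linear precision is exact.

The registered cohort is an isotopological set: one connectivity, per
subject an `n x 3` coordinate array and per-node feature vectors.

# Morphometry

Cortical thickness at an outer-surface node is the exact shortest distance
to the inner surface (point-to-triangle minimum over all faces, with
bounding-box pruning that provably returns the brute-force value).
Generalised Procrustes alignment (translation, proper rotation, optional
scale; reflections rejected — anatomy is chiral) iterates to a mean-shape
change below `1e-10`. Scale factors are the Procrustes scale of the
mean-to-subject fit, reported relative to the cohort geometric mean, so a
cohort of identical shapes has scale exactly 1 and planted global size
multipliers are recovered proportionally. Shape modes are principal
components of the aligned, mean-centred coordinate vectors (default 5
modes); with scale normalised, mode-1 scores are uncorrelated with size,
so the modes can serve as shape confounders in the node-wise models.

# Statistical parametric mapping

Node-wise ordinary least squares with a shared design (group indicators,
body weight, scale factor, shape-mode scores; impact force for strain
models), t-statistic of the group contrast with residual `df = n - p`.
Nodes with control-mean thickness below 1 mm are masked (image-resolution
limit). Supra-threshold clusters are connected components (template mesh
edges) of nodes with one-sided `p < 0.005`; each group-versus-control
contrast is run one-sided in each direction and reported with its sign.

Cluster-level family-wise error control:

* **Permutation (primary)**: Freedman-Lane — fit the nuisance-only model,
  permute its residuals over subjects, refit the full model, record the
  maximal supra-threshold cluster extent; the cluster p-value is the
  (add-one) tail proportion of the null maxima. Exact under
  exchangeability, seeded and reproducible bit-for-bit.
* **Random field theory (`method = "rft"`)**: the expected-Euler-
  characteristic approximation for a 2D t field, with residual smoothness
  (FWHM) estimated from normalized-residual gradients along template
  edges. Provided for comparability with the SPM literature and flagged
  as an approximation (it warns below 1000 nodes).

Significant clusters are summarised by their mean percent difference
`100*(mean_group - mean_control)/mean_control` and a node-count histogram;
composite maps label each node with the set of groups whose significant
clusters contain it (`"n/s"` when none). A relaxed cluster-forming
threshold is a plotting convenience only and is never used for inference.

# The synthetic femur generator

Because cohort-level results from the original imaging data are not
reproducible without that data, every claim the package tests is grounded
in a seeded generator (`femur_spec()`, `make_femur()`, `make_cohort()`).
It emulates a proximal femur as a flattened dome continued by a shaft tube
with one open distal boundary, plus Gaussian radial protrusions for FH
(medial, large), GT (lateral, opposite) and LT (medial, distal to FH), and
a concentric inner shell offset along vertex normals with a
curvature-limited step. Defaults (dome radius 22 mm, shaft radius 15 mm,
shaft length 60 mm, dome flattening 0.45, bump amplitudes 13/9/4.5 mm,
shell thickness 2 mm) were chosen once to give the qualitative anatomy —
two dominant processes separated by a saddle, a weaker distal LT — at
proximal-femur scale. With the default azimuths the mesh is *exactly*
mirror symmetric about the FH-GT plane (trig tables are built so mirrored
vertices agree bitwise up to the sign of y, and triangulation diagonals
flip across the plane); this symmetry is what makes "FH at pi" an exact
property of the fixtures.

Cohorts add subject-level variation (log-normal shaft length and global
size, bump positions along the generatrix), spatially smoothed
multiplicative thickness noise (10% per node, 5% between subjects),
planted group effects (a region's thickness multiplied by `1 + pct/100`),
and covariates (weight ~ N(65, 8) kg, sideways-fall impact force ~
N(2600, 350) N). `simulate_thickness_cohort()` generates per-node fields
directly on a fixed template for the statistical calibration experiments.

What the generator does *not* emulate: real segmentation noise,
non-manifold defects, anteversion/neck-shaft angle variation, anisotropic
cortices, or realistic strain fields. Passing tests therefore demonstrate
the correctness and calibration of the machinery, not clinical validity on
MR-derived surfaces.

# Problem sizes and runtimes

Tests run at mesh resolutions of roughly 1.1k vertices (28 azimuthal x 40
axial samples) and a ~1.2k-node template; a full parametrisation takes
about one second at this size, and the statistical calibration (200 null
cohorts x 500 permutations, n = 20 vs 20) a few minutes. These sizes were
chosen as the smallest at which every geometric property (peak separation,
slit topology, clamp behaviour) is comfortably resolved; all operations
scale to the ~25k-vertex meshes typical of imaging studies, where a
parametrisation takes on the order of a minute.

# Known limitations

* The FH-at-pi property is exact only for slit sides of equal conformal
  length (e.g. the symmetric fixtures); for general anatomy FH lands near,
  not at, pi, and the package reports its coordinate.
* Region matching uses translation plus symmetric scaling; residual
  rotational anisotropy between subjects is not corrected.
* Correspondence in inter-feature regions is only as good as conformal
  alignment plus two local corrections; anisometric variation between the
  features is not explicitly modelled.
* The RFT cluster correction is an asymptotic approximation on a mesh;
  the permutation route is the calibrated default.
* Clamped (out-of-domain) template nodes are excluded from statistics, so
  cohorts with widely varying distal extents lose distal rows.
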