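---
title: "Vision-based tray phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vision-based tray phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phenotray recovers three growth traits of tray-grown seedlings — plant
height, visible leaf area and leaf weight — from a fixed overhead RGBD
camera, without touching the plants. This vignette explains the models
each stage implements, the parameters that matter, what the synthetic
scene generator does and does not emulate, and the design choices made
where the method left room.

## The imaging model

The camera is fixed above the tray and is the world reference frame.
Its calibration matrix is

$$K = \begin{pmatrix} f m_x & s & p_x m_x \\ 0 & f m_y & p_y m_y \\
0 & 0 & 1\end{pmatrix},$$

with focal length $f$ (mm), pixel densities $m_x, m_y$ (px/mm), skew
$s$ and a principal point expressed in normalized units, so that the
matrix carries $p_x m_x$ and $p_y m_y$ — the convention of
`camera_intrinsics()`, documented everywhere because it differs from
the common pixels-only form. Pixel coordinates are 0-based, `x` =
column, `y` = row, with pixel centers on integers.

Radial distortion is corrected about a distortion center:
$\hat x = x_c + L(r)(x - x_c)$, with
$L(r) = 1 + \kappa_1 r + \kappa_2 r + \dots$ **as printed in the
sensor-style convention this package follows**: each coefficient
multiplies $r$ linearly. This is almost certainly a typographical
collapse of the conventional even-power series
$1 + \kappa_1 r^2 + \kappa_2 r^4 + \dots$, which is available behind
`undistort_pixel(..., series = "even")`; the default reproduces the
printed form rather than silently "fixing" it.

A depth pixel $(\hat x, \hat y, d)$, with $d$ the integer range in mm
and $d = 0$ meaning *missing*, deprojects to
$(X,Y,Z)^\top = d\,K^{-1}R\,(\hat x, \hat y, 1)^\top + t$. With the
default extrinsics $R = I$, $t = 0$, depth equals the $Z$ coordinate.

## Depth fusion

A single depth frame is sparse (reflection holes) and noisy.
Ventilation and flicker move the leaves slightly between captures, so
the four frames taken per day act like small camera motions; merging
them per pixel over the non-zero samples fills holes and averages
noise. The default aggregator is the **median** (robust to jitter
outliers; the mean is a config switch) over a default window of 4
frames, the per-day capture count. Zeros never enter the aggregate: a
pixel stays missing only when missing everywhere.

The merged map is smoothed with a normalized Gaussian kernel
(11 × 11, σ = 1.3 px). The convolution is *masked*: zero pixels are
excluded from the weighted average and stay zero. This matters twice —
sensor holes must not drag heights toward zero, and the grid-line
pixels zeroed by the line mask must not bleed tray depth into the
canopy.

## Tray geometry: plane, registration, metric rescale

The tray plane is fitted by random triple consensus (inlier threshold
3 mm, the depth-noise scale) followed by a total-least-squares refit on
the inliers; consensus makes the fit immune to the canopy, which
dominates the cloud at later days. Points beyond the plane are
clipped. Two clouds from consecutive merge windows are aligned by
point-to-point ICP (nearest neighbours + closed-form rigid motion,
monotone RMS) and points without support in the second cloud within
5 mm are removed as loose correspondences.

Deprojected coordinates are only approximately metric — the camera is
not perfectly aligned with the tray, and factory intrinsics are
imprecise — so the cloud is rescaled from known geometry: the four
vertices of one visible cell, which are 30 mm apart. The fitted map
$V_E = T V_M$ is by default a **similarity** transform (rotation,
translation, one isotropic scale, closed form); whether the original
formulation intends anisotropic scaling is unstated, so a full affine
fit sits behind `model = "affine"`. Four coplanar points
under-determine a 3D affine map; the fit is completed by constraining
the plane normal to map to the target plane normal.

## The cell grid and per-cell heights

Cell boundaries are visible only at early days, so the grid is
detected once per rack, at the earliest day, and reused. Detection is
Canny-style edge extraction (Sobel gradients + two-threshold
hysteresis) followed by a Hough transform restricted to two
orientation bands (±5° around vertical and horizontal — the tray is
axis-aligned up to rig tilt). One physical line excites several
(ρ, θ) bins, so candidates are clustered by a θ-invariant position and
each cluster keeps the sharpest θ with a vote-weighted centroid ρ; the
vote threshold is relative to the strongest line per orientation
(default 0.5) because the tray need not span the frame. Detected lines
are rasterized 1 px wide into the binary mask `L`, and the masked
depth is the Hadamard product `Ml = M ∘ L`.

Vertices are pixels whose four neighbours are all line pixels — the
signature of a crossing — then refined to the analytic intersection of
their two nearest detected lines (the rasterized crossing sits on
integer pixels; the refinement is sub-pixel). Cells are vertex triples
$(V_i, V_j, V_k)$ — two consecutive edges of the cell parallelogram —
and a projected point lies in a cell iff the projections of
$(V_i - \hat p)$ on $(V_i - V_j)$ and of $(V_j - \hat p)$ on
$(V_j - V_k)$ both lie **strictly** between 0 and the squared edge
length. Strictness means boundary pixels belong to no cell; they
coincide with the zeroed line pixels, so no height sample is lost
ambiguously, and cells are provably disjoint.

The height surface is $H_p = D(\pi, \tau) - M_l$ with
$D(\pi,\tau) = 505$ mm, the rig's camera-to-tray distance — a required
configuration constant, defaulting to 505 mm. The residual noise term
in that relation is not sampled anywhere: it denotes what survives
smoothing, and is handled by clamping (counted) negative heights to
zero. Per cell, the statistics are the maximum, the mean, and the
sample standard deviation with the $N-1$ denominator, over pixels with
positive height. Heights are metric end-to-end because depth is metric;
x, y remain in pixels for cell assignment, which needs no rescaling.

## Leaves: segmentation, projection, occlusion, surface

Instance segmentation is a pluggable backend: anything that maps a
colour image to an integer label matrix attaches through the same
interface (a deep instance-segmentation model in the original setting).
The bundled classical fallback thresholds green-dominant pixels, uses
bright blade interiors as seeds (the darker leaf margins separate
touching leaves) and propagates the seeds over the green support, with
a distance-transform watershed as the seedless fallback. It assumes
surface leaves are distinguishable from the shaded understory by
colour; a learned backend relaxes that. Leaves occluded by more than
about 60% of their area are outside the measurement contract.

Each mask gets a unique colour id and is projected into 3D as an
indicator on the cloud: a point is in leaf $j$ iff its source pixel
carries mask $j$'s colour. Per-point normals come from a plane fit to
the $k = 12$ nearest neighbours, oriented toward the camera.

A leaf occluded in the image may be partly disoccluded in 3D; its
label is grown outward from its boundary with the cost
$w_n(P,P') = \kappa D(P,P') + (1-\kappa)(1 - n_P\!\cdot\!n_{P'})$,
absorbing unlabelled candidates whose minimal cost over the boundary
falls below a threshold, iterated to a fixed point. Defaults:
$\kappa = 0.5$, threshold 0.3 (an empirical constant with no published
value), $D$ = Euclidean distance normalized by the cloud's mean k-NN
radius so both terms are dimensionless. **Deviation, deliberately:**
the cost as printed in the source formulation uses $+\,n_P \cdot
n_{P'}$, which under arg-min *rewards misaligned normals* and would
absorb perpendicular surfaces — contradicting its stated purpose. The
default uses $1 - n_P\cdot n_{P'}$; the printed form is available with
`as_printed = TRUE`. Points already owned by another leaf are never
absorbed, so growth is monotone and label-safe.

## Leaf area

Leaves at the measured stages are near-planar organs, so surfaces are
parameterized on the principal plane of the labelled points (covariance
eigenvectors). Two estimators:

* **Triangulation** — Delaunay in the plane parameterization, lifted to
  3D; area is the sum of triangle areas. Dense depth points carry
  quantization and residual noise that would tilt every small triangle
  and inflate the area, so the normal displacement is smoothed over 8
  neighbours before lifting.
* **Spring-relaxed quad mesh** — a regular grid at pitch `quad_size`
  (default 2 mm against leaf scales of 20–60 mm; the pitch trades
  smoothness against fit, and is deliberately config-exposed) on the
  principal-plane bounding box, relaxed by damped descent sweeps
  (damping 0.5, tolerance 1e-3 mm, max 500 sweeps, energy kept
  non-increasing by step halving, with an energy-plateau stop). The
  energy is data fidelity plus a spring term $(\|e\| - q)^2$ per grid
  edge. Fidelity has two zones: vertices *inside* the data support are
  pulled onto the local tangent plane only (normal displacement, so
  the in-plane pitch is preserved), while rim vertices overhanging the
  support snap to their nearest data point so boundary quads contract
  to the leaf outline; edges touching snapped vertices leave the
  spring term, otherwise the rim contraction would compress the whole
  lattice below pitch. The exact energy of the original spring
  formulation is not published; this instantiation is the package's
  own and is config-exposed.

After relaxation, faces containing no data point are deleted, **but
only while on the mesh boundary**; interior empty faces — occlusion
holes — are retained so the surface is not punctured. Area is the sum
of face areas, quads split into two triangles. Before either fit, points
far off the leaf's dominant plane (stray understory or neighbour pixels
picked up at mask borders) are trimmed by a median/MAD filter on the
normal displacement.

## Weight from area

A reference sample of destructively measured leaves relates single-leaf
weight to area. The default model is the leaf density
$\rho_{BL} = W_{BL} / \mathrm{Area}_{BL}$ (g/mm²), estimated as the
mean per-sample ratio — with one sample it is the exact ratio. A small
fully connected network (one hidden layer of width 8, logistic
activations, linear output, full-batch fit at a fixed seed) and a
polynomial are alternatives; the network mirrors the original two-layer
regressor but is *not* the default because its reported training
behaviour cannot be reproduced without the original reference sample,
and we report RMSE rather than an "accuracy" for a regression.
Whatever the kind, the fitted map must be strictly increasing over the
observed weight range — that is what makes inversion well-posed — and
is rejected otherwise.

The manual protocol weighs all leaves of a plug and counts them, so
area is predicted from the mean single-leaf weight,
$A_W = \mathrm{net}(W_{\mathrm{leaves}}/N_{\mathrm{leaves}})$, and
weight is predicted from vision-measured area by bracketed root finding
on the same map (closed form for the density model). The leaf count is
always an *input*: the pipeline does not predict how many leaves a plug
carries. Within the pipeline, the per-day area fed to the inversion is
the **median** over segmented leaves — robust to the occasional partial
crescent of an occluded leaf or a merged mask. Values at unmeasured
days are interpolated by least-squares polynomials in the day index.

## Evaluation

Predicted samples are every canopy pixel (order 10^5); manual samples
are a few dozen harvested plugs. Paired comparison is meaningless at
such unequal sizes, so each side is summarized as a Gaussian and
compared with the closed-form Bhattacharyya distance

$$D_B = \tfrac14\ln\!\Big(\tfrac14\big(\tfrac{\sigma_p^2}{\sigma_m^2} +
\tfrac{\sigma_m^2}{\sigma_p^2} + 2\big)\Big) +
\tfrac14\frac{(\mu_p - \mu_m)^2}{\sigma_p^2 + \sigma_m^2},$$

natural logarithm (the standard convention; the base is unstated in the
original formulation). $D_B$ is symmetric, zero iff the summaries are
identical, and invariant to common unit changes. Normality is assumed,
as the protocol does for height. The density-class comparison is
descriptive: per-class histograms, pairwise feature scatter tables and
a standardized mean difference per feature — no classifier is fitted.

## The synthetic scene generator

No image corpus is deposited with the original study, so the generator
is the package's test bed: it renders the rig — a planar tray at
505 mm, dark grid lines at 30 mm pitch, 720 × 1280 frames, four per day
with ≤1 px jitter, Gaussian depth noise (σ = 2 mm), 10% holes — with
per-cell canopies of planar elliptical leaves. Rendering is exact ray
casting against the leaf planes, so every depth pixel deprojects onto
the true 3D surface and leaf areas are analytically $\pi a b$.

Choices a scientist should know about:

* Canopy height follows a logistic in days (midpoint day 14, rate
  0.45), with asymptotes 140 mm (high density) / 120 mm (low) and
  between-cell spread 4 mm (high) / 6 mm (low) — denser planting
  stabilizes heights through competition, so the generator encodes the
  tighter spread for the dense class.
* Leaf size scales with the same logistic: lines are visible early
  (grid detection uses day 7), a closed canopy forms from about day
  15. Four surface leaves per plug sit near quadrant anchors with
  semi-axes 6.5–8.5 × 5–6.5 mm at full size and tilt ≤ 20°.
* Once the canopy closes, a shaded understory pad fills each cell
  8 mm below the surface leaves, slightly darker and less
  green-dominant than sunlit blades, extending a 6 mm margin across
  cell borders (lower foliage does not respect cell lines, and the
  margin also closes parallax wedges between pads of unequal height).
* Leaf density is 2e-4 g/mm², a realistic fresh-leaf value; leaf
  weight is exactly density × area, so the biomass chain has exact
  truth.
* All randomness flows from one seed; scenes are bit-reproducible.

What the generator does **not** emulate: leaf curvature (planar
ellipses only), specular highlights, true occlusion release over time,
plant-level structure within a plug, or the texture that a learned
segmentation model would use. Passing tests therefore demonstrate the
geometry and statistics of the pipeline, not segmentation quality on
real imagery — the segmentation backend is exactly the replaceable
part.

Problem sizes in the shipped tests and in `scripts/acceptance.R` are
the package's own choices: the full 720 × 1280 rig frame with a 12 × 12
cell tray for the grid/height checks, and reduced 5 × 6-cell racks at
340 × 400 px (both density classes, days 21/24/28) for the end-to-end
run — small enough to re-run routinely, large enough that every stage
sees realistic geometry.

## Known limitations

* The classical segmentation fallback needs a colour contrast between
  surface leaves and what lies beneath; it is a stand-in interface
  contract, not a replacement for a trained instance model.
* Heavily occluded leaves (>60%) are out of contract end to end, as in
  the original protocol; the occlusion extension recovers only parts
  that are disoccluded in 3D.
* Depth quantization (integer mm) plus smoothing leaves a sub-mm
  floor on height accuracy; per-cell means are good to well under
  1 mm, individual pixels are not.
* The ICP cleaning pairs consecutive merge windows; the original
  formulation does not state the pairing and other choices are
  possible.
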