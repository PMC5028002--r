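---
title: "corticomap: models, procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{corticomap: models, procedures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticomap)
```

# The problem

Cortical area V5/MT and its neighbour MST are defined three different ways:
histologically, by a dense band of intracortical myelin across the deep
layers; structurally in vivo, by high signal in myelin-weighted MRI
(T1w/T2w ratio maps or MP2RAGE-like acquisitions); and functionally, by
motion-selective fMRI responses, ipsilateral-field responses (MST), and
contralateral retinotopy (V5/MT). `corticomap` provides the quantitative
machinery for asking how well these definitions agree: areal overlap
statistics with permutation-calibrated chance levels, threshold-sensitivity
sweeps, a histological validation arm, and a synthetic phantom whose ground
truth is known analytically.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices made where the procedure was genuinely
open, what the phantom does and does not emulate, and known limitations.
All empirical statements here are computed by the test suite or the
acceptance script; none are copied from elsewhere.

# Myelin-weighted mapping

**Ratio maps.** Repeat scans of each modality are averaged voxelwise and
then divided: `R = mean(T1w) / mean(T2w)`. Averaging precedes division
(dividing per-repeat and averaging afterwards is not the same operation
under noise). Voxels whose mean T2w falls at or below a guard level
(`eps = 1e-6`) are flagged invalid, never set to infinity; invalid voxels
propagate to invalid vertices during sampling and are excluded from every
statistic. The ratio cancels multiplicative receive-bias fields shared by
the two acquisitions; the phantom deliberately gives each modality an
*independent* bias field so that the residual (non-cancelling) error is
exercised and bounded in tests.

**Depth sampling.** A vertex at white coordinate $w$ and pial coordinate
$p$ is sampled at $w + f\,(p - w)$ by trilinear interpolation, where
$f \in [0,1]$ is the cortical thickness fraction ($f=0$ white, $f=1$
pial). The working depth is chosen by exhaustive search over
$f = 0, 0.1, \dots, 1$, maximizing the mean over valid vertices; exact
ties break toward the smaller fraction (recorded via the `"means"`
attribute). On the default phantom the search returns $f = 0.6$, the
constructed profile peak.

**Thresholding.** Two rules are implemented:

- `topFraction(f)` keeps vertices at or above the $(1-f)$ quantile of the
  valid, non-excluded values (ties at the boundary all included). The
  phrase "top third of the intensity values" admits a second reading — a
  cut at $\min + \tfrac{2}{3}(\max - \min)$ of the intensity *range* —
  which is available via `reading = "intensity_range"`; the per-vertex
  quantile is the default because it fixes the mask's size rather than
  making it depend on the tail shape.
- `meanPlusKSEM(k)` keeps vertices strictly above
  $\bar{x} + k\, s/\sqrt{n}$. The population for $\bar{x}$, $s$ and $n$
  is the valid, non-excluded vertex set of that hemisphere's map; excluded
  vertices (e.g. a temporal-lobe artifact mask) enter neither the
  statistics nor the mask. Whether such exclusions should also be removed
  from the reference population is not dictated by the procedure itself;
  we remove them from both, which keeps the threshold a function of the
  data actually under analysis.

Note that *adding* exclusions can lower the threshold (removing high
values drags the mean down) and therefore legitimately admit new vertices:
exclusion is not a monotone operation on the output mask, and the package
does not pretend otherwise. Both rules are invariant under positive
rescaling of the map.

**Areas.** Per-vertex area is one third of the summed areas of incident
triangles, computed on the midthickness surface (the mean of white and
pial coordinates). Which layer the area should be measured on is
underdetermined — white and pial areas differ systematically in curved
cortex — and midthickness is the least biased single choice. The
"contiguous densely myelinated area" is the sum of per-vertex areas over
the edge-connected component of the thresholded mask containing a seed
vertex.

**Display clipping** (`displayClip`, defaults 4%/96% of the full value
range) affects visualization output only; no statistic uses clipped
values.

# Functional ROI definitions

**Cluster extraction.** Connected components of $\{z > z_{thr}\}$
(default 2.3) under 6/18/26-connectivity (default 26). Cluster-level
inference via Gaussian random field theory is out of scope; instead the
extent criterion is calibrated by permutation: 1000 sign-flip surrogates
of the z-map (each suprathreshold-able voxel keeps its magnitude and draws
a random sign), the null distribution of the largest suprathreshold
cluster, and the extent at the $1-\alpha$ quantile (default
$\alpha = 0.05$). A fixed voxel-count override is available and is what
the tests mostly use, for speed and exactness.

**Assignment rules.** hMT+ is the surviving cluster whose peak lies
nearest a user-supplied world-coordinate anchor — the "putative anatomical
location" is observer knowledge the software cannot infer, so it is an
explicit input. Proximity beats size; exact ties keep the higher-peak
cluster and say so. MST is the union of ipsilateral-motion clusters that
intersect hMT+, each included *in full*, including voxels outside hMT+
(ipsilateral activation that forms one cluster extending beyond the
complex belongs to MST in its entirety). V5/MT is the set of hMT+ voxels
with retinotopic coherence above threshold (default 0.25), minus MST — so
V5/MT and MST are disjoint by construction.

**Phase-encoded retinotopy.** Per run, each voxel's time course is
projected onto a design containing an intercept, a linear trend, and the
stimulus-frequency sine/cosine pair; only the intercept and trend are
removed. This matters: over a finite run a linear ramp is not exactly
orthogonal to the stimulus frequency, and removing a *naively* fitted
trend leaks a pure tone into neighbouring bins and biases its phase (the
bias is small — $10^{-3}$–$10^{-2}$ rad — but the noiseless contract here
is $10^{-6}$). The detrended series is DFT'd; complex components are
averaged across repeat runs *before* phase extraction (vector averaging:
averaging phases directly would be a different, inferior estimator near
the noise floor, and the choice is recorded here rather than guessed as
anyone's intent). Phase is reported in $[0, 2\pi)$ under the
$\cos(2\pi f t - \varphi)$ convention; coherence is the stimulus-bin
amplitude divided by the root-sum-square amplitude over all positive
non-DC bins, so a noiseless tone has coherence 1 and white noise
concentrates near $1/\sqrt{K}$ for $K$ bins. The stimulus period must
divide the run length into at least two whole cycles (the frequency must
sit on a DFT bin); violations raise a named error with guidance rather
than silently interpolating off-bin.

**Group masks** binarize, sum and keep locations present in at least the
given fraction of individuals; the boundary case (exactly half under
`minFraction = 0.5`) is included, matching an "at least 50%" rule.

# Correspondence statistics and nulls

Whole-cortex correspondence is $100\,|A \cap B| / |A \cup B|$ — the
overlap counted once in the denominator. Within an ROI $R$ the analogous
statistic is $100\,|A \cap B \cap R| / |(A \cup B) \cap R|$; the wording
"total number of thresholded voxels present within the ROI" could also be
read as $|A \cap R| + |B \cap R|$ (a Dice-like variant with double
counting), which is provided via `denominator = "sum"`, with the
union reading as the default by parallelism with the whole-cortex
definition. Percent-of-ROI-myelinated is $100\,|R \cap M| / |R|$. All
percentages are exact ratios of recorded integer counts.

Chance levels come from intensity shuffling: each permutation
independently permutes each map's valid values across its valid vertices,
re-thresholds with the same rule, and recomputes the statistic. Shuffling
values (not binary masks) preserves the value distribution, hence exactly
the mask size under quantile rules and approximately under SEM rules. The
p-value uses the add-one convention $p = (1 + \#\{null \ge obs\})/(n+1)$,
which cannot return zero from a finite permutation set. For independent
random masks of densities $p, q$ the expected correspondence is
$100\,pq/(p + q - pq)$ — with $p = q = 0.1$, about 5.26% — and the test
suite checks the shuffle null against this closed form within Monte-Carlo
error.

The threshold sweep re-derives the myelin mask for
$k \in \{0, 0.5, 1, 1.5\}$ SEM and the functional ROI for
$z \in \{1.3, 1.8, 2.3, 2.8\}$ and tabulates sizes, the
percent-of-ROI-myelinated and whole-cortex correspondence per cell; the
margins are monotone by construction of the rules, and the
$(k{=}1, z{=}2.3)$ cell reproduces the standalone pipeline exactly (no
hidden state).

Functional ROIs are defined in the volume but compared with
surface-defined myelin masks; the bridge (`maskToSurface`) marks a vertex
as inside an ROI when its depth-fraction sample point falls in a member
voxel. This is nearest-voxel membership, deliberately the same geometry as
the sampling that produced the myelin map.

# Histology arm

Intensity profiles are sampled every 15 µm along an operator-supplied
pial-to-white path, with 6 lateral samples perpendicular to the local path
direction per position (means and SDs recorded). Smoothing is robust
locally weighted least squares with a second-degree polynomial model and
bisquare reweighting (`loess`, `family = "symmetric"`) — exact on
quadratics, resistant to isolated outliers. Profile comparison is the
two-sample KS statistic on the raw per-position means: the smoothed curve
is for display, and testing smoothed values would understate the sample
variability.

Myelinated length per section walks the pial trace and samples the stain
at 70% of the local pial-to-white distance — the deep-layer band — and
counts contiguous runs darker than the operator's stain threshold,
returning pial arc length (not the straight chord; the arc is what a
tracing tool measures). Areas aggregate across a section series by the
trapezoid rule $\sum_i \tfrac{1}{2}(l_i + l_{i+1})\,\Delta$ with $\Delta$
the spacing between retained sections. Section thickness is carried as
metadata but *not* added to the trapezoid — the spacing between retained
sections already spans the cut tissue; an optional thickness end-cap mode
exists for the alternative reading. Zero-length sections in the series
participate, tapering the ends; a single non-zero section flanked by
zeros contributes length × spacing.

Printed-table summaries use the arithmetic mean and sample SD ($n-1$);
a single-valued group reports a missing SD, never zero, and missing table
entries stay missing. Method agreement is a two-sided Pearson correlation
over complete (sMRI, histology) pairs; incomplete pairs are dropped with a
message. On the four complete left-hemisphere pairs of the shipped table
the correlation computes to 0.996; the package reports what the supplied
pairs give and makes no attempt to force any particular printed value.

# The phantom: a stated world

The synthetic dataset is one sheet of cortex, not a whole brain: a
rectangular sheet (default 30 × 30 mm at 0.3 mm vertex spacing, 10 201
vertices), optionally folded sinusoidally in one direction and tilted
against the voxel grid (default slope 0.15). Because the sheet curves in
at most one direction it is developable: its intrinsic geometry is flat,
geodesic discs are exact Euclidean discs in arc-length coordinates, and a
patch of radius $r$ has true area $\pi r^2$ wherever it fits. White and
pial surfaces are vertical offsets $\pm h(x)$ with
$h = \tfrac{t}{2}\sqrt{1 + f'(x)^2}$, chosen so the *normal* thickness is
exactly $t$ (default 2 mm) everywhere — so per-voxel depth fractions are
available in closed form and the ground truth never depends on rendering.

The tilt deserves a note: a perfectly grid-aligned slab makes voxel
centres fall symmetrically about mid-depth for every vertex
simultaneously, and the discrete depth-fraction search then ties or peaks
at the voxel-centre depth instead of the true profile peak — an alignment
degeneracy that real, curved, obliquely cut cortex never exhibits. The
default tilt sweeps the ribbon across voxel phases exactly as anatomy
does, and is part of the stated world, not a tuning knob.

The myelin field is `floor + (1-floor) * exp(-(d - peak)^2 / (2 w^2))`
with peak depth 0.6, width 0.2 and floor 0.5, multiplied by the patch
contrast (default 1.5) inside the patch. Structural contrast is linear in
myelin (T1w up, T2w down) so the ratio is strictly increasing in true
myelin; background classes use CSF analogues and a white-matter analogue
whose ratio sits just *below* peak cortical ratio — dense deep-layer
myelin approaches white matter intensity, and this ordering keeps the
depth search driven by intracortical contrast rather than boundary
partial-volume. Bias fields are random quadratic polynomials normalized
to a ±20%-bounded amplitude (default 10%); noise is additive Gaussian.
Functional maps are Gaussian-profile clusters (truth voxel set: noiseless
z > 2.3) on an N(0,1) background; retinotopy time courses are
`A cos(2π f t - φ)` with the true phase the polar angle around the cluster
centre (defaults: 256 frames, TR 2 s, 64 s period — 8 cycles, at which
run length the coherence-0.25 criterion excludes over 99% of pure-noise
voxels); histology sections are cut across the sheet with stain darkness
increasing in myelin.

What the phantom does **not** emulate: MR physics (no Bloch simulation,
k-space artifacts, distortion or motion), physiological noise,
multi-subject anatomical variability, true two-directional Gaussian
curvature, stain-batch variation, or registration error (all images are
rendered in one space, because registration is outside the package's
scope). A green phantom test therefore establishes the correctness of the
measurement and statistics chain given correctly registered inputs — not
robustness to acquisition artifacts.

Recovery benchmarks use the truth-occupancy threshold
`topFraction(patchArea / totalArea)`: it isolates the geometric estimator
chain from the threshold-selection question, which is assessed separately
(the sweep, the SEM rules, the shuffle nulls). Recovery phantoms are
tilted sheets rather than folded ones: under a constant tilt the pial and
midthickness arc lengths coincide, so the histology arm's pial-arc
measurements are commensurate with the midthickness-area truth; on a fold
the pial arc is systematically longer — a geometry fact, not an estimator
error — and the folded case is exercised by the structural-arm tests
instead.

# Numerical choices and degenerate inputs

- Quantile thresholds use R's default type-7 quantile; boundary ties are
  all included. SEM thresholds are strict inequalities.
- Depth-fraction ties break toward the smaller fraction; anchor ties in
  hMT+ selection keep the higher-peak cluster, with a message.
- Non-finite voxels/vertices are zeroed *and* flagged in validity masks at
  construction; they are excluded from every mean, SD, quantile and
  threshold, and they round-trip through NIfTI as NaN.
- Images on different grids are refused with a named error
  (`corticomap_grid_mismatch`); `resampleNearest` is the explicit opt-in.
- Off-bin retinotopy periods, empty ROIs, empty post-exclusion
  populations, out-of-range stain thresholds and sub-2-cycle runs each
  raise their own named condition class (`corticomap_*`), so callers can
  match failures precisely.
- Permutation p-values use the add-one convention; every stochastic
  operation takes an explicit seed and restores the caller's RNG state.

# Known limitations

- Geodesic patch membership uses shortest paths along mesh edges
  (Dijkstra), an upper bound on true geodesic distance; on the regular
  phantom meshes the error is negligible, on irregular meshes it biases
  patch definitions slightly small.
- The permutation extent calibration assumes exchangeable signs under the
  null (symmetric noise); heavy spatial autocorrelation in real z-maps
  makes the criterion conservative relative to field-theory thresholds.
- The intensity-shuffle null destroys spatial autocorrelation, so its
  chance levels are lower than those of spatially structured nulls
  (spin/variogram methods are out of scope); reported p-values against
  this null are anti-conservative for smooth maps and should be read as
  "better than value-randomization chance".
- Histology length measurement pairs pial and white traces by arc-length
  fraction, which assumes roughly commensurate trace lengths; strongly
  divergent traces would need explicit correspondence points.
- GIFTI support covers the geometry and per-vertex scalar arrays this
  package writes (ASCII and Base64/GZip encodings on read); it is not a
  general GIFTI implementation.
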