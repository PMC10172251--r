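---
title: "Quantifying planar polarity and beat frequency of multiciliated epithelia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planar polarity and beat frequency of multiciliated epithelia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliapol)
```

## The measurement problem

Multiciliated epithelial cells — the motivating system is the ependyma
lining the brain ventricles — show two layers of planar cell polarity
(PCP). *Translational* polarity: the patch of ciliary basal bodies sits
off-centre on the apical surface, displaced in a direction shared across
the tissue. *Rotational* polarity: each cilium's basal foot points in
its effective-stroke direction, and these beating directions align
within a cell and across cells. Both are read out from immunostained
whole mounts in which cell outlines, patch outlines and, per cilium, a
basal-body marker point and a basal-foot marker point have been traced.
`ciliapol` starts from those tracings (it performs no segmentation) and
produces per-cell metrics, field summaries and group-level inference,
plus a beat-frequency estimator for fluorescence time-lapse recordings.

## Coordinate conventions

All geometry runs in the image frame: origin top-left, x to the right, y
downward, pixel units. Angles are `atan2(dy, dx)` in degrees wrapped to
[−180, 180), with both boundaries mapping to −180. Because every
polarity statistic is a *relative* angle (cell versus field mean, or
displacement versus orientation within a cell), the choice of frame
cancels; only internal consistency matters, and one convention is used
everywhere. Physical units enter exactly once: areas and lengths are
converted to µm/µm² at reporting time via the field's pixel size
(default 0.09 µm — 90 nm pixels, a typical high-NA confocal sampling).

Contour centroids are the area-weighted (shoelace-moment) centroids, not
vertex averages; for unevenly spaced manual tracings the two can differ
by several pixels. This is a deliberate choice where tracing software
may be ambiguous, and it is the defensible one: the quantity of interest
is the geometric centre of the enclosed region.

## Per-cell metrics

For a cell with contour area $A$ (px²), contour centroid $c$, patch
centroid $p$, and usable cilium angles $\theta_1 \dots \theta_n$ (each
the direction of the basal-body→basal-foot vector):

* displacement vector $v = p - c$, with angle `disp_angle` and
  **strength** $= \lVert v \rVert / \sqrt{A/\pi}$. The denominator is
  the equivalent cell radius, so strength is dimensionless and
  comparable across cell sizes (0.3 ≈ patch centre displaced 30% of the
  way to the cell edge). The source tools leave this normalisation
  undefined; this package fixes it explicitly.
* circular mean direction $\bar\theta = \mathrm{atan2}(\sum_j \sin
  \theta_j, \sum_j \cos\theta_j)$, mean resultant length $R \in [0, 1]$
  and circular standard deviation
  $\mathrm{CSD} = (180/\pi)\sqrt{-2 \ln R}$ degrees.

Undefined values propagate as missing, never as zero:

* Fewer than `min_cilia` (default 3) usable cilia: CSD and mean
  orientation undefined. One or two angles always look coherent; their
  "CSD" would be noise masquerading as coordination.
* $R = 0$ (perfectly balanced angles): no mean direction exists; CSD is
  reported as `Inf`, a sentinel meaning "direction-free", which flows
  into the overflow bin of `csd_histogram()` and is excluded from
  linear CSD comparisons.
* CSD above `csd_threshold_deg` (default 45°, the conventional validity
  cut for this assay): the cell's beating orientation is considered
  undefined (`orient_valid = FALSE`).
* A cell with no patch contour and exactly one cilium runs in
  *primary-cilium mode* (immature cells): the single basal-body point
  stands in for the patch centre, and rotational metrics stay undefined.
* Coincident basal-body/basal-foot points give a zero-length vector with
  no angle; the cilium is skipped with a warning, not an error.

## Field-referenced angle families

Per field, the mean displacement direction and the mean orientation
direction are *unit-weighted* circular means over cells — each cell
contributes its direction only. Weighting by vector length would let
large or strongly displaced cells dominate what is a question about
directional coordination. Then, per cell:

* **vpatchD** = `disp_angle` − field mean displacement direction;
* **vpatchO** = mean cilium direction − field mean orientation
  direction, defined only for `orient_valid` cells (the field mean
  orientation is likewise taken over valid cells only);
* **vpatchDO** = `disp_angle` − mean cilium direction, within the cell.

vpatchDO is computed from the raw per-cell vectors rather than the
field-referenced ones. The two definitions differ by a constant rotation
(the difference of the two field means), and the downstream Watson U²
test is invariant under common rotations, so group inference is
identical either way; the per-cell vector difference is the more direct
reading of "angle between the two vectors". vpatchDO inherits the
orientation-validity gate: a cell with CSD > 45° has no defined mean
beating direction, so neither vpatchO nor vpatchDO exists for it. This
reproduces the characteristic pattern of real datasets where the
alignment metric has a smaller n than the displacement metric in
disorganised tissue.

By construction the circular mean of a field's vpatchD sample is 0
(the reference is that sample's own mean); its *dispersion* is the
information, summarised by the CSD of the vpatchD sample or by rose
plots (18 × 20° sectors, area-proportional, with a resultant-length
arrow).

## Group inference

Angular metrics are compared with Watson's two-sample U². With pooled
ECDFs $F_1, F_2$ evaluated at the $N = n_1 + n_2$ pooled observations,

$$U^2 = \frac{n_1 n_2}{N^2}\Big[\sum_k d_k^2 - \big(\sum_k d_k\big)^2/N\Big],
\qquad d_k = F_1(\theta_k) - F_2(\theta_k),$$

where each $d_k$ is evaluated *after consuming all observations tied at
that value*, and tied observations each contribute the shared $d_k$.
That tie rule is the only one under which two identical samples give
exactly $U^2 = 0$. The statistic is invariant under common rotation of
both samples, which is what licenses pooling field-referenced angles
across fields and groups.

p-values come from seeded random relabelling of the pooled angles into
groups of the original sizes, with the add-one estimator
$p = (1 + \#\{U^2_{perm} \ge U^2_{obs}\})/(1 + B)$ (default $B = 999$).
A permutation p-value is exact at any sample size and carries no
dependence on asymptotic tables; it will not numerically match
closed-form approximations printed by legacy circular-statistics
software, but it is calibrated — the test suite verifies a type-I error
within [0.03, 0.07] at $\alpha = 0.05$ over 1000 null pairs, and exact
agreement with a brute-force ECDF implementation on all small instances
including ties.

Linear metrics (CSD, strength, areas, cilia counts, beat frequencies)
use the classical pooled-variance two-tailed t test with $N - 2$
degrees of freedom. Cells lacking a metric are excluded from that metric
only, with per-metric n reported — no imputation anywhere.

## Beat-frequency estimation

The time-lapse model is 600 frames at 21 frames/s (both parameters of
the data, never hard-coded in the math). Preprocessing applies, in
order: per-pixel temporal-minimum background subtraction (a simple,
monotone stand-in for rolling-ball style routines; config-switchable),
division by a mono-exponential fit to the frame means renormalised to
the first frame (skipped with a warning when the means do not decay),
and 3×3 spatial mean smoothing. Kymograms are sampled by bilinear
interpolation at unit-spaced positions along a polyline; the trace is
the per-frame mean over those positions (a single-row option exists —
averaging along a short line crossing several cilia is more robust than
one row, at the price of cancelling anti-phase contributions).

The estimator mean-subtracts the trace and takes the raw FFT magnitude
spectrum with a rectangular window. At $T = 600$ the bin width is
$f_s/T = 0.035$ Hz and ependymal-range peaks are well separated, so
leakage control is not worth the resolution loss; a Hann option is
available. The search band is $(f_{min}, f_s/2]$ with
$f_{min} = 0.5$ Hz, excluding residual bleach/drift power near DC. The
in-band maximum is accepted only above median + $k$·MAD of the in-band
magnitudes ($k = 4$; MAD with the standard 1.4826 consistency constant —
the threshold is scale-free, so estimates are invariant to intensity
rescaling, which also makes the 16-bit TIFF round-trip harmless).
Frequencies above Nyquist alias to $f_s - f$: a 12 Hz beat sampled at
21 frames/s reports 9 Hz. This is a property of the acquisition, not the
estimator, and is documented by test.

## The generators: what they emulate, and what they do not

`generate_tissue()` builds an epithelium as a Voronoi tessellation of
Lloyd-relaxed random points in a square field (1024 px default, ~50
cells), constructed exactly by perpendicular-bisector half-plane
clipping against the nearest seeds. Two relaxation sweeps give realistic
convex-polygonal cells of fairly even size. Angular structure is
hierarchical, matching the biology's separation of translational and
rotational polarity: per-cell displacement direction ~ vonMises(µ,
κ_D); per-cell orientation ~ vonMises(µ, κ_O); per-cilium angle ~
vonMises(cell orientation, κ_cil). The von Mises family is the
maximum-entropy circular analogue of the Gaussian and admits a closed
form for the population CSD,
$(180/\pi)\sqrt{-2\ln(I_1(\kappa)/I_0(\kappa))}$, which the tests use
as an analytic oracle. The patch is a small circle (radius 0.35 of the
equivalent cell radius) displaced by a per-cell fraction drawn around
`disp_frac` (mean 0.3, SD a quarter of that, clamped to keep the patch
inside the cell), and each cilium is realised as a basal-body point in
the patch plus a basal-foot point 0.5 µm away along its angle — the
scale of a real basal-body/basal-foot pair. Presets: *control*
κ_D = κ_O = 6, κ_cil = 8 (a coordinated tissue whose vpatchD
distribution concentrates well within ±45°); *mutant* κ_D = κ_O = 1,
κ_cil = 2 (dispersed placement and beating, with a sizeable fraction of
cells failing the CSD ≤ 45° gate). Cilia counts are uniform on 15–40
per cell.

`generate_trace()` models a cilium's fluorescence as
$(b + A\sin(2\pi f t + \phi))e^{-t/\tau} + \varepsilon_t$; defaults
$b = 200$, $A = 100$, noise SD 20 (SNR 5), $\tau = 20$ s, with true
frequencies drawn from a normal population (mean 4.96 Hz, SD 0.4 Hz — a
typical control ependymal population). `generate_stack()` renders
Gaussian spots (σ = 1.3 px) oscillating along 2.5 px arcs and emits one
polyline per cilium along its arc, so the full
preprocess → kymogram → trace → FFT chain can be exercised.

What the generators deliberately do **not** model: point-spread-function
blur beyond the Gaussian spot, camera shot noise and gain, cell-shape
anisotropy, spatial correlation of polarity beyond the single tissue
direction, metachronal phase coupling between neighbouring cilia, and
frequency drift within a recording. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated statistical
model, not robustness to every instrumental artefact of real microscopy.

Everything is deterministic given the seed: generators draw from a
private RNG stream (the caller's `.Random.seed` is saved and restored),
per-field seeds are derived arithmetically from the study seed, and the
CLI's outputs are byte-identical across reruns with the same seed.

## Numerical choices and degenerate inputs

* Angle wrapping uses the half-open convention [−180, 180); +180 maps
  to −180 so every direction has one representation.
* $R$ within double rounding of 1 is clamped so identical-angle samples
  report CSD exactly 0; $R \le n\,\epsilon$ reports the `Inf` sentinel.
* Polygons with fewer than 3 distinct vertices or zero area raise
  invalid-geometry errors; a duplicated closing vertex is tolerated.
* The permutation comparison uses `>=` with a $10^{-12}$ guard so
  ties between permuted and observed statistics count conservatively
  (never anti-conservatively).
* The pooled t test refuses zero pooled variance unless both samples are
  the same constant (then t = 0, p = 1, the only consistent reading of
  "identical groups").
* Bilinear sampling rejects polylines leaving the image; positions on
  the far edge clamp to the last valid pixel pair.

## Problem sizes in the test suite

The suite validates the statistical claims at sizes chosen to keep a
full run within a few minutes on one core while leaving the checked
effects far from their decision boundaries: Watson calibration over
1000 null pairs (n = m = 50, 199 permutations); CSD oracle agreement at
n = 5000 for κ ∈ {0.5, 1, 2, 4}; the control-versus-mutant study
contrast at 5 fields × 50 cells per group, with 100 independent
control-versus-control replicates bounding the null rejection rate; and
frequency recovery on 100-trace batches and on rendered videos. Where an
invariant is stated at a larger scale, the test runs a scaled version of
the same property with correspondingly relaxed binomial bounds.

## Known limitations

* Watson U² p-values are permutation-based; published tables or
  software using the asymptotic series will print different (usually
  close) p-values for the same data.
* The CSD validity threshold treats each cell's CSD as the cell's
  dispersion summary; alternative per-patch maximum rules found in
  tracing software are not implemented.
* The trace reduction (mean along the line) can cancel anti-phase
  signal; use short lines or the single-row option for tightly packed
  cilia beating out of phase.
* Beat frequencies above $f_s/2$ (10.5 Hz at default acquisition) are
  reported at their alias; the estimator cannot detect folding from a
  single recording.
* The generators make convex cells; strongly concave real cell shapes
  (where the centroid can fall outside the cell) are handled by the
  geometry but not exercised by synthetic data.
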