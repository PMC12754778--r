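---
title: "Methods: hub and reporter quantification in hubtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hub and reporter quantification in hubtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hubtrack` quantifies three kinds of signal in multi-channel time-lapse
movies of syncytial fly embryos: the clustering of nuclear proteins
(Brd4 bookmarks, Cdc7 early-replicating hubs), the per-nucleus ON/OFF
kinetics of an MS2/MCP transcription reporter, and the 5′/3′ elongation
relationship of a dual MS2/PP7 reporter. This vignette records the
models behind each stage, the defaults and why they were chosen, the
numerical decisions, and what the synthetic-movie tests do and do not
establish about real data.

## Image preparation

Raw data are 5-D stacks `(T, Z, C, Y, X)`. Analysis operates on
maximum-intensity projections; quantified intensities are therefore
projected a.u., never volumetric sums. Background is removed per frame
and channel with a rolling-ball estimate: a grayscale morphological
opening with a hemispherical (ball) structuring element of radius 50 px
by default, the surface swept by a ball rolling under the intensity
landscape. Negative residuals are clamped to zero, so all downstream
intensities are non-negative and cumulative sums are monotone.

Numerics: the opening is computed exactly in compiled code for radii up
to 16 px. For larger radii the image is min-pooled by a shrink factor
(4 up to radius 64, 8 beyond), the ball is rolled at the reduced scale
and the background is bilinearly enlarged — the classical speed
strategy for large-radius rolling balls. On piecewise-smooth synthetic
backgrounds the approximation error is well below the 1–5% envelopes the
test-suite oracles enforce. Out-of-bounds structuring-element positions
are ignored rather than padded, so a constant image opens to itself
everywhere, including corners.

The processing order is projection → background subtraction → optional
interior crop. The order of the last two steps is not externally
constrained; subtracting before cropping keeps the background estimate
supported on the full field, and the chosen order is recorded in each
movie's provenance along with crop offsets, so spot coordinates can
always be mapped back to raw-frame coordinates.

Intensity conventions: all values are arbitrary units, compared only
within a channel. Integer TIFFs (8/16-bit) round-trip exactly; float
TIFFs are stored normalised by an explicit `intensity_scale` because
TIFF float storage is only defined on [0, 1].

## Segmentation

Both segmentation paths are built on the same two primitives.

**Bright-focus suppression.** A few sub-nuclear foci (histone-locus
bodies, hubs) can be 50× brighter than the nucleoplasm; a histogram
threshold computed on the raw frame then separates foci from everything
else instead of nuclei from background. Pixels above a cap are therefore
replaced by a sub-cap constant *before* blurring and thresholding. The
cap in the original workflow is a manual choice; for unattended runs
the default cap is the 99.5th intensity percentile of the frame, and the
replacement value is the median of sub-cap pixels inside a provisional
Otsu foreground — which keeps the replaced pixels in the foreground
class. Both are configurable (`cap_percentile`, or a fully manual
`suppression_params()`).

**Otsu threshold.** The threshold maximises the between-class variance
over the 255 cuts of a 256-bin histogram spanning the frame's range.
Per-bin *sums of actual pixel values* are accumulated (not bin centres),
so the selected partition is exactly the maximiser among bin-boundary
partitions, and the returned threshold is the largest pixel value of the
lower class — `img > thr` reproduces the partition with no edge-case
ambiguity. Ties break toward the lowest qualifying threshold. For 8-bit
data the 256 bins are injective over the integer values, which is why
the implementation agrees exactly with an exhaustive unique-value
search in the acceptance tests.

*Territory masks* (hub dynamics): the two channels are summed,
suppressed, Gaussian-blurred (σ = 2 px) and thresholded; connected
components become the combined chromosome/nucleus territory. *Nucleus
masks* (reporter workflows): the nuclear channel is suppressed, blurred
and thresholded, the mask is dilated by 3 px so peripheral reporter foci
fall inside their nucleus, touching nuclei are split by a watershed on
the distance transform, and objects smaller than 50 px² or touching the
X–Y border are removed. Blur sigma, dilation radius and minimum area are
package choices (the procedure they implement names none), all exposed
in configuration.

Watershed seeding is the one genuinely open design point: the transform
is standard, the seeding is not specified anywhere. The default
tolerance — the minimum distance-map depth separating two catchment
basins — is a quarter of the distance-map maximum. The maximum of the
distance transform estimates the (dilated) nucleus radius even when
several nuclei merge into one component, unlike area-based estimates
which inflate under merging; a quarter of a radius still splits pairs
overlapping by ~20% of a radius while ignoring 1–2 px roughness bumps
on mask boundaries.

Z-truncated nuclei ("touching the top or bottom of the stack") cannot
be recognised from a projection; the minimum-area filter acts as the
proxy, and this substitution is deliberate and visible in the mask
parameters.

Coordinates are 1-based `(row = y, col = x)` throughout, matching R
indexing; "touches the border" means any pixel in the first or last row
or column.

## Hub dynamics

Within-mask statistics per frame are the arithmetic mean, the
*population* variance (divide by N — the estimator choice is recorded in
the series metadata) and the maximum. Mean tracks nuclear abundance;
variance tracks clustering: a focus concentrates intensity without
changing the mask mean much, so the variance is the clustering proxy.
Frames whose mask is empty are recorded as missing, never zero, so a
segmentation dropout cannot fake a minimum or win a peak.

Temporal peaks are the maxima of mean and variance restricted to a
declared window — typically the ~2-minute interval following kinase
recruitment at S-phase entry — with ties broken toward the earliest
frame. Cycle windows are user-declared frame intervals; automatic
mitosis detection is out of scope. Peaks are extracted per movie
(per embryo); pooling across embryos and averaging is left to the
caller, and per-embryo values are what the workflow CSVs contain.

Treatment comparisons use per-nucleus mean or maximum intensities,
pooled across embryos, under a two-sided Mann–Whitney U test. The exact
null distribution is used when `n1 + n2 ≤ 20` with no ties, otherwise
the normal approximation with tie and continuity corrections; the method
used is recorded. Bonferroni correction multiplies by the declared
number of comparisons `m` and caps at 1 — `m` comes from the analysis
configuration, since the family of comparisons is an analysis choice,
not a property of any single test. Box summaries use type-7
(linear-interpolation) quartiles and whiskers at the most extreme points
within 1.5 IQR, the estimator recorded in the output.

## ON/OFF state kinetics

Nuclei are tracked by greedy nearest-neighbour linking of mask
centroids, gated at half the median equivalent nucleus diameter per
frame by default. Only nuclei present in every frame are retained —
state counting needs a complete denominator — and the number of
discarded fragments is reported. Tracking uses the (dilated) mask
centroids the states are assigned on; an undilated-centroid variant
would differ by a sub-pixel offset and was not pursued.

Foci are detected as local maxima of the scale-normalised
Laplacian-of-Gaussian response, `σ² · (−Δ)(G_σ ∗ I)`, over a geometric
ladder of four scales between σ = 1.5 and 4 px. Two numerical choices
matter:

- each scale's response is divided by its own robust noise SD
  (1.4826 · MAD), estimated *inside the nucleus masks*, because photon
  noise is higher inside nuclei than in the dark background and a
  frame-wide estimate systematically under-scales the threshold there;
- the outermost 2-pixel ring is excluded from both the noise estimate
  and the maxima search: the replicate-boundary Laplacian inflates the
  response on the first ring by several-fold, which otherwise produces
  border artifacts.

The detection threshold is then `k = 5` noise SDs — the presence
criterion in the source workflow is never quantified, so this rule is a
package stand-in, flagged in the detection attributes and configurable.
A nucleus is ON in a frame iff at least one focus lies in its mask; no
intensity persistence is required (an optional minimum-run smoothing
parameter exists and defaults to off). Transitions are recorded at the
first frame of the new state. Cumulative curves report, per frame since
S-phase entry, the percentage of retained nuclei whose first OFF→ON has
occurred, and the percentage that after first turning ON have had an
ON→OFF; both are non-decreasing, bounded by 100, and disappearance
never exceeds appearance by construction. "Subsequently lost" counts
only nuclei that were ever ON.

## Dual-reporter elongation

Spots are detected in the MCP channel by difference of Gaussians
(σ = 1.6/2.6 px by default), thresholded at `k = 5` robust SDs of the
response, with sub-pixel refinement by the positive-response centroid in
a 3×3 neighbourhood. Linking is greedy nearest neighbour with memory: a
track may be resumed after up to 5 consecutive missing frames (the
boundary is exact — absent 5 resumes, absent 6 splits) within a spatial
gate of 5 px; the spatial gate is a package choice, as only the temporal
gap is externally specified. Single-frame tracks and tracks approaching
the border are discarded; the border margin equals the quantification
half-width (8 px), which guarantees every quantification window fits.

Both channels are quantified as the mean over a 17×17-px square centred
on the *MCP* position — the large window absorbs the small chromatic/
genomic displacement of the 3′ focus (a 3-px displacement keeps >90% of
a σ = 2 px spot's windowed signal; the acceptance test checks this
against the analytic Gaussian integral). Gap frames are not
interpolated: cumulative sums skip them, so no signal is invented.
Spot-local background (annulus) correction is not applied; the global
rolling-ball subtraction is the only background model, a deliberate
difference recorded here. Tracks sort by ascending first appearance,
then descending total PCP; montages crop the same 17×17 window per
frame with blank tiles at gaps and shared per-channel display scaling
(recorded in the montage object). The cumulative MCP-vs-PCP table
reports the Spearman rank correlation of per-track totals.

The elongation-defect classifier (`classify_elongation_defects()`)
automates what is otherwise read off montages by eye: PCP counts as
acquired after ≥ 2 consecutive frames above `k` noise SDs; unacquired
tracks split into transient (span < 10 frames), unstable (MCP
coefficient of variation > 0.5) and stable classes; acquired tracks are
delayed if onset trails first appearance by more than 15 frames (~5 min
at 20 s/frame). All thresholds are arguments, and the classification is
a package addition, not a reimplementation of a published rule.

## The synthetic-movie generator

The generator is the package's substitute for raw movies: it renders
what the analysis assumes and reports the exact truth needed to score
recovery. A scene comprises:

- nuclei as linear-edge disks (radius 11 ± 1 px ≈ 2.4 µm at 0.22 µm/px)
  placed by rejection sampling at blastoderm-like spacing (≥ 2.4 radii
  apart, a margin from the border) and drifting as a reflected random
  walk (0.3 px/frame SD);
- hub foci and reporter spots as 2-D Gaussians of PSF σ = 1.5 px at
  scheduled times, with amplitudes expressed in units of the local
  per-pixel noise SD (`spot_snr`, default 10; floored at 1 a.u. so
  noise-free renders still carry signal);
- reporter-channel nucleoplasm rendered faint and heavily smoothed
  (σ = 3 px), reflecting diffuse unbound coat protein;
- Poisson photon noise followed by Gaussian read noise (SD 2 a.u.);
  setting `photon_scale = Inf` and zero read noise gives the noise-free
  limit;
- optional mitotic frames in which nuclei shrink to 60% radius, a crude
  stand-in for chromosome condensation;
- 20 s frame interval, 0.5 µm z-step, and (by default) 3 z-slices with
  a Gaussian axial attenuation profile.

All draws come from one seeded stream in a fixed order (placement,
radii, drift, hub offsets, spot offsets, dropout, pixel noise), so a
seed fully determines the movie, and schedules are drawn from a
separate derived stream so the same regime can be rendered under
different noise realisations.

Regimes encode the perturbation contrasts in *direction and order of
magnitude only* — the quantitative distributions are not published, so
the magnitudes are synthetic calibrations chosen once: control spots
switch on uniformly within frames 3–12 (≈ 1–4 min, matching synchronous
activation within ~5 minutes), 10% are lost, all acquire PCP after a
10-frame (~3.3 min) delay; the kinase-inhibited regime delays onset to
frames 8–28, raises the loss fraction to 45%, makes 40% of loci never
acquire PCP and attenuates the rest to 30% with a 15-frame delay;
the acetyltransferase-knockdown regime zeroes hub amplitudes; the
bromodomain-inhibitor regime attenuates the bookmark channel and delays
the kinase channel.

What the generator does **not** emulate — and what passing tests
therefore cannot certify on real data: realistic chromatin texture and
nuclear shape, 3-D point-spread functions and optical aberrations,
photobleaching, stage drift and registration error, nuclear divisions
within a movie (tracking across mitosis), intensity variation between
spots of the same state, and partial-Z truncation of nuclei. Results on
real movies depend on segmentation and threshold parameters in ways the
clean synthetic geometry does not probe.

## Test and verification sizes

The test-suite movies use 160×160 px frames with 10 nuclei (the default
density), 20–40 frames, one z-slice, and reporter SNR 8–10; state
recovery and regime separation are checked across 5 seeds each; the
rank-test null calibration uses 2000 replicates at n = 20 per group.
These sizes were chosen as the smallest scenes that still exercise every
stage at the study's conditions.

## Known limitations

- The combined-territory path labels connected components; nuclei whose
  territories touch merge into one object there (the watershed path is
  the one that separates neighbours).
- Greedy nearest-neighbour linking is not globally optimal; at high
  density or large drift an assignment-problem linker would be more
  robust.
- The ON/OFF criterion is presence-based; burst-kinetics inference
  (two-state promoter models) is explicitly out of scope.
- Bonferroni `m` must be declared by the analyst; the package cannot
  know the intended family of comparisons.
- Cycle windows (per-nuclear-cycle peak extraction) are user-declared
  frame intervals, not auto-detected.
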