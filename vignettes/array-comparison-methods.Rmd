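---
title: "Methods: simulating and comparing sparse and high-density fNIRS arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and comparing sparse and high-density fNIRS arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsarray)
```

# The question the package addresses

Traditional fNIRS arrays place sources and detectors on a 30 mm grid: every
channel has the same depth sensitivity, channels do not overlap, and image
reconstruction from such data is poorly conditioned. High-density (HD)
arrays use a hexagonal pattern with overlapping channels at several
separations (8, 19 and 33 mm here), which buys depth discrimination at the
price of hardware and setup cost. `nirsarray` provides a complete synthetic
test bed for quantifying what the HD geometry buys: it simulates the same
cortical ground truth seen by both arrays, runs both recordings through an
identical processing chain, and compares the arrays in channel space and in
reconstructed image space with paired statistics.

Everything is planar and synthetic by design: the package's claims are
about the *relative* behavior of the two geometries under a controlled
generative model, not about any individual's anatomy.

# Probe geometry

`build_sparse_layout()` constructs a 3 x 11 alternating source/detector
grid at 30 mm pitch (17 sources, 16 detectors, 52 channels of exactly
30 mm) plus eight short-separation (SS) detectors 8 mm from the eight
sources nearest the midline in the top and bottom rows, for 60 channels.

`build_hd_layout()` places all 83 optodes on a five-row triangular lattice
with 19 mm pitch. On such a lattice the first neighbor distance is 19 mm
and the second is 19·sqrt(3) = 32.9 mm, so a single role assignment yields
both channel classes: sources occupy the even columns of the outer rows
(except the center column) and the odd columns plus center of the middle
row. This gives exactly 25 sources, 58 detectors, 106 channels at 19 mm and
94 at 33 mm, with a field of view matching the sparse grid within 10%.
Eight SS detectors attach to the eight sources nearest the midline in the
outer rows, offset outward perpendicular to the rows: at that position no
foreign source falls within any distance bin, so the SS detectors add
exactly eight 8 mm channels. Channel enumeration (`enumerate_channels`) is
a distance-bin filter over all source-detector pairs with a +-2 mm
tolerance and deterministic ordering.

# Forward model

The head is a homogeneous semi-infinite medium below the optode plane,
sampled on two congruent 5 mm lateral grids: a scalp surface at 3 mm depth
and a cortical surface at 15 mm. Optical properties default to typical
adult-head effective values (mu_a = 0.018/mm, mu_s' = 1.1/mm at 760 nm;
0.019 and 1.0 at 850 nm). Channel sensitivity uses the Rytov adjoint form

S(ch, v) = G(r_s, r_v) G(r_v, r_d) / G(r_s, r_d) × V_voxel,

with `G` the semi-infinite diffusion Green's function with an
extrapolated-boundary image source (effective reflection 0.493, i.e.
tissue index ~1.4) and surface optodes represented by an isotropic source
at depth 1/mu_s'. Entries carry pathlength units (mm) so that optical
density is extinction × sensitivity × concentration. The two-surface
planar model preserves the property the reconstruction depends on —
short channels see almost only scalp, long channels see progressively more
brain — while remaining deterministic and fast. It deliberately omits
CSF, skull, curvature and subject anatomy; consequences are discussed
under *Limitations*.

Total-sensitivity maps are normalized to a maximum of 1 and displayed or
masked at a threshold of 0.01, applied to the linear normalized value; the
mask defines the array's usable field of view and all image-space peak
searches are restricted to it.

# Synthetic recordings

`generate_schedule()` produces the block design: 20 s initial rest, then
18 blocks of 18 s (9 congruent, 9 incongruent, order permuted) with rest
jittered uniformly in [10, 15] s. `simulate_recording()` assembles, in
optical-density space,

* cortical activation: a 10 mm-radius Gaussian-edged disc per hemisphere
  whose vertices follow the canonical double-gamma HRF (peak ~6 s,
  undershoot ~16 s) convolved with the 18 s block boxcar, with HbO
  amplitudes of 5 µM (congruent) and 10 µM (incongruent) and HbR at
  -0.3×. These local tissue amplitudes were set so that after the model's
  ~5-8% partial-volume factor the *channel-level* deltas land at a few
  tenths of a µM, the scale a selected channel shows in practice;
* a superficial signal: one shared band-limited time course (0.04-0.12 Hz
  sinusoids plus smoothed noise) carried by every scalp vertex, scaled by a
  smooth spatial gain field (20 mm correlation length, SD 0.5) and a global
  amplitude of 0.4 µM. The shared time course is what short-separation
  regression exploits; the spatially varying gain reflects scalp
  vasculature and is what makes brain/scalp separation genuinely
  ill-posed for a non-overlapping array;
* nuisance terms per channel: a cardiac sinusoid at 1.1 Hz (0.02 OD,
  above the 0.5 Hz low-pass so the filter is exercised), a smooth random
  cubic instrument-drift trend (0.005 OD SD) plus a linear term
  (0.005 OD) — the aperiodic drift that polynomial GLM regressors are
  designed for, with periodic low-frequency physiology belonging to the
  superficial signal;
* motion artifacts: four exponential spikes (~0.3 OD) and two baseline
  steps (~0.1 OD) at seeded random channels and times;
* white noise added on detected intensity (0.5% of the 30 mm baseline
  level). Baseline intensity falls off with source-detector separation
  (effective attenuation 0.14/mm plus inverse-square, normalized at
  30 mm), so short channels are bright and clean while 33 mm channels are
  the noisiest — this reproduces the raw SNR ordering seen in practice
  (19 mm ≈ 58 > 33 mm ≈ 48, with the bulk of channels in the 40-60
  range).

Every stochastic element is reproducible from a single integer seed.
Sampling rates default to 24.4 Hz (sparse) and 17.5 Hz (HD).

# Processing chain

`preprocess_recording()` applies, in order: channel pruning (mean
intensity < 0.001 or mean/SD < 5 at either wavelength, strict
inequalities; zero-variance channels count as infinite SNR and are kept);
optical density OD = -ln(I/mean I); spline + Savitzky-Golay motion
correction; a zero-phase 3rd-order Butterworth low-pass at 0.5 Hz (meaning
>20 dB attenuation at 1.1 Hz after the forward-backward pass); and the
modified Beer-Lambert law with Gratzer/Prahl extinction coefficients
(base-e, 1/(mm·µM)), channel separation as pathlength and a partial
pathlength factor of 1.

Motion handling deserves detail because the correction must pass clean
data untouched. Contaminated samples are flagged where the
sample-to-sample difference exceeds 6 robust SDs (`mad` of the first
difference): smooth oscillations of any amplitude pass, while spikes and
steps are caught. A windowed-excursion detector referenced to the channel
SD was rejected during design: referenced to the derivative scale it
false-alarms on any smooth signal, and referenced to the signal SD it
misses 10-SD baseline steps because the artifact inflates its own
reference. Flagged segments (padded by 0.5 s) have a close-fitting
smoothing-spline trend removed and are re-anchored to the preceding
median level; the following samples are re-leveled by the median step
across the segment, which removes baseline shifts. Remaining flagged
samples are replaced by their Savitzky-Golay smoothed value (order 3,
10 s frame). Unflagged samples are never modified, so a clean channel
passes through bit-identical.

An automated amplitude-threshold block/subject rejection helper
(`reject_blocks_and_subjects`) drops blocks whose concentration range
exceeds a configurable threshold and excludes subjects left with four or
fewer blocks in either condition.

# GLM

One ordinary-least-squares GLM per channel and chromophore: per condition,
26 Gaussian basis functions (SD 1 s) centered at integer offsets -2..23 s
around onset (both endpoints included), summed over that condition's
blocks; global polynomial drift of order 0-3; and one short-separation
regressor — the concentration trace of the unpruned 8 mm channel most
correlated with the long channel (ties to the lowest index). The fit uses
a shared Gram matrix with the SS column as a rank-one border, so a
220-channel recording fits in under a second; an SS trace that is flat or
(numerically) inside the design span is dropped for that channel rather
than poisoning the solve. The estimated HRF is the basis expansion on the
-2..23 s grid. Residual variance never increases when the SS regressor is
added (an OLS projection fact, verified in tests); with the shared
superficial signal present it typically drops by >90%.

Drift polynomials are per run; the -2..23 s window truncates a response
that genuinely outlasts it, so estimates of a fully convolved block
response carry an irreducible window-truncation bias — recovery
invariants are therefore stated for basis-expressible responses.

# Image reconstruction

The multispectral operator stacks the per-wavelength sensitivities with
extinction coefficients so the unknowns are (HbO, HbR) per vertex
directly. With `A` that operator, the inversion is

L_vv = sqrt((AᵀA)_vv + α_spatial · max diag(AᵀA)),  Â = A L⁻¹,
x = L⁻¹ Âᵀ (Â Âᵀ + α_meas · max diag(Â Âᵀ) · I)⁻¹ y,

with α_spatial = α_meas = 0.001. The vertex-wise rescaling keeps the
inversion from dumping everything onto the high-sensitivity scalp
vertices; α_meas smooths. The channel-space system is solved by Cholesky
factorization, never an explicit inverse. A `brain_only` mode restricts
the operator to brain columns and skips the rescaling. `image_timecourse`
converts estimated HRF concentrations back to optical density through the
forward Beer-Lambert relation and reconstructs one image per second.

A note on the rescaling: the dimensionally consistent form requires a
vertex-wise diagonal built from AᵀA with a square root, which is what the
spatially-variant-regularization literature uses and what is implemented
here.

# Statistics

The unit of analysis is the block delta: mean concentration over
[onset+7, onset+18) minus mean over [onset-2, onset) (start-inclusive
windows). Per-channel and per-vertex t statistics across blocks use the
n-1 sample SD; zero-variance inputs are flagged degenerate. ROI channels
are those whose midpoint lies within 30 mm of the nominal activation
center; ROI vertices come from the HD sensitivity in two stages (summed
ROI-channel sensitivity above 0.01 of maximum, then strictly above the
stage-1 mean) and are shared by both arrays. Per subject and side the
channel (or the mean of the 25 vertices) with maximum HbO t (minimum for
HbR) is selected, and arrays are compared with two-tailed paired Student
t tests. The group map threshold at n = 17 and alpha = 0.05 is t = 2.12.

The channel-space family-wise test is a cluster-based sign-flip
permutation test: channels with |t| above the two-tailed critical value
join clusters by center distance <= 33 mm, cluster mass is the sum of |t|,
and the null of the maximum mass is built from 5000 random whole-subject
sign flips; cluster p = (1 + #null >= observed)/(1 + n_perm). Singleton
clusters are allowed and tested like any other. The literature leaves the
cluster statistic and null unspecified in many reports; sum-of-|t| mass
with subject sign flips is the standard neuroimaging construction and all
choices are configurable. Monte-Carlo calibration on null data (20
channels, 15 subjects, 200 permutations, 500 replicates) gives a
family-wise rejection rate of ~0.05, inside [0.02, 0.09].

# The experiment driver

`run_experiment()` simulates `n_subjects` synthetic subjects. Each subject
has their own ground truth: the activation centers are jittered uniformly
within 10 mm of the nominal (±70, 0) mm centers — inter-subject anatomical
variability is the reason per-subject ROI selection exists at all — and
the superficial gain field is redrawn per subject. Both arrays record the
same truth (with independent noise), are processed identically, and
contribute per-subject channel and image ROI deltas, t values, an
optional GLM HRF summary, and a peak-localization error: the distance
from the subject's true center to the peak of the across-block t image,
searched over brain vertices inside the array's sensitivity mask on the
correct hemisphere. The t image rather than the mean image is used
because that is the display/selection statistic of the analysis, and
because it suppresses vertices whose across-block variance is inflated by
drift. Group outputs are paired t tests per space/side/condition with the
fraction of subjects where HD > sparse, and mean localization errors.

Typical behavior at the default conditions: HD image-space ROI deltas
exceed the sparse ones in >=80% of subjects, and HD mean localization
error is well below the sparse error — sparse reconstructions fail
catastrophically for occasional subjects whose superficial gain field
places a scalp blob near the ROI, which is precisely the ill-posedness
that overlapping multidistance channels resolve. Channel-space
differences are much weaker, mirroring the motivating observation that
a sparse array can detect strong activation in channel space while its
images are unreliable.

# Problem sizes and determinism

The default head model has 1170 vertices per surface (5 mm sampling over
the union field of view); sensitivity matrices build in under a second
per array. A full 20-subject, two-array experiment with GLM runs in a few
minutes on one core. The test suite uses 8 mm sampling and single-array
heads for unit fixtures, 20 subjects for the array-comparison property,
and the full 500-replicate permutation calibration. All randomness flows
from explicit integer seeds; identical configuration and seeds reproduce
byte-identical result tables.

# Serialization

Probe layouts serialize to JSON (optodes, channels, bins); recordings,
schedules and images serialize to JSON/TSV text with full double
precision (round-trip accurate to better than 1e-9, verified). The
experiment driver writes tidy TSV tables plus a configuration JSON
carrying an MD5 content hash. The exported functions are the package's
interface; the driver covers the simulate → preprocess → GLM →
reconstruct → compare pipeline end to end.

# Limitations

* The homogeneous planar two-surface head abstracts away skull, CSF,
  curvature and anatomical variability. At a single effective cortical
  depth of 15 mm, 30 mm sparse channels localize a smooth isolated blob
  nearly as well as HD channels when the superficial signal is spatially
  uniform; the HD localization advantage in this model emerges from
  brain/scalp separation under spatially structured scalp physiology,
  not from depth resolution per se. Passing tests therefore demonstrate
  the geometry-driven separability mechanism, not performance on real
  anatomy.
* The superficial signal is a single shared time course with a spatial
  gain; real scalp physiology mixes several time courses (cardiac, Mayer
  waves, respiration) with partial spatial coherence.
* Motion artifacts are idealized spikes and steps; slow, shape-changing
  artifacts that defeat automated correction in practice (and motivate
  manual block rejection) are not modeled.
* The GLM is plain OLS; serially correlated noise makes its standard
  errors optimistic, which is why inference here rests on block deltas
  and permutation tests rather than GLM coefficient statistics.
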