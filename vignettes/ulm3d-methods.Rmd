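---
title: "Volumetric ultrasound localization microscopy with ulm3d: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric ultrasound localization microscopy with ulm3d: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ulm3d)
```

## The method in one paragraph

Ultrasound localization microscopy (ULM) breaks the diffraction limit of
B-mode imaging by exploiting temporal sparsity: intravascular microbubbles
are point scatterers, so although each one is imaged as a point-spread
function (PSF) hundreds of micrometres wide, its *center* can be estimated
with micrometre-scale precision, and accumulating millions of such centers
over tens of seconds of ultrafast acquisition paints the vascular tree at a
resolution set by localization precision rather than by the wavelength.
`ulm3d` implements the volumetric (3-D + time) version of this chain for a
1024-element matrix array driven at 7.81 MHz and 500 volumes/s:
plane-wave delay-and-sum beamforming with coherent 5-angle compounding on a
λ/2 (98.6 µm) isotropic grid, block-wise SVD clutter filtering,
dual-threshold sub-voxel localization by PSF-matched filtering and weighted
centroids, Hungarian frame-to-frame tracking with Savitzky–Golay smoothing,
accumulation of the tracks onto a λ/20 (9.86 µm) grid for structural and
axial-velocity maps, and single-volume Fourier shell correlation (FSC) with
the 1/2-bit threshold for resolution estimation. A ground-truthed synthetic
scene generator exercises every stage without access to a scanner.

## Conventions

All physical lengths are millimetres internally; user-facing resolution
figures are micrometres. The axis order is (axial z, lateral x, elevation
y) throughout, and `VolumeSequence` data are stored as (z, x, y, t) arrays.
Voxel indices are 1-based with a voxel-center convention — voxel (1,1,1)
sits exactly at the grid origin — which is R's native indexing; mappings
between index and physical space (`voxelToPhys`, `physToVoxel`) are exact
bijections on the lattice. The sound speed defaults to 1540 m/s, the
standard soft-tissue value and the one that reproduces the 98.6 µm
half-wavelength at 7.81 MHz.

## Acquisition arithmetic

`acquisitionPlan()`/`planAcquisition()` model the streaming acquisition's
timing and storage with exact rational arithmetic: a 100-volume block at
500 volumes/s lasts 0.2 s; 100,000 volumes last 200 s; four systems at a
measured 245 MB per block store 980 MB per block and 980 GB for the full
acquisition. The per-system block size normally derives from
samples × transmits × volumes × channels × bytes (2 bytes per sample,
the 16-bit convention of research scanners), but a measured value can be
supplied — hardware framing overheads mean the measured figure is an
input, not a derived quantity.

## Beamforming

Transmit delays use the plane-wave law with direction cosines
`(sqrt(1 − sin²a_lat − sin²a_elev), sin a_lat, sin a_elev)`, which reduces
to `(z cos a + x sin a)/c` for a single tilt and handles the dual-tilt
members of the 5-angle set {(0,0), (±3°,0), (0,±3°)} without ambiguity.
Receive delays are exact element-to-voxel path lengths. Channel traces are
Hilbert-transformed before summation by default, so the beamformed voxels
are complex analytic samples and the envelope is their modulus; this avoids
the carrier aliasing that envelope detection *after* summation suffers on a
λ/2 grid, where the round-trip RF oscillation period equals one voxel.
Inter-sample interpolation is linear and out-of-range samples contribute
zero. Compounding is the coherent (pre-envelope) mean across angles,
and envelope detection follows filtering, matching the processing order of
the acquisition chain the package models. Receive apodization is off by
default with an optional F-number mask.

## SVD clutter filtering

Tissue and skull echoes are orders of magnitude brighter than bubbles but
temporally coherent, so in the Casorati (space × time) matrix of a block
they concentrate in the largest singular values. `svdClutterFilter()`
zeroes the `K = ceiling(removedFraction × n_t)` largest components of each
non-overlapping block (defaults: 200-frame blocks, 15% → exactly 30
components) and reconstructs. The reconstruction is computed as the
projection `X − X V_K V_K*` with `V_K` the top-K eigenvectors of the
temporal Gram matrix `X*X` — algebraically identical to truncating the SVD
(the unit tests verify this against a direct `svd()` truncation oracle)
but much cheaper for thin Casorati matrices, and valid for complex
pre-envelope data. `K` is counted against the temporal dimension; ceiling
rounding makes "15% of 200" remove exactly 30. A trailing block shorter
than two frames is merged into its predecessor.

## Localization

Each envelope frame is normalized to maximum 1 and values below
`noiseThresholdFrac` (default 0.03, typical range 0.01–0.07) are zeroed.
The frame is then convolved with a unit-sum anisotropic Gaussian matched to
the PSF (`σ = FWHM/2.355` per axis, kernel half-width 3σ, reflective
boundaries), thresholded at `mean + k·sd` of the convolved frame
(statistics over the whole frame), labeled into connected components
(26-connectivity default; components smaller than 2 voxels dropped), and
each blob is reduced to its intensity-weighted centroid in physical
coordinates, with weights taken from the convolved volume (the volume the
segmentation operates on; raw-envelope weights are available via
`weightsFrom = "raw"`).

The pass is run twice — `k = 1.5` ("low") and `k = 3.5` ("high") by
default, mid-range choices within the typical 1–4 range — because a single
global threshold cannot serve both dim bubbles and dense clusters of
bright ones: the low threshold keeps dim bubbles but lets the
supra-threshold supports of nearby bright bubbles merge into one blob with
a useless centroid, while the high threshold separates them but discards
the dim population. Note the corollary, which the tests exercise
explicitly: raising the threshold is *not* monotone in blob count in
general, because splitting a merged blob increases the count — that
splitting is precisely what the high pass is for. Monotonicity holds only
for isolated unimodal spots.

## Tracking

Localizations in consecutive frames are paired by a minimum-total-distance
one-to-one assignment (an O(n³) potentials/augmenting-path Hungarian
solver, written in-package since no assignment solver is available among
the package's dependencies, and verified against permutation enumeration),
with a gate `maxLinkDistance` that both forbids implausible pairings and
sets the maximum detectable speed (`gate × frame rate`; the default gate
is `vMax/frameRate` with `vMax` = 100 mm/s). There is no gap closing: a
missed detection terminates the track, matching the basic Hungarian mode
of common particle trackers. Tracks shorter than 10 positions are
discarded (a 10-position track is kept — "below ten" is strict). Each
coordinate is smoothed with a Savitzky–Golay filter (window 5, order 2;
the filter is standard but its parameters are a package choice), and
per-segment speeds and signed axial velocities are computed from the
smoothed positions as displacement × frame rate. Track-angle or
acceleration pruning is deliberately not applied by default: such filters
can destroy genuinely tortuous vessels, the very feature many studies
target.

## Rendering

Every track segment is rasterized as the 3-D digital line of λ/20 voxels
between consecutive smoothed positions (supersampled at a quarter voxel
and uniqued — "all pixels in the track", not just its endpoints); each
visited voxel increments the intensity and density maps and accumulates
the segment's signed axial velocity. The mean-velocity map is the
accumulated velocity divided by density, median-filtered (3×3×3 default)
to remove residual noisy tracks; the median is only evaluated where the
neighborhood contains signal, since elsewhere it is identically zero. The
two localization passes are fused voxelwise — mean where both are
non-zero, the value itself where only one is — so twice-detected vessels
do not render twice as bright. A final isotropic Gaussian of σ = 0.8
rendering voxels slightly improves visual appearance. Directional maps
split by the sign of the axial velocity, with the color-map saturation set
at the 99.9th percentile of the non-zero velocity magnitudes (computed as
an exact order statistic). Vessel widths are measured as the full width at
half maximum of spline-interpolated (10× upsampled) cross-sections, and
bifurcation separability as the valley intensity — the minimum threshold
above which the two peaks form disjoint supra-threshold components — with
a 25%-of-maximum peak-significance floor to ignore spline ringing.

## Fourier shell correlation

Resolution is estimated from a single rendering by checkerboard
decimation: the volume is split 2×2 along the lateral and elevation axes
into four sub-volumes ("four sub-images", so only two axes are decimated;
the axial axis is untouched), the FSC
`Re[Σ F₁F₂*] / sqrt(Σ|F₁|² Σ|F₂|²)` is computed over spherical shells one
frequency bin wide for the two complementary pairs (even/even with
odd/odd, even/odd with odd/even), and the two curves — whose shells are
identical by construction — are averaged. Frequencies are expressed
against the decimated (doubled) voxel spacing so the reported resolution
is a physical length. The resolution is the inverse of the first frequency
at which the averaged curve falls below the 1/2-bit information threshold
`T(n) = (0.2071 + 1.9102/√n)/(1.2071 + 0.9102/√n)` after having been above
it; single-shell dips followed by recovery are tolerated as spikes
(configurable). If the curve never crosses, the resolution is reported as
beyond Nyquist (`Inf`). Fixed thresholds (0.5, 0.143) are deliberately not
the primary criterion. One caveat inherent to checkerboard splitting: the
half-sample shift between sub-volumes attenuates correlation near the
sub-volume Nyquist, so cutoffs close to Nyquist are estimated
conservatively; the band-limited-phantom test places its cutoff at 60% of
Nyquist, where the attenuation is mild.

## The synthetic scene generator

The generator is first-class, tested code; every downstream recovery test
reads the exported ground truth rather than re-deriving it.

**Vessels.** `buildVesselTree()` grows a binary tree of straight
cylindrical segments: child radii follow Murray's law
(`r → r·2^(−1/3)`), centerline speeds scale by the same factor so
volumetric flow (area × mean speed, mean = peak/2 for a parabolic
profile) is conserved at every bifurcation, and children deviate from the
parent by a fixed branch angle at a seeded random azimuth. Radii spanning
roughly 30–200 µm and speeds up to tens of mm/s cover the physiological
range of a rodent cortical tree.

**Bubbles.** `simulateBubbles()` injects bubbles at the root as a Poisson
process whose rate is calibrated by Little's law (`λ = N/E[T]`, with the
mean transit time estimated by Monte Carlo over flux-weighted radial
offsets) so the expected in-view count hits its target. Each bubble keeps
a fixed fractional radial offset `u = r/R` drawn from the flux-weighted
profile (pdf ∝ `u(1−u²)`, capped at 0.95 so wall-grazing bubbles cannot
stall) and advances at the local Poiseuille speed `v = v_peak(1−u²)`,
choosing branches with probability proportional to flow. Amplitudes are
log-uniform over 1–10×, the brightness spread that motivates the
dual-threshold scheme. A `centerline` mode puts every bubble on the axis
at the peak speed — the configuration used to verify speed recovery under
ideal detection.

**Point spread function.** An anisotropic Gaussian with FWHM λ/2 axially
and 1.5λ laterally/in elevation — the diffraction-limited figures for this
array — stamped at the true sub-voxel position; the bubble image is
exactly linear in amplitude.

**Clutter and noise.** Clutter is a static smooth random field 30× the
unit bubble amplitude plus 29 weaker fluctuating modes per 200-frame
chunk, with spatial modes orthonormalized against each other and the base
and temporal coefficients orthonormalized against each other and the
constant. This makes the clutter rank within any processing block exactly
30 with a flat, far-above-bubble singular spectrum — a sharp
clutter/bubble cliff. That construction encodes two facts about the regime
in which SVD filtering is used in vivo: the removed fraction is an
empirical knob tuned to sit at the clutter/bubble transition of the
spectrum, and a *fraction* (rather than a fixed count) works across batch
lengths because tissue-clutter complexity grows with observation time —
hence modes are allocated per unit time, proportionally fewer for shorter
chunks. Electronic noise is half-normal with σ = 0.05 of the unit bubble
amplitude: sub-voxel sampling already reduces a dim bubble's brightest
voxel to ≈ 0.4 of its amplitude, and the noise floor of a working ULM
acquisition sits well below the dimmest usable bubble, not at a quarter
of it.

**What the generator does not emulate.** No acoustic propagation
(speckle, reverberation, aberration through the skull), no nonlinear
bubble dynamics or bubble destruction, no tissue motion, straight rather
than tortuous vessels, and intensity superposition rather than coherent
(phase-sensitive) summation of echoes. Passing the recovery tests
therefore demonstrates the correctness and calibration of the *processing
chain* under the stated statistical structure, not performance on real
transcranial data.

**Scene scale.** The packaged recovery scene is a 4-generation tree
spanning a 32×48×48-voxel λ/2 grid (≈ 3.2×4.7×4.7 mm) with 20 bubbles in
view over 500 frames (1 s at 500 volumes/s). The tree depth matters more
than it may appear: with a short tree the bubble stream occupies each
vessel voxel most of the time, and the temporal-DC component of that
quasi-continuous stream is removed together with the static clutter,
attenuating every bubble. Real ULM operates at low per-voxel duty cycle —
20 bubbles spread over centimetres of vasculature — and the deeper tree
reproduces that regime. Rendering and FSC in the bundled pipeline run on a
region of interest around the first bifurcations (≈ 1.8×2.1×1.8 mm at
λ/20) to keep the volumes at a few million voxels.

## Recovery metrics

The bundled acceptance analysis measures, on the packaged scene: the
fraction of isolated-PSF bubble appearances recovered (a bubble counts as
isolated in a frame when it lies inside the imaging grid and its nearest
simulated neighbour — in view or not — is more than 1 mm away, beyond the
merge radius of the low segmentation threshold; recovery means a
localization of either pass within 0.15 mm); per-axis localization RMSE
over those matches; mean track speed against the simulated centerline
speed on a noise-free single-vessel scene (the tracker's own invariant is
stated at detection rate 1 — with noise, localization jitter inflates path
length and biases speeds upward by several percent); separability of a
two-vessel phantom with 60 µm center separation on the λ/20 rendering
versus a λ/2 localization histogram; and single-image FSC resolution of
the rendering, plus recovery of a known spectral cutoff on a
band-limited phantom.

## Degenerate inputs and numerical choices

All-zero frames pass through noise thresholding unchanged with a warning
and produce no localizations. Blobs with zero total weight are discarded.
Blobs touching the volume border are kept but flagged. An empty
segmentation mask is a valid zero-blob result. FSC shells with no voxels
or zero power are dropped; a never-crossing FSC reports `Inf`. Odd
dimensions along FSC split axes are trimmed by one voxel with a warning.
Track linking with an empty frame simply terminates and starts tracks.
FWHM estimation refuses profiles with multiple peaks above half maximum or
without two half-maximum crossings. The λ/20 figure is 9.859 µm at full
precision; a truncation display mode reproduces the one-decimal convention
of reporting it as 9.8.

## Known limitations

Beamforming is a reference implementation in plain R — adequate for the
point-scatterer validation scenes, far from the GPU throughput needed for
10⁵-volume acquisitions. The clutter model's sharp rank cliff is an
idealization; real clutter spectra roll off smoothly and the removed
fraction then trades clutter rejection against bubble loss. Speed
estimates from noisy localizations are positively biased (path-length
inflation), mitigated but not removed by Savitzky–Golay smoothing.
Checkerboard single-image FSC underestimates resolution near the
sub-volume Nyquist. The Hungarian linker is O(n³) per frame pair, fine for
tens of bubbles per volume.
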