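---
title: "Quantifying intermittent intraneuronal transport from fluorescence video microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intermittent intraneuronal transport from fluorescence video microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Endosomes and lysosomes are carried along neuronal branches by molecular
motors in a characteristically intermittent way: processive "go" runs at
roughly 1 um/s interrupted by pauses of the order of a second. cargotrack
quantifies this motion from fluorescence video microscopy of labelled
cargoes (photostable tracers such as fluorescent nanodiamonds internalized
into endosomes, or lysosomal dyes), under the acquisition conditions the
pipeline was designed around: 2-minute videos at 20 frames/s with 80 nm
pixels, a field of view of roughly 40 x 80 um, and optionally a dual-view
sensor carrying two spectral channels side by side for dynamic
colocalization.

The pipeline is, in order: per-frame sub-pixel spot localization, frame-to-
frame linking into trajectories, segmentation of each trajectory into go
and stop phases by thresholding a sliding-window confinement ratio,
extraction of per-trajectory transport parameters and per-FoV summaries,
organelle-size estimation by quadrature PSF deconvolution, track-level
two-channel colocalization, and nonparametric condition comparisons.
A synthetic-microscopy generator with full ground truth backs every stage's
tests.

## Spot localization and linking

`locate_spots()` finds strict local maxima above a pixel threshold
(`median + 3 * mad` of the frame unless set explicitly) and refines each
candidate with a least-squares fit of a **pixel-integrated** 2-D Gaussian —
amplitude, sub-pixel centre, isotropic width `sigma`, flat background —
via Levenberg–Marquardt. Integrating the model over pixel areas (an `erf`
model rather than a sampled Gaussian) matters for the morphometry below: a
sampled-Gaussian fit inflates the recovered width by about `1/12 px^2` in
variance, which is a 2–4 nm bias at these pixel sizes. When a fit does not
converge or is implausible (width larger than half the search diameter,
non-positive amplitude) the spot falls back to a background-subtracted
weighted centroid. Detections closer than `spot_diameter_px` are reduced to
the brightest, and `min_mass` (integrated counts above background) rejects
noise candidates.

`link_spots()` implements Crocker–Grier frame-to-frame assignment: within
each frame, candidate links (distance at most `max_displacement_px`) are
grouped into independent sub-networks, and each sub-network is solved
exactly (branch and bound) for the assignment minimizing total squared
displacement, with `max_displacement_px^2` as the cost of opening a new
track. A track unmatched for at most `memory_frames` frames keeps its
identity. Sub-networks larger than 10 new spots — which do not occur at the
particle densities this assay targets — fall back to a greedy
nearest-first assignment. `filter_trajectories()` then drops tracks shorter
than `min_track_frames` (default 50 spots, i.e. 2.5 s at 20 Hz): long
enough to suppress spurious noise tracks, short enough to keep movers that
exit the field quickly. The per-FoV particle count reported downstream is
the number of surviving trajectories, static ones included.

## Go/stop segmentation by confinement ratio

For each spot the confinement ratio is computed over a centred window of
`window_frames` spots: net displacement between the window endpoints
divided by the summed step path length inside it. It is 1 for perfectly
directed motion, near 0 for stationary jitter, and is invariant to spatial
rescaling. Frames with ratio above `confinement_threshold` (0.8) are "go",
the rest "stop"; runs shorter than `min_phase_frames` are absorbed into
their neighbours (shortest first, earliest on ties), leaving maximal
phases that partition the trajectory.

**Window length is a resolution trade-off, and we chose it deliberately.**
A pause inside a window only drives the ratio below the 0.8 threshold once
the pause's jitter-dominated path length outweighs a quarter of the
directed displacement contributed by the go frames in the same window; for
localization-scale jitter this requires the pause to fill roughly half the
window. A 21-frame window (about 1 s) therefore cannot see sub-second
pauses at all, and with exponentially distributed pauses of mean 1 s it
misrecovers both pausing statistics badly (in our simulations: mean
pausing time overestimated by more than a factor 2, pausing frequency
undercounted by about 40%). The package default is `window_frames = 5`
(0.25 s at 20 Hz) with `min_phase_frames = 2`, which in the same
simulations recovers velocity within ~4%, mean pausing time within ~15%
and pausing frequency within ~10%. Both parameters are configurable; if
your pauses are long and your localization noisy, a longer window is the
safer choice.

Two conventions worth knowing:

* *Step attribution.* The step from spot `k` to `k + 1` belongs to the
  phase of spot `k` — the phase label describes the motion state over the
  following inter-frame interval. Consequently the final phase of a
  trajectory spans one interval fewer than its spot count, phase durations
  sum to the observation span `(n - 1) / frame_rate`, and a uniform
  straight run has exactly velocity `v` at any sampling rate.
* *Residual bias.* Pauses shorter than the detection floor (about 0.15 s
  at the defaults) are invisible, which biases the mean pausing time
  upward by roughly that amount and the pausing frequency downward by the
  share of pauses below the floor. This is a property of any
  threshold-on-windowed-statistic segmentation; we report it rather than
  hide it.

## Transport parameters

Per trajectory (`transport_parameters()`):

* **velocity** — total go path length / total go time. This is the
  time-weighted mean speed over go phases; the per-phase-averaged
  alternative weights a 0.2 s run equally with a 10 s run and is noisier.
* **run length** — mean go-phase path length (the mean go-phase *net*
  displacement is reported alongside as `run_net_um`).
* **pausing time** — mean stop-phase duration.
* **pausing frequency** — stop events per minute of observed trajectory
  duration. Using the full observed duration (not just moving time) keeps
  the quantity comparable across mostly-static and mostly-moving tracks.
* **total length** — sum of go-phase run lengths.

A trajectory is "moving" (`classify_moving()`) when at least one go phase
achieves a net displacement of `min_directed_displacement_um` (default
1 um — several diffraction limits, unreachable by stationary jitter).
`summarize_fov()` reports per-FoV particle counts, mover counts and the
moving fraction, and restricts the parameter table to movers, which is the
population plotted in per-trajectory comparisons.

## Organelle size by quadrature deconvolution

A fluorescent organelle of Gaussian-equivalent SD `sigma_L` imaged through
a Gaussian PSF of SD `sigma_PSF` appears as a spot of SD
`sigma_T^2 = sigma_PSF^2 + sigma_L^2`. `estimate_lysosome_diameter()`
inverts this and reports the FWHM diameter `d_L = 2 sqrt(2 ln 2) sigma_L`.
The deconvolution PSF defaults to the measured 112 nm (the width of the
smallest tracer spots); the theoretical chain is also carried:
`compute_psf_constants(700, 1.49)` gives the Airy radius
`0.61 * lambda / NA = 286.6 nm` and the empirical Gaussian approximation
`Airy / 3 = 95.5 nm`, selectable with `use_empirical = TRUE`. Spots no
wider than the PSF (possible under noise) report diameter 0 with
`resolvable = FALSE` rather than an imaginary width, so per-FoV size
tables stay totalizable. Per-trajectory sizes use the median fitted width
over the trajectory's spots (`trajectory_sizes()`), which is robust to the
occasional bad fit.

## Two-channel colocalization and ROI intensity

Dual-view frames are split by `split_channels()`; the red view is
translated by a rigid config-supplied offset into the green view's frame.
Full affine registration is out of scope — the dual-view optics motivate
no more than a translation, and the offset is an explicit, auditable
config entry.

`match_trajectories()` works at the trajectory level, not pixel level: a
green–red pair sharing at least `min_overlap_frames` frames (default 20,
i.e. 1 s) qualifies when the median inter-channel distance over the common
frames is at most `max_distance_nm` (default 320 nm = 4 px, about the
two-colour localization scale of this optical configuration). Each moving
green trajectory takes its nearest qualifying partner, and the
colocalized fraction is computed over moving green trajectories — the
moving-assembly population. The median (rather than mean) summary distance
makes the criterion robust to brief linking glitches. Pearson/Manders
pixel-correlation coefficients are deliberately not implemented: the
readout of interest is "this moving assembly travels with a lysosome",
which is a statement about trajectories.

`branch_roi_intensity()` is the standard decoration readout: mean counts
per pixel over a polygonal ROI drawn along a branch (conventionally 30 um
of branch length), minus the same mean over a background polygon; pixel
inclusion is centre-in-polygon. A background polygon overlapping signal
biases the result downward; the function warns when the polygons overlap.

## Condition comparisons

`compare_conditions()` compares each non-control group with the control
using the two-tailed Wilcoxon Mann–Whitney test: exact by enumeration of
the rank distribution when `n_a * n_b <= 400` with no ties, otherwise the
normal approximation with tie and continuity corrections. An F
variance-ratio test is recorded per comparison as a descriptive screen —
it never switches the main test. Stars follow 0.05 / 0.01 / 0.001. No
multiple-testing correction is applied by default (each figure-level
family is small and the comparisons are planned); Holm adjustment is one
flag away. Trajectories are pooled across coverslips and cultures — the
hierarchical structure of such experiments is a known limitation of this
design, not modelled here.

## The synthetic-microscopy generator

`simulate_motion()` + `render_video()` emulate exactly the statistical
structure the analysis assumes: particles on branch-like polyline paths
(default: one straight lane per particle spanning the FoV) alternate
memoryless exponential go phases (advancing at `v_go_um_s`) and stop
phases (jitter only, `jitter_sd_nm = 10` — localization-scale); a
`1 - p_moving` share never moves; a mover reaching its branch end simply
leaves the simulation, as a cargo exiting the FoV. Rendering integrates a
Gaussian of SD `sqrt(sigma_psf_nm^2 + object_sigma_nm^2)` over pixel
areas, with Poisson photon noise over a uniform background plus Gaussian
read noise. Identical seeds give identical output.

What the generator deliberately does **not** emulate: photobleaching and
blinking (the motivating tracer is photostable), EM-gain excess noise,
axial defocus, curved or branching paths, heterogeneous per-particle
speeds, and motor mechanochemistry. Green tests on this generator
therefore demonstrate that the *algorithms* recover known truth under the
assay's nominal conditions — not that real neurons contain no further
surprises (crossing trajectories, uneven background, out-of-focus spots
all degrade real data first through the detector and linker).

## Validation problem sizes

The test suite and the acceptance script validate, at these scales:

* phase parsing equal frame-for-frame to a brute-force reference on 1000
  random go/stop trajectories;
* transport-parameter and moving-fraction recovery on 100 particles
  (30 movers, `v_go` 1 um/s, go 2 s, stop 1 s, 20 Hz, 120 s, ~5000
  photons/frame) rendered onto a reduced 400 x 800 px (32 x 64 um) FoV
  and re-tracked from the pixels;
* size round-trips for object SDs of 100/150/200 nm at sigma_PSF 112 nm;
* planted colocalized fraction 0.40 among 50 moving green trajectories
  with 40 interleaved red distractors;
* Mann–Whitney exactness against full enumeration for all group sizes up
  to 8, and null calibration over 1000 simulated datasets.

## Numerical and degenerate-input choices

* Trajectories shorter than the confinement window use the whole
  trajectory as the window; windows truncate at trajectory ends.
* Zero-path windows (all spots coincident) give ratio 0, i.e. "stop".
* Merging ties go to the earliest shortest run; a trajectory can collapse
  to a single phase.
* Trajectories with no go phase report `NA` velocity and run length
  (flagged, not zero), total length 0.
* Empty FoVs summarize as zero particles with an `NA` moving fraction.
* Video TIFFs are written as 16-bit integer counts; integer stacks within
  [0, 65535] round-trip exactly.
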