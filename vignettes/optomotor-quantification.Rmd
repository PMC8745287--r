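---
title: "Quantifying the optomotor response: measurement model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the optomotor response: measurement model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optodrum)
```

## The assay and its model

A mouse sits on a stationary platform inside a drum lined with vertical
black/white stripes. The drum rotates at a constant angular speed and
reverses direction on a fixed schedule; a camera above the platform records
the scene. An animal that resolves the stripes reflexively turns its head and
body with them, so the angular speed at which the animal moves *in the
stimulus direction* is a behavioral proxy for whether the grating is visible.

`optodrum` models one trial as three coupled per-frame time series —

* the drum direction $d_t \in \{\mathrm{CW}, \mathrm{CCW},
  \mathrm{UNKNOWN}\}$, inferred from pixels rather than trusted from the
  motor controller (recordings do not carry the motor state),
* the position angle $\theta^{pos}_t \in [0^\circ, 360^\circ)$ of the
  animal's centroid around the arena center, and
* the axial body-orientation angle $\theta^{or}_t \in [0^\circ, 180^\circ)$,

— and two scalar endpoints, the conditional means

$$\bar v^{run} = \mathrm{mean}\{\,|v^{pos}_t| : \text{frame } t \text{
matched on position}\,\}, \qquad
\bar v^{orient} = \mathrm{mean}\{\,|v^{or}_t| : \text{frame } t \text{
matched on orientation}\,\},$$

where $v_t = \Delta\theta_t \cdot f$ is the forward-difference angular
velocity at frame rate $f$, and a frame is *matched* when its velocity sign
agrees with $d_t$, its magnitude clears a small dead band, and $d_t$ is
known.

All angles are defined in image coordinates as seen by the overhead camera:
$\theta^{pos}$ is measured clockwise from the upward vertical (0° up, 90°
right), $\theta^{or}$ clockwise from the image vertical (0° vertical body
axis, 90° horizontal), and clockwise velocity is positive. The physical
handedness of the drum is irrelevant: the method only ever compares mouse
and drum direction within the same image.

### Assumptions

* One animal, darker than everything else inside the circular monitored
  region, under stable lighting (a constant segmentation threshold
  suffices).
* The stripe band directly above the monitored region is visible and shows
  at least two stripe cycles, so lateral pattern motion is measurable there.
* Frames arrive at a known, constant frame rate.

## Stimulus-direction detection

The strip above the center is collapsed to a 1-D profile of column means
(stripes are vertical in that cut, so averaging rows loses no direction
information and suppresses row noise), binarized against a local mean
(`binarize_adaptive`), and compared with the previous frame's profile over
every integer shift $s \in [-s_{max}, s_{max}]$. The chosen shift maximizes
the agreement fraction; the description "compare stripe order and
black/white pixel counts with the previous frame" is operationalized as this
shift-agreement scan (binary cross-correlation) because it subsumes that
comparison, is deterministic, and has a trivially verifiable brute-force
oracle. Rightward pattern motion above the center corresponds to clockwise
rotation; `invert_stimulus_sign` accommodates mirrored camera mounts.

Tunables, all exposed in `run_config()`:

| parameter | default | rationale |
|---|---|---|
| `window` (adaptive threshold) | 15 px | slightly under one stripe period of the default stimulus at the default geometry (~19 px), so the local mean straddles both stripe colors |
| `max_shift` | profile length / 4 | caps the scan well below the period aliasing point (half a period) |
| `min_shift` | 1 px | a best shift of 0 px means "no detectable motion", never a direction |
| `min_confidence` | 0.6 | agreement is 1.0 on clean video and ~0.5 for unrelated binary profiles; 0.6 rejects the latter while tolerating edge effects |
| `smooth_window` | 5 frames | majority vote long enough to cancel single-frame flips, short next to the 600-frame bouts |

Numerical conventions: ties in agreement break toward the smallest $|s|$
(favoring "no motion"), then toward positive $s$, making the scan fully
deterministic. Frame 0 is always UNKNOWN. Smoothing relabels only frames
that already have a known direction; UNKNOWN never spreads or fills.
Swapping the two frames negates the estimated shift and flips the call —
except at an exact agreement tie between $+s$ and $-s$, where the tie-break
picks $+s$ for both orders; clean stripe video has a unique maximum, so this
corner is not observable there.

## Pose

Each frame is converted to grayscale (0.299 R + 0.587 G + 0.114 B for color
input), masked to the closed disc of radius `mask_radius` (the boundary
pixel at exactly the radius is kept; outside pixels are filled with the
bright background so they cannot survive segmentation), and thresholded with
strict `intensity < threshold` so the dark mouse becomes the white
foreground. The default threshold of 128 sits halfway up the 8-bit scale;
the value is a config input because it depends on the rig's lighting.

The position angle comes from the foreground centroid. The orientation is
the **principal (orthogonal-distance) axis** of the foreground cloud, not a
y-on-x regression line: y-on-x is degenerate for a vertical animal and not
rotation-equivariant, which would contradict the convention that 0° *is* the
vertical. This was a genuinely open design point; the principal axis is the
only choice consistent with the stated conventions, and the test suite pins
it against a brute-force orthogonal-distance fit (0.1° grid) to within 0.2°.

Degenerate inputs yield explicit missing values, never defaults: fewer than
`min_foreground` pixels (pipeline default 50 px; the bare geometric
primitives default to 1 px so they remain usable on small synthetic masks),
a centroid within `eps` = 1 px of the center (position direction undefined),
or principal variances equal within `iso_tol` = 0.05 (isotropic blob, axis
undefined). A frame is valid only when *both* angles exist; a half-valid
frame is demoted entirely so downstream velocities never mix channels of
different quality. Missing angles propagate: both forward differences
touching an invalid frame are missing. Zero-filling would bias the endpoint
speeds downward, and "no tracking behavior observed" must stay
distinguishable from "tracked at speed 0" — an empty matched set therefore
reports `NA`, never 0.

No morphological cleanup runs by default (the measurement needs none on
well-lit recordings); `largest_component = TRUE` enables a 4-connected
largest-component filter for noisy rigs.

## Kinematics

Velocities are forward differences through the circular wrap
(`angular_difference`, result in $(-\mathrm{period}/2, \mathrm{period}/2]$;
period 360° for position, 180° for the axial orientation), assigned to the
earlier frame — the simplest causal estimator. The endpoints average
**absolute** velocity over matched frames only: the assay's definition is a
conditional mean over stimulus-direction-matched movement, and the absolute
value makes clockwise and counterclockwise bouts commensurable. The
`dead_band` of 2 deg/s exists because pixel quantization of a near-stationary
blob generates small velocities of arbitrary sign that would otherwise count
as matched frames. An optional centered moving median (window 5) is off by
default; no temporal smoothing is part of the core definition.

One property worth knowing when interpreting noisy recordings: differencing
amplifies per-frame angle jitter by the frame rate, and the sign-gating then
*selects* frames whose noise pushes them in the stimulus direction, so under
heavy jitter the conditional mean of $|v|$ is biased upward relative to the
true following speed. The dead band trims the worst of it; the bias is a
property of the endpoint's definition, not of this implementation, and
vanishes on low-noise video (the gain-recovery tests run noiseless and
recover $g \times 50$ deg/s within 5% for gains 0.25–1.0).

## The synthetic arena

`render_trial()` emulates the study conditions: a 72-cycle stripe annulus
(0.2 cycles/degree around the drum) rotating at 50 deg/s and reversing every
20 s, a bright central platform inside a 200 px mask radius on a 480×480 px
frame, and the mouse as a dark ellipse (60×24 px default) whose position
angle integrates `following_gain` × drum speed in the drum direction delayed
by `response_latency`, with per-frame Gaussian angle jitter; the body axis
is tangential to the center ray. The renderer derives pixels from the
ground-truth table, never the reverse, every mouse pixel is strictly darker
than every in-mask background pixel (segmentation is well-posed by
construction), and trials are fully deterministic given (config, behavior,
seed). Bout boundaries are half-open — the boundary instant belongs to the
later bout — so the schedule is plain floor arithmetic. The first bout's
direction is a required configuration choice (clockwise by default); the
alternation schedule itself does not determine it.

What the simulator does **not** emulate: fur texture and photorealistic
shading, lens distortion, varying radial position (the animal sits at a
fixed 0.6 × mask radius), rearing/grooming postures, multi-animal scenes,
and exploratory movement beyond the gain/latency/noise model. Passing tests
on synthetic video therefore demonstrate the correctness of the measurement
chain, not robustness to every artifact of real recordings; the
segmentation threshold, dead band and direction-confidence cutoffs are the
knobs to revisit on real data. The 480×480 px default (rather than a
camera's full 1920×1080) keeps desk-scale runs fast; all geometry is
configurable.

Test and validation runs use desk-scale problem sizes chosen to exercise
every code path with comfortable margins: 60 s trials (1800 frames) for
end-to-end speed recovery, 120 s stimulus-only recordings (3600 frames) for
reversal statistics, and 2–16 s trials elsewhere.

## Input formats and determinism

Recordings are read as directories of numbered PNG/TIFF frames (`read_frames`,
half-open 0-based frame ranges). Lossless frame sequences are the package's
on-disk format by design: they round-trip pixel-exactly, need no codec
stack, and make reruns byte-reproducible — `run_pipeline()` on identical
input and configuration writes byte-identical CSV/JSON. The run
configuration loader rejects unknown keys by name and reports every
invariant violation with its field, and `save_run_config()` writes all
effective values so a saved configuration reloads to exactly the same run.

## The EAU composite score

For fundus-graded eyes, `eau_composite()` returns the unrounded arithmetic
mean of the optic disc, retinal vessel and retinal tissue grades, each
bounded by a configurable maximum (default 4). The mean is not rounded and
any nonnegative grade within bounds is accepted (integer or half-point
scales both occur in practice); permutation invariance, monotonicity and
boundedness are pinned by tests.
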