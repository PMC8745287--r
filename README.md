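# optodrum

Quantification of the rodent **optomotor response** from overhead video of a
rotating striped drum.

The optomotor reflex — an involuntary head/body movement following a rotating
high-contrast grating — is a standard behavioral read-out of visual function
in mice: an animal that resolves the stripes turns with them, an animal that
does not sits still. `optodrum` turns an overhead recording of a mouse inside
a striped drum into the two endpoints used to compare groups in visual-acuity
and ocular-disease studies (for example experimental autoimmune
uveoretinitis, EAU):

* **angular orientation speed** — the mean angular velocity of the animal's
  snout–tail axis over frames where it turns with the stimulus, and
* **angular running speed** — the mean angular velocity of the animal's body
  center around the arena center over stimulus-matched frames.

It is written for vision and neuroimmunology labs that run drum-style
optomotor assays and want a scriptable, fully testable analysis instead of a
one-off lab script.

## The measurement

Angles follow the overhead-camera conventions: the *position angle*
θ<sub>pos</sub> ∈ [0°, 360°) is measured clockwise from the upward vertical
through the arena center (0° up, 90° right); the *orientation angle*
θ<sub>or</sub> ∈ [0°, 180°) is the axial angle between the image vertical and
the body axis (0° vertical, 90° horizontal). Clockwise angular velocity is
positive.

Per frame *t* the pipeline computes:

1. **Stimulus direction.** A cut directly above the arena center, in which
   two stripes are ideally visible, is collapsed to a 1-D profile of column
   means, binarized by adaptive thresholding (each sample against its local
   mean), and compared with the previous frame's profile over all integer
   lateral shifts *s*: the shift maximizing the agreement fraction gives the
   stripe displacement, its sign the drum direction (rightward motion above
   the center = clockwise). Sub-threshold shifts or low agreement give
   UNKNOWN; isolated flips are removed by majority voting.
2. **Pose.** The frame is converted to grayscale, masked to the circular
   monitored area, and thresholded so the dark mouse on the bright platform
   becomes the white foreground. θ<sub>pos</sub>(t) is the angle of the
   center→centroid ray; θ<sub>or</sub>(t) is the angle of the principal
   (orthogonal-distance) axis of the foreground pixels.
3. **Kinematics.** Forward differences through the circular wrap give the
   angular velocities v<sub>pos</sub>(t), v<sub>or</sub>(t) =
   Δθ · frame rate. A frame is *matched* when its velocity sign agrees with
   the detected drum direction, exceeds a small dead band, and the direction
   is known. The endpoints are the means of |v| over the matched frames of
   each channel; a trial with no matched frames reports *missing*, not zero.

A **synthetic arena** renders ground-truthed trials — 72-cycle stripe annulus
(0.2 cycles/degree) reversing every 20 s at 50 degrees/s, plus a dark
elliptical mouse with configurable following gain, response latency and angle
noise — so every stage of the chain is testable without recorded data.

## Worked example

A 20 s synthetic trial in which the mouse follows the drum at 80% of the
drum speed:

```r
library(optodrum)
cfg   <- arena_config()        # 50 deg/s drum, 20 s alternation, 30 fps
geo   <- arena_geometry()      # 480x480 px frame, mask radius 200 px
beh   <- behavior_params(following_gain = 0.8, seed = 42)
trial <- render_trial(cfg, geo, beh, duration = 20)
res   <- analyze_frames(trial$frames, run_config(arena = cfg, geometry = geo))
res
#> Optomotor trial
#>   angular orientation speed: 40.00 deg/s (598 matched frames)
#>   angular running speed:     40.00 deg/s (598 matched frames)
#>   frames: 600 total, 600 valid pose, 1 unknown stimulus
```

Both endpoints recover 0.8 × 50 = 40 deg/s. Frame 0 has unknown stimulus
direction (there is no previous frame to compare against), and the last frame
has no forward difference, leaving 598 matched frames. The frame-level table
behind the summary:

```r
head(as.data.frame(res)[, c("frame", "time_s", "position_angle_deg",
                            "stim_direction", "position_velocity_degps",
                            "position_matched")], 4)
#>   frame     time_s position_angle_deg stim_direction position_velocity_degps position_matched
#> 1     0 0.00000000           0.000000        UNKNOWN                40.53973            FALSE
#> 2     1 0.03333333           1.351324             CW                39.61093             TRUE
#> 3     2 0.06666667           2.671689             CW                38.73454             TRUE
#> 4     3 0.10000000           3.962840             CW                40.95853             TRUE
```

For recorded data, point `run_pipeline()` (or the `inst/cli/optodrum` script)
at a directory of numbered PNG/TIFF frames plus a JSON/YAML run
configuration; it writes the frame-level CSV, a summary JSON and the
effective configuration. `score_eau_table()` computes the composite EAU
clinical score — the mean of the optic disc, retinal vessel and retinal
tissue grades — for fundus-grading tables.

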