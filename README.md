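# gazeframe

Reference-frame analysis of saccade direction biases under head tilt.

## What this is for

Saccades during free viewing are not uniform in direction: horizontal
movements dominate, vertical ones come next, oblique ones are rare. When
the head is rolled to the side, this anisotropy can stay put in the world
(gravity-anchored), rotate with the head, or follow the eye — which
counter-rolls a few degrees back toward upright (ocular counter-roll,
OCR). Telling these apart is a question about the coordinate frame in
which saccades are generated, and it matters to anyone modelling gaze,
building eye-tracking analyses for tilted observers, or studying
vestibular influences on oculomotor control.

gazeframe implements the complete measurement chain for this question:

1. **Saccade detection** from raw gaze traces by a velocity-threshold
   algorithm: five-point differential smoothing filter, per-trial robust
   thresholds `eta = lambda * sqrt(med(v^2) - med(v)^2)` with `lambda = 8`,
   elliptic criterion `(vx/eta_x)^2 + (vy/eta_y)^2 > 1`.
2. **Circular KDE** of saccade directions: wrapped Gaussian kernel, sd
   0.1 rad, evaluated from 0° to 360° in 0.1° steps.
3. **Displacement estimation**: the angular lag Δ (clockwise-positive)
   maximising the circular cross-correlation between two direction
   densities, searched within ±45° to avoid the 90°/180° symmetry
   aliases; per-subject bootstrap 95% CIs.
4. **Reference frame index**: `RFindex = (Δ₊ − Δ₋) / (2T)` — 0 when the
   bias stays in the measurement frame, 1 when it rotates fully with the
   tilt — plus an OCR-scaled variant that divides by each subject's
   measured change in median ocular counter-roll instead of T.
5. A seeded **synthetic gaze simulator** emulating the full head-tilt
   free-viewing design (14 subjects, ±30°/0° head-tilt blocks, 60 trials
   per block at 15 s / 120 Hz, saturating OCR, configurable anchoring),
   so the whole chain is testable without recorded data.

## Worked example

Simulate a retina-anchored study (counter-roll gain 0.1), detect saccades,
and fit the fractal head-tilt analysis with the torsion summary attached:

```r
library(gazeframe)

cfg  <- gaze_config(anchor = "retina", ocr_gain = 0.1, ocr_saturation = 10,
                    image_types = "fractal", seed = 42)
gaze <- generate_study(cfg)   # 14 subjects x 90 fractal trials, 15 s @ 120 Hz
sacc <- detect_study(gaze)    # saccade table with condition columns
fit  <- rf_fit(sacc, "fractal_head_tilt", torsion = torsion_summary(gaze))
fit
```

```
Reference-frame fit: fractal_head_tilt 
  14 subjects, head frame, T = 27.04 deg
  delta_pos:  -1.60 deg  (95% CI [-3.68, 0.43], n = 14)
  delta_neg:  +3.25 deg  (95% CI [1.79, 4.64], n = 14)
  RFindex: 0.09 (signed -0.09)
  OCR-scaled RFindex: 0.90 (3 subjects excluded)
```

Reading this: in head coordinates the direction bias is displaced a few
degrees opposite in sign to the head tilt, the retinal signature (a
world-anchored bias would sit near ∓27°, a head-anchored one near 0°).
Scaled by the ~27° measured tilt this gives a small RFindex of 0.09, but
scaled by each subject's own ~2.7° counter-roll change it is 0.90, i.e.
the bias rotated about as far as the eye counter-rolled: retinal
anchoring recovered. (Three of the 14 simulated subjects lack a torsion
channel, emulating real torsion-tracking dropout, and are excluded from
the OCR-scaled index. The example takes about a minute.)

`summary(fit)` adds per-subject displacement tables, `coef(fit)` returns
`(delta_pos, delta_neg, rf_index)`, `confint(fit)` the group bootstrap
CIs, and `plot(fit)` polar densities of the condition pairs. The same
interface fits `"scene_earth_upright"` (Earth-upright scenes across head
tilts, world coordinates) and `"scene_tilt_upright"` (tilted scenes with
the head upright). `run_pipeline()` chains simulation/ingest, validation,
detection, all three analyses and a versioned JSON report; see
`vignettes/reference-frames.Rmd` for the model, conventions and
limitations.

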