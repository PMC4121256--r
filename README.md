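# nbracm

Narrow-band, localized region-based active contours for segmenting noisy
multi-channel (color) images, channel by channel.

## The problem and the model

Piecewise-constant active contours of the Chan–Vese family segment an image
by evolving a level-set function φ whose zero crossing is the contour
(interior = {φ < 0}). They compare each pixel against the *global* mean
intensities u (inside) and v (outside), which makes them fragile under heavy
noise, and they are usually applied to a gray-scale reduction of a color
image, which merges objects whose colors differ but whose channel averages
do not.

This package implements a model that addresses both weaknesses:

- **Localized force.** For every pixel x, windowed local means are gathered
  over a ball B(x, y) of radius r (default 2 px),

      u_x = Σ_y B(x,y) H(φ(y)) I(y) / Σ_y B(x,y) H(φ(y)),
      v_x = Σ_y B(x,y) (1−H(φ(y))) I(y) / Σ_y B(x,y) (1−H(φ(y))),

  with H a smoothed Heaviside of width ε = 1.5. The force driving the
  contour is the difference between squared deviations of the local means
  from the global ones,

      F(x) = (u − u_x)² − (v − v_x)²,

  and the evolution is

      ∂φ/∂t(x) = δ(φ(x)) F(x) Σ_y B(x,y) δ(φ(y)) + ν δ(φ(x)) κ(x),

  with κ the mean curvature and ν a length penalty. Averaging over the ball
  suppresses pixel noise while the global means keep the phase assignment
  globally anchored.

- **Narrow band.** φ is maintained as a signed-distance function and only
  pixels within a band |φ| ≤ w (w = 3 px) are updated; the field is
  periodically reinitialized by a signed Euclidean distance transform with
  sub-pixel interface localization.

- **Channel-to-channel segmentation.** Each color channel evolves its own
  contour; the per-channel signs are combined into a per-pixel sign sequence
  giving up to 2^N region labels for N channels (8 for RGB). Objects with
  equal gray-scale intensity but different colors receive distinct labels.

Two classical baselines are included for comparison — the vectorial
multiphase Chan–Vese model (two level sets, four phases, channel-averaged
residuals) and the channel-wise Chan–Vese model with sign-sequence
combination (STP-CV) — together with the overlap metrics JS (Jaccard), DSC
(Dice), RFP and RFN, and a seeded generator of synthetic colored-shape
scenes (circles, rectangles, stars; Gaussian, salt-and-pepper and
multiplicative speckle noise) with pixel-exact ground truth.

## Worked example

```r
library(nbracm)

scene <- scene_preset("three_disks", 128)          # 3 colored disks
rend  <- render_scene(scene)                        # image + exact truth
noisy <- add_noise(rend$image, "gaussian", v = 0.05, seed = 1)

seg <- segment_image(noisy, "nbracm",
                     cfg = evolution_config(track_energy = FALSE))
print(seg)
#> <segmentation> model nbracm | 128 x 128 | 6 labels

truth  <- truth_sign_labels(rend)
report <- per_label_overlap(truth, seg$labeling$labels)
print(report[, c("truth_label", "pred_label", "js", "dice", "rfp", "rfn")],
      digits = 3)
#>   truth_label pred_label    js  dice     rfp     rfn
#> 1           0          7 0.996 0.998 0.00206 0.00198
#> 2           1          6 0.979 0.989 0.01114 0.01035
#> 3           3          4 0.986 0.993 0.01432 0.00000
#> 4           6          1 0.985 0.992 0.01512 0.00000
misclassified_pixels(truth, seg$labeling$labels)
#> [1] 77
```

Each row compares one ground-truth region (background plus the three disks)
with its best-matching predicted label: under Gaussian noise of variance
0.05 every region is recovered with Dice ≥ 0.99, and 77 of the 16384 pixels
are misclassified. Labels are matched by maximal overlap because the
interior/exterior orientation of each channel's contour depends on the
initialization. The six predicted labels include two thin spurious
boundary-transition regions, which the matching ignores.

A thin command-line wrapper over the same functions is installed at
`inst/cli/nbracm.R` with subcommands `segment`, `synth`, `eval` and `sweep`.

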