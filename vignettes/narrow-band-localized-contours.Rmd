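---
title: "Narrow-band localized active contours for noisy color images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Narrow-band localized active contours: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbracm)
```

## The segmentation model

A contour is represented implicitly as the zero crossing of a level-set
function φ on the pixel grid, with the interior convention φ < 0. Interior
and exterior weights come from a smoothed Heaviside of width ε,

$$H(\phi) = \begin{cases} 1 & \phi < -\varepsilon \\
\tfrac12\left(1 - \phi/\varepsilon - \sin(\pi\phi/\varepsilon)/\pi\right) &
|\phi| \le \varepsilon \\ 0 & \phi > \varepsilon,\end{cases}$$

which is continuous and non-increasing, so H ≈ 1 on the interior; the
matching Dirac weight is the cosine bump
$\delta(\phi) = (1+\cos(\pi\phi/\varepsilon))/(2\varepsilon)$ on
$|\phi|\le\varepsilon$ and 0 outside, so that $\delta = |H'|$ and
$\int\delta = 1$. (Some presentations print the transition branch of H with
the opposite slope, which is discontinuous against the outer branches and
contradicts the interior convention used by the rest of the model; we keep
the outer branches and orient the transition to match them. Likewise the
Dirac is supported on $|\phi|\le\varepsilon$, where a literal reading of the
piecewise conditions would make it vanish there.)

For a single channel $I$ with global interior/exterior means $u, v$
(H-weighted means over the whole image) and windowed local means $u_x, v_x$
(the same means restricted to a ball of radius $r$ centered on $x$, windows
clipped at the image border), the evolution is

$$\frac{\partial\phi}{\partial t}(x) \;=\;
\delta(\phi(x))\,\bigl[(u-u_x)^2-(v-v_x)^2\bigr]
\sum_{\|y-x\|<r}\delta(\phi(y)) \;+\; \nu\,\delta(\phi(x))\,\kappa(x),$$

with $\kappa$ the mean curvature by central differences. The squared-
deviation difference pushes a pixel toward the phase whose global mean its
local neighborhood resembles; averaging over the ball is what makes the
force robust to pixel noise, while the global means preserve global phase
coherence. If the ball covers the whole image the local means equal the
global ones and the force vanishes identically — the model degenerates, so
$r$ must stay well below the image size.

Each color channel evolves independently with its own φ. The final labeling
assigns each pixel the N-bit sign sequence $s_i = \mathbf 1[\phi_i > 0]$
(with $\phi_i = 0$ mapping to $s_i = 0$), encoded as
$\sum_i s_i 2^{N-i}$ — up to $2^N$ regions, 8 for RGB, with channel order
fixed (R, G, B) so labels are stable. Because the interior/exterior
orientation of a converged channel depends on its initialization, labels are
compared to ground truth by maximal-overlap matching, never by value.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `epsilon` | 1.5 | px | Heaviside/Dirac regularization width |
| `r` | 2 | px | ball radius for local means |
| `nu` | 0.2 | – | curvature (length) weight on [0,1] intensities |
| `band_halfwidth` | 3 | px | narrow band half-width, must exceed 2 |
| `reinit_every` | 5 | iterations | distance-function maintenance period |
| `smooth_sigma` | 0.5 | px | Gaussian smoothing of the field per iteration |
| `max_iter` | 200 | iterations | cap for the narrow-band evolution |
| `convergence_patience` | 10 | iterations | stability window |

`r = 2` is the standard operating point: smaller radii make the force
revert to the global (noise-sensitive) comparison, larger radii oversmooth
the fitting image and distort boundaries — the `radius_sweep()` study
quantifies this trade-off. For severe noise (Gaussian variance above 0.1 on
the [0,1] scale) we raise the length penalty to `nu = 0.5`: the penalty
should scale with the noise level, and at variance 0.5 the default leaves
residual noise pots for some noise realizations. The band half-width must
exceed twice the unit space step so the band holds at least one pixel on
each side of the interface; `narrow_band()` enforces this.

Convergence is declared when the zero-crossing pixel set (the interior
mask) is unchanged for `convergence_patience` consecutive iterations; runs
that exhaust `max_iter` are returned with `converged = FALSE` rather than
failing, since the mask is typically long stable in all but a few flickering
boundary pixels.

## Numerical choices

**Time stepping.** The forward-Euler step uses a robust CFL-style rule: the
step is scaled so that the 0.9 quantile of the active |update| equals 0.45
px, and individual increments are clamped at 0.45 px. Normalizing by the
*maximum* update instead stalls multi-object scenes: contour segments that
have already locked onto a boundary keep oscillating with near-maximal
residual and throttle the step for everything else. A fixed `dt` can be
supplied; the descent-trend tests use one, because the adaptive rule keeps
moving 0.45 px somewhere and limit-cycles once the contour has converged.

**Reinitialization.** The signed-distance property is restored every
`reinit_every` iterations by a signed Euclidean distance transform
(EBImage's `distmap`), corrected by half a pixel for the pixel-grid
interface offset, with sub-pixel linear interpolation at interface-adjacent
pixels, followed by a few Godunov upwind relaxation sweeps of the
reinitialization equation restricted to the near-interface zone. The
interface-adjacent values and the distance ridge (skeleton) are frozen
during relaxation: the former pin the contour and the sign pattern exactly,
the latter would otherwise be eroded by the upwind scheme's bias at
characteristic collisions. The result is within half a pixel of the true
distance everywhere and has unit gradient on the vast majority of band
pixels. This replaces a fast-marching Eikonal solver; the contract — signed
distance to the zero crossing within half a pixel, signs preserved — is
what the evolution needs, not the particular solver. Field smoothing after
each step is plain Gaussian smoothing (σ = 0.5), a stand-in for an
unspecified smoothing step in the original procedure.

**Energy.** The localized energy (Dirac-weighted ball integral of the
squared deviations plus ν times contour length) is tracked per iteration on
the *canonical* (reinitialized) field: per-iteration smoothing flattens
|∇φ|, deflating the Dirac-weighted terms, so the raw trace jumps at every
reinitialization; the canonical trace depends only on the contour. The flow
is not the exact gradient of this energy (the force uses the mean-deviation
form), so the trend assertions are trend assertions, not strict
monotonicity.

**Convolutions.** Windowed sums use direct shift-and-add with zero fill
(equivalent to clipping windows at the border) for small balls and an
FFT-based same-size convolution for large ones; both are exercised against
exhaustive double-loop oracles in the tests.

**Degenerate inputs.** All-interior or all-exterior initializations, empty
phases, vanished contours, single-signed fields, non-positive widths and
radii each raise a classed error (`nbracm_*`); a contour that vanishes
*during* evolution terminates the run with an empty interior rather than
erroring.

## The baselines

The vectorial multiphase Chan–Vese model minimizes the four-phase
piecewise-constant energy with channel-averaged residuals over two level
sets; the update for each field is driven by the differences of the
residuals of the phases it separates, weighted by the other field's
Heaviside, with phase means recomputed every iteration (empty phases carry
their previous mean). The per-channel baseline (STP-CV) runs the two-phase
Chan–Vese flow in every channel and combines signs exactly as the main
model. Its printed update subtracts both quadratic data terms, which cannot
select between phases; the classical signs
$+\lambda_1(I-c_1)^2-\lambda_2(I-c_2)^2$ (oriented for the φ<0-interior
convention) are used instead.

Both baselines use the *non-compact* regularized Dirac
$\delta_\varepsilon(\phi)=\varepsilon/(\pi(\varepsilon^2+\phi^2))$ in their
updates — the implementation choice of the original Chan–Vese method. With
the compactly supported bump the baselines are hostage to their
initialization: a level set whose contour has retreated from a region can
never re-enter it, and the four-phase model then settles into a local
minimum that merges two object colors while duplicating the background.
The non-compact form lets contours nucleate anywhere, which is also what
makes these models take isolated noise-favored pixels as objects ("noise
pots") under heavy noise — the behavior the localized model is designed to
avoid. Baselines run full-domain (no narrow band), with a higher iteration
cap (500) since their contours may sweep the whole image, and a length
weight μ = 0.1, the classical scale for unit-normalized intensities.

The four-phase model needs two initial sign fields; `segment_image()` uses
two circle grids of different density (4×4 and 5×5). Note a structural
limitation verified in development: when the colored objects are small
minorities against a dominant background, the four-phase descent reliably
converges to a duplicated-background minimum from any geometric
initialization — comparable phase areas are required for clean four-phase
recovery, and the bundled `four_color_distinct` preset is built that way.

## The synthetic scenes

The generator rasterizes circles, rectangles and star polygons in flat
colors on a uniform background, hard-edged (no anti-aliasing) so the label
image is pixel-exact, and corrupts images with seeded Gaussian,
salt-and-pepper, or multiplicative speckle noise ($I + nI$, $n$ zero-mean
Gaussian of the stated variance) on the [0,1] scale, clipped.

Preset design encodes the regimes the models are meant to separate:

- `three_disks` uses moderate per-channel contrast (0.15 vs 0.85). This is
  deliberate: with fully saturated colors every model in the package is
  near-perfect at Gaussian variance 0.08 and the comparison degenerates.
  At contrast 0.7, per-pixel quadratic classification misassigns a pixel
  whenever noise crosses half the contrast (about one pixel in five at
  variance 0.08), while the ball-averaged local means cross it with
  negligible probability — the regime where localization pays off.
- `four_color_shapes` contains color pairs that differ in a single channel
  (red/yellow, yellow/white): the "similar intensities" setting in which
  channel-wise segmentation is claimed to outperform vectorial reduction.
- `equal_mean_pair` is the color-discrimination probe: a red and a green
  disk with identical per-pixel channel means, indistinguishable to any
  gray-scale reduction.
- `many_shapes` (mixed shapes, strong contrasts, dark background) is the
  severe-noise fixture.

What the generator does *not* emulate: intensity inhomogeneity, texture,
anti-aliased or blurred edges, correlated noise, and photographic content.
Passing tests therefore demonstrate the models' behavior under piecewise-
constant conditions with independent pixel noise — the setting the models
assume — and say nothing about textured or shading-dominated real images.

## Problem sizes and runtime

Tests and the acceptance script run the full pipelines at 96–128 px canvas
sizes with the default iteration caps; oracle-equality checks run at
7–32 px where exhaustive double loops are exact and fast. At 128×128 a
three-channel narrow-band segmentation takes a few seconds.

## Known limitations

- Piecewise-constant assumption: intensity inhomogeneity within a region is
  not modeled and defeats the global means.
- One level set per channel: at most $2^N$ regions; scenes with more
  distinguishable regions than sign sequences cannot be labeled uniquely.
- The interior/exterior orientation of each channel is
  initialization-dependent; only the partition, not the orientation, is
  meaningful.
- The RFP/RFN ratios follow their defining formulas with S1 = truth,
  S2 = prediction; note that this naming is reversed relative to common
  usage (the "false positive" ratio measures missed truth).
- Convergence is a mask-stability heuristic; heavy noise can keep a few
  boundary pixels flickering, in which case the run reports
  `converged = FALSE` with a perfectly usable labeling.
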