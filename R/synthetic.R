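#' Shape primitives for synthetic scenes
#'
#' Constructors for the geometric shapes a [scene_spec()] can contain.
#' Coordinates are pixel coordinates (row = y from 1 at the top, col = x);
#' rasterization is hard-edged (no anti-aliasing) so ground-truth labels are
#' pixel-exact.
#'
#' @param cy,cx center in pixels.
#' @param radius circle radius (pixels); a pixel belongs to the circle when
#'   its center is within `radius` (inclusive).
#' @param color length-3 RGB vector in `[0, 1]`.
#' @name shapes
NULL

#' @rdname shapes
#' @export
shape_circle <- function(cy, cx, radius, color) {
  stopifnot(radius > 0, length(color) == 3, all(color >= 0 & color <= 1))
  structure(list(kind = "circle", cy = cy, cx = cx, radius = radius,
                 color = as.numeric(color)), class = "scene_shape")
}

#' @rdname shapes
#' @param y0,x0,y1,x1 inclusive corner coordinates of the rectangle.
#' @export
shape_rect <- function(y0, x0, y1, x1, color) {
  stopifnot(y1 >= y0, x1 >= x0, length(color) == 3, all(color >= 0 & color <= 1))
  structure(list(kind = "rect", y0 = y0, x0 = x0, y1 = y1, x1 = x1,
                 color = as.numeric(color)), class = "scene_shape")
}

#' @rdname shapes
#' @param r_outer,r_inner outer/inner vertex radii of the star polygon.
#' @param n_points number of star points (default 5).
#' @param rotation rotation in radians (default 0: one point up).
#' @export
shape_star <- function(cy, cx, r_outer, r_inner = r_outer * 0.45,
                       n_points = 5L, rotation = 0, color = c(1, 0, 0)) {
  stopifnot(r_outer > 0, r_inner > 0, r_inner < r_outer, n_points >= 3,
            length(color) == 3, all(color >= 0 & color <= 1))
  structure(list(kind = "star", cy = cy, cx = cx, r_outer = r_outer,
                 r_inner = r_inner, n_points = as.integer(n_points),
                 rotation = rotation, color = as.numeric(color)),
            class = "scene_shape")
}

#' Scene specification
#'
#' A synthetic test scene: colored geometric shapes on a contrasting uniform
#' background.  Later shapes overdraw earlier ones; the ground-truth label
#' image is derived exactly from the specification.
#'
#' @param height,width canvas size in pixels.
#' @param background length-3 RGB background color in `[0, 1]`.
#' @param shapes list of shapes from [shape_circle()], [shape_rect()],
#'   [shape_star()].
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(height, width, background = c(1, 1, 1), shapes = list()) {
  stopifnot(height >= 8, width >= 8, length(background) == 3,
            all(background >= 0 & background <= 1))
  if (!all(vapply(shapes, inherits, logical(1), "scene_shape")))
    stop_invalid("`shapes` must be a list of scene shapes", "nbracm_invalid_spec")
  structure(list(height = as.integer(height), width = as.integer(width),
                 background = as.numeric(background), shapes = shapes),
            class = "scene_spec")
}

shape_mask <- function(shape, height, width) {
  Y <- matrix(seq_len(height), height, width)
  X <- matrix(seq_len(width), height, width, byrow = TRUE)
  switch(shape$kind,
    circle = (Y - shape$cy)^2 + (X - shape$cx)^2 <= shape$radius^2,
    rect = Y >= shape$y0 & Y <= shape$y1 & X >= shape$x0 & X <= shape$x1,
    star = {
      k <- 2L * shape$n_points
      ang <- shape$rotation + 2 * pi * (seq_len(k) - 1L) / k
      rad <- rep(c(shape$r_outer, shape$r_inner), shape$n_points)
      vx <- shape$cx + rad * sin(ang)
      vy <- shape$cy - rad * cos(ang)
      inside <- matrix(FALSE, height, width)
      j <- k
      for (i in seq_len(k)) {
        crosses <- (vy[i] > Y) != (vy[j] > Y)
        xi <- (vx[j] - vx[i]) * (Y - vy[i]) / (vy[j] - vy[i]) + vx[i]
        flip <- crosses & (X < xi)
        inside <- xor(inside, flip)
        j <- i
      }
      inside
    },
    stop_invalid(paste("unknown shape kind:", shape$kind), "nbracm_invalid_spec"))
}

#' Render a scene to an image and its ground-truth labels
#'
#' Deterministic hard-edged rasterization.  Label 0 is the background; shape
#' k (in list order) paints label k, with later shapes overdrawing earlier
#' ones.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (H x W x 3 array in `[0, 1]`), `labels`
#'   (integer matrix), and `spec`.
#' @export
render_scene <- function(spec) {
  if (!inherits(spec, "scene_spec"))
    stop_invalid("`spec` must be a scene_spec", "nbracm_invalid_spec")
  H <- spec$height; W <- spec$width
  img <- array(rep(spec$background, each = H * W), c(H, W, 3L))
  labels <- matrix(0L, H, W)
  for (k in seq_along(spec$shapes)) {
    sh <- spec$shapes[[k]]
    m <- shape_mask(sh, H, W)
    if (!any(m))
      stop_invalid(sprintf("shape %d lies outside the canvas", k), "nbracm_invalid_spec")
    labels[m] <- k
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[m] <- sh$color[ch]
      img[, , ch] <- pl
    }
  }
  list(image = img, labels = labels, spec = spec)
}

#' Add noise to an image
#'
#' The three noise models used in the evaluation, all seeded and applied on
#' the `[0, 1]` intensity scale:
#' \describe{
#'   \item{gaussian}{per pixel-channel i.i.d. additive N(0, `v`), clipped to
#'     `[0, 1]`.}
#'   \item{salt_pepper}{a fraction `d` of pixels set to 0 or 1 (equal
#'     probability); all channels of a corrupted pixel are set together.}
#'   \item{multiplicative}{speckle `I + n * I` with `n` ~ N(0, `v`) per
#'     pixel-channel, clipped.}
#' }
#'
#' @param image H x W x C array (or matrix) in `[0, 1]`.
#' @param kind one of `"gaussian"`, `"salt_pepper"`, `"multiplicative"`.
#' @param v variance of the Gaussian/multiplicative noise (on the `[0,1]`
#'   scale); ignored for salt-and-pepper.
#' @param d corruption density for salt-and-pepper, in `[0, 1]`.
#' @param seed integer seed for reproducibility (optional).
#' @return noisy array of the same shape.
#' @export
add_noise <- function(image, kind = c("gaussian", "salt_pepper", "multiplicative"),
                      v = 0.05, d = 0.05, seed = NULL) {
  kind <- match.arg(kind)
  if (v < 0 || d < 0 || d > 1)
    stop_invalid("need v >= 0 and 0 <= d <= 1", "nbracm_invalid_parameter")
  dm <- dim(image)
  is_mat <- is.matrix(image)
  arr <- if (is_mat) array(image, c(dm, 1L)) else image
  H <- dim(arr)[1L]; W <- dim(arr)[2L]; C <- dim(arr)[3L]
  out <- with_seed(seed, {
    switch(kind,
      gaussian = {
        if (v == 0) arr
        else pmin(pmax(arr + array(stats::rnorm(H * W * C, 0, sqrt(v)),
                                   dim(arr)), 0), 1)
      },
      multiplicative = {
        if (v == 0) arr
        else pmin(pmax(arr * (1 + array(stats::rnorm(H * W * C, 0, sqrt(v)),
                                        dim(arr))), 0), 1)
      },
      salt_pepper = {
        if (d == 0) arr
        else {
          hit <- matrix(stats::runif(H * W) < d, H, W)
          val <- matrix(stats::runif(H * W) < 0.5, H, W)  # TRUE = salt
          res <- arr
          for (ch in seq_len(C)) {
            pl <- res[, , ch]
            pl[hit] <- as.numeric(val[hit])
            res[, , ch] <- pl
          }
          res
        }
      })
  })
  if (is_mat) matrix(out, H, W) else out
}

#' Per-channel ground-truth foreground of a scene
#'
#' A channel's foreground is the set of pixels whose scene color has that
#' component present (value > 0.5), i.e. the region a channel-wise contour
#' should enclose.
#'
#' @param render output of [render_scene()].
#' @param channel channel index (1 = R, 2 = G, 3 = B).
#' @return logical matrix.
#' @export
channel_truth <- function(render, channel) {
  render$image[, , channel] > 0.5
}

#' Ground-truth sign-sequence labels of a scene
#'
#' The region labeling a perfect channel-by-channel segmentation should
#' produce under the [msc_combine()] convention: channel i's sign is 0 where
#' component i is present (interior) and 1 elsewhere, encoded as
#' `sum((1 - present_i) * 2^(N - i))`.
#'
#' @inheritParams channel_truth
#' @param n_channels number of channels (default 3).
#' @return integer matrix of labels in `[0, 2^N)`.
#' @export
truth_sign_labels <- function(render, n_channels = 3L) {
  H <- dim(render$image)[1L]; W <- dim(render$image)[2L]
  labels <- matrix(0L, H, W)
  for (i in seq_len(n_channels)) {
    s <- 1L - (render$image[, , i] > 0.5)
    labels <- labels + s * 2L^(n_channels - i)
  }
  labels
}

#' Bundled scene presets
#'
#' Small parametric scenes emulating the structural features of the test
#' images used in the evaluation (counts, contrasts, shape variety), named
#' by content:
#' \describe{
#'   \item{three_disks}{three disks (yellow, blue, red) on a light
#'     background, at the moderate contrast (0.15 vs 0.85 per channel)
#'     typical of the synthetic benchmarks this emulates.}
#'   \item{four_color_shapes}{five sizable shapes in three colors on white
#'     (four colors total), including close color pairs that differ in a
#'     single channel (red/yellow, yellow/white) -- the regime where
#'     channel-wise local statistics pay off.}
#'   \item{four_color_distinct}{same geometry with mutually well-separated
#'     colors (red, green, blue on white).}
#'   \item{many_shapes}{circle, rectangle and star in distinct colors on a
#'     dark background, for severe-noise runs.}
#'   \item{radius_study}{two high-contrast shapes on white, for the
#'     localization-radius sweep.}
#'   \item{equal_mean_pair}{a red and a green disk on white: equal per-pixel
#'     channel mean, different colors (color-discrimination probe).}
#' }
#'
#' @param name preset name.
#' @param size canvas side in pixels (square canvas; default 128).
#' @return a [scene_spec()].
#' @export
scene_preset <- function(name = c("three_disks", "four_color_shapes",
                                  "four_color_distinct", "many_shapes",
                                  "radius_study", "equal_mean_pair"),
                         size = 128L) {
  name <- match.arg(name)
  s <- size / 128
  switch(name,
    three_disks = scene_spec(size, size, background = c(0.85, 0.85, 0.85), shapes = list(
      shape_circle(36 * s, 64 * s, 20 * s, c(0.8, 0.8, 0.15)),
      shape_circle(88 * s, 36 * s, 20 * s, c(0.15, 0.15, 0.8)),
      shape_circle(88 * s, 92 * s, 20 * s, c(0.8, 0.15, 0.15)))),
    four_color_shapes = scene_spec(size, size, background = c(1, 1, 1), shapes = list(
      shape_rect(8 * s, 8 * s, 60 * s, 60 * s, c(1, 0, 0)),
      shape_circle(34 * s, 96 * s, 26 * s, c(1, 1, 0)),
      shape_rect(68 * s, 8 * s, 120 * s, 60 * s, c(0, 1, 0)),
      shape_star(96 * s, 96 * s, 28 * s, 13 * s, color = c(1, 1, 0)),
      shape_circle(96 * s, 64 * s, 12 * s, c(1, 0, 0)))),
    four_color_distinct = scene_spec(size, size, background = c(1, 1, 1), shapes = list(
      shape_rect(8 * s, 8 * s, 60 * s, 60 * s, c(1, 0, 0)),
      shape_circle(34 * s, 96 * s, 26 * s, c(0, 1, 0)),
      shape_rect(68 * s, 8 * s, 120 * s, 60 * s, c(0, 0, 1)),
      shape_star(96 * s, 96 * s, 28 * s, 13 * s, color = c(1, 0, 0)),
      shape_circle(96 * s, 64 * s, 12 * s, c(0, 1, 0)))),
    many_shapes = scene_spec(size, size, background = c(0, 0, 0.1), shapes = list(
      shape_circle(36 * s, 36 * s, 20 * s, c(1, 1, 0)),
      shape_rect(70 * s, 16 * s, 110 * s, 56 * s, c(0, 1, 1)),
      shape_star(40 * s, 94 * s, 24 * s, 11 * s, color = c(1, 0, 1)),
      shape_circle(94 * s, 92 * s, 20 * s, c(1, 1, 1)))),
    radius_study = scene_spec(size, size, background = c(1, 1, 1), shapes = list(
      shape_circle(64 * s, 40 * s, 24 * s, c(0, 0, 1)),
      shape_rect(32 * s, 80 * s, 96 * s, 112 * s, c(1, 0, 0)))),
    equal_mean_pair = scene_spec(size, size, background = c(1, 1, 1), shapes = list(
      shape_circle(40 * s, 64 * s, 20 * s, c(1, 0, 0)),
      shape_circle(92 * s, 64 * s, 20 * s, c(0, 1, 0)))))
}
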