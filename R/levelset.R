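#' Smoothed Heaviside of a level-set value
#'
#' Regularized step function used to weight interior/exterior integrals.
#' With the interior-negative convention (`phi < 0` inside the contour) the
#' function is 1 for `phi < -epsilon`, 0 for `phi > epsilon`, and follows the
#' smooth, monotone non-increasing transition
#' \deqn{H(\phi) = \tfrac12\left(1 - \phi/\varepsilon -
#'   \sin(\pi\phi/\varepsilon)/\pi\right)}
#' on `|phi| <= epsilon`, so that `H` is continuous and `H = 1` on the interior.
#'
#' @param phi numeric vector/matrix of level-set values.
#' @param epsilon positive regularization width (default 1.5 pixels).
#' @return values in `[0, 1]`, same shape as `phi`.
#' @seealso [dirac()]
#' @export
heaviside <- function(phi, epsilon = 1.5) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop_invalid("`epsilon` must be a single positive number", "nbracm_invalid_parameter")
  out <- 0.5 * (1 - phi / epsilon - sin(pi * phi / epsilon) / pi)
  out[phi < -epsilon] <- 1
  out[phi > epsilon] <- 0
  pmin(pmax(out, 0), 1)   # clip rounding spill at the branch joins
}

#' Smoothed Dirac delta of a level-set value
#'
#' Cosine bump supported on `|phi| <= epsilon`:
#' \deqn{\delta(\phi) = \frac{1}{2\varepsilon}(1 + \cos(\pi\phi/\varepsilon))}
#' and 0 outside, so that `dirac` equals `|dH/dphi|` of [heaviside()] and
#' integrates to 1.  It selects the neighborhood of the zero level set.
#'
#' @inheritParams heaviside
#' @return non-negative values, same shape as `phi`.
#' @export
dirac <- function(phi, epsilon = 1.5) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop_invalid("`epsilon` must be a single positive number", "nbracm_invalid_parameter")
  out <- (1 + cos(pi * phi / epsilon)) / (2 * epsilon)
  out[abs(phi) > epsilon] <- 0
  out
}

#' Binary level-set initialization
#'
#' Builds the two-valued initial level-set field: -1 on the interior seed
#' region, +1 elsewhere.  [reinitialize()] turns it into a signed-distance
#' field before evolution.
#'
#' @param interior_mask logical matrix; `TRUE` marks the initial interior.
#' @return numeric matrix taking only the values -1 and +1.
#' @export
init_binary <- function(interior_mask) {
  if (!is.matrix(interior_mask) || !is.logical(interior_mask))
    stop_invalid("`interior_mask` must be a logical matrix", "nbracm_invalid_input")
  if (all(interior_mask) || !any(interior_mask))
    stop_invalid("initial interior must be a nonempty strict subset of the grid",
                 "nbracm_degenerate_init")
  phi <- matrix(1, nrow(interior_mask), ncol(interior_mask))
  phi[interior_mask] <- -1
  phi
}

#' Reinitialize a level-set field to a signed distance function
#'
#' Replaces `phi` with the signed Euclidean distance to its zero crossing,
#' preserving the sign pattern exactly.  Distances are computed with a
#' Euclidean distance transform and corrected to sub-pixel accuracy at
#' interface-adjacent pixels by linear interpolation of the input values, so
#' the result is within 0.5 px of the true distance to the interface.
#'
#' @param phi numeric matrix that changes sign somewhere.
#' @return numeric matrix: the signed-distance field (interior negative).
#' @export
reinitialize <- function(phi) {
  assert_matrix(phi)
  neg <- phi < 0
  if (all(neg) || !any(neg))
    stop_invalid("field has no interface: `phi` does not change sign",
                 "nbracm_no_interface")
  # pixel-grid signed EDT; the interface lies between pixels, hence the -0.5
  d_to_neg <- EBImage::distmap(matrix(as.numeric(!neg), nrow(phi)))
  d_to_pos <- EBImage::distmap(matrix(as.numeric(neg), nrow(phi)))
  sdf <- ifelse(neg, -(pmax(d_to_pos - 0.5, 0)), pmax(d_to_neg - 0.5, 0))
  sdf <- matrix(as.numeric(sdf), nrow(phi))
  # sub-pixel correction where a 4-neighbor has the opposite sign:
  # the interface crosses the edge at |phi_p| / (|phi_p| + |phi_q|)
  a <- abs(phi)
  best <- matrix(Inf, nrow(phi), ncol(phi))
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb_phi <- shift_rep(phi, d[1L], d[2L])
    opp <- (phi < 0) != (nb_phi < 0)
    frac <- a / (a + abs(nb_phi))
    best[opp] <- pmin(best[opp], frac[opp])
  }
  adj <- is.finite(best)
  sdf[adj] <- ifelse(neg[adj], -best[adj], best[adj])
  # polish |grad phi| toward 1 with a few Godunov upwind relaxation steps of
  # the reinitialization equation, keeping the interface-adjacent values (and
  # hence the sub-pixel interface location and the sign pattern) frozen
  s_sign <- ifelse(neg, -1, 1)
  # also freeze the distance ridge (skeleton): at characteristic collisions
  # the one-sided slopes both count and the scheme would erode the cone tip
  m <- s_sign * sdf
  ridge <- m >= pmax(shift_rep(m, 0L, -1L), shift_rep(m, 0L, 1L),
                     shift_rep(m, -1L, 0L), shift_rep(m, 1L, 0L))
  # only the near-interface zone needs unit gradients (band evolution);
  # farther out the EDT values are already within half a pixel
  frozen <- adj | ridge | (m > 6)
  for (k in 1:8) {
    a <- sdf - shift_rep(sdf, 0L, -1L)   # backward x
    b <- shift_rep(sdf, 0L, 1L) - sdf    # forward x
    cc <- sdf - shift_rep(sdf, -1L, 0L)  # backward y
    d <- shift_rep(sdf, 1L, 0L) - sdf    # forward y
    gpos <- sqrt(pmax(pmax(a, 0)^2, pmin(b, 0)^2) +
                 pmax(pmax(cc, 0)^2, pmin(d, 0)^2))
    gneg <- sqrt(pmax(pmin(a, 0)^2, pmax(b, 0)^2) +
                 pmax(pmin(cc, 0)^2, pmax(d, 0)^2))
    G <- ifelse(neg, gneg, gpos)
    upd <- sdf - 0.5 * s_sign * (G - 1)
    upd[frozen] <- sdf[frozen]
    # never let the relaxation flip a sign: non-adjacent pixels are at least
    # half a pixel from the interface
    sdf <- ifelse(neg, pmin(upd, -0.1), pmax(upd, 0.1))
  }
  sdf
}

#' Mean curvature of a level-set field
#'
#' Central finite differences with replicate (Neumann) boundaries:
#' \deqn{\kappa = \frac{\phi_{xx}\phi_y^2 - 2\phi_x\phi_y\phi_{xy} +
#'   \phi_{yy}\phi_x^2}{(\phi_x^2 + \phi_y^2 + \eta)^{3/2}}}
#' with a small guard `eta = 1e-8` so flat regions return 0.  For a
#' signed-distance field of a disk of radius R the contour value is 1/R.
#'
#' @param phi numeric matrix, at least 3x3.
#' @return numeric matrix of curvature values.
#' @export
curvature <- function(phi) {
  assert_matrix(phi)
  if (nrow(phi) < 3L || ncol(phi) < 3L)
    stop_invalid("`phi` must be at least 3x3", "nbracm_invalid_input")
  eta <- 1e-8
  l <- shift_rep(phi, 0L, -1L); r <- shift_rep(phi, 0L, 1L)
  u <- shift_rep(phi, -1L, 0L); d <- shift_rep(phi, 1L, 0L)
  px  <- (r - l) / 2
  py  <- (d - u) / 2
  pxx <- r - 2 * phi + l
  pyy <- d - 2 * phi + u
  pxy <- (shift_rep(phi, 1L, 1L) + shift_rep(phi, -1L, -1L) -
          shift_rep(phi, 1L, -1L) - shift_rep(phi, -1L, 1L)) / 4
  (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) / (px^2 + py^2 + eta)^1.5
}

#' Narrow band of a level-set field
#'
#' The set of pixels within distance `w` of the zero level set,
#' `{x : |phi(x)| <= w}`.  The half-width must exceed twice the unit space
#' step so the band holds at least one pixel per side of the interface.
#'
#' @param phi numeric matrix (signed-distance field).
#' @param w band half-width in pixels, strictly greater than 2.
#' @return logical matrix marking band pixels.
#' @export
narrow_band <- function(phi, w) {
  assert_matrix(phi)
  if (!is.numeric(w) || length(w) != 1L || w <= 2)
    stop_invalid("band half-width `w` must exceed 2 (twice the space step)",
                 "nbracm_invalid_width")
  abs(phi) <= w
}

#' Gaussian smoothing of a signed-distance field
#'
#' Separable Gaussian filter with replicate boundaries, applied after each
#' evolution step to regularize the level-set field.  `sigma = 0` is the
#' identity.
#'
#' @param phi numeric matrix.
#' @param sigma Gaussian standard deviation in pixels, `>= 0`.
#' @return smoothed numeric matrix.
#' @export
smooth_sdf <- function(phi, sigma) {
  assert_matrix(phi)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop_invalid("`sigma` must be a single non-negative number", "nbracm_invalid_parameter")
  if (sigma == 0) return(phi)
  R <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-R, R))^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(phi), ncol(phi))
  for (i in seq_along(k)) out <- out + k[i] * shift_rep(phi, 0L, i - R - 1L)
  out2 <- matrix(0, nrow(phi), ncol(phi))
  for (i in seq_along(k)) out2 <- out2 + k[i] * shift_rep(out, i - R - 1L, 0L)
  out2
}

#' Signed-distance field of a disk
#'
#' Analytic SDF `sqrt((y-cy)^2 + (x-cx)^2) - radius` on a pixel grid
#' (interior negative), a convenient exact fixture and initialization.
#'
#' @param dim `c(height, width)` of the grid.
#' @param center `c(y, x)` disk center in pixel coordinates.
#' @param radius disk radius in pixels.
#' @return numeric matrix.
#' @export
sdf_disk <- function(dim, center, radius) {
  Y <- matrix(seq_len(dim[1L]), dim[1L], dim[2L])
  X <- matrix(seq_len(dim[2L]), dim[1L], dim[2L], byrow = TRUE)
  sqrt((Y - center[1L])^2 + (X - center[2L])^2) - radius
}
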