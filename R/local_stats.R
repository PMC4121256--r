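#' Ball mask of integer offsets
#'
#' The set of integer displacements `(dy, dx)` with Euclidean norm strictly
#' less than `r`, used to gather local statistics around each pixel.  The
#' origin is always included and the set is symmetric under negation.
#'
#' @param r ball radius in pixels, `> 0`.  `Inf` marks a ball covering the
#'   whole image (local statistics degenerate to the global ones).
#' @return an object of class `ball_mask` with fields `r` and `offsets`
#'   (two-column integer matrix of `(dy, dx)` pairs).
#' @export
ball_mask <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0)
    stop_invalid("ball radius `r` must be a single positive number", "nbracm_invalid_parameter")
  if (is.infinite(r)) {
    off <- matrix(integer(), 0L, 2L)
  } else {
    R <- ceiling(r) - 1L
    g <- expand.grid(dy = -R:R, dx = -R:R)
    keep <- g$dy^2 + g$dx^2 < r^2
    off <- cbind(as.integer(g$dy[keep]), as.integer(g$dx[keep]))
  }
  structure(list(r = r, offsets = off), class = "ball_mask")
}

#' @export
print.ball_mask <- function(x, ...) {
  cat(sprintf("<ball_mask> r = %g, %d offsets\n", x$r,
              if (is.infinite(x$r)) Inf else nrow(x$offsets)))
  invisible(x)
}

#' Global interior/exterior intensity means
#'
#' Heaviside-weighted means of one channel over the whole image:
#' `u = sum(H * I) / sum(H)` (interior) and
#' `v = sum((1 - H) * I) / sum(1 - H)` (exterior).
#'
#' @param channel numeric matrix of intensities in `[0, 1]`.
#' @param H_field numeric matrix of Heaviside weights in `[0, 1]`
#'   (1 = interior), same shape.
#' @return list with components `u` and `v`.
#' @export
global_means <- function(channel, H_field) {
  assert_matrix(channel); assert_matrix(H_field)
  sH <- sum(H_field); sHc <- sum(1 - H_field)
  if (sH <= 0 || sHc <= 0)
    stop_invalid("one phase is empty: cannot form interior/exterior means",
                 "nbracm_empty_phase")
  list(u = sum(H_field * channel) / sH,
       v = sum((1 - H_field) * channel) / sHc)
}

#' Windowed local interior/exterior means
#'
#' For every pixel, the Heaviside-weighted mean intensity inside and outside
#' the contour restricted to the ball window centered there (windows are
#' clipped at the image border).  Where a phase has no Heaviside mass in the
#' window the local mean is undefined and returned as `NA`; such pixels
#' contribute zero force.  With a ball covering the whole image the local
#' means equal the global ones everywhere.
#'
#' @inheritParams global_means
#' @param mask a [ball_mask()].
#' @param at optional logical matrix restricting which pixels are reported
#'   (others set to `NA`); statistics at reported pixels are unaffected.
#' @return an object of class `local_stats` with per-pixel matrices `u_local`
#'   and `v_local`, scalars `u` and `v` (global means), and `mask`.
#' @export
local_means <- function(channel, H_field, mask, at = NULL) {
  assert_matrix(channel); assert_matrix(H_field)
  if (!inherits(mask, "ball_mask"))
    stop_invalid("`mask` must be a ball_mask", "nbracm_invalid_parameter")
  g <- global_means(channel, H_field)
  if (is.infinite(mask$r)) {
    u_loc <- matrix(g$u, nrow(channel), ncol(channel))
    v_loc <- matrix(g$v, nrow(channel), ncol(channel))
  } else {
    Hc <- 1 - H_field
    num_u <- conv_offsets(H_field * channel, mask$offsets)
    den_u <- conv_offsets(H_field, mask$offsets)
    num_v <- conv_offsets(Hc * channel, mask$offsets)
    den_v <- conv_offsets(Hc, mask$offsets)
    tol <- 1e-12
    u_loc <- ifelse(den_u > tol, num_u / den_u, NA_real_)
    v_loc <- ifelse(den_v > tol, num_v / den_v, NA_real_)
  }
  if (!is.null(at)) {
    u_loc[!at] <- NA_real_
    v_loc[!at] <- NA_real_
  }
  structure(list(u_local = u_loc, v_local = v_loc, u = g$u, v = g$v,
                 mask = mask), class = "local_stats")
}

#' Localized region force field
#'
#' The force driving the narrow-band evolution,
#' \deqn{F(x) = (u - u_x)^2 - (v - v_x)^2,}
#' the difference between the squared deviations of the windowed local means
#' from the global interior/exterior means.  Pixels whose local mean is
#' undefined (one phase absent from the window) get force 0.
#'
#' @param stats a `local_stats` object from [local_means()].
#' @return numeric matrix of force values.
#' @export
local_force <- function(stats) {
  if (!inherits(stats, "local_stats"))
    stop_invalid("`stats` must come from local_means()", "nbracm_invalid_parameter")
  f <- (stats$u - stats$u_local)^2 - (stats$v - stats$v_local)^2
  f[is.na(f)] <- 0
  f
}
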