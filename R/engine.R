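#' Evolution configuration
#'
#' Parameters of the narrow-band localized active-contour evolution.
#'
#' @param epsilon Heaviside/Dirac regularization width (pixels); default 1.5.
#' @param r ball radius for local statistics (pixels); default 2.
#' @param nu curvature (contour length) weight on `[0,1]`-scaled intensities;
#'   default 0.2.
#' @param dt fixed time step, or `NULL` (default) for an adaptive CFL-style
#'   step `cfl / max|L|` per iteration.
#' @param cfl maximal per-pixel increment when `dt` is adaptive; default 0.45.
#' @param band_halfwidth narrow-band half-width `w > 2` (pixels); default 3.
#' @param reinit_every reinitialize the signed-distance field every this many
#'   iterations; default 5.
#' @param smooth_sigma Gaussian sigma for per-iteration SDF smoothing;
#'   default 0.5.
#' @param max_iter iteration cap; default 200.
#' @param convergence_patience iterations the zero-crossing pixel set must
#'   stay unchanged to declare convergence; default 10.
#' @param track_energy record the localized energy every iteration.
#' @param seed optional integer seed recorded with results.
#' @param verbose 0 = silent, 1 = per-iteration log line.
#' @return an `nb_config` list.
#' @export
evolution_config <- function(epsilon = 1.5, r = 2, nu = 0.2, dt = NULL,
                             cfl = 0.45, band_halfwidth = 3, reinit_every = 5L,
                             smooth_sigma = 0.5, max_iter = 200L,
                             convergence_patience = 10L, track_energy = TRUE,
                             seed = NULL, verbose = 0L) {
  if (epsilon <= 0) stop_invalid("`epsilon` must be positive", "nbracm_invalid_parameter")
  if (r <= 0) stop_invalid("`r` must be positive", "nbracm_invalid_parameter")
  if (nu < 0) stop_invalid("`nu` must be non-negative", "nbracm_invalid_parameter")
  if (!is.null(dt) && dt <= 0) stop_invalid("`dt` must be positive", "nbracm_invalid_parameter")
  if (band_halfwidth <= 2)
    stop_invalid("`band_halfwidth` must exceed 2", "nbracm_invalid_width")
  if (smooth_sigma < 0) stop_invalid("`smooth_sigma` must be >= 0", "nbracm_invalid_parameter")
  if (max_iter < 1L) stop_invalid("`max_iter` must be >= 1", "nbracm_invalid_parameter")
  structure(list(epsilon = epsilon, r = r, nu = nu, dt = dt, cfl = cfl,
                 band_halfwidth = band_halfwidth,
                 reinit_every = as.integer(reinit_every),
                 smooth_sigma = smooth_sigma, max_iter = as.integer(max_iter),
                 convergence_patience = as.integer(convergence_patience),
                 track_energy = isTRUE(track_energy), seed = seed,
                 verbose = as.integer(verbose)),
            class = "nb_config")
}

# Evolution operator L of the discrete update phi <- phi + dt * L, evaluated
# everywhere:
#   L(x) = delta(phi(x)) * F(x) * sum_{y in ball(x)} delta(phi(y))
#        + nu * delta(phi(x)) * kappa(x)
# with F(x) = (u - u_x)^2 - (v - v_x)^2 from the windowed local means.
evolution_operator <- function(phi, channel, cfg) {
  dlt <- dirac(phi, cfg$epsilon)
  H <- heaviside(phi, cfg$epsilon)
  st <- local_means(channel, H, ball_mask(cfg$r))
  Fx <- local_force(st)
  S <- if (is.infinite(cfg$r)) {
    matrix(sum(dlt), nrow(phi), ncol(phi))
  } else {
    conv_offsets(dlt, ball_mask(cfg$r)$offsets)
  }
  L <- dlt * Fx * S
  if (cfg$nu > 0) L <- L + cfg$nu * dlt * curvature(phi)
  L
}

#' One narrow-band evolution step
#'
#' Applies a single forward-Euler update of the localized region flow at the
#' narrow-band pixels; pixels outside the band are unchanged.  The update is
#' identical to the full-domain evolution restricted to the band.
#'
#' @param phi numeric matrix: the current signed-distance field.
#' @param channel numeric matrix of intensities in `[0, 1]`.
#' @param cfg an [evolution_config()].
#' @return the updated field, with attribute `"dt"` giving the step used.
#' @export
evolve_step <- function(phi, channel, cfg = evolution_config()) {
  assert_matrix(phi); assert_matrix(channel)
  band <- narrow_band(phi, cfg$band_halfwidth)
  if (!any(band) || all(phi < 0) || !any(phi < 0))
    stop_invalid("contour vanished: narrow band is empty or field is single-signed",
                 "nbracm_contour_vanished")
  L <- evolution_operator(phi, channel, cfg)
  st <- euler_increment(L[band], cfg$dt, cfg$cfl)
  out <- phi
  out[band] <- out[band] + st$incr
  attr(out, "dt") <- st$dt
  out
}

#' Localized region energy
#'
#' The band-restricted energy whose gradient flow drives the evolution: the
#' Dirac-weighted ball integral of the squared deviations of the local means
#' from the global means in each phase, plus `nu` times the contour length,
#' \deqn{E = \sum_x \delta(\phi(x)) \sum_y B(x,y)\left[(u-u_y)^2 H(\phi(y)) +
#'  (v-v_y)^2 (1-H(\phi(y)))\right] + \nu \sum_x \delta(\phi(x)) |\nabla\phi(x)|.}
#'
#' @inheritParams evolve_step
#' @return a single number.
#' @export
compute_energy <- function(phi, channel, cfg = evolution_config()) {
  assert_matrix(phi); assert_matrix(channel)
  dlt <- dirac(phi, cfg$epsilon)
  H <- heaviside(phi, cfg$epsilon)
  st <- local_means(channel, H, ball_mask(cfg$r))
  du <- (st$u - st$u_local)^2; du[is.na(du)] <- 0
  dv <- (st$v - st$v_local)^2; dv[is.na(dv)] <- 0
  G <- du * H + dv * (1 - H)
  inner <- if (is.infinite(cfg$r)) {
    matrix(sum(G), nrow(phi), ncol(phi))
  } else {
    conv_offsets(G, ball_mask(cfg$r)$offsets)
  }
  band <- narrow_band(phi, cfg$band_halfwidth)
  l <- shift_rep(phi, 0L, -1L); r <- shift_rep(phi, 0L, 1L)
  u <- shift_rep(phi, -1L, 0L); d <- shift_rep(phi, 1L, 0L)
  gradmag <- sqrt(((r - l) / 2)^2 + ((d - u) / 2)^2)
  sum((dlt * inner)[band]) + cfg$nu * sum((dlt * gradmag)[band])
}

#' Evolve one channel to convergence
#'
#' The full narrow-band iteration: reinitialize the binary initialization to
#' a signed-distance field, then repeat \{global and local means, force,
#' curvature, forward-Euler update on the band, SDF smoothing, periodic
#' reinitialization\} until the zero-crossing pixel set is unchanged for
#' `convergence_patience` consecutive iterations or `max_iter` is reached.
#'
#' @param channel numeric matrix of intensities in `[0, 1]`.
#' @param init numeric matrix from [init_binary()] (or any sign-changing
#'   field; it is reinitialized first).
#' @param cfg an [evolution_config()].
#' @return a `channel_result` list: `phi_final`, `interior_mask`
#'   (`phi_final < 0`), `iterations_run`, `converged`, `energy_trace`.
#' @export
run_channel <- function(channel, init, cfg = evolution_config()) {
  assert_matrix(channel)
  phi <- reinitialize(init)
  energy <- numeric(0)
  stable <- 0L
  prev_mask <- phi < 0
  converged <- FALSE
  iter <- 0L
  vanished <- FALSE
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    phi_new <- tryCatch(evolve_step(phi, channel, cfg),
                        nbracm_contour_vanished = function(e) NULL)
    if (is.null(phi_new)) { vanished <- TRUE; break }
    phi <- smooth_sdf(phi_new, cfg$smooth_sigma)
    if (iter %% cfg$reinit_every == 0L && any(phi < 0) && !all(phi < 0))
      phi <- reinitialize(phi)
    if (cfg$track_energy && any(phi < 0) && !all(phi < 0)) {
      # energy of the contour, evaluated on its canonical SDF so the trace
      # is invariant to smoothing-induced gradient flattening
      canon <- if (iter %% cfg$reinit_every == 0L) phi else reinitialize(phi)
      energy <- c(energy, compute_energy(canon, channel, cfg))
    }
    mask <- phi < 0
    if (identical(mask, prev_mask)) stable <- stable + 1L else stable <- 0L
    prev_mask <- mask
    if (cfg$verbose > 0L)
      message(sprintf("iter %3d | band %5d | zero-crossing interior %5d | stable %d",
                      iter, sum(abs(phi) <= cfg$band_halfwidth), sum(mask), stable))
    if (!any(mask) || all(mask)) { vanished <- TRUE; break }
    if (stable >= cfg$convergence_patience) { converged <- TRUE; break }
  }
  structure(list(phi_final = unname(phi),
                 interior_mask = phi < 0,
                 iterations_run = iter,
                 converged = converged,
                 vanished = vanished,
                 energy_trace = energy,
                 config = cfg),
            class = "channel_result")
}

#' @export
print.channel_result <- function(x, ...) {
  cat(sprintf("<channel_result> %d x %d | %d iterations | %s | interior %d px\n",
              nrow(x$phi_final), ncol(x$phi_final), x$iterations_run,
              if (x$converged) "converged" else if (x$vanished) "contour vanished"
              else "max_iter reached", sum(x$interior_mask)))
  invisible(x)
}
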