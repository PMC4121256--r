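# Baseline models: vectorial multiphase Chan-Vese (two level sets, four
# phases, channel-averaged residuals) and channel-wise Chan-Vese with
# sign-sequence combination (STP-CV).  Both run full-domain, matching their
# original formulations.

#' Baseline configuration
#'
#' Shared parameters for the two baseline models.
#'
#' @param mu curvature (length) weight.
#' @param nu_area area weight (STP-CV only); default 0.
#' @param lambda1,lambda2 positive data-term weights (STP-CV only).
#' @param epsilon Heaviside/Dirac regularization width.
#' @param dt fixed time step or `NULL` for adaptive CFL-style steps.
#' @param cfl maximal per-pixel increment for adaptive steps.
#' @param reinit_every reinitialization period (iterations).
#' @param max_iter iteration cap; full-domain contours may need to sweep the
#'   whole image, so the default is higher than the narrow-band model's.
#' @param convergence_patience stability window for convergence.
#' @param track_energy record the model energy each iteration (vectorial CV).
#' @return a `baseline_config` list.
#' @export
baseline_config <- function(mu = 0.1, nu_area = 0, lambda1 = 1, lambda2 = 1,
                            epsilon = 1.5, dt = NULL, cfl = 0.45,
                            reinit_every = 5L, max_iter = 500L,
                            convergence_patience = 10L, track_energy = TRUE) {
  if (lambda1 <= 0 || lambda2 <= 0)
    stop_invalid("`lambda1` and `lambda2` must be positive", "nbracm_invalid_parameter")
  if (epsilon <= 0) stop_invalid("`epsilon` must be positive", "nbracm_invalid_parameter")
  structure(list(mu = mu, nu_area = nu_area, lambda1 = lambda1,
                 lambda2 = lambda2, epsilon = epsilon, dt = dt, cfl = cfl,
                 reinit_every = as.integer(reinit_every),
                 max_iter = as.integer(max_iter),
                 convergence_patience = as.integer(convergence_patience),
                 track_energy = isTRUE(track_energy)),
            class = "baseline_config")
}

# Non-compact regularized Dirac (Cauchy kernel), the classical choice for
# the multiphase piecewise-constant updates: the force acts on all level
# lines, so contours can nucleate anywhere (including single noise-favored
# pixels) instead of being confined to the current interface.
dirac_global <- function(phi, epsilon) {
  epsilon / (pi * (epsilon^2 + phi^2))
}

# Four-phase weights from the two Heaviside fields.
vcv_phase_weights <- function(H1, H2) {
  list(w11 = H1 * H2, w12 = H1 * (1 - H2), w21 = (1 - H1) * H2,
       w22 = (1 - H1) * (1 - H2))
}

# Phase mean colors; empty phases keep their previous mean (prev is a 4 x C
# matrix or NULL).
vcv_phase_means <- function(image, H1, H2, prev = NULL) {
  w <- vcv_phase_weights(H1, H2)
  C <- dim(image)[3L]
  c_mat <- matrix(NA_real_, 4L, C,
                  dimnames = list(c("c11", "c12", "c21", "c22"), NULL))
  for (p in 1:4) {
    wp <- w[[p]]
    sw <- sum(wp)
    for (i in seq_len(C)) {
      c_mat[p, i] <- if (sw > 1e-9) sum(wp * image[, , i]) / sw
                     else if (!is.null(prev)) prev[p, i] else NA_real_
    }
  }
  c_mat
}

#' Vectorial multiphase Chan-Vese energy
#'
#' The four-phase piecewise-constant energy with channel-averaged quadratic
#' residuals: for phases cut out by the products of `H(phi1)` and `H(phi2)`,
#' \deqn{E = \sum_{p,q} \int \tfrac1C \sum_i (I^i - c^i_{pq})^2 w_{pq}
#'   + \int (|\nabla H(\phi_1)| + |\nabla H(\phi_2)|).}
#'
#' @param state list with `phi1`, `phi2` (numeric matrices) and `c`
#'   (4 x C matrix of phase means, rows c11, c12, c21, c22).
#' @param image H x W x C array in `[0, 1]`.
#' @param epsilon Heaviside regularization width.
#' @return a single number.
#' @export
vcv_energy <- function(state, image, epsilon = 1.5) {
  H1 <- heaviside(state$phi1, epsilon); H2 <- heaviside(state$phi2, epsilon)
  w <- vcv_phase_weights(H1, H2)
  C <- dim(image)[3L]
  E <- 0
  for (p in 1:4) {
    resid <- 0
    for (i in seq_len(C)) resid <- resid + (image[, , i] - state$c[p, i])^2
    E <- E + sum(resid / C * w[[p]])
  }
  for (phi in list(state$phi1, state$phi2)) {
    dlt <- dirac(phi, epsilon)
    l <- shift_rep(phi, 0L, -1L); r <- shift_rep(phi, 0L, 1L)
    u <- shift_rep(phi, -1L, 0L); d <- shift_rep(phi, 1L, 0L)
    E <- E + sum(dlt * sqrt(((r - l) / 2)^2 + ((d - u) / 2)^2))
  }
  E
}

#' Evolve the vectorial multiphase Chan-Vese model
#'
#' Alternating gradient descent on the two level sets: each field is driven
#' by the difference of the channel-averaged squared residuals of the two
#' phases it separates (weighted by the other field's Heaviside), plus a
#' curvature term; phase means are recomputed each iteration, with empty
#' phases carrying their previous mean.
#'
#' @param image H x W x C array in `[0, 1]`.
#' @param init1,init2 binary initializations from [init_binary()].
#' @param cfg a [baseline_config()].
#' @return a `vcv_result` list: `phi1`, `phi2`, `c`, `labeling`
#'   (a `region_labeling` over the sign pairs), `iterations_run`,
#'   `converged`, `energy_trace`.
#' @export
vcv_evolve <- function(image, init1, init2, cfg = baseline_config()) {
  phi1 <- reinitialize(init1)
  phi2 <- reinitialize(init2)
  C <- dim(image)[3L]
  c_mat <- NULL
  energy <- numeric(0)
  stable <- 0L; converged <- FALSE; iter <- 0L
  prev_masks <- list(phi1 < 0, phi2 < 0)
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    H1 <- heaviside(phi1, cfg$epsilon); H2 <- heaviside(phi2, cfg$epsilon)
    c_mat <- vcv_phase_means(image, H1, H2, prev = c_mat)
    e <- vector("list", 4L)
    for (p in 1:4) {
      resid <- 0
      for (i in seq_len(C)) resid <- resid + (image[, , i] - c_mat[p, i])^2
      e[[p]] <- resid / C
    }
    d1 <- dirac_global(phi1, cfg$epsilon); d2 <- dirac_global(phi2, cfg$epsilon)
    L1 <- d1 * (cfg$mu * curvature(phi1) +
                (e[[1L]] - e[[3L]]) * H2 + (e[[2L]] - e[[4L]]) * (1 - H2))
    L2 <- d2 * (cfg$mu * curvature(phi2) +
                (e[[1L]] - e[[2L]]) * H1 + (e[[3L]] - e[[4L]]) * (1 - H1))
    s1 <- euler_increment(L1, cfg$dt, cfg$cfl, scale_mask = abs(phi1) <= 3)
    s2 <- euler_increment(L2, cfg$dt, cfg$cfl, scale_mask = abs(phi2) <= 3)
    phi1 <- phi1 + s1$incr
    phi2 <- phi2 + s2$incr
    if (iter %% cfg$reinit_every == 0L) {
      if (any(phi1 < 0) && !all(phi1 < 0)) phi1 <- reinitialize(phi1)
      if (any(phi2 < 0) && !all(phi2 < 0)) phi2 <- reinitialize(phi2)
    }
    if (cfg$track_energy) {
      # evaluate on canonical SDFs so the trace reflects contour movement,
      # not drift of the level-set parameterization between reinitializations
      p1 <- if (any(phi1 < 0) && !all(phi1 < 0)) reinitialize(phi1) else phi1
      p2 <- if (any(phi2 < 0) && !all(phi2 < 0)) reinitialize(phi2) else phi2
      energy <- c(energy, vcv_energy(list(phi1 = p1, phi2 = p2, c = c_mat),
                                     image, cfg$epsilon))
    }
    masks <- list(phi1 < 0, phi2 < 0)
    if (identical(masks, prev_masks)) stable <- stable + 1L else stable <- 0L
    prev_masks <- masks
    if (stable >= cfg$convergence_patience) { converged <- TRUE; break }
  }
  structure(list(phi1 = phi1, phi2 = phi2, c = c_mat,
                 labeling = msc_combine(list(phi1, phi2)),
                 iterations_run = iter, converged = converged,
                 energy_trace = energy, config = cfg),
            class = "vcv_result")
}

#' One channel-wise Chan-Vese update (STP-CV)
#'
#' A single forward-Euler update of the per-channel Chan-Vese flow with the
#' interior-negative convention:
#' \deqn{\partial\phi/\partial t = \delta(\phi)\left[\mu\,\kappa - \nu +
#'   \lambda_1 (I - c_1)^2 - \lambda_2 (I - c_2)^2\right],}
#' where `c1`/`c2` are the Heaviside-weighted means inside/outside the curve,
#' recomputed from the current field.  A pixel fitting the interior mean
#' better is pushed toward the interior.  As in the vectorial multiphase
#' baseline, the update uses the non-compact regularized Dirac (the classical
#' implementation choice), so the force acts on all level lines; this is
#' also what lets isolated noise-favored pixels become spurious regions
#' ("noise pots") under heavy noise.
#'
#' @param phi numeric matrix (signed-distance field).
#' @param channel numeric matrix in `[0, 1]`.
#' @param cfg a [baseline_config()].
#' @param dt fixed step; `NULL` for the adaptive CFL step.
#' @return updated field with attribute `"dt"`.
#' @export
stpcv_step <- function(phi, channel, cfg = baseline_config(), dt = cfg$dt) {
  assert_matrix(phi); assert_matrix(channel)
  H <- heaviside(phi, cfg$epsilon)
  g <- global_means(channel, H)   # errors if a phase is empty
  L <- stpcv_operator(phi, channel, g$u, g$v, cfg)
  st <- euler_increment(L, dt, cfg$cfl, scale_mask = abs(phi) <= 3)
  out <- phi + st$incr
  attr(out, "dt") <- st$dt
  out
}

stpcv_operator <- function(phi, channel, c1, c2, cfg) {
  dlt <- dirac_global(phi, cfg$epsilon)
  dlt * (cfg$mu * curvature(phi) - cfg$nu_area +
         cfg$lambda1 * (channel - c1)^2 - cfg$lambda2 * (channel - c2)^2)
}

#' Run STP-CV on all channels and combine
#'
#' Evolves the per-channel Chan-Vese flow to convergence in each channel
#' independently (full domain), then combines the contours into region
#' labels with [msc_combine()].
#'
#' @param image H x W x C array (or a matrix for C = 1) in `[0, 1]`.
#' @param init binary initialization from [init_binary()], shared by all
#'   channels.
#' @param cfg a [baseline_config()].
#' @return a `stpcv_result` list: `labeling`, `phis` (per-channel fields),
#'   `iterations_run` (per channel), `converged` (per channel).
#' @export
stpcv_run <- function(image, init, cfg = baseline_config()) {
  arr <- if (is.matrix(image)) array(image, c(dim(image), 1L)) else image
  C <- dim(arr)[3L]
  phis <- vector("list", C)
  iters <- integer(C); conv <- logical(C)
  for (i in seq_len(C)) {
    phi <- reinitialize(init)
    stable <- 0L; iter <- 0L
    prev_mask <- phi < 0
    while (iter < cfg$max_iter) {
      iter <- iter + 1L
      ok <- tryCatch({ phi <- stpcv_step(phi, arr[, , i], cfg); TRUE },
                     nbracm_empty_phase = function(e) FALSE)
      if (!ok) break
      if (iter %% cfg$reinit_every == 0L && any(phi < 0) && !all(phi < 0))
        phi <- reinitialize(phi)
      mask <- phi < 0
      if (identical(mask, prev_mask)) stable <- stable + 1L else stable <- 0L
      prev_mask <- mask
      if (stable >= cfg$convergence_patience) { conv[i] <- TRUE; break }
    }
    phis[[i]] <- phi
    iters[i] <- iter
  }
  structure(list(labeling = msc_combine(phis), phis = phis,
                 iterations_run = iters, converged = conv, config = cfg),
            class = "stpcv_result")
}
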