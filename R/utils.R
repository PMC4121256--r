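# Internal helpers: matrix shifts, clipped-window convolution, seeded RNG.

# Shift a matrix by (dy, dx) with replicate (Neumann) boundary handling:
# out[y, x] = m[clamp(y + dy), clamp(x + dx)].
shift_rep <- function(m, dy = 0L, dx = 0L) {
  H <- nrow(m); W <- ncol(m)
  yi <- pmin(pmax(seq_len(H) + dy, 1L), H)
  xi <- pmin(pmax(seq_len(W) + dx, 1L), W)
  m[yi, xi, drop = FALSE]
}

# Sum of m over a set of integer offsets with zero fill outside the image,
# out[y, x] = sum_k m[y + off[k,1], x + off[k,2]].  Zero fill is equivalent to
# clipping the window at the image border.
conv_offsets_direct <- function(m, offsets) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (k in seq_len(nrow(offsets))) {
    dy <- offsets[k, 1L]; dx <- offsets[k, 2L]
    ys <- max(1L, 1L - dy):min(H, H - dy)
    xs <- max(1L, 1L - dx):min(W, W - dx)
    out[ys, xs] <- out[ys, xs] + m[ys + dy, xs + dx, drop = FALSE]
  }
  out
}

# FFT-based equivalent for large kernels.  The kernel is the 0/1 indicator of
# the offset set; zero padding reproduces the clipped-window semantics.
conv_offsets_fft <- function(m, offsets) {
  H <- nrow(m); W <- ncol(m)
  R <- max(abs(offsets))
  K <- 2L * R + 1L
  kern <- matrix(0, K, K)
  kern[cbind(offsets[, 1L] + R + 1L, offsets[, 2L] + R + 1L)] <- 1
  PH <- stats::nextn(H + K - 1L)
  PW <- stats::nextn(W + K - 1L)
  A <- matrix(0, PH, PW); A[seq_len(H), seq_len(W)] <- m
  B <- matrix(0, PH, PW); B[seq_len(K), seq_len(K)] <- kern
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (PH * PW)
  # centre of the 'full' convolution; correlation == convolution for the
  # negation-symmetric ball offsets
  full[R + seq_len(H), R + seq_len(W), drop = FALSE]
}

conv_offsets <- function(m, offsets) {
  if (nrow(offsets) <= 80L) {
    conv_offsets_direct(m, offsets)
  } else {
    conv_offsets_fft(m, offsets)
  }
}

# Run code with a temporary RNG state seeded by `seed` (NULL = leave RNG alone).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(msg, class) {
  stop(structure(class = c(class, "nbracm_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_invalid(sprintf("`%s` must be a numeric matrix", name), "nbracm_invalid_input")
  x
}

# Shared forward-Euler increment: fixed dt, or a robust CFL-style step that
# scales by the 0.9 quantile of |L| and clamps increments at cfl so residual
# oscillation at converged contour segments cannot throttle the rest.
euler_increment <- function(L, dt, cfl, scale_mask = NULL) {
  if (!is.null(dt)) return(list(incr = dt * L, dt = dt))
  a <- abs(L)
  # scale from the active pixels (optionally restricted to the contour
  # region, where the flow actually moves the interface)
  act <- if (is.null(scale_mask)) a[a > 1e-15] else a[scale_mask & a > 1e-15]
  sc <- if (length(act)) stats::quantile(act, 0.9, names = FALSE) else 0
  step <- if (sc > 1e-12) cfl / sc else 0
  list(incr = pmin(pmax(step * L, -cfl), cfl), dt = step)
}
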