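# Brute-force scalar-loop oracles, independent of the vectorized paths they
# check, plus small shared fixtures.

# Windowed local means by explicit double loop (clipped windows, strict
# Euclidean ball).
oracle_local_means <- function(channel, H, r) {
  HH <- nrow(channel); WW <- ncol(channel)
  u <- v <- matrix(NA_real_, HH, WW)
  for (y in seq_len(HH)) for (x in seq_len(WW)) {
    nu <- du <- nv <- dv <- 0
    for (yy in seq_len(HH)) for (xx in seq_len(WW)) {
      if ((yy - y)^2 + (xx - x)^2 < r^2) {
        nu <- nu + H[yy, xx] * channel[yy, xx]; du <- du + H[yy, xx]
        nv <- nv + (1 - H[yy, xx]) * channel[yy, xx]; dv <- dv + (1 - H[yy, xx])
      }
    }
    if (du > 1e-12) u[y, x] <- nu / du
    if (dv > 1e-12) v[y, x] <- nv / dv
  }
  list(u_local = u, v_local = v)
}

# Full-domain evolution operator evaluated pointwise from the definitions.
oracle_evolution_operator <- function(phi, channel, cfg) {
  HH <- nrow(phi); WW <- ncol(phi)
  H <- heaviside(phi, cfg$epsilon)
  dlt <- dirac(phi, cfg$epsilon)
  u <- sum(H * channel) / sum(H)
  v <- sum((1 - H) * channel) / sum(1 - H)
  kap <- curvature(phi)
  lm <- oracle_local_means(channel, H, cfg$r)
  L <- matrix(0, HH, WW)
  for (y in seq_len(HH)) for (x in seq_len(WW)) {
    S <- 0
    for (yy in seq_len(HH)) for (xx in seq_len(WW))
      if ((yy - y)^2 + (xx - x)^2 < cfg$r^2) S <- S + dlt[yy, xx]
    Fx <- if (!is.na(lm$u_local[y, x]) && !is.na(lm$v_local[y, x]))
      (u - lm$u_local[y, x])^2 - (v - lm$v_local[y, x])^2 else 0
    L[y, x] <- dlt[y, x] * Fx * S + cfg$nu * dlt[y, x] * kap[y, x]
  }
  L
}

# Band-restricted localized energy by explicit double loop.
oracle_energy <- function(phi, channel, cfg) {
  HH <- nrow(phi); WW <- ncol(phi)
  H <- heaviside(phi, cfg$epsilon)
  dlt <- dirac(phi, cfg$epsilon)
  u <- sum(H * channel) / sum(H)
  v <- sum((1 - H) * channel) / sum(1 - H)
  lm <- oracle_local_means(channel, H, cfg$r)
  G <- matrix(0, HH, WW)
  for (y in seq_len(HH)) for (x in seq_len(WW)) {
    du <- if (!is.na(lm$u_local[y, x])) (u - lm$u_local[y, x])^2 else 0
    dv <- if (!is.na(lm$v_local[y, x])) (v - lm$v_local[y, x])^2 else 0
    G[y, x] <- du * H[y, x] + dv * (1 - H[y, x])
  }
  E <- 0
  for (y in seq_len(HH)) for (x in seq_len(WW)) {
    if (abs(phi[y, x]) > cfg$band_halfwidth) next
    inner <- 0
    for (yy in seq_len(HH)) for (xx in seq_len(WW))
      if ((yy - y)^2 + (xx - x)^2 < cfg$r^2) inner <- inner + G[yy, xx]
    yl <- max(1, y - 1); yh <- min(HH, y + 1)
    xl <- max(1, x - 1); xh <- min(WW, x + 1)
    gx <- (phi[y, xh] - phi[y, xl]) / 2
    gy <- (phi[yh, x] - phi[yl, x]) / 2
    E <- E + dlt[y, x] * inner + cfg$nu * dlt[y, x] * sqrt(gx^2 + gy^2)
  }
  E
}

# Four-phase vectorial energy by explicit per-pixel summation.
oracle_vcv_energy <- function(state, image, epsilon) {
  HH <- dim(image)[1]; WW <- dim(image)[2]; C <- dim(image)[3]
  H1 <- heaviside(state$phi1, epsilon); H2 <- heaviside(state$phi2, epsilon)
  E <- 0
  for (y in seq_len(HH)) for (x in seq_len(WW)) {
    w <- c(H1[y, x] * H2[y, x], H1[y, x] * (1 - H2[y, x]),
           (1 - H1[y, x]) * H2[y, x], (1 - H1[y, x]) * (1 - H2[y, x]))
    for (p in 1:4) {
      resid <- 0
      for (i in seq_len(C)) resid <- resid + (image[y, x, i] - state$c[p, i])^2
      E <- E + resid / C * w[p]
    }
  }
  for (phi in list(state$phi1, state$phi2)) {
    dlt <- dirac(phi, epsilon)
    for (y in seq_len(HH)) for (x in seq_len(WW)) {
      yl <- max(1, y - 1); yh <- min(HH, y + 1)
      xl <- max(1, x - 1); xh <- min(WW, x + 1)
      gx <- (phi[y, xh] - phi[y, xl]) / 2
      gy <- (phi[yh, x] - phi[yl, x]) / 2
      E <- E + dlt[y, x] * sqrt(gx^2 + gy^2)
    }
  }
  E
}

# Random blob mask: union of a few random disks (seeded).
random_blob_mask <- function(dim, seed) {
  set.seed(seed)
  m <- matrix(FALSE, dim[1], dim[2])
  Y <- row(m); X <- col(m)
  for (k in 1:3) {
    cy <- runif(1, dim[1] * 0.25, dim[1] * 0.75)
    cx <- runif(1, dim[2] * 0.25, dim[2] * 0.75)
    r <- runif(1, dim[1] / 8, dim[1] / 4)
    m <- m | ((Y - cy)^2 + (X - cx)^2 <= r^2)
  }
  if (!any(m)) m[dim[1] %/% 2, dim[2] %/% 2] <- TRUE
  if (all(m)) m[1, 1] <- FALSE
  m
}

# Two-phase disk image fixture on [0,1].
disk_image <- function(dim = c(64, 64), center = dim / 2, radius = 12,
                       fg = 0.9, bg = 0.1) {
  img <- matrix(bg, dim[1], dim[2])
  img[sdf_disk(dim, center, radius) <= 0] <- fg
  img
}
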