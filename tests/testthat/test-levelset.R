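test_that("heaviside matches its closed form and is a continuous decreasing step", {
  expect_equal(heaviside(-3, 1.5), 1)
  expect_equal(heaviside(3, 1.5), 0)
  expect_equal(heaviside(0, 1.5), 0.5)
  # hand-evaluated transition: 0.5 * (1 - 0.5 - sin(pi/2)/pi)
  expect_equal(heaviside(0.75, 1.5), 0.09085, tolerance = 1e-4)
  grid <- seq(-3, 3, by = 1e-4)
  Hg <- heaviside(grid, 1.5)
  expect_true(all(Hg >= 0 & Hg <= 1))
  expect_true(all(diff(Hg) <= 1e-12))          # monotone non-increasing
  expect_lt(max(abs(diff(Hg))), 1e-3)          # continuity
  expect_error(heaviside(0, 0), class = "nbracm_invalid_parameter")
})

test_that("dirac is the cosine bump, equals |dH/dphi|, and integrates to 1", {
  expect_equal(dirac(3, 1.5), 0)
  expect_equal(dirac(0, 1.5), 2 / 3, tolerance = 1e-4)
  expect_equal(stats::integrate(dirac, -1.5, 1.5, epsilon = 1.5,
                                rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
  # numerical derivative of heaviside on the open transition interval
  h <- 1e-6
  phis <- seq(-1.4, 1.4, by = 0.05)
  num <- -(heaviside(phis + h, 1.5) - heaviside(phis - h, 1.5)) / (2 * h)
  expect_equal(num, dirac(phis, 1.5), tolerance = 1e-3)
  expect_error(dirac(0, -1), class = "nbracm_invalid_parameter")
})

test_that("binary initialization marks interiors with -1 and rejects degenerate masks", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  b <- init_binary(m)
  expect_equal(b[3, 3], -1)
  expect_equal(sum(b == 1), 24)
  two <- init_circle(c(32, 32), c(10, 10), 5) | init_circle(c(32, 32), c(24, 24), 5)
  expect_true(all(init_binary(two)[two] == -1))
  expect_error(init_binary(matrix(TRUE, 4, 4)), class = "nbracm_degenerate_init")
  expect_error(init_binary(matrix(FALSE, 4, 4)), class = "nbracm_degenerate_init")
})

test_that("reinitialization recovers signed distances and preserves signs", {
  phi <- sdf_disk(c(64, 64), c(32, 32), 10)
  expect_lte(max(abs(reinitialize(phi) - phi)), 0.5)  # SDF is a fixed point
  disk <- init_binary(sdf_disk(c(32, 32), c(16, 16), 8) <= 0)
  r <- reinitialize(disk)
  expect_equal(r[16, 16], -8, tolerance = 1)
  # gradient magnitude ~ 1 on >= 90% of band pixels
  gx <- (r[, c(2:32, 32)] - r[, c(1, 1:31)]) / 2
  gy <- (r[c(2:32, 32), ] - r[c(1, 1:31), ]) / 2
  band <- abs(r) <= 3
  ok <- abs(sqrt(gx^2 + gy^2) - 1) <= 0.1
  expect_gte(mean(ok[band]), 0.9)
  for (seed in 1:20) {
    m <- random_blob_mask(c(24, 24), seed)
    b <- init_binary(m)
    expect_identical(reinitialize(b) < 0, b < 0)
  }
  expect_error(reinitialize(matrix(1, 4, 4)), class = "nbracm_no_interface")
})

test_that("reinitialization is idempotent up to half a pixel", {
  for (seed in c(3, 9)) {
    phi <- init_binary(random_blob_mask(c(32, 32), seed))
    r1 <- reinitialize(phi)
    expect_lt(max(abs(reinitialize(r1) - r1)), 0.5)
  }
})

test_that("curvature matches analytic values and is antisymmetric", {
  plane <- matrix(seq_len(32), 32, 32, byrow = TRUE)
  expect_lt(max(abs(curvature(plane))), 1e-10)
  phi <- sdf_disk(c(64, 64), c(32, 32), 10)
  k <- curvature(phi)
  contour <- abs(phi) < 0.5
  expect_true(all(abs(k[contour] - 0.1) < 0.02))
  expect_lt(max(abs(curvature(-phi) + k)), 1e-10)
  # convex interior: curvature at contour pixels not below -0.05
  expect_gte(min(k[contour]), -0.05)
})

test_that("narrow band is exactly the |phi| <= w set and is nested in w", {
  phi <- sdf_disk(c(64, 64), c(32, 32), 10)
  nb <- narrow_band(phi, 3)
  d <- sqrt((row(phi) - 32)^2 + (col(phi) - 32)^2)
  expect_identical(nb, d >= 7 & d <= 13)
  expect_equal(sum(nb), sum(abs(phi) <= 3))   # exhaustive scan
  expect_true(all(narrow_band(phi, 2.5) <= narrow_band(phi, 4)))
  expect_error(narrow_band(phi, 1), class = "nbracm_invalid_width")
  expect_error(narrow_band(phi, 2), class = "nbracm_invalid_width")
})

test_that("SDF smoothing is identity at sigma 0, affine-preserving, and interface-stable", {
  phi <- sdf_disk(c(64, 64), c(32, 32), 10)
  expect_identical(smooth_sdf(phi, 0), phi)
  aff <- 2 + 0.3 * matrix(seq_len(32), 32, 32) + 0.1 * matrix(seq_len(32), 32, 32, byrow = TRUE)
  sm <- smooth_sdf(aff, 1)
  expect_equal(sm[5:28, 5:28], aff[5:28, 5:28], tolerance = 1e-8)
  s <- smooth_sdf(phi, 0.5)
  zc <- abs(s) < 0.5
  rad <- sqrt((row(s)[zc] - 32)^2 + (col(s)[zc] - 32)^2)
  expect_true(all(rad >= 9 & rad <= 11))
  expect_error(smooth_sdf(phi, -0.1), class = "nbracm_invalid_parameter")
})
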