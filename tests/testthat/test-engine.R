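test_that("the local force field follows (u-ux)^2 - (v-vx)^2", {
  st <- structure(list(u_local = matrix(0.6, 2, 2), v_local = matrix(0.3, 2, 2),
                       u = 0.8, v = 0.2, mask = ball_mask(2)),
                  class = "local_stats")
  expect_equal(local_force(st)[1, 1], 0.2^2 - 0.1^2, tolerance = 1e-12)
  st$u_local[] <- st$u; st$v_local[] <- st$v
  expect_true(all(local_force(st) == 0))
})

test_that("a narrow-band step equals the full-domain update at every band pixel", {
  cfg <- evolution_config(dt = 0.1, nu = 0.2, r = 2)
  for (seed in 1:10) {
    set.seed(seed)
    img <- matrix(runif(32 * 32), 32, 32)
    phi <- reinitialize(init_binary(random_blob_mask(c(32, 32), seed + 100)))
    stepped <- evolve_step(phi, img, cfg)
    L <- oracle_evolution_operator(phi, img, cfg)
    band <- abs(phi) <= cfg$band_halfwidth
    expected <- phi
    expected[band] <- expected[band] + cfg$dt * L[band]
    expect_lt(max(abs(stepped - expected)), 1e-12)
    expect_identical(stepped[!band], phi[!band])
  }
})

test_that("constant images and sharp phase-aligned edges are stationary", {
  cfg <- evolution_config(dt = 0.1, nu = 0)
  phi <- sdf_disk(c(32, 32), c(16, 16), 8)
  out <- evolve_step(phi, matrix(0.5, 32, 32), cfg)
  expect_lt(max(abs(out - phi)), 1e-12)
  # straight vertical edge between pixel columns; with a sub-pixel Dirac
  # width the interface carries no Dirac mass at pixel centers and the
  # exact solution stays put
  X <- matrix(seq_len(32), 32, 32, byrow = TRUE)
  phi_e <- X - 16.5
  img <- matrix(0.9, 32, 32); img[X > 16.5] <- 0.1
  cfg_e <- evolution_config(dt = 0.1, nu = 0, epsilon = 0.4)
  out_e <- evolve_step(phi_e, img, cfg_e)
  expect_lt(max(abs(out_e - phi_e)), 1e-10)
})

test_that("evolve_step signals a vanished contour", {
  cfg <- evolution_config()
  expect_error(evolve_step(matrix(5, 8, 8) + sdf_disk(c(8, 8), c(4, 4), 1),
                           matrix(0.5, 8, 8), cfg),
               class = "nbracm_contour_vanished")
})

test_that("the localized energy matches the brute-force double sum", {
  cfg <- evolution_config(nu = 0.3, r = 2)
  set.seed(17)
  img <- matrix(runif(256), 16, 16)
  phi <- reinitialize(init_binary(random_blob_mask(c(16, 16), 5)))
  expect_equal(compute_energy(phi, img, cfg), oracle_energy(phi, img, cfg),
               tolerance = 1e-9)
  # constant image, nu = 0: zero energy
  expect_equal(compute_energy(phi, matrix(0.5, 16, 16),
                              evolution_config(nu = 0)), 0, tolerance = 1e-12)
})

test_that("the energy length term recovers the circumference of a circle", {
  phi <- sdf_disk(c(64, 64), c(32, 32), 10)
  e <- compute_energy(phi, matrix(0.5, 64, 64), evolution_config(nu = 1))
  expect_equal(e, 2 * pi * 10, tolerance = 0.05 * 2 * pi * 10)
})

test_that("a noiseless disk is recovered from an offset initialization", {
  img <- disk_image()
  truth <- img > 0.5
  init <- init_binary(init_circle(c(64, 64), c(36, 36), 12))
  res <- run_channel(img, init, evolution_config(track_energy = FALSE))
  expect_gte(overlap(truth, res$interior_mask)$dice, 0.98)
  expect_identical(res$interior_mask, res$phi_final < 0)
  expect_lte(res$iterations_run, 200L)
})

test_that("an on-boundary initialization converges almost immediately", {
  img <- disk_image()
  cfg <- evolution_config(track_energy = FALSE)
  init <- init_binary(img > 0.5)
  res <- run_channel(img, init, cfg)
  expect_true(res$converged)
  expect_lte(res$iterations_run, cfg$convergence_patience + 5L)
  expect_gte(overlap(img > 0.5, res$interior_mask)$dice, 0.98)
})

test_that("a noisy disk (variance 0.05) is still recovered", {
  img <- add_noise(disk_image(), "gaussian", v = 0.05, seed = 0)
  init <- init_binary(init_circle(c(64, 64), c(36, 36), 12))
  res <- run_channel(img, init, evolution_config(track_energy = FALSE))
  expect_gte(overlap(disk_image() > 0.5, res$interior_mask)$dice, 0.95)
})

test_that("the contour energy trends downward along the noiseless evolution", {
  img <- disk_image()
  init <- init_binary(init_circle(c(64, 64), c(36, 36), 12))
  res <- run_channel(img, init, evolution_config(dt = 0.5, nu = 0.1))
  e <- res$energy_trace
  i0 <- res$config$reinit_every   # after the first reinitialization
  expect_gte(mean(diff(e[i0:length(e)]) <= 1e-9), 0.9)
})

test_that("whole-image windows make the model degenerate", {
  img <- add_noise(disk_image(c(32, 32), c(16, 16), 8), "gaussian", v = 0.02, seed = 1)
  phi <- sdf_disk(c(32, 32), c(16, 16), 8)
  st <- local_means(img, heaviside(phi, 1.5), ball_mask(Inf))
  expect_true(all(local_force(st) == 0))
  # evolution with nu = 0 and no SDF smoothing: zero-crossing set unchanged
  cfg <- evolution_config(r = Inf, nu = 0, smooth_sigma = 0, max_iter = 20,
                          track_energy = FALSE)
  res <- run_channel(img, init_binary(phi <= 0), cfg)
  expect_identical(res$interior_mask, reinitialize(init_binary(phi <= 0)) < 0)
})

test_that("evolution is bit-identical across repeated runs", {
  img <- add_noise(disk_image(), "gaussian", v = 0.05, seed = 9)
  init <- init_binary(init_circle(c(64, 64)))
  cfg <- evolution_config(max_iter = 40)
  a <- run_channel(img, init, cfg)
  b <- run_channel(img, init, cfg)
  expect_identical(a$phi_final, b$phi_final)
  expect_identical(a$energy_trace, b$energy_trace)
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(evolution_config(epsilon = 0), class = "nbracm_invalid_parameter")
  expect_error(evolution_config(band_halfwidth = 2), class = "nbracm_invalid_width")
  expect_error(evolution_config(dt = -1), class = "nbracm_invalid_parameter")
  expect_error(evolution_config(nu = -0.1), class = "nbracm_invalid_parameter")
})
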