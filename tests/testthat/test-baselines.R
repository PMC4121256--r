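test_that("the vectorial four-phase energy matches the brute-force oracle", {
  set.seed(6)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  state <- list(phi1 = reinitialize(init_binary(random_blob_mask(c(8, 8), 1))),
                phi2 = reinitialize(init_binary(random_blob_mask(c(8, 8), 2))),
                c = matrix(runif(12), 4, 3))
  expect_equal(vcv_energy(state, img, 1.5),
               oracle_vcv_energy(state, img, 1.5), tolerance = 1e-9)
})

test_that("the vectorial energy reduces to the length terms on exact fits", {
  X <- matrix(seq_len(16), 16, 16, byrow = TRUE)
  Y <- matrix(seq_len(16), 16, 16)
  phi1 <- ifelse(X > 8, 1, -1)
  phi2 <- ifelse(Y > 8, 1, -1)
  eps <- 0.5   # below min |phi|: Heavisides are exact indicators
  cols <- matrix(c(0.9, 0.1, 0.3, 0.7, 0.2, 0.8, 0.1, 0.6, 0.4, 0.5, 0.5, 0.9),
                 4, 3, byrow = TRUE)
  phase <- ifelse(phi1 < 0, ifelse(phi2 < 0, 1, 2), ifelse(phi2 < 0, 3, 4))
  img <- array(0, c(16, 16, 3))
  for (i in 1:3) img[, , i] <- matrix(cols[phase, i], 16, 16)
  st <- list(phi1 = phi1, phi2 = phi2, c = cols)
  length_terms <- local({
    s <- 0
    for (phi in list(phi1, phi2)) {
      dlt <- dirac(phi, eps)
      gx <- (phi[, c(2:16, 16)] - phi[, c(1, 1:15)]) / 2
      gy <- (phi[c(2:16, 16), ] - phi[c(1, 1:15), ]) / 2
      s <- s + sum(dlt * sqrt(gx^2 + gy^2))
    }
    s
  })
  expect_equal(vcv_energy(st, img, eps), length_terms, tolerance = 1e-9)
  # constant image with matching phase means: the same pure length energy
  st2 <- list(phi1 = phi1, phi2 = phi2, c = matrix(0.4, 4, 3))
  expect_equal(vcv_energy(st2, array(0.4, c(16, 16, 3)), eps), length_terms,
               tolerance = 1e-12)
})

test_that("four-phase descent recovers a noiseless four-color scene", {
  rd <- render_scene(scene_preset("four_color_distinct", 96))
  td <- truth_sign_labels(rd)
  res <- segment_image(rd$image, "vcv", cfg = baseline_config(track_energy = FALSE))
  rep_ <- per_label_overlap(td, res$labeling$labels)
  expect_gte(min(rep_$dice), 0.95)
})

test_that("the four-phase energy trends downward on the noiseless scene", {
  rd <- render_scene(scene_preset("four_color_distinct", 96))
  res <- segment_image(rd$image, "vcv", cfg = baseline_config(dt = 1, max_iter = 250))
  e <- res$channel_results$energy_trace
  rel_ok <- diff(e) <= 1e-3 * abs(e[-length(e)])
  expect_gte(mean(rel_ok), 0.9)
})

test_that("channel-wise CV steps carry the classical force structure", {
  phi <- sdf_disk(c(32, 32), c(16, 16), 8)
  img <- matrix(0.1, 32, 32); img[phi < 0] <- 0.9
  cfg <- baseline_config(mu = 0, lambda1 = 1, lambda2 = 1)
  H <- heaviside(phi, cfg$epsilon)
  g <- global_means(img, H)
  L <- nbracm:::stpcv_operator(phi, img, g$u, g$v, cfg)
  # at an interior-adjacent interface pixel (I = c1) the data force has
  # magnitude lambda2 * (c1 - c2)^2 * dirac(phi)
  px <- which(abs(phi) < 0.6 & phi < 0 & img == 0.9, arr.ind = TRUE)[1, ]
  d0 <- nbracm:::dirac_global(phi[px[1], px[2]], cfg$epsilon)
  # exact with the computed phase means
  expect_equal(L[px[1], px[2]],
               d0 * ((0.9 - g$u)^2 - (0.9 - g$v)^2), tolerance = 1e-12)
  # approximately -0.64 * dirac for the 0.9/0.1 two-phase image
  expect_equal(abs(L[px[1], px[2]]), 0.64 * d0, tolerance = 0.1)
  # constant image: zero data force everywhere
  Lc <- nbracm:::stpcv_operator(phi, matrix(0.5, 32, 32), 0.5, 0.5, cfg)
  expect_true(all(Lc == 0))
})

test_that("with only the length term the flow shrinks circles", {
  phi <- sdf_disk(c(48, 48), c(24, 24), 15)
  img <- matrix(0.5, 48, 48)
  cfg <- baseline_config(mu = 0.5, nu_area = 0, lambda1 = 1e-12, lambda2 = 1e-12,
                         dt = 1)
  areas <- numeric(0)
  for (k in 1:50) {
    phi <- stpcv_step(phi, img, cfg)
    if (k %% 5 == 0) phi <- reinitialize(phi)
    areas <- c(areas, sum(phi < 0))
  }
  expect_lt(areas[50], areas[1])
  expect_true(all(diff(areas[seq(5, 50, 5)]) <= 0))
})

test_that("channel-wise CV with combination recovers the noiseless disks", {
  rd <- render_scene(scene_preset("three_disks", 96))
  td <- truth_sign_labels(rd)
  res <- segment_image(rd$image, "stpcv")
  expect_gte(min(per_label_overlap(td, res$labeling$labels)$dice), 0.95)
})

test_that("channel-wise CV tolerates light salt-and-pepper noise", {
  rd <- render_scene(scene_preset("three_disks", 96))
  td <- truth_sign_labels(rd)
  noisy <- add_noise(rd$image, "salt_pepper", d = 0.01, seed = 2)
  res <- segment_image(noisy, "stpcv")
  expect_gte(min(per_label_overlap(td, res$labeling$labels)$dice), 0.9)
})

test_that("all three models agree on a noiseless high-contrast separable scene", {
  rd <- render_scene(scene_preset("four_color_distinct", 96))
  td <- truth_sign_labels(rd)
  for (model in c("nbracm", "stpcv", "vcv")) {
    res <- segment_image(rd$image, model,
                         cfg = if (model == "nbracm")
                           evolution_config(track_energy = FALSE) else
                           baseline_config(track_energy = FALSE))
    expect_gte(min(per_label_overlap(td, res$labeling$labels)$dice), 0.95)
  }
})

test_that("empty-phase steps raise an informative error", {
  phi <- matrix(10, 16, 16); phi[8, 8] <- 9  # single-signed: empty interior
  expect_error(stpcv_step(phi, matrix(0.5, 16, 16)), class = "nbracm_empty_phase")
})
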