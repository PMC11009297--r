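# Forward model and scene generator.

test_that("domain layout places discs of the requested scale", {
  grid <- grid_spec(64, 64, 0.5)
  expect_equal(sum(make_domain_layout(grid, 0, seed = 1)$labels), 0)

  lay <- make_domain_layout(grid, 1, radius_um = 5, seed = 3)
  area <- sum(lay$labels == 1) * 0.5^2
  expect_lt(abs(area - pi * 25) / (pi * 25), 0.03)
  # default radius 5 um -> ca. 10 um diameters
  expect_equal(2 * lay$domains$radius, 10)

  lay2 <- make_domain_layout(grid, 3, radius_um = 5, min_gap_um = 2, seed = 7)
  dmat <- as.matrix(dist(lay2$domains[, c("cx", "cy")]))
  expect_true(all(dmat[upper.tri(dmat)] >= 12))
  # deterministic per seed
  lay3 <- make_domain_layout(grid, 3, radius_um = 5, min_gap_um = 2, seed = 7)
  expect_identical(lay2$labels, lay3$labels)
  # impossible packing fails loudly, naming the parameters
  expect_error(make_domain_layout(grid, 9, radius_um = 7, seed = 1,
                                  max_tries = 200),
               "could not place|does not fit")
})

test_that("texture fields follow their parametric forms", {
  grid <- grid_spec(32, 32, 0.5)
  f <- make_texture_field(texture_model("linear", beta = 40), grid)
  expect_true(all(abs(f$theta[f$mask] - 40) < 1e-12))

  # tangential texture: concentric circles of lipids; at (1, 0) from the
  # centre the direction is 90 degrees
  tx <- texture_model("boojum", centre = c(0, 0), k = 1, beta = 90, q = 0)
  expect_equal(texture_theta(tx, 1, 0), 90)
  expect_equal(texture_theta(tx, 0, 1), 180)
  # undefined at the exact centre -> masked
  f2 <- make_texture_field(tx, grid)
  expect_false(f2$mask[1, 1])
  expect_true(is.na(f2$theta[1, 1]))
})

test_that("iso-direction pixels of a pitched boojum lie on the Archimedean curve", {
  grid <- grid_spec(64, 64, 0.5)
  beta <- 20; q <- 3
  tx <- texture_model("boojum", centre = c(16, 16), k = 1, beta = beta, q = q)
  f <- make_texture_field(tx, grid)
  pts <- grid_points(grid)
  level <- 130
  # brute-force search for equal-angle pixels
  hit <- which(abs(circ_diff_deg(f$theta, level)) < 1 & f$mask)
  expect_gt(length(hit), 10)
  dx <- pts$x[hit] - 16; dy <- pts$y[hit] - 16
  r <- sqrt(dx^2 + dy^2)
  psi <- atan2(dy, dx) * 180 / pi
  expect_lt(max(abs(circ_diff_deg(psi, level - beta - q * r))), 1 + 1e-9)
})

test_that("rotation series obeys the in-plane/out-of-plane structure", {
  # out-of-plane-only model: spectra identical at every rotation for a
  # rotationally symmetric scene
  mod <- default_band_table()
  mod$bands$a_ip <- 0
  sc <- single_disc_scene(texture_model("linear", beta = 10),
                         grid = grid_spec(32, 32, 0.5), centre = c(7.75, 7.75),
                         radius = 4)
  ser <- synthesize_chi2_series(sc, mod, optical_geometry(),
                                omega = seq(2700, 3100, 20))
  for (j in 2:length(ser$stacks))
    expect_lt(max(abs(ser$stacks[[j]]$data - ser$stacks[[1]]$data)), 1e-12)

  # cosine antisymmetry: phi and phi + 180 have equal out-of-plane part and
  # sign-flipped in-plane part
  mod2 <- default_band_table()
  ser2 <- synthesize_chi2_series(sc, mod2, optical_geometry(),
                                 omega = seq(2700, 3100, 20))
  i0 <- which(ser2$angles == 0); i180 <- which(ser2$angles == 180)
  op_part <- (ser2$stacks[[i0]]$data + ser2$stacks[[i180]]$data) / 2
  expect_lt(max(abs(op_part - ser$stacks[[1]]$data -
                    (mod2$chi_nr - mod$chi_nr))), 1e-10)
})

test_that("emitted chi matches the scalar closed form at a single pixel", {
  grid <- grid_spec(32, 32, 0.5)
  sc <- single_disc_scene(texture_model("linear", beta = 55), grid = grid,
                         centre = c(7.75, 7.75), radius = 4)
  mod <- default_band_table()
  omega <- seq(2700, 3100, 10)
  geom <- optical_geometry(rotation_angles_deg = c(0, 120, 240))
  # rotation about the disc centre, probed at a pixel on the disc
  ser <- synthesize_chi2_series(sc, mod, geom, omega,
                                rotation_centre_um = c(7.75, 7.75))
  ff <- field_fractions(36)
  for (j in seq_along(geom$rotation_angles_deg)) {
    phi <- geom$rotation_angles_deg[j]
    # lab pixel (17, 16): sample point = inverse rotation about the centre
    p <- c(16 * 0.5, 15 * 0.5)
    a <- -phi * pi / 180
    u <- c(7.75, 7.75) + c(cos(a) * (p[1] - 7.75) - sin(a) * (p[2] - 7.75),
                           sin(a) * (p[1] - 7.75) + cos(a) * (p[2] - 7.75))
    stopifnot(sum((u - 7.75)^2) <= 16)
    chi_ref <- mod$chi_nr
    for (m in seq_len(nrow(mod$bands))) {
      b <- mod$bands[m, ]
      L <- 1 / (b$omega0 - omega - 1i * b$gamma)
      d <- 55 + b$d_offset
      chi_ref <- chi_ref + L * 1 *
        (ff[["f_op"]] * b$a_op +
         ff[["f_ip"]] * 0.8 * b$a_ip * cos((d + phi) * pi / 180))
    }
    expect_lt(max(abs(ser$stacks[[j]]$data[17, 16, ] - chi_ref)), 1e-12)
  }
})

test_that("band-sign rule: SS and FR positive, AS negative for upright chains", {
  sc <- single_disc_scene(texture_model("boojum", centre = c(26, 16),
                                        k = 1, beta = -90, q = 2))
  ser <- synthesize_chi2_series(sc, omega = default_omega_grid())
  st <- correct_dark_baseline(ser$stacks[[1]])
  sp <- apply(st$data, 3, mean)
  im_at <- function(w) Im(sp[which.min(abs(st$omega - w))])
  expect_gt(im_at(2875), 0)
  expect_gt(im_at(2935), 0)
  expect_lt(im_at(2965), 0)
})

test_that("interferogram synthesis is linear and recovers band positions", {
  grid <- grid_spec(16, 16, 0.5)
  pulse <- pulse_spec(delay_stop_fs = 1500)
  omega <- dft_omega_grid(pulse, c(2700, 3100))
  geom <- optical_geometry(rotation_angles_deg = c(0, 120, 240))
  sc <- single_disc_scene(texture_model("linear", beta = 0), grid = grid,
                         centre = c(3.75, 3.75), radius = 2.5)
  ser <- synthesize_chi2_series(sc, geometry = geom, omega = omega)
  # chi = 0 -> zero traces
  ser0 <- ser
  ser0$stacks <- lapply(ser0$stacks, function(s) { s$data[] <- 0; s })
  expect_equal(max(abs(synthesize_interferograms(ser0, pulse)[[1]]$data)), 0)
  # linearity in chi
  ser2 <- ser
  ser2$stacks <- lapply(ser2$stacks, function(s) { s$data <- 2 * s$data; s })
  i1 <- synthesize_interferograms(ser, pulse)
  i2 <- synthesize_interferograms(ser2, pulse)
  expect_lt(max(abs(i2[[1]]$data - 2 * i1[[1]]$data)), 1e-9)
  # single Lorentzian: FFT peak within one resolution element of omega0
  mod1 <- spectral_model(lorentzian_band("only", 2875, 6, a_op = 1), chi_nr = 0)
  ser3 <- synthesize_chi2_series(sc, mod1, geom, omega)
  tr <- synthesize_interferograms(ser3, pulse)[[1]]
  sp <- interferogram_to_spectrum(tr, roi = c(2700, 3100))
  prof <- apply(abs(sp$data), 3, mean)
  dw <- attr(omega, "delta")
  expect_lt(abs(sp$omega[which.max(prof)] - 2875), dw + 1e-9)
})

test_that("quartz reference is flat, coarse, and deterministic", {
  grid <- grid_spec(16, 16, 0.5)
  pulse <- pulse_spec()            # -300..3000 fs
  refp <- pulse_spec(delay_start_fs = -300, delay_stop_fs = 300)
  ref <- synthesize_reference(refp, grid, sample_pulse = pulse)
  # frequency grid ~5.5x coarser than the sample grid
  ratio <- attr(dft_omega_grid(refp), "delta") / attr(dft_omega_grid(pulse), "delta")
  expect_equal(ratio, length(delay_axis(pulse)) / length(delay_axis(refp)),
               tolerance = 1e-12)
  expect_gt(ratio, 5); expect_lt(ratio, 6)
  # flat magnitude (after envelope division), zero phase inside the envelope
  sp <- interferogram_to_spectrum(ref, roi = refp$ir_centre_cm + c(-100, 100))
  env <- pulse_envelope(refp, sp$omega)
  mag <- Mod(sp$data[1, 1, ]) / env
  expect_lt(diff(range(mag)) / mean(mag), 1e-6)
  expect_lt(max(abs(Arg(sp$data[1, 1, ]))), 1e-9)
  # reduced range must sit inside the sample range
  expect_error(synthesize_reference(pulse_spec(delay_start_fs = -400,
                                               delay_stop_fs = 300),
                                    grid, sample_pulse = pulse), "inside")
  ref2 <- synthesize_reference(refp, grid, sample_pulse = pulse)
  expect_identical(ref$data, ref2$data)
})

test_that("detection noise is seeded, calibrated and sigma = 0 is the identity", {
  grid <- grid_spec(16, 16, 0.5)
  st <- new_interferogram_stack(array(0, c(16, 16, 400)), seq_len(400), 0, 0.5)
  expect_identical(add_detection_noise(st, 0, seed = 1)$data, st$data)
  n1 <- add_detection_noise(st, 0.3, seed = 5)
  n2 <- add_detection_noise(st, 0.3, seed = 5)
  expect_identical(n1$data, n2$data)
  expect_lt(abs(sd(n1$data - st$data) - 0.3) / 0.3, 0.02)  # 102400 samples
})

test_that("mirroring is an involution and maps theta to 360 - theta", {
  sc <- make_classification_scene("spiral", "CW", "virtual", seed = 2)
  mm <- mirror_scene(mirror_scene(sc))
  expect_equal(mm$rho, sc$rho)
  expect_equal(mm$theta, sc$theta)
  expect_equal(mm$domains$cy, sc$domains$cy)
  f <- make_texture_field(texture_model("linear", beta = 90), grid_spec(16, 16, 0.5))
  expect_true(all(abs(mirror_scene(f)$theta[f$mask] - 270) < 1e-12))
  # mirroring the scene and mirroring its synthesized stacks commute
  ser_m <- synthesize_chi2_series(mirror_scene(sc), omega = seq(2700, 3100, 25))
  ser <- synthesize_chi2_series(sc, omega = seq(2700, 3100, 25))
  flip <- ser$stacks[[1]]$data[, rev(seq_len(64)), ]
  # at phi = 0 the lab frame equals the sample frame: mirrored scene's 0-fold
  # (out-of-plane) content is the y-flip of the original
  ser0 <- ser; ser0$stacks <- lapply(ser0$stacks, function(s) s)
  op_orig <- (ser$stacks[[1]]$data + ser$stacks[[4]]$data) / 2   # 0 and 180 deg
  op_mirr <- (ser_m$stacks[[1]]$data + ser_m$stacks[[4]]$data) / 2
  expect_lt(max(abs(op_mirr - op_orig[, rev(seq_len(64)), ])), 1e-10)
})
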