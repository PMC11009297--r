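# Registration, azimuthal decomposition, SVD grouping, director extraction.

test_that("aligning identical zero-rotation frames is the identity", {
  sc <- single_disc_scene(texture_model("linear", beta = 30),
                         grid = grid_spec(32, 32, 0.5), centre = c(7.75, 7.75),
                         radius = 4)
  geom0 <- optical_geometry(rotation_angles_deg = c(0, 120, 240))
  ser <- synthesize_chi2_series(sc, geometry = geom0, omega = seq(2700, 3100, 20))
  # overwrite every frame with the phi = 0 frame and zero angles
  for (j in 2:3) { ser$stacks[[j]] <- ser$stacks[[1]] }
  ser$angles <- c(0, 0, 0)
  for (j in 1:3) ser$stacks[[j]]$rotation <- 0
  al <- align_rotation_series(ser, estimate_centre = FALSE, refine_shift = FALSE)
  expect_true(all(al$mask))
  expect_lt(max(abs(al$data[, , , 2] - al$data[, , , 1])), 1e-14)
  expect_lt(max(abs(al$data[, , , 1] - ser$stacks[[1]]$data)), 1e-14)
})

test_that("the common mask shrinks monotonically as angles are added", {
  sc <- single_disc_scene(texture_model("linear", beta = 30))
  ser <- synthesize_chi2_series(sc, omega = seq(2800, 3000, 50),
                                rotation_centre_um = c(14, 17))
  masks <- sapply(3:6, function(n) {
    sub <- ser
    sub$stacks <- ser$stacks[seq_len(n)]
    sub$angles <- ser$angles[seq_len(n)]
    sum(align_rotation_series(sub, estimate_centre = FALSE,
                              refine_shift = FALSE)$mask)
  })
  expect_true(all(diff(masks) <= 0))
})

test_that("an off-centre rotation axis is recovered within a pixel", {
  grid <- grid_spec(64, 64, 0.5)
  lay <- make_domain_layout(grid, 3, radius_um = 4, seed = 12)
  # zero in-plane order: the magnitude images are rotation-invariant, so any
  # disagreement after alignment is pure registration error
  sc <- synthetic_scene(grid, lay, texture_model("linear", beta = 75),
                        order_domain = 0)
  true_c <- c(14.9, 14.2)
  ser <- synthesize_chi2_series(sc, omega = seq(2800, 3000, 25),
                                rotation_centre_um = true_c)
  ser$rotation_centre_um <- NULL      # hide the truth from the estimator
  al <- align_rotation_series(ser)
  expect_lt(max(abs(al$centre_px - true_c / 0.5)), 1)
  # aligned magnitude images agree with the zero-rotation frame away from
  # the one-pixel partial-volume ring at the domain boundaries
  away <- erode_mask(sc$labels > 0, 1.5) | erode_mask(sc$labels == 0, 1.5)
  m0 <- apply(abs(al$data[, , , 1]), c(1, 2), sum)
  for (j in 2:dim(al$data)[4]) {
    mj <- apply(abs(al$data[, , , j]), c(1, 2), sum)
    ok <- al$mask & away
    expect_lt(sqrt(mean((mj[ok] - m0[ok])^2)) / max(m0[ok]), 0.02)
  }
})

test_that("azimuthal decomposition matches a least-squares sinusoid fit", {
  nx <- 24; ny <- 24; nw <- 3; N <- 6
  ang <- seq(0, 300, by = 60); phi <- ang * pi / 180
  withr::with_seed(11, {
    c0 <- array(complex(real = rnorm(nx * ny * nw), imaginary = rnorm(nx * ny * nw)), c(nx, ny, nw))
    B <- array(runif(nx * ny * nw, 0.5, 2), c(nx, ny, nw))
    d0 <- array(runif(nx * ny * nw, 0, 360), c(nx, ny, nw))
  })
  dat <- array(0 + 0i, c(nx, ny, nw, N))
  for (j in 1:N) dat[, , , j] <- c0 + B * cos((d0 + ang[j]) * pi / 180)
  al <- structure(list(data = dat, mask = matrix(TRUE, nx, ny),
                       centre_px = c(11.5, 11.5), angles = ang,
                       omega = c(2800, 2900, 3000), pixel_size = 0.5),
                  class = "aligned4d")
  cp <- azimuthal_decompose(al)
  # least-squares oracle on the [1, cos, sin] design, pixel by pixel
  X <- cbind(1, cos(phi), sin(phi))
  Ymat <- matrix(aperm(dat, c(4, 1, 2, 3)), nrow = N)
  cf <- t(solve(crossprod(X), t(X) %*% Ymat))
  F0_ls <- array(cf[, 1], c(nx, ny, nw))
  F1_ls <- array((cf[, 2] - 1i * cf[, 3]) / 2, c(nx, ny, nw))
  expect_lt(max(abs(cp$F0 - F0_ls)), 1e-10)
  expect_lt(max(abs(cp$F1 - F1_ls)), 1e-10)
  # amplitude/phase convention: |F1| = B/2, arg F1 = d
  expect_lt(max(abs(Mod(cp$F1) - B / 2)), 1e-10)
  expect_lt(max(abs(circ_diff_deg(Arg(cp$F1) * 180 / pi, d0))), 1e-8)
  # a phi-constant signal has F1 = 0 and F0 equal to the constant
  dat0 <- dat; for (j in 1:N) dat0[, , , j] <- c0
  al0 <- al; al0$data <- dat0
  cp0 <- azimuthal_decompose(al0)
  expect_lt(max(abs(cp0$F1)), 1e-12)
  expect_lt(max(abs(cp0$F0 - c0)), 1e-12)
  # 2-fold modulation is orthogonal to both retained orders at N = 6
  dat2 <- dat0; for (j in 1:N) dat2[, , , j] <- c0 * cos(2 * phi[j])
  al2 <- al; al2$data <- dat2
  cp2 <- azimuthal_decompose(al2)
  expect_lt(max(abs(cp2$F1)), 1e-12)
  # non-uniform angles: refused, unless the flagged fallback is requested
  alnu <- al; alnu$angles <- c(0, 50, 120, 180, 240, 300)
  expect_error(azimuthal_decompose(alnu), "uniform")
  expect_true(azimuthal_decompose(alnu, allow_nonuniform = TRUE)$nonuniform_fallback)
})

test_that("F0 is stable under dropping one angle for sinusoidal data", {
  nx <- 8; ny <- 8; nw <- 2
  ang <- seq(0, 300, by = 60)
  withr::with_seed(3, {
    c0 <- array(complex(real = rnorm(nx * ny * nw)), c(nx, ny, nw))
    B <- array(runif(nx * ny * nw), c(nx, ny, nw))
  })
  dat <- array(0 + 0i, c(nx, ny, nw, 6))
  for (j in 1:6) dat[, , , j] <- c0 + B * cos((40 + ang[j]) * pi / 180)
  al <- structure(list(data = dat, mask = matrix(TRUE, nx, ny), angles = ang,
                       centre_px = c(3.5, 3.5), omega = c(2800, 2900),
                       pixel_size = 0.5), class = "aligned4d")
  F0_full <- azimuthal_decompose(al)$F0
  for (drop in c(2, 4, 6)) {
    ald <- al
    ald$data <- al$data[, , , -drop, drop = FALSE]
    ald$angles <- ang[-drop]
    F0_d <- azimuthal_decompose(ald, allow_nonuniform = TRUE)$F0
    expect_lt(max(abs(F0_d - F0_full)), 1e-10)
  }
})

test_that("SVD is rank-2 on two-chromophore scenes and spans the truth", {
  sc <- make_classification_scene("spiral", "CW", "virtual", seed = 5)
  res <- analyse_scene(sc)
  sv <- svd_decompose(res$aligned)
  expect_lt(sv$d[3] / sv$d[1], 1e-8)
  expect_gt(sv$d[2] / sv$d[1], 1e-3)
  # retained spectra span the {out-of-plane, in-plane} model subspace
  mod <- default_band_table()
  anc <- vsfgmap:::anchor_selection(sv$omega, list(c(-Inf, 2800), c(3050, Inf)))
  bl <- function(v) as.vector(vsfgmap:::baseline_apply(matrix(v, 1), sv$omega, anc))
  op <- bl(evaluate_model(mod, sv$omega, "op"))
  sgn <- ifelse(mod$bands$d_offset == 180, -1, 1)
  ip <- bl(evaluate_model(mod, sv$omega, sgn * mod$bands$a_ip, include_nr = FALSE))
  Q1 <- qr.Q(qr(cbind(op, ip)))
  Q2 <- qr.Q(qr(sv$spectra))
  expect_true(all(svd(Conj(t(Q1)) %*% Q2)$d > 0.999))
  # sign convention: positive Im at the CH3 SS for every retained component
  ssbin <- which.min(abs(sv$omega - 2875))
  expect_true(all(Im(sv$spectra[ssbin, ]) > 0))
  # homogeneity: doubling the data doubles the singular values only
  al2 <- res$aligned; al2$data <- 2 * al2$data
  sv2 <- svd_decompose(al2)
  expect_equal(sv2$d[1:2], 2 * sv$d[1:2], tolerance = 1e-10)
  expect_lt(min(abs(colSums(Conj(sv2$spectra) * sv$spectra))), 1.000001)
  expect_gt(min(Mod(colSums(Conj(sv2$spectra) * sv$spectra))), 0.999999)
})

test_that("director extraction recovers uniform fields and the dipole convention", {
  sc <- single_disc_scene(texture_model("linear", beta = 137))
  res <- analyse_scene(sc)
  core <- erode_mask(sc$labels > 0, 1.5) & res$director$mask
  # the generator writes the CH3 SS dipole at theta + 180; extraction must
  # return theta itself, not theta + 180
  expect_lt(abs(circ_mean_deg(res$director$theta[core]) - 137), 0.1)
  expect_lt(circ_rmse_deg(res$director$theta[core], 137), 0.1)
  # confidence is high where the signal is sinusoidal
  expect_gt(min(res$director$confidence[core]), 0.99)
  # SVD-based extraction agrees with the per-band azimuthal route
  dir2 <- extract_director(svd_decompose(res$aligned), default_band_table())
  expect_lt(circ_rmse_deg(dir2$theta[core], res$director$theta[core]), 0.2)
})

test_that("rigid rotation of the scene shifts every director equally", {
  grid <- grid_spec(64, 64, 0.5)
  ctr <- c(15.75, 15.75)
  tx1 <- texture_model("boojum", centre = c(24, 10), k = 1, beta = -70, q = 1.5)
  sc1 <- single_disc_scene(tx1, grid = grid, centre = c(20, 12), radius = 4.5)
  # scene rotated rigidly by 90 degrees about the grid centre: for a k = 1
  # texture the centre rotates and beta is unchanged; theta gains 90
  rot90 <- function(p) ctr + c(-(p[2] - ctr[2]), p[1] - ctr[1])
  tx2 <- texture_model("boojum", centre = rot90(c(24, 10)), k = 1, beta = -70, q = 1.5)
  sc2 <- single_disc_scene(tx2, grid = grid, centre = rot90(c(20, 12)), radius = 4.5)
  r1 <- analyse_scene(sc1); r2 <- analyse_scene(sc2)
  core1 <- erode_mask(sc1$labels > 0, 1.5) & r1$director$mask
  # compare pixel p in scene 1 with rot90(p) in scene 2
  idx <- which(core1, arr.ind = TRUE)
  p2 <- t(apply(idx, 1, function(ij) round(rot90((ij - 1) * 0.5) / 0.5) + 1))
  keep <- p2[, 1] >= 1 & p2[, 1] <= 64 & p2[, 2] >= 1 & p2[, 2] <= 64
  th1 <- r1$director$theta[idx[keep, , drop = FALSE]]
  th2 <- r2$director$theta[p2[keep, , drop = FALSE]]
  ok <- is.finite(th1) & is.finite(th2)
  expect_gt(sum(ok), 100)
  expect_lt(circ_rmse_deg(th2[ok], th1[ok] + 90), 0.2)
})

test_that("counter-directional (inversion-symmetric) packing cancels F1", {
  sc_a <- single_disc_scene(texture_model("linear", beta = 20))
  sc_b <- single_disc_scene(texture_model("linear", beta = 200))
  ser_a <- synthesize_chi2_series(sc_a, omega = seq(2700, 3100, 10))
  ser_b <- synthesize_chi2_series(sc_b, omega = seq(2700, 3100, 10))
  # equal mixture of the two opposite populations in every pixel
  ser_a$stacks <- Map(function(x, y) { x$data <- (x$data + y$data) / 2; x },
                      ser_a$stacks, ser_b$stacks)
  ser_a$stacks <- lapply(ser_a$stacks, correct_dark_baseline)
  al <- align_rotation_series(ser_a, estimate_centre = FALSE)
  cp <- azimuthal_decompose(al)
  expect_lt(max(abs(cp$F1[is.finite(cp$F1)])), 1e-10)
})

test_that("arrow maps average blocks like the brute-force vector sum", {
  f <- make_texture_field(texture_model("linear", beta = 77), grid_spec(24, 24, 0.5))
  a <- arrow_map(f, block = 6)
  expect_equal(nrow(a), 16)
  expect_true(all(abs(circ_diff_deg(a$theta_deg, 77)) < 1e-10))
  # brute-force oracle on a random field
  grid <- grid_spec(24, 24, 0.5)
  withr::with_seed(8, {
    th <- matrix(runif(576, 0, 360), 24, 24)
    mg <- matrix(runif(576, 0.5, 2), 24, 24)
  })
  fld <- director_field(th, mg, matrix(TRUE, 24, 24), 0.5)
  a2 <- arrow_map(fld, block = 6, min_resultant = 0)
  for (r in seq_len(nrow(a2))) {
    i0 <- floor(a2$x_um[r] / (0.5 * 6)) * 6 + 1
    j0 <- floor(a2$y_um[r] / (0.5 * 6)) * 6 + 1
    z <- 0
    for (i in i0:(i0 + 5)) for (j in j0:(j0 + 5))
      z <- z + mg[i, j] * exp(1i * th[i, j] * pi / 180)
    expect_lt(abs(circ_diff_deg(a2$theta_deg[r], Arg(z) * 180 / pi)), 1e-10)
  }
  # perfectly cancelling block is omitted
  th2 <- matrix(0, 24, 24); th2[, seq(1, 24, 2)] <- 180
  fld2 <- director_field(th2, matrix(1, 24, 24), matrix(TRUE, 24, 24), 0.5)
  a3 <- arrow_map(fld2, block = 6)
  expect_equal(nrow(a3), 0)
})
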