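# Core rotational inference: back-rotation registration into the sample
# frame, azimuthal (0-fold / 1-fold) Fourier decomposition, time-domain SVD
# grouping, and extraction of the absolute in-plane director map.

# Rotate an image plane BY angle_deg (CCW) about centre_px (0-based pixel
# coords): output(p) = input(R(-angle) (p - c) + c), bilinear, NA outside.
rotate_weights <- function(nx, ny, angle_deg, centre_px) {
  ix <- rep(seq_len(nx) - 1, times = ny)
  iy <- rep(seq_len(ny) - 1, each = nx)
  ca <- cos(deg2rad(-angle_deg)); sa <- sin(deg2rad(-angle_deg))
  dx <- ix - centre_px[1]; dy <- iy - centre_px[2]
  bilinear_weights(nx, ny,
                   centre_px[1] + ca * dx - sa * dy,
                   centre_px[2] + sa * dx + ca * dy)
}

rotate_image_about <- function(img, angle_deg, centre_px, fill = NA) {
  bw <- rotate_weights(nrow(img), ncol(img), angle_deg, centre_px)
  matrix(apply_bilinear(bw, img, fill = fill), nrow(img), ncol(img))
}

# band-integrated magnitude image of one lab-frame stack (used for
# registration only)
stack_magnitude <- function(stack) apply(abs(stack$data), c(1, 2), sum)

# Mean correlation of the back-rotated magnitude images with the phi = 0
# image over a set of candidate rotation centres. Rotation about centre c is
# a rotation about the origin plus a c-dependent translation, so the
# trigonometry is hoisted out of the candidate loop.
centre_search <- function(mags, angles, centres) {
  ref <- mags[[which.min(abs(angles))]]
  nx <- nrow(ref); ny <- ncol(ref)
  ix <- rep(seq_len(nx) - 1, times = ny)
  iy <- rep(seq_len(ny) - 1, each = nx)
  scores <- rep(0, nrow(centres)); counts <- 0
  for (j in seq_along(angles)) {
    if (angles[j] == 0) next
    ca <- cos(deg2rad(angles[j])); sa <- sin(deg2rad(angles[j]))
    rx <- ca * ix - sa * iy
    ry <- sa * ix + ca * iy
    counts <- counts + 1
    for (m in seq_len(nrow(centres))) {
      cx <- centres[m, 1]; cy <- centres[m, 2]
      tx <- cx - (ca * cx - sa * cy)
      ty <- cy - (sa * cx + ca * cy)
      bw <- bilinear_weights(nx, ny, rx + tx, ry + ty)
      br <- apply_bilinear(bw, mags[[j]])
      ok <- is.finite(br)
      scores[m] <- scores[m] + if (sum(ok) < 16) -Inf else
        suppressWarnings(stats::cor(br[ok], ref[ok]))
    }
  }
  if (counts == 0) rep(1, nrow(centres)) else scores / counts
}

# integer translation (dx, dy) of img that best matches ref, searched over
# +/- max_shift px; returns the shift to apply to img
estimate_shift <- function(img, ref, max_shift = 2) {
  best <- c(0, 0); best_sc <- -Inf
  nx <- nrow(img); ny <- ncol(img)
  for (sx in -max_shift:max_shift) for (sy in -max_shift:max_shift) {
    xr <- max(1, 1 + sx):min(nx, nx + sx)
    yr <- max(1, 1 + sy):min(ny, ny + sy)
    a <- img[xr - sx, yr - sy]; bmat <- ref[xr, yr]
    ok <- is.finite(a) & is.finite(bmat)
    if (sum(ok) < 16) next
    sc <- suppressWarnings(stats::cor(a[ok], bmat[ok]))
    if (is.finite(sc) && sc > best_sc) { best_sc <- sc; best <- c(sx, sy) }
  }
  best
}

shift_image <- function(img, shift) {
  if (all(shift == 0)) return(img)
  nx <- nrow(img); ny <- ncol(img)
  out <- matrix(NA_real_, nx, ny)
  xr <- max(1, 1 + shift[1]):min(nx, nx + shift[1])
  yr <- max(1, 1 + shift[2]):min(ny, ny + shift[2])
  out[xr, yr] <- img[xr - shift[1], yr - shift[2]]
  out
}

#' Register a rotation series into the sample frame
#'
#' Back-rotates each lab-frame stack by its rotation angle about the
#' rotation centre (bilinear interpolation), optionally refining the centre
#' by a coarse-then-fine search that maximises the correlation of the
#' back-rotated band-integrated magnitude images with the zero-rotation
#' image, and refining residual integer translations by cross-correlation.
#' Pixels outside any frame's rotated footprint are marked invalid rather
#' than zero-filled; the common-region mask is the intersection of all
#' footprints.
#'
#' @param series a `rotation_series`.
#' @param centre_guess_px rotation-centre guess, 0-based pixel coordinates
#'   (default: metadata centre, else the image centre).
#' @param estimate_centre refine the centre by grid search.
#' @param refine_shift estimate residual integer translations.
#' @param corr_threshold minimum acceptable registration correlation.
#' @return an `aligned4d`: complex array `(nx, ny, n_omega, n_phi)`, common
#'   mask, centre, per-angle shifts and registration correlations.
#' @export
align_rotation_series <- function(series, centre_guess_px = NULL,
                                  estimate_centre = TRUE, refine_shift = TRUE,
                                  corr_threshold = 0.7) {
  stacks <- series$stacks
  angles <- series$angles
  if (length(angles) < 3) stopf("need at least 3 rotation angles")
  nx <- dim(stacks[[1]]$data)[1]; ny <- dim(stacks[[1]]$data)[2]
  px <- stacks[[1]]$pixel_size
  if (is.null(centre_guess_px)) {
    centre_guess_px <- if (!is.null(series$rotation_centre_um))
      series$rotation_centre_um / px else c((nx - 1) / 2, (ny - 1) / 2)
  }
  mags <- lapply(stacks, stack_magnitude)
  centre <- centre_guess_px
  if (estimate_centre && any(angles != 0)) {
    coarse <- as.matrix(expand.grid(dx = -3:3, dy = -3:3))
    sc <- centre_search(mags, angles, sweep(coarse, 2, centre_guess_px, `+`))
    centre <- centre_guess_px + coarse[which.max(sc), ]
    fine <- as.matrix(expand.grid(dx = seq(-0.75, 0.75, 0.25),
                                  dy = seq(-0.75, 0.75, 0.25)))
    sc <- centre_search(mags, angles, sweep(fine, 2, centre, `+`))
    centre <- unname(centre + fine[which.max(sc), ])
  }
  nw <- length(series$omega)
  out <- array(NA_complex_, c(nx, ny, nw, length(angles)))
  shifts <- matrix(0, length(angles), 2)
  cors <- numeric(length(angles))
  ref_mag <- mags[[which.min(abs(angles))]]
  for (j in seq_along(angles)) {
    bw <- rotate_weights(nx, ny, -angles[j], centre)
    br_mag <- matrix(apply_bilinear(bw, mags[[j]]), nx, ny)
    if (refine_shift) shifts[j, ] <- estimate_shift(br_mag, ref_mag)
    re <- stacks[[j]]$data
    for (k in seq_len(nw)) {
      sl <- matrix(apply_bilinear(bw, re[, , k]), nx, ny)
      out[, , k, j] <- shift_image_c(sl, shifts[j, ])
    }
    fin <- shift_image(br_mag, shifts[j, ])
    ok <- is.finite(fin) & is.finite(ref_mag)
    cors[j] <- if (all(angles[j] == 0) && all(shifts[j, ] == 0)) 1 else
      suppressWarnings(stats::cor(fin[ok], ref_mag[ok]))
    if (!is.finite(cors[j]) || cors[j] < corr_threshold)
      stopf("registration failed at rotation %g deg (correlation %.3f < %.3f)",
            angles[j], cors[j], corr_threshold)
  }
  mask <- apply(is.finite(out[, , 1, , drop = FALSE]), c(1, 2), all)
  structure(list(data = out, mask = mask, centre_px = centre,
                 shifts = shifts, registration_cor = cors,
                 angles = angles, omega = series$omega, pixel_size = px,
                 anchors = stacks[[1]]$anchors),
            class = "aligned4d")
}

# complex-aware integer shift
shift_image_c <- function(img, shift) {
  if (all(shift == 0)) return(img)
  nx <- nrow(img); ny <- ncol(img)
  out <- matrix(NA_complex_, nx, ny)
  xr <- max(1, 1 + shift[1]):min(nx, nx + shift[1])
  yr <- max(1, 1 + shift[2]):min(ny, ny + shift[2])
  out[xr, yr] <- img[xr - shift[1], yr - shift[2]]
  out
}

#' @export
print.aligned4d <- function(x, ...) {
  cat(sprintf("<aligned4d> %d x %d px, %d frequencies, %d angles, mask %.1f%%, centre (%.2f, %.2f) px\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], dim(x$data)[4],
              100 * mean(x$mask), x$centre_px[1], x$centre_px[2]))
  invisible(x)
}

#' Azimuthal Fourier decomposition of an aligned rotation series
#'
#' Computes `F_n = (1/N) sum_j S(phi_j) exp(-i n phi_j)` for n = 0 and 1.
#' The 0-fold component carries the rotation-invariant out-of-plane
#' response; the 1-fold component carries the in-plane response, whose phase
#' encodes the lab-frame dipole azimuth (`|F1|` equals half the cosine
#' amplitude under this 1/N normalisation). Angles must sample the full turn
#' uniformly; with `allow_nonuniform = TRUE` a least-squares sinusoid fit is
#' used instead and the result flagged.
#'
#' @param aligned an `aligned4d`.
#' @param allow_nonuniform fall back to weighted least squares for
#'   non-uniform angle sets.
#' @return `azimuthal_components` with complex `F0`, `F1` cubes, the common
#'   mask, and the per-pixel residual (non 0/1-fold) power fraction.
#' @export
azimuthal_decompose <- function(aligned, allow_nonuniform = FALSE) {
  ang <- aligned$angles
  N <- length(ang)
  step <- diff(sort(ang))
  uniform <- max(abs(step - step[1])) < 1e-6 && abs(N * step[1] - 360) < 1e-6
  d <- aligned$data
  nx <- dim(d)[1]; ny <- dim(d)[2]; nw <- dim(d)[3]
  dm <- d; dim(dm) <- c(nx * ny * nw, N)
  phi <- deg2rad(ang)
  flagged <- FALSE
  if (uniform) {
    F0 <- dm %*% (exp(-0i * phi) / N)
    F1 <- dm %*% (exp(-1i * phi) / N)
    # total and residual azimuthal power over all integer orders 0..N-1;
    # the sinusoidal in-plane model of a complex signal occupies orders
    # {0, +1, -1}, so the conjugate order N-1 is part of the model, not of
    # the residual
    ptot <- matrix(0, nx * ny, 1); p01 <- matrix(0, nx * ny, 1)
    for (n in 0:(N - 1)) {
      Fn <- dm %*% (exp(-1i * n * phi) / N)
      pw <- rowSums(matrix(Mod(Fn)^2, nx * ny, nw))
      ptot <- ptot + pw
      if (n %in% c(0, 1, N - 1)) p01 <- p01 + pw
    }
  } else {
    if (!allow_nonuniform) stopf("rotation angles are not uniform on [0, 360); set allow_nonuniform = TRUE for a least-squares fallback")
    flagged <- TRUE
    X <- cbind(1, cos(phi), sin(phi))
    H <- solve(crossprod(X), t(X))  # 3 x N
    cf <- dm %*% t(H)
    F0 <- cf[, 1, drop = FALSE]
    F1 <- (cf[, 2, drop = FALSE] - 1i * cf[, 3, drop = FALSE]) / 2
    fitted <- cf %*% t(X)
    res <- dm - fitted
    ptot <- rowSums(matrix(Mod(dm)^2 / N, nx * ny, nw * N))
    p01 <- ptot - rowSums(matrix(Mod(res)^2 / N, nx * ny, nw * N))
  }
  dim(F0) <- c(nx, ny, nw); dim(F1) <- c(nx, ny, nw)
  resid_frac <- matrix(pmax(0, 1 - p01 / pmax(ptot, 1e-300)), nx, ny)
  structure(list(F0 = F0, F1 = F1, mask = aligned$mask, omega = aligned$omega,
                 pixel_size = aligned$pixel_size, angles = ang,
                 resid_power_frac = resid_frac,
                 normalization = "1/N, exp(-i n phi)",
                 nonuniform_fallback = flagged,
                 anchors = aligned$anchors),
            class = "azimuthal_components")
}

#' @export
print.azimuthal_components <- function(x, ...) {
  cat(sprintf("<azimuthal_components> %d x %d px, %d frequencies, %d angles%s\n",
              dim(x$F0)[1], dim(x$F0)[2], dim(x$F0)[3], length(x$angles),
              if (x$nonuniform_fallback) " (least-squares fallback)" else ""))
  invisible(x)
}

#' Time-domain SVD grouping of the aligned 4D dataset
#'
#' Truncates the spectra to `roi`, converts each (pixel, angle) spectrum to
#' a real time trace by an exactly invertible one-sided inverse DFT (the roi
#' bins are placed at an offset of a zero-padded real DFT so signal and
#' conjugate bins never alias), performs an SVD over (pixels x angles)
#' against time, and transforms the retained component traces back to the
#' frequency domain. Component spectra are unit-normalised and their sign
#' fixed so the imaginary part at the CH3 symmetric stretch is positive.
#'
#' @param aligned an `aligned4d`.
#' @param roi optional frequency window `c(lo, hi)`, cm^-1.
#' @param n_keep number of retained components.
#' @param ss_omega CH3 SS frequency used for the sign convention, cm^-1.
#' @return an `svd_result`: singular values, component spectra `(n_omega x
#'   n_keep)`, loading array `(nx, ny, n_phi, n_keep)`.
#' @export
svd_decompose <- function(aligned, roi = NULL, n_keep = 2, ss_omega = 2875) {
  omega <- aligned$omega
  sel <- if (is.null(roi)) rep(TRUE, length(omega)) else
    omega >= roi[1] & omega <= roi[2]
  if (!any(sel)) stopf("roi excludes every frequency")
  omega <- omega[sel]
  K <- length(omega)
  Nf <- 4 * K
  if (Nf < n_keep) stopf("fewer time points than requested components")
  d <- aligned$data[, , sel, , drop = FALSE]
  nx <- dim(d)[1]; ny <- dim(d)[2]; nphi <- dim(d)[4]
  mask <- aligned$mask
  # flatten to (masked pixels * angles) x K
  d <- aperm(d, c(1, 2, 4, 3))
  dim(d) <- c(nx * ny * nphi, K)
  keep_rows <- rep(as.vector(mask), times = nphi)
  d <- d[keep_rows, , drop = FALSE]
  # real time traces: bins b_k = K .. 2K-1 of an Nf-point real DFT
  bins <- K + 0:(K - 1)
  W <- exp(-2i * pi * outer(bins, 0:(Nf - 1)) / Nf)
  X <- Re(d %*% W)
  n_keep <- min(n_keep, Nf)
  sv <- svd(X, nu = 0, nv = n_keep)
  dvals <- sv$d
  V <- sv$v
  loadings <- X %*% V                      # rows x n_keep  (= U * d)
  # back to the frequency domain: chi_k = (2/Nf) sum_n v_n e^{+2 pi i b_k n / Nf}
  spectra <- (2 / Nf) * (Conj(W) %*% V)
  # unit-normalise spectra, push scale into the loadings
  nrm <- sqrt(colSums(Mod(spectra)^2))
  spectra <- sweep(spectra, 2, nrm, `/`)
  loadings <- sweep(loadings, 2, nrm, `*`) * (2 / Nf)
  # sign convention: Im chi at the CH3 SS positive
  ssbin <- which.min(abs(omega - ss_omega))
  for (k in seq_len(n_keep)) {
    if (Im(spectra[ssbin, k]) < 0) {
      spectra[, k] <- -spectra[, k]
      loadings[, k] <- -loadings[, k]
    }
  }
  # scatter loadings back onto the full lattice
  load_arr <- array(NA_real_, c(nx * ny, nphi, n_keep))
  idx <- which(as.vector(mask))
  for (k in seq_len(n_keep)) {
    lm_ <- matrix(loadings[, k], ncol = nphi)
    load_arr[idx, , k] <- lm_
  }
  dim(load_arr) <- c(nx, ny, nphi, n_keep)
  structure(list(d = dvals, spectra = spectra, loadings = load_arr,
                 omega = omega, angles = aligned$angles, mask = mask,
                 pixel_size = aligned$pixel_size, n_keep = n_keep),
            class = "svd_result")
}

#' @export
print.svd_result <- function(x, ...) {
  cat(sprintf("<svd_result> %d component(s) retained; leading singular values: %s\n",
              x$n_keep, paste(signif(x$d[1:min(4, length(x$d))], 3), collapse = ", ")))
  invisible(x)
}

# which retained component is the in-plane (1-fold) one, which out-of-plane
identify_components <- function(svdres) {
  nphi <- length(svdres$angles)
  phi <- deg2rad(svdres$angles)
  frac1 <- vapply(seq_len(svdres$n_keep), function(k) {
    lm_ <- svdres$loadings[, , , k]
    dim(lm_) <- c(length(lm_) / nphi, nphi)
    lm_ <- lm_[stats::complete.cases(lm_), , drop = FALSE]
    F1 <- lm_ %*% (exp(-1i * phi) / nphi)
    F0 <- rowMeans(lm_)
    tot <- rowSums(lm_^2) / nphi
    sum(2 * Mod(F1)^2) / max(sum(tot), 1e-300)
  }, numeric(1))
  list(ip = which.max(frac1), op = which.min(frac1), frac1 = frac1)
}

#' Extract the absolute in-plane director map
#'
#' From azimuthal components: per pixel the 1-fold spectrum is projected
#' onto the model's complex in-plane reference line shape (which carries the
#' per-band dipole azimuth offsets, including the 180-degree CH3 SS
#' relation: the molecular direction points exactly opposite the CH3 SS
#' in-plane dipole), so the argument of the projection is directly the
#' molecular direction theta and its magnitude half the in-plane cosine
#' amplitude.
#'
#' From an SVD result: the in-plane component is identified by its 1-fold
#' loading power; the complex 1-fold coefficient of the per-pixel loading
#' gives theta after applying the same dipole convention (+180 degrees,
#' because the component sign is fixed CH3-SS-positive while the in-plane
#' CH3 SS dipole opposes the molecular direction).
#'
#' @param x an `azimuthal_components` or `svd_result`.
#' @param model the `spectral_model` (band table with dipole offsets).
#' @param noise_floor pixels with director magnitude below this are masked
#'   out rather than assigned a direction.
#' @return a [director_field()]; `confidence` is `1 -` the non-0/1-fold
#'   azimuthal power fraction.
#' @export
extract_director <- function(x, model = default_band_table(), noise_floor = 0)
  UseMethod("extract_director")

#' @export
extract_director.azimuthal_components <- function(x, model = default_band_table(),
                                                  noise_floor = 0) {
  P <- inplane_reference(model, x$omega)
  # the data passed through the dark/baseline correction; apply the same
  # operator to the reference line shape so the projection stays unbiased
  if (!is.null(x$anchors))
    P <- as.vector(baseline_apply(matrix(P, 1), x$omega,
                                  anchor_selection(x$omega, x$anchors)))
  if (sum(Mod(P)^2) == 0) stopf("model has no in-plane amplitude")
  nx <- dim(x$F1)[1]; ny <- dim(x$F1)[2]; nw <- dim(x$F1)[3]
  F1m <- x$F1; dim(F1m) <- c(nx * ny, nw)
  z <- as.vector(F1m %*% Conj(P)) / sum(Mod(P)^2)
  theta <- matrix(wrap_deg(rad2deg(Arg(z))), nx, ny)
  mag <- matrix(2 * Mod(z), nx, ny)
  conf <- 1 - x$resid_power_frac
  mask <- x$mask & mag > noise_floor
  director_field(theta, mag, mask, x$pixel_size, confidence = conf)
}

#' @export
extract_director.svd_result <- function(x, model = default_band_table(),
                                        noise_floor = 0) {
  id <- identify_components(x)
  nphi <- length(x$angles)
  phi <- deg2rad(x$angles)
  lm_ <- x$loadings[, , , id$ip]
  nx <- dim(lm_)[1]; ny <- dim(lm_)[2]
  dim(lm_) <- c(nx * ny, nphi)
  lm0 <- lm_; lm0[!is.finite(lm0)] <- 0
  z <- lm0 %*% (exp(-1i * phi) / nphi)
  theta <- matrix(wrap_deg(rad2deg(Arg(z)) + 180), nx, ny)
  mag <- matrix(2 * Mod(z), nx, ny)
  # confidence: fraction of loading power in azimuthal orders 0 and 1
  F0 <- rowMeans(lm0)
  tot <- rowSums(lm0^2) / nphi
  p01 <- Mod(F0)^2 + 2 * Mod(z)^2
  conf <- matrix(pmin(1, p01 / pmax(tot, 1e-300)), nx, ny)
  mask <- x$mask & mag > noise_floor
  director_field(theta, mag, mask, x$pixel_size, confidence = conf)
}

#' Block-averaged arrow map of a director field
#'
#' Averages the field over `block x block` pixel tiles (default 6, matching
#' the display convention for phase arrows): each tile's direction is the
#' magnitude-weighted circular mean; tiles whose mean resultant length falls
#' below `min_resultant` (mutually cancelling directions) are omitted.
#'
#' @param field a `director_field`.
#' @param block tile size in pixels (>= 1).
#' @param min_resultant minimum mean resultant length to keep a tile.
#' @param min_px minimum number of valid pixels per tile.
#' @return data.frame with tile centres (um), direction (deg), mean
#'   magnitude and resultant length.
#' @export
arrow_map <- function(field, block = 6, min_resultant = 0.25, min_px = 3) {
  if (block < 1) stopf("block must be >= 1")
  nx <- nrow(field$theta); ny <- ncol(field$theta)
  bx <- ceiling(nx / block); by <- ceiling(ny / block)
  res <- list()
  for (i in seq_len(bx)) for (j in seq_len(by)) {
    xr <- ((i - 1) * block + 1):min(i * block, nx)
    yr <- ((j - 1) * block + 1):min(j * block, ny)
    th <- field$theta[xr, yr]; mg <- field$magnitude[xr, yr]
    ok <- field$mask[xr, yr] & is.finite(th)
    if (sum(ok) < min_px) next
    z <- sum(mg[ok] * exp(1i * deg2rad(th[ok])))
    wsum <- sum(mg[ok])
    if (wsum <= 0) next
    rl <- Mod(z) / wsum
    if (rl < min_resultant) next
    res[[length(res) + 1]] <- data.frame(
      x_um = (mean(xr) - 1) * field$pixel_size,
      y_um = (mean(yr) - 1) * field$pixel_size,
      theta_deg = wrap_deg(rad2deg(Arg(z))),
      magnitude = mean(mg[ok]), resultant = rl)
  }
  if (!length(res))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      theta_deg = numeric(0), magnitude = numeric(0),
                      resultant = numeric(0)))
  do.call(rbind, res)
}
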