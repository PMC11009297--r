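# Mesoscale analysis: LC-domain segmentation, inside/outside spectra,
# coverage / density / order estimation, phase contours, and boojum / spiral
# texture fitting and classification with handedness.

#' Segment condensed domains from an out-of-plane CH3 magnitude image
#'
#' Otsu threshold (default), connected components, minimum-area filter and
#' boundary extraction.
#'
#' @param image non-negative magnitude image `(nx, ny)`.
#' @param pixel_size micrometres per pixel.
#' @param min_area_um2 minimum domain area, um^2.
#' @param threshold optional explicit threshold (skips Otsu).
#' @return a `domain_set`: relabelled label image (contiguous positive
#'   integers, background 0), per-domain table (area um^2, centroid um),
#'   boundary polygons (um), and the pixel size. An all-background image
#'   yields an empty (not an error) `domain_set`.
#' @export
segment_domains <- function(image, pixel_size, min_area_um2 = 3, threshold = NULL) {
  if (any(image < 0, na.rm = TRUE)) stopf("magnitude image must be non-negative")
  rng <- range(image, finite = TRUE)
  empty <- function() structure(list(
    labels = matrix(0L, nrow(image), ncol(image)),
    domains = data.frame(label = integer(0), area_um2 = numeric(0),
                         cx = numeric(0), cy = numeric(0)),
    boundaries = list(), pixel_size = pixel_size), class = "domain_set")
  if (!is.finite(rng[1]) || rng[2] <= rng[1]) return(empty())
  image[!is.finite(image)] <- rng[1]   # out-of-footprint pixels -> background
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  if (is.null(threshold)) threshold <- EBImage::otsu(norm, range = c(0, 1))
  bin <- norm > threshold
  lab <- EBImage::bwlabel(EBImage::Image(bin))
  lab <- round(EBImage::imageData(lab))
  counts <- table(lab[lab > 0])
  keep <- as.integer(names(counts))[counts * pixel_size^2 >= min_area_um2]
  if (!length(keep)) return(empty())
  out <- matrix(0L, nrow(image), ncol(image))
  bnd <- list()
  tab <- data.frame(label = seq_along(keep), area_um2 = NA_real_,
                    cx = NA_real_, cy = NA_real_)
  for (i in seq_along(keep)) {
    px <- lab == keep[i]
    out[px] <- i
    idx <- which(px, arr.ind = TRUE)
    tab$area_um2[i] <- nrow(idx) * pixel_size^2
    tab$cx[i] <- (mean(idx[, 1]) - 1) * pixel_size
    tab$cy[i] <- (mean(idx[, 2]) - 1) * pixel_size
    oc <- EBImage::ocontour(EBImage::Image(px))
    bnd[[i]] <- if (length(oc)) oc[[1]] * pixel_size else NULL
  }
  structure(list(labels = out, domains = tab, boundaries = bnd,
                 pixel_size = pixel_size), class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cat(sprintf("<domain_set> %d domain(s), coverage %.1f%%\n",
              nrow(x$domains), 100 * mean(x$labels > 0)))
  invisible(x)
}

#' Mean complex spectra inside, outside and across the whole image
#'
#' @param stack a `spectral_stack` (or complex array with `omega` attribute)
#'   co-registered with the labels.
#' @param domains a `domain_set`.
#' @param mask optional logical map restricting the valid pixels.
#' @return list with `omega`, complex `inside`, `outside`, `total` spectra,
#'   `coverage` (fraction of valid pixels inside domains), and logical
#'   `absent` flags for empty regions. `total` equals the coverage-weighted
#'   combination of inside and outside.
#' @export
mean_spectra <- function(stack, domains, mask = NULL) {
  if (inherits(stack, "spectral_stack")) { arr <- stack$data; omega <- stack$omega }
  else { arr <- stack; omega <- attr(stack, "omega") }
  nx <- dim(arr)[1]; ny <- dim(arr)[2]; nw <- dim(arr)[3]
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  inside <- domains$labels > 0 & mask
  outside <- domains$labels == 0 & mask
  am <- arr; dim(am) <- c(nx * ny, nw)
  mean_or_na <- function(sel) if (any(sel)) colMeans(am[sel, , drop = FALSE]) else
    rep(NA_complex_, nw)
  cov <- sum(inside) / max(sum(mask), 1)
  structure(list(omega = omega, inside = mean_or_na(inside),
                 outside = mean_or_na(outside), total = mean_or_na(mask),
                 coverage = cov,
                 absent = c(inside = !any(inside), outside = !any(outside))),
            class = "mean_spectra")
}

#' Coverage, relative density and orientational order of the domains
#'
#' Relative DPPC density is read from the in-domain mean of the
#' band-integrated out-of-plane (0-fold) CH3 magnitude (the out-of-plane
#' response per molecule is taken orientation-invariant across samples);
#' the in-plane order scale from the in-domain mean of `2|F1|/|F0|` over the
#' CH3 windows. Both are relative (arbitrary-unit) quantities meant for
#' between-sample comparisons via [compare_composition()].
#'
#' @param components an `azimuthal_components`.
#' @param domains a `domain_set`.
#' @param model `spectral_model` defining the CH3 integration windows.
#' @param noise_floor pixels with `|F0|` CH3 magnitude at or below this are
#'   excluded from the order ratio; domains with no usable pixel get `NA`.
#' @return a `domain_composition`: per-domain table (`rho_rel`, `s_rel`,
#'   area), overall coverage, mean in-domain density, outside density and
#'   DPPC excess `(rho_in - rho_out)/rho_out`.
#' @export
estimate_density_order <- function(components, domains, model = default_band_table(),
                                   noise_floor = 0) {
  m0 <- integrate_band_magnitude(components, model, component = "F0")$CH3
  m1 <- integrate_band_magnitude(components, model, component = "F1")$CH3
  ok <- components$mask
  lab <- domains$labels
  tab <- domains$domains
  tab$rho_rel <- NA_real_; tab$s_rel <- NA_real_
  for (i in seq_len(nrow(tab))) {
    px <- lab == tab$label[i] & ok
    tab$rho_rel[i] <- mean(m0[px])
    use <- px & m0 > noise_floor
    tab$s_rel[i] <- if (any(use)) mean(2 * m1[use] / m0[use]) else NA_real_
  }
  inside <- lab > 0 & ok
  outside <- lab == 0 & ok
  rho_in <- if (any(inside)) mean(m0[inside]) else NA_real_
  rho_out <- if (any(outside)) mean(m0[outside]) else NA_real_
  use <- inside & m0 > noise_floor
  s_in <- if (any(use)) mean(2 * m1[use] / m0[use]) else NA_real_
  structure(list(domains = tab,
                 coverage = sum(inside) / max(sum(ok), 1),
                 rho_in = rho_in, rho_out = rho_out, s_in = s_in,
                 dppc_excess = (rho_in - rho_out) / rho_out),
            class = "domain_composition")
}

#' Percent differences in composition between two samples
#'
#' @param a,b `domain_composition` objects (reference `a`).
#' @return list of percent differences `(b - a)/a * 100` for density, order
#'   and DPPC excess, plus the coverage difference in percentage points.
#' @export
compare_composition <- function(a, b) {
  pct <- function(x, y) (y / x - 1) * 100
  list(density_pct = pct(a$rho_in, b$rho_in),
       order_pct = pct(a$s_in, b$s_in),
       excess_pct = pct(a$dppc_excess, b$dppc_excess),
       coverage_points = 100 * (b$coverage - a$coverage))
}

#' Wrap-aware iso-direction contours of a director field
#'
#' For each level the zero crossings of `sin(theta - level)` restricted to
#' `cos(theta - level) > 0` are traced (so only true crossings of the level,
#' not of level + 180, are kept), giving the phase contour lines connecting
#' locations of equal molecular direction.
#'
#' @param field a `director_field`.
#' @param levels direction levels, degrees.
#' @param mask optional logical map restricting the traced region.
#' @return list (one entry per level) of lists of polyline data.frames
#'   `(x_um, y_um)`. If the field is effectively uniform the result is empty
#'   with attribute `degenerate = TRUE`.
#' @export
phase_contours <- function(field, levels = seq(0, 330, by = 30), mask = NULL) {
  if (is.null(mask)) mask <- field$mask
  th <- field$theta
  ok <- mask & is.finite(th)
  vals <- th[ok]
  # degenerate: circular spread below a tenth of a degree
  R <- Mod(mean(exp(1i * deg2rad(vals))))
  if (!length(vals) || sqrt(pmax(0, -2 * log(pmin(R, 1)))) * 180 / pi < 0.1) {
    out <- stats::setNames(vector("list", length(levels)), as.character(levels))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  xs <- (seq_len(nrow(th)) - 1) * field$pixel_size
  ys <- (seq_len(ncol(th)) - 1) * field$pixel_size
  out <- lapply(levels, function(lv) {
    s <- sin(deg2rad(th - lv))
    s[!ok] <- NA
    cl <- grDevices::contourLines(x = xs, y = ys, z = s, levels = 0)
    polys <- list()
    for (seg in cl) {
      ix <- pmin(pmax(round(seg$x / field$pixel_size) + 1, 1), nrow(th))
      iy <- pmin(pmax(round(seg$y / field$pixel_size) + 1, 1), ncol(th))
      keep <- ok[cbind(ix, iy)] &
        cos(deg2rad(th[cbind(ix, iy)] - lv)) > 0
      # split the polyline at dropped vertices
      r <- rle(keep)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (g in which(r$values & r$lengths >= 2)) {
        polys[[length(polys) + 1]] <-
          data.frame(x_um = seg$x[starts[g]:ends[g]],
                     y_um = seg$y[starts[g]:ends[g]])
      }
    }
    polys
  })
  stats::setNames(out, as.character(levels))
}

# --- texture fitting ---------------------------------------------------------

# circular residual: weighted mean of 1 - cos(theta_obs - theta_model)
circ_resid <- function(theta_obs, theta_model, w) {
  1 - sum(w * cos(deg2rad(theta_obs - theta_model))) / sum(w)
}

# best offset beta and residual for given angle-free part base (deg)
best_offset <- function(theta_obs, base, w) {
  z <- sum(w * exp(1i * deg2rad(theta_obs - base)))
  beta <- wrap_deg(rad2deg(Arg(z)))
  list(beta = beta, resid = 1 - Mod(z) / sum(w))
}

fit_linear_texture <- function(xo, yo, th, w) {
  obj <- function(g) best_offset(th, g[1] * xo + g[2] * yo, w)$resid
  # initial gradient from finite-difference circular slopes
  est_slope <- function(co) {
    o <- order(co)
    dd <- circ_diff_deg(th[o][-1], th[o][-length(o)])
    dc <- diff(co[o])
    ok <- dc > 1e-9
    if (!any(ok)) 0 else stats::median(dd[ok] / dc[ok])
  }
  inits <- list(c(0, 0), c(est_slope(xo), est_slope(yo)))
  best <- NULL
  for (g0 in inits) {
    op <- stats::optim(g0, obj, method = "Nelder-Mead",
                       control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || op$value < best$value) best <- op
  }
  bo <- best_offset(th, best$par[1] * xo + best$par[2] * yo, w)
  list(family = "linear", g = best$par, beta = bo$beta, resid = bo$resid)
}

# boojum family (k = 1): theta = psi + beta + q r. Coarse centre (and q) grid
# search with the offset solved in closed form, then Nelder-Mead refinement.
fit_boojum_texture <- function(xo, yo, th, w, spiral = TRUE,
                               margin_factor = 1.5, q_max = 6) {
  bb_x <- range(xo); bb_y <- range(yo)
  diam <- max(diff(bb_x), diff(bb_y))
  margin <- margin_factor * diam
  step <- max(diam / 8, 1e-6)
  cxs <- seq(bb_x[1] - margin, bb_x[2] + margin, by = step)
  cys <- seq(bb_y[1] - margin, bb_y[2] + margin, by = step)
  qs <- if (spiral) seq(-q_max, q_max, by = 0.25) else 0
  eth <- exp(1i * deg2rad(th))
  wsum <- sum(w)
  best <- list(val = Inf)
  for (cx in cxs) for (cy in cys) {
    dx <- xo - cx; dy <- yo - cy
    r <- sqrt(dx^2 + dy^2)
    if (any(r < 1e-9)) next
    base <- w * eth * exp(-1i * atan2(dy, dx))
    if (length(qs) > 1) {
      resz <- Mod(crossprod(exp(-1i * deg2rad(outer(r, qs))), base))
      kbest <- which.max(resz)
      val <- 1 - resz[kbest] / wsum
      qb <- qs[kbest]
    } else {
      val <- 1 - Mod(sum(base)) / wsum
      qb <- 0
    }
    if (val < best$val) best <- list(val = val, cx = cx, cy = cy, q = qb)
  }
  obj <- function(p) {
    dx <- xo - p[1]; dy <- yo - p[2]
    r <- sqrt(dx^2 + dy^2)
    if (any(r < 1e-9)) return(2)
    q <- if (spiral) p[3] else 0
    base <- rad2deg(atan2(dy, dx)) + q * r
    best_offset(th, base, w)$resid
  }
  p0 <- c(best$cx, best$cy, if (spiral) best$q)
  op <- stats::optim(p0, obj, method = "Nelder-Mead",
                     control = list(maxit = 800, reltol = 1e-12))
  cx <- op$par[1]; cy <- op$par[2]; q <- if (spiral) op$par[3] else 0
  dx <- xo - cx; dy <- yo - cy
  bo <- best_offset(th, rad2deg(atan2(dy, dx)) + q * sqrt(dx^2 + dy^2), w)
  list(family = "boojum", centre = c(cx, cy), k = 1L, q = q,
       beta = bo$beta, resid = op$value)
}

# magnitude-weighted mean directional derivative of theta along the director
# (deg / um); negative values = clockwise packing curvature under the
# CCW-positive angle convention
curvature_statistic <- function(field, mask = NULL) {
  th <- field$theta; w <- field$magnitude
  ok <- field$mask & is.finite(th)
  if (!is.null(mask)) ok <- ok & mask
  nx <- nrow(th); ny <- ncol(th); h <- field$pixel_size
  ic <- 2:(nx - 1); jc <- 2:(ny - 1)
  dthx <- matrix(NA_real_, nx, ny); dthy <- matrix(NA_real_, nx, ny)
  dthx[ic, ] <- circ_diff_deg(th[ic + 1, ], th[ic - 1, ]) / (2 * h)
  dthy[, jc] <- circ_diff_deg(th[, jc + 1], th[, jc - 1]) / (2 * h)
  okx <- ok & !is.na(dthx); oky <- ok & !is.na(dthy)
  val <- dthx * cos(deg2rad(th)) + dthy * sin(deg2rad(th))
  use <- ok & is.finite(val)
  if (!any(use)) return(NA_real_)
  sum(w[use] * val[use]) / sum(w[use])
}

#' Fit and classify the mesoscale director texture of a domain
#'
#' Fits the linear (parallel-contour) and boojum (k = 1) families by
#' circular least squares (minimising the weighted mean of
#' `1 - cos(theta_obs - theta_model)`); the boojum centre is searched on a
#' grid extending `margin_factor` domain diameters beyond the mask (virtual
#' centres allowed) and refined. Model selection uses a parsimony margin:
#' the boojum family must beat the linear residual by at least
#' `parsimony` (relative) and `abs_margin` (absolute), and likewise the free
#' pitch (spiral) must beat the pitch-free radial fit, so flat or radial
#' fields are never called spirals spuriously.
#'
#' Labels: class parallel / radial / spiral; packing curvature CW (negative
#' magnitude-weighted mean of the directional derivative of theta along the
#' director) or ACW; spiral sign `+` if the phase contours wind clockwise
#' moving outward from the centre (pitch q > 0) and `-` otherwise; boojum
#' real if the fitted centre lies inside the domain mask, else virtual.
#'
#' @param field a `director_field`.
#' @param mask logical domain mask (default: the field mask). At least 50
#'   valid pixels are required.
#' @param erode_px erosion radius (pixels) applied to the mask before
#'   fitting: boundary pixels are partial-volume mixtures across the domain
#'   edge (and pick up back-rotation interpolation error), so the rim is
#'   excluded from the circular least squares. Set 0 to disable. If erosion
#'   leaves fewer than 50 pixels the full mask is used instead.
#' @param parsimony relative residual margin for accepting a more complex
#'   model.
#' @param abs_margin absolute residual margin (on the `1 - cos` scale); the
#'   default sits well above the chance improvement an extra parameter buys
#'   on pure noise (about residual/n_pixels) but below any real curvature
#'   signal, so degenerate near-zero residual ties never promote a spiral.
#' @param margin_factor centre-search margin in domain diameters.
#' @param reject_threshold residual above which the texture is labelled
#'   `"unclassified"` rather than silently guessed.
#' @return a `texture_fit` with the fitted parameters, per-family residuals
#'   (deg RMS equivalents in `resid_deg`) and the class labels.
#' @export
fit_and_classify_texture <- function(field, mask = NULL, parsimony = 0.10,
                                     abs_margin = 1e-5, margin_factor = 1.5,
                                     reject_threshold = 0.3, erode_px = 1.5) {
  if (is.null(mask)) mask <- field$mask
  ok <- mask & field$mask & is.finite(field$theta)
  if (sum(ok) < 50) stopf("need at least 50 valid pixels to classify (got %d)", sum(ok))
  if (erode_px > 0) {
    er <- erode_mask(mask, erode_px) & field$mask & is.finite(field$theta)
    if (sum(er) >= 50) ok <- er
  }
  idx <- which(ok, arr.ind = TRUE)
  xo <- (idx[, 1] - 1) * field$pixel_size
  yo <- (idx[, 2] - 1) * field$pixel_size
  th <- field$theta[ok]
  w <- field$magnitude[ok]
  if (all(w <= 0)) w <- rep(1, length(th))

  flin <- fit_linear_texture(xo, yo, th, w)
  frad <- fit_boojum_texture(xo, yo, th, w, spiral = FALSE,
                             margin_factor = margin_factor)
  fspi <- fit_boojum_texture(xo, yo, th, w, spiral = TRUE,
                             margin_factor = margin_factor)
  better <- function(candidate, incumbent)
    (incumbent - candidate) >= pmax(parsimony * incumbent, abs_margin)

  spiral_wins <- better(fspi$resid, frad$resid)
  boo <- if (spiral_wins) fspi else frad
  use_boojum <- better(boo$resid, flin$resid)
  fit <- if (use_boojum) boo else flin
  class <- if (!use_boojum) "parallel" else if (spiral_wins) "spiral" else "radial"
  if (fit$resid > reject_threshold) class <- "unclassified"

  curv <- curvature_statistic(field, ok)
  curvature <- if (!is.finite(curv) || class == "unclassified") NA_character_
               else if (curv < 0) "CW" else "ACW"
  spiral_sign <- if (class == "spiral") (if (fit$q > 0) "+" else "-") else "n/a"
  boojum <- if (class %in% c("radial", "spiral")) {
    ctr_px <- round(fit$centre / field$pixel_size) + 1
    inside <- ctr_px[1] >= 1 && ctr_px[1] <= nrow(mask) &&
      ctr_px[2] >= 1 && ctr_px[2] <= ncol(mask) &&
      isTRUE(mask[ctr_px[1], ctr_px[2]])
    if (inside) "real" else "virtual"
  } else "n/a"

  structure(list(
    family = if (class == "parallel") "linear" else "boojum",
    centre_um = if (use_boojum) fit$centre else c(NA_real_, NA_real_),
    k = if (use_boojum) 1L else 0L,
    beta = fit$beta,
    q = if (use_boojum) fit$q else 0,
    g = if (!use_boojum) flin$g else c(NA_real_, NA_real_),
    resid = fit$resid,
    resid_deg = rad2deg(sqrt(2 * pmax(fit$resid, 0))),
    resids = c(linear = flin$resid, radial = frad$resid, spiral = fspi$resid),
    curvature_stat = curv,
    class = class, curvature = curvature,
    spiral_sign = spiral_sign, boojum = boojum,
    n_px = sum(ok)), class = "texture_fit")
}

#' @export
print.texture_fit <- function(x, ...) {
  cat(sprintf("<texture_fit> class %s, curvature %s, spiral sign %s, boojum %s (residual %.3g, ~%.2f deg RMS, %d px)\n",
              x$class, x$curvature, x$spiral_sign, x$boojum,
              x$resid, x$resid_deg, x$n_px))
  invisible(x)
}
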