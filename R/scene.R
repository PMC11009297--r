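# Synthetic scenes: condensed-domain layouts, parametric director textures,
# density/order maps, and mirror reflection. The generator is the ground
# truth against which the whole analysis pipeline is verified.

#' Parametric director texture
#'
#' Two families reproduce the observed texture classes:
#' * boojum family: `theta(r, psi) = k*psi + beta + q*r` about a centre
#'   (winding `k` in -1/0/1, offset `beta` in degrees, pitch `q` in degrees
#'   per micrometre). `k = 1, q = 0` gives radial phase contours (concentric
#'   circles of lipids); `k = 1, q != 0` gives spirals whose sign follows `q`.
#' * linear family: `theta(x, y) = beta + g . (x, y)` (parallel contours).
#'
#' @param family `"boojum"` or `"linear"`.
#' @param centre texture centre `(x, y)` in micrometres (boojum family).
#' @param k integer winding, one of -1, 0, 1.
#' @param beta angular offset, degrees.
#' @param q radial pitch, degrees per micrometre (boojum family).
#' @param g gradient 2-vector, degrees per micrometre (linear family).
#' @return a `texture_model`.
#' @export
texture_model <- function(family = c("boojum", "linear"), centre = c(0, 0),
                          k = 1L, beta = 0, q = 0, g = c(0, 0)) {
  family <- match.arg(family)
  if (family == "boojum") {
    if (!k %in% c(-1L, 0L, 1L)) stopf("winding k must be -1, 0 or 1")
    g <- c(0, 0)
  } else {
    k <- 0L; q <- 0
    if (length(g) != 2) stopf("linear family needs a 2-vector gradient g")
  }
  structure(list(family = family, centre = as.numeric(centre), k = as.integer(k),
                 beta = beta, q = q, g = as.numeric(g)),
            class = "texture_model")
}

# evaluate theta (degrees, wrapped) at arbitrary coordinates; NA at the exact
# boojum centre where the angle is undefined
texture_theta <- function(texture, x, y) {
  if (texture$family == "linear") {
    wrap_deg(texture$beta + texture$g[1] * x + texture$g[2] * y)
  } else {
    dx <- x - texture$centre[1]; dy <- y - texture$centre[2]
    r <- sqrt(dx^2 + dy^2)
    th <- wrap_deg(texture$k * rad2deg(atan2(dy, dx)) + texture$beta + texture$q * r)
    th[r == 0] <- NA_real_
    th
  }
}

#' Place non-overlapping circular domains on a grid
#'
#' Rejection-samples `n_domains` disc centres so that discs stay inside the
#' field of view and keep a pairwise edge gap of at least `min_gap_um`.
#' Deterministic for a given seed.
#'
#' @param grid a [grid_spec()].
#' @param n_domains number of discs (0 gives an all-background mask).
#' @param radius_um disc radius, micrometres (default 5: ca. 10 um diameter).
#' @param min_gap_um minimum edge-to-edge gap, micrometres.
#' @param seed RNG seed.
#' @param max_tries placement attempts before giving up.
#' @return a `domain_layout`: integer label image (`0` = background) plus a
#'   centres table.
#' @export
make_domain_layout <- function(grid, n_domains, radius_um = 5, min_gap_um = 2,
                               seed = 1, max_tries = 500 * max(1, n_domains)) {
  cc <- grid_coords(grid)
  lim_x <- range(cc$x); lim_y <- range(cc$y)
  if (n_domains > 0 &&
      (diff(lim_x) < 2 * radius_um || diff(lim_y) < 2 * radius_um))
    stopf("a disc of radius %g um does not fit a %g x %g um grid",
          radius_um, diff(lim_x), diff(lim_y))
  centres <- matrix(numeric(0), ncol = 2)
  if (n_domains > 0) {
    withr::with_seed(seed, {
      tries <- 0
      while (nrow(centres) < n_domains) {
        tries <- tries + 1
        if (tries > max_tries)
          stopf("could not place %d discs of radius %g um with gap %g um on a %g x %g um grid after %d tries",
                n_domains, radius_um, min_gap_um, diff(lim_x), diff(lim_y), max_tries)
        cand <- c(stats::runif(1, lim_x[1] + radius_um, lim_x[2] - radius_um),
                  stats::runif(1, lim_y[1] + radius_um, lim_y[2] - radius_um))
        if (nrow(centres) == 0 ||
            all(sqrt(rowSums(sweep(centres, 2, cand)^2)) >= 2 * radius_um + min_gap_um))
          centres <- rbind(centres, cand)
      }
    })
  }
  pts <- grid_points(grid)
  labels <- matrix(0L, grid$nx, grid$ny)
  if (n_domains > 0) {
    for (l in seq_len(nrow(centres))) {
      inside <- (pts$x - centres[l, 1])^2 + (pts$y - centres[l, 2])^2 <= radius_um^2
      labels[inside] <- l
    }
  }
  tab <- data.frame(label = seq_len(n_domains),
                    cx = if (n_domains) centres[, 1] else numeric(0),
                    cy = if (n_domains) centres[, 2] else numeric(0),
                    radius = rep(radius_um, n_domains))
  structure(list(labels = labels, domains = tab, grid = grid, seed = seed),
            class = "domain_layout")
}

#' Per-pixel director field
#'
#' @param theta direction map, degrees in `[0, 360)`; `NA` where undefined.
#' @param magnitude non-negative magnitude map.
#' @param mask logical validity map.
#' @param pixel_size micrometres per pixel.
#' @param confidence optional per-pixel confidence in `[0, 1]`.
#' @return a `director_field`.
#' @export
director_field <- function(theta, magnitude, mask, pixel_size, confidence = NULL) {
  stopifnot(all(dim(theta) == dim(magnitude)), all(dim(theta) == dim(mask)))
  theta <- wrap_deg(theta)
  theta[!mask] <- NA_real_
  magnitude[!mask] <- 0
  structure(list(theta = theta, magnitude = magnitude, mask = mask,
                 pixel_size = pixel_size, confidence = confidence),
            class = "director_field")
}

#' @export
print.director_field <- function(x, ...) {
  cat(sprintf("<director_field> %d x %d px, %.3g um/px, %d valid px\n",
              nrow(x$theta), ncol(x$theta), x$pixel_size, sum(x$mask)))
  invisible(x)
}

#' Rasterise a texture model into a director field
#'
#' @param texture a [texture_model()].
#' @param grid a [grid_spec()].
#' @param mask logical map of pixels carrying the texture (default: all).
#' @return a [director_field()] with unit magnitude inside the mask; the
#'   exact boojum-centre pixel (angle undefined) is masked out.
#' @export
make_texture_field <- function(texture, grid, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, grid$nx, grid$ny)
  pts <- grid_points(grid)
  th <- matrix(texture_theta(texture, pts$x, pts$y), grid$nx, grid$ny)
  mask <- mask & is.finite(th)
  director_field(th, matrix(as.numeric(mask), grid$nx, grid$ny), mask, grid$pixel_size)
}

#' Ground-truth synthetic scene
#'
#' Combines a domain layout with per-domain textures, a relative molecular
#' density map rho (condensed domains denser than the surrounding
#' liquid-expanded phase, which still contributes signal) and an in-plane
#' orientational order map s (0 outside the domains: the LE phase carries no
#' net in-plane direction).
#'
#' @param grid a [grid_spec()].
#' @param layout a [make_domain_layout()] result.
#' @param textures a single [texture_model()] or a list, one per domain.
#' @param rho_domain relative density inside each domain (scalar or vector).
#' @param rho_background relative density of the LE background.
#' @param order_domain in-plane order s in `[0, 1]` inside each domain.
#' @param seed stored generator seed.
#' @return a `synthetic_scene` holding both the parametric description and
#'   rasterised `labels`, `rho`, `s`, `theta` maps.
#' @export
synthetic_scene <- function(grid, layout, textures,
                            rho_domain = 1, rho_background = 0.35,
                            order_domain = 0.8, seed = 1) {
  nd <- nrow(layout$domains)
  if (inherits(textures, "texture_model")) textures <- rep(list(textures), nd)
  if (length(textures) != nd) stopf("need one texture per domain (%d)", nd)
  rho_domain <- rep_len(rho_domain, nd)
  order_domain <- rep_len(order_domain, nd)
  if (any(rho_domain < 0) || rho_background < 0) stopf("densities must be >= 0")
  if (any(order_domain < 0 | order_domain > 1)) stopf("order must lie in [0, 1]")
  dom <- layout$domains
  dom$rho <- rho_domain
  dom$s <- order_domain

  pts <- grid_points(grid)
  labels <- layout$labels
  rho <- matrix(rho_background, grid$nx, grid$ny)
  s <- matrix(0, grid$nx, grid$ny)
  theta <- matrix(NA_real_, grid$nx, grid$ny)
  for (l in seq_len(nd)) {
    px <- labels == l
    rho[px] <- rho_domain[l]
    s[px] <- order_domain[l]
    theta[px] <- texture_theta(textures[[l]], pts$x[px], pts$y[px])
  }
  s[is.na(theta)] <- 0
  structure(list(grid = grid, domains = dom, textures = textures,
                 labels = labels, rho = rho, s = s, theta = theta,
                 rho_background = rho_background, seed = seed,
                 mirrored = FALSE),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d domain(s), coverage %.1f%%%s\n",
              x$grid$nx, x$grid$ny, nrow(x$domains),
              100 * mean(x$labels > 0), if (x$mirrored) ", mirrored" else ""))
  invisible(x)
}

# Parametric evaluation of the scene at arbitrary sample-frame coordinates:
# used by the forward model so that rotated views are sampled analytically
# rather than by interpolating rasters. Points outside every disc (or outside
# the grid) take the background values.
scene_eval <- function(scene, x, y) {
  n <- length(x)
  rho <- rep(scene$rho_background, n)
  s <- numeric(n)
  theta <- rep(NA_real_, n)
  dom <- scene$domains
  for (l in seq_len(nrow(dom))) {
    inside <- (x - dom$cx[l])^2 + (y - dom$cy[l])^2 <= dom$radius[l]^2
    if (!any(inside)) next
    rho[inside] <- dom$rho[l]
    th <- texture_theta(scene$textures[[l]], x[inside], y[inside])
    theta[inside] <- th
    s[inside] <- ifelse(is.finite(th), dom$s[l], 0)
  }
  list(rho = rho, s = s, theta = theta)
}

#' Mirror a scene or director field
#'
#' Reflects the geometry about the grid's horizontal midline (y -> y_max - y)
#' and maps every direction theta -> (360 - theta) mod 360, producing the
#' enantiomeric counterpart: clockwise textures become anti-clockwise and
#' spiral signs flip. Applying it twice is the identity.
#'
#' @param x a `synthetic_scene` or `director_field`.
#' @return object of the same class, mirrored.
#' @export
mirror_scene <- function(x) UseMethod("mirror_scene")

# reflect a texture about the line y = ymax/2 combined with theta -> -theta
mirror_texture <- function(tx, y_max) {
  if (tx$family == "boojum") {
    texture_model("boojum", centre = c(tx$centre[1], y_max - tx$centre[2]),
                  k = tx$k, beta = wrap_deg(-tx$beta), q = -tx$q)
  } else {
    texture_model("linear", beta = wrap_deg(-tx$beta - tx$g[2] * y_max),
                  g = c(-tx$g[1], tx$g[2]))
  }
}

flip_y <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

#' @export
mirror_scene.synthetic_scene <- function(x) {
  y_max <- (x$grid$ny - 1) * x$grid$pixel_size
  dom <- x$domains
  dom$cy <- y_max - dom$cy
  theta <- flip_y(x$theta)
  out <- x
  out$domains <- dom
  out$textures <- lapply(x$textures, mirror_texture, y_max = y_max)
  out$labels <- flip_y(x$labels)
  out$rho <- flip_y(x$rho)
  out$s <- flip_y(x$s)
  out$theta <- wrap_deg(360 - theta)
  out$mirrored <- !x$mirrored
  out
}

#' @export
mirror_scene.director_field <- function(x) {
  th <- flip_y(x$theta)
  director_field(wrap_deg(360 - th), flip_y(x$magnitude), flip_y(x$mask),
                 x$pixel_size,
                 confidence = if (!is.null(x$confidence)) flip_y(x$confidence))
}

#' Gaussian detection noise
#'
#' Adds zero-mean Gaussian noise: to each real sample of an interferogram
#' stack, or independently to the real and imaginary quadratures of each
#' spectral sample. For a rotation series the single seed drives one RNG
#' stream across all frames, so the result is deterministic per seed.
#'
#' @param x an `interferogram_stack`, `spectral_stack` or `rotation_series`.
#' @param sigma noise standard deviation (per quadrature), >= 0.
#' @param seed RNG seed.
#' @return object of the same class with noise added.
#' @export
add_detection_noise <- function(x, sigma, seed = 1) {
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(x)
  withr::with_seed(seed, add_noise_(x, sigma))
}

add_noise_ <- function(x, sigma) UseMethod("add_noise_")

#' @export
add_noise_.interferogram_stack <- function(x, sigma) {
  x$data <- x$data + stats::rnorm(length(x$data), 0, sigma)
  x
}

#' @export
add_noise_.spectral_stack <- function(x, sigma) {
  n <- length(x$data)
  x$data <- x$data + complex(real = stats::rnorm(n, 0, sigma),
                             imaginary = stats::rnorm(n, 0, sigma))
  x
}

#' @export
add_noise_.rotation_series <- function(x, sigma) {
  x$stacks <- lapply(x$stacks, add_noise_, sigma = sigma)
  x
}
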