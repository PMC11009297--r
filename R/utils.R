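# Internal helpers: circular statistics, phase handling, bilinear resampling.

# speed of light in cm per fs; converts wavenumber (cm^-1) * time (fs) to cycles
.c_cm_fs <- 2.99792458e-5

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to [0, 360)
#' @param x angles in degrees.
#' @return wrapped angles in degrees.
#' @export
wrap_deg <- function(x) x %% 360

#' Signed circular difference a - b in (-180, 180]
#' @param a,b angles in degrees.
#' @return signed differences in degrees.
#' @export
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Weighted circular mean of angles in degrees
#' @param theta angles in degrees.
#' @param w non-negative weights (default equal).
#' @return mean direction in [0, 360), or `NA` if the resultant vanishes.
#' @export
circ_mean_deg <- function(theta, w = NULL) {
  ok <- is.finite(theta)
  if (!is.null(w)) ok <- ok & is.finite(w)
  theta <- theta[ok]
  if (!length(theta)) return(NA_real_)
  w <- if (is.null(w)) rep(1, length(theta)) else w[ok]
  z <- sum(w * exp(1i * deg2rad(theta)))
  if (Mod(z) < 1e-300) return(NA_real_)
  wrap_deg(rad2deg(Arg(z)))
}

#' Circular root-mean-square error between two angle sets
#' @param a,b angles in degrees (recycled).
#' @param w optional weights.
#' @return RMS of the signed circular differences, degrees.
#' @export
circ_rmse_deg <- function(a, b, w = NULL) {
  d <- circ_diff_deg(a, b)
  ok <- is.finite(d)
  d <- d[ok]
  if (!length(d)) return(NA_real_)
  if (is.null(w)) sqrt(mean(d^2)) else {
    w <- w[ok]
    sqrt(sum(w * d^2) / sum(w))
  }
}

# 1D phase unwrap (radians)
unwrap_rad <- function(p) {
  if (length(p) < 2) return(p)
  dp <- diff(p)
  jump <- -round(dp / (2 * pi)) * 2 * pi
  p + c(0, cumsum(jump))
}

# Precompute bilinear interpolation weights for sampling a (nx, ny) image at
# continuous pixel coordinates (xp, yp), 0-based (pixel centres at integers).
# Returns index/weight vectors; out-of-footprint points get ok = FALSE.
bilinear_weights <- function(nx, ny, xp, yp) {
  x0 <- floor(xp); y0 <- floor(yp)
  fx <- xp - x0;  fy <- yp - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nx - 2 + (fx == 0) & y0 <= ny - 2 + (fy == 0)
  # clamp so index arithmetic stays in range; masked by ok afterwards
  x0c <- pmin(pmax(x0, 0), nx - 1)
  y0c <- pmin(pmax(y0, 0), ny - 1)
  x1c <- pmin(x0c + 1, nx - 1)
  y1c <- pmin(y0c + 1, ny - 1)
  list(
    i00 = x0c + 1 + nx * y0c, i10 = x1c + 1 + nx * y0c,
    i01 = x0c + 1 + nx * y1c, i11 = x1c + 1 + nx * y1c,
    w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
    w01 = (1 - fx) * fy,       w11 = fx * fy,
    ok = ok
  )
}

# Apply precomputed bilinear weights to one image plane (vector or matrix).
apply_bilinear <- function(bw, img, fill = NA) {
  v <- bw$w00 * img[bw$i00] + bw$w10 * img[bw$i10] +
       bw$w01 * img[bw$i01] + bw$w11 * img[bw$i11]
  v[!bw$ok] <- fill
  v
}

# stop() with sprintf formatting
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Erode a logical mask by a pixel radius
#'
#' Keeps pixels whose full disc neighbourhood of radius `r_px` lies inside
#' the mask. Used to separate a domain's interior from the one-pixel rim
#' whose back-rotation interpolation support straddles the boundary.
#'
#' @param mask logical matrix.
#' @param r_px erosion radius in pixels.
#' @return eroded logical matrix.
#' @export
erode_mask <- function(mask, r_px = 1.5) {
  r <- ceiling(r_px)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= r_px^2, , drop = FALSE]
  nx <- nrow(mask); ny <- ncol(mask)
  out <- mask
  for (i in seq_len(nrow(off))) {
    sh <- matrix(FALSE, nx, ny)
    xr <- max(1, 1 + off$dx[i]):min(nx, nx + off$dx[i])
    yr <- max(1, 1 + off$dy[i]):min(ny, ny + off$dy[i])
    sh[xr, yr] <- mask[xr - off$dx[i], yr - off$dy[i]]
    out <- out & sh
  }
  out
}
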