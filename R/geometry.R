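# Image lattice and optical geometry.
#
# Conventions used throughout the package: x rightward, y upward, angles in
# degrees measured counter-clockwise from +x; sample rotation positive
# counter-clockwise; image arrays are indexed [ix, iy] with pixel centres at
# 0-based integer coordinates, so pixel (ix, iy) sits at
# x = (ix - 1) * pixel_size, y = (iy - 1) * pixel_size (micrometres).

#' Image lattice specification
#'
#' @param nx,ny pixel counts (at least 16).
#' @param pixel_size pixel pitch in micrometres.
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(nx = 128L, ny = 128L, pixel_size = 0.5) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 16L || ny < 16L) stopf("grid must be at least 16 x 16 pixels (got %d x %d)", nx, ny)
  if (!is.numeric(pixel_size) || pixel_size <= 0) stopf("pixel_size must be > 0")
  structure(list(nx = nx, ny = ny, pixel_size = pixel_size, origin = "lower-left"),
            class = "grid_spec")
}

# physical coordinates (um) of pixel centres
grid_coords <- function(grid) {
  list(x = (seq_len(grid$nx) - 1) * grid$pixel_size,
       y = (seq_len(grid$ny) - 1) * grid$pixel_size)
}

# all pixel-centre coordinates as vectors of length nx*ny (column-major)
grid_points <- function(grid) {
  cc <- grid_coords(grid)
  list(x = rep(cc$x, times = grid$ny), y = rep(cc$y, each = grid$nx))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d px, %.3g um/px (%.3g x %.3g um)\n",
              x$nx, x$ny, x$pixel_size,
              (x$nx - 1) * x$pixel_size, (x$ny - 1) * x$pixel_size))
  invisible(x)
}

#' Optical geometry of the vSFG microscope
#'
#' Holds the beam incidence angle (from the surface normal), the PPP
#' polarisation tag, the sample rotation angles of the azimuthal series and
#' the IR envelope parameters.
#'
#' @param incidence_deg incidence angle in degrees, strictly between 0 and 90.
#' @param polarization polarisation combination tag.
#' @param rotation_angles_deg sample rotation angles; at least 3 distinct
#'   angles uniformly covering 360 degrees.
#' @param ir_centre_cm,ir_fwhm_cm IR envelope centre and FWHM in cm^-1.
#' @return an `optical_geometry` object.
#' @export
optical_geometry <- function(incidence_deg = 36,
                             polarization = "PPP",
                             rotation_angles_deg = seq(0, 300, by = 60),
                             ir_centre_cm = 1e7 / 3450,
                             ir_fwhm_cm = 300) {
  if (incidence_deg <= 0 || incidence_deg >= 90)
    stopf("incidence_deg must be strictly between 0 and 90 (got %g)", incidence_deg)
  ang <- sort(unique(wrap_deg(rotation_angles_deg)))
  if (length(ang) < 3) stopf("need at least 3 distinct rotation angles")
  step <- diff(ang)
  if (max(abs(step - step[1])) > 1e-6 || abs(ang[1] + 360 - ang[length(ang)] - step[1]) > 1e-6)
    stopf("rotation angles must uniformly cover 360 degrees")
  structure(list(incidence_deg = incidence_deg, polarization = polarization,
                 rotation_angles_deg = ang,
                 ir_centre_cm = ir_centre_cm, ir_fwhm_cm = ir_fwhm_cm),
            class = "optical_geometry")
}

#' In-plane and out-of-plane field fractions of the P-polarised beam
#'
#' For incidence angle \eqn{\vartheta} from the surface normal the P-polarised
#' driving field projects onto the surface plane and the surface normal as
#' \eqn{f_{ip} = \cos\vartheta/(\cos\vartheta+\sin\vartheta)} and
#' \eqn{f_{op} = \sin\vartheta/(\cos\vartheta+\sin\vartheta)}; the two always
#' sum to one. At the instrument's 36 degrees this gives 0.579 / 0.421.
#'
#' @param incidence_deg incidence angle in degrees, in `[0, 90]`.
#' @return named numeric vector `c(f_ip = , f_op = )`.
#' @export
field_fractions <- function(incidence_deg) {
  if (!is.numeric(incidence_deg) || length(incidence_deg) != 1 ||
      !is.finite(incidence_deg) || incidence_deg < 0 || incidence_deg > 90)
    stopf("incidence_deg must be a single angle in [0, 90] degrees")
  ct <- cos(deg2rad(incidence_deg)); st <- sin(deg2rad(incidence_deg))
  c(f_ip = ct / (ct + st), f_op = st / (ct + st))
}
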