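# Forward model: synthesises the lab-frame rotation series of complex
# spectral cubes and the heterodyne time-domain interferograms the analysis
# pipeline consumes.
#
# Per pixel p, band m and sample rotation phi the emitted susceptibility is
#   chi(w; p, phi) = chi_NR
#     + sum_m L_m(w) * rho(p) * [ f_op*a_op,m + f_ip*s(p)*a_ip,m*cos(d_m(p)+phi) ]
# with L_m the complex Lorentzian, d_m = theta + d_offset_m the sample-frame
# azimuth of the band's in-plane transition dipole, and (f_ip, f_op) the
# field projections of the P-polarised beam. Images are emitted in the lab
# frame: the camera sees the sample rotated by +phi about the rotation
# centre, so the pipeline must back-rotate.

#' Pulse / delay-axis specification for interferogram synthesis
#'
#' @param ir_centre_cm,ir_fwhm_cm IR amplitude-envelope centre and FWHM, cm^-1.
#' @param delay_start_fs,delay_stop_fs,delay_step_fs IR-visible delay axis,
#'   femtoseconds (defaults: 2 fs steps from -300 to 3000 fs).
#' @param lo_amp,lo_phase_deg local-oscillator amplitude and phase.
#' @return a `pulse_spec`.
#' @export
pulse_spec <- function(ir_centre_cm = 1e7 / 3450, ir_fwhm_cm = 300,
                       delay_start_fs = -300, delay_stop_fs = 3000,
                       delay_step_fs = 2, lo_amp = 1, lo_phase_deg = 0) {
  if (delay_step_fs <= 0) stopf("delay_step_fs must be > 0")
  if (delay_stop_fs <= delay_start_fs) stopf("empty delay axis")
  structure(list(ir_centre_cm = ir_centre_cm, ir_fwhm_cm = ir_fwhm_cm,
                 delay_start_fs = delay_start_fs, delay_stop_fs = delay_stop_fs,
                 delay_step_fs = delay_step_fs,
                 lo_amp = lo_amp, lo_phase_deg = lo_phase_deg),
            class = "pulse_spec")
}

delay_axis <- function(pulse) seq(pulse$delay_start_fs, pulse$delay_stop_fs,
                                  by = pulse$delay_step_fs)

# Gaussian amplitude envelope of the IR pulse
pulse_envelope <- function(pulse, omega)
  exp(-4 * log(2) * ((omega - pulse$ir_centre_cm) / pulse$ir_fwhm_cm)^2)

#' Frequency grid commensurate with a delay axis
#'
#' The DFT of an N-sample delay axis with step dt resolves frequencies in
#' multiples of 1/(c N dt). Synthesising spectra on this grid makes the
#' simulate -> FFT round trip exact up to windowing.
#'
#' @param pulse a [pulse_spec()].
#' @param range frequency window `c(min, max)`, cm^-1.
#' @return frequency grid, cm^-1 (attribute `"delta"` holds the spacing).
#' @export
dft_omega_grid <- function(pulse, range = c(2700, 3100)) {
  nt <- length(delay_axis(pulse))
  dw <- 1 / (.c_cm_fs * nt * pulse$delay_step_fs)
  k <- seq(ceiling(range[1] / dw), floor(range[2] / dw))
  structure(k * dw, delta = dw)
}

#' Default analysis frequency grid (2700-3100 cm^-1, 5 cm^-1 steps)
#' @return numeric frequency grid, cm^-1.
#' @export
default_omega_grid <- function() seq(2700, 3100, by = 5)

new_spectral_stack <- function(data, omega, frame, rotation, pixel_size,
                               flags = "raw") {
  if (is.unsorted(omega, strictly = TRUE)) stopf("omega axis must be strictly increasing")
  structure(list(data = data, omega = omega, frame = frame,
                 rotation = rotation, pixel_size = pixel_size, flags = flags),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  cat(sprintf("<spectral_stack> %d x %d px, %d frequencies (%.0f-%.0f cm^-1), frame %s, rotation %g deg, flags: %s\n",
              dim(x$data)[1], dim(x$data)[2], length(x$omega),
              min(x$omega), max(x$omega), x$frame, x$rotation,
              paste(x$flags, collapse = " > ")))
  invisible(x)
}

#' Synthesise the lab-frame rotation series of complex spectral cubes
#'
#' For each rotation angle the scene is sampled analytically at the
#' back-rotated coordinates of every lab pixel (the camera lattice is fixed;
#' the sample turns), the per-band in-plane dipoles pick up the +phi lab
#' azimuth, and the result is assembled from the band table.
#'
#' @param scene a [synthetic_scene()].
#' @param model a [spectral_model()] (band table empty -> error).
#' @param geometry an [optical_geometry()] (rotation angles, incidence).
#' @param omega frequency grid, cm^-1.
#' @param rotation_centre_um rotation-stage centre in sample coordinates
#'   (default: centre of the field of view).
#' @return a `rotation_series`: per-angle lab-frame `spectral_stack`s plus
#'   the angle list and rotation centre.
#' @export
synthesize_chi2_series <- function(scene, model = default_band_table(),
                                   geometry = optical_geometry(),
                                   omega = default_omega_grid(),
                                   rotation_centre_um = NULL) {
  b <- model$bands
  if (nrow(b) == 0) stopf("band table is empty")
  grid <- scene$grid
  if (is.null(rotation_centre_um))
    rotation_centre_um <- c((grid$nx - 1) / 2, (grid$ny - 1) / 2) * grid$pixel_size
  ff <- field_fractions(geometry$incidence_deg)
  pts <- grid_points(grid)
  L <- sapply(seq_len(nrow(b)), function(m) lorentz(omega, b$omega0[m], b$gamma[m]))
  angles <- geometry$rotation_angles_deg
  stacks <- vector("list", length(angles))
  for (j in seq_along(angles)) {
    phi <- angles[j]
    cphi <- cos(deg2rad(-phi)); sphi <- sin(deg2rad(-phi))
    dx <- pts$x - rotation_centre_um[1]; dy <- pts$y - rotation_centre_um[2]
    ux <- rotation_centre_um[1] + cphi * dx - sphi * dy
    uy <- rotation_centre_um[2] + sphi * dx + cphi * dy
    ev <- scene_eval(scene, ux, uy)
    base <- deg2rad(ev$theta + phi)
    cb <- cos(base); sb <- sin(base)
    cb[!is.finite(cb)] <- 0; sb[!is.finite(sb)] <- 0
    coef <- matrix(0, length(ev$rho), nrow(b))
    for (m in seq_len(nrow(b))) {
      dlt <- deg2rad(b$d_offset[m])
      cosd <- cb * cos(dlt) - sb * sin(dlt)
      coef[, m] <- ff["f_op"] * b$a_op[m] * ev$rho +
        ff["f_ip"] * b$a_ip[m] * ev$rho * ev$s * cosd
    }
    cube <- coef %*% t(L)  # (npix x n_omega), complex
    cube <- cube + model$chi_nr
    dim(cube) <- c(grid$nx, grid$ny, length(omega))
    stacks[[j]] <- new_spectral_stack(cube, omega, frame = "lab", rotation = phi,
                                      pixel_size = grid$pixel_size)
  }
  structure(list(stacks = stacks, angles = angles,
                 rotation_centre_um = rotation_centre_um,
                 grid = grid, omega = omega),
            class = "rotation_series")
}

#' @export
print.rotation_series <- function(x, ...) {
  cat(sprintf("<rotation_series> %d angles (%s deg), %d x %d px, %d frequencies\n",
              length(x$angles), paste(round(x$angles), collapse = ", "),
              x$grid$nx, x$grid$ny, length(x$omega)))
  invisible(x)
}

new_interferogram_stack <- function(data, delay_fs, rotation, pixel_size,
                                    meta = list()) {
  structure(list(data = data, delay_fs = delay_fs, rotation = rotation,
                 pixel_size = pixel_size, meta = meta),
            class = "interferogram_stack")
}

#' @export
print.interferogram_stack <- function(x, ...) {
  cat(sprintf("<interferogram_stack> %d x %d px, %d delays (%g..%g fs), rotation %g deg\n",
              dim(x$data)[1], dim(x$data)[2], length(x$delay_fs),
              min(x$delay_fs), max(x$delay_fs), x$rotation))
  invisible(x)
}

# heterodyne cross-term traces from a complex spectral cube
traces_from_chi <- function(chi_mat, omega, pulse, delay_fs) {
  G <- pulse_envelope(pulse, omega)
  LO <- pulse$lo_amp * exp(1i * deg2rad(pulse$lo_phase_deg))
  A <- sweep(chi_mat, 2, G * Conj(LO), `*`)
  E <- exp(-1i * 2 * pi * .c_cm_fs * outer(omega, delay_fs))
  Re(A %*% E)
}

#' Synthesise heterodyne interferogram stacks from a rotation series
#'
#' Each pixel's real trace is the heterodyne cross-term
#' `Re[sum_w chi(w) G(w) LO* exp(-i 2 pi c w t)]` with Gaussian IR amplitude
#' envelope `G`; homodyne terms are omitted (balanced imaging isolates the
#' cross-term, which is the analysed quantity). If the envelope does not
#' cover the spectral grid a warning string is recorded in the metadata.
#'
#' @param series a [synthesize_chi2_series()] result.
#' @param pulse a [pulse_spec()].
#' @return list of `interferogram_stack`, one per rotation angle, with the
#'   series geometry attached as attributes.
#' @export
synthesize_interferograms <- function(series, pulse = pulse_spec()) {
  t_fs <- delay_axis(pulse)
  omega <- series$omega
  meta <- list()
  gmin <- min(pulse_envelope(pulse, range(omega)))
  if (gmin < 0.01)
    meta$warning <- sprintf("IR envelope covers band range poorly (min relative amplitude %.2g)", gmin)
  out <- lapply(series$stacks, function(st) {
    chi <- st$data
    dim(chi) <- c(prod(dim(chi)[1:2]), dim(chi)[3])
    tr <- traces_from_chi(chi, omega, pulse, t_fs)
    dim(tr) <- c(dim(st$data)[1:2], length(t_fs))
    new_interferogram_stack(tr, t_fs, st$rotation, st$pixel_size, meta)
  })
  attr(out, "angles") <- series$angles
  attr(out, "rotation_centre_um") <- series$rotation_centre_um
  attr(out, "pulse") <- pulse
  out
}

#' Synthesise the z-cut quartz reference measurement
#'
#' A spatially uniform, spectrally flat (constant real chi) reference
#' recorded on a reduced delay axis (default -300..300 fs), giving the
#' coarser frequency grid used to normalise the sample spectra.
#'
#' @param pulse_reduced a [pulse_spec()] with the reduced scanning range.
#' @param grid a [grid_spec()] (the reference shares the camera lattice).
#' @param chi_q constant real quartz susceptibility.
#' @param sample_pulse optional sample [pulse_spec()]; if supplied, the
#'   reduced range must lie strictly inside the sample range.
#' @return an `interferogram_stack`.
#' @export
synthesize_reference <- function(pulse_reduced = pulse_spec(delay_start_fs = -300,
                                                            delay_stop_fs = 300),
                                 grid = grid_spec(), chi_q = 1,
                                 sample_pulse = NULL) {
  if (!is.null(sample_pulse) &&
      !(pulse_reduced$delay_start_fs >= sample_pulse$delay_start_fs &&
        pulse_reduced$delay_stop_fs < sample_pulse$delay_stop_fs))
    stopf("reference delay range must lie inside the sample range")
  t_fs <- delay_axis(pulse_reduced)
  # synthesis grid: commensurate bins covering the envelope
  cover <- pulse_reduced$ir_centre_cm + c(-1, 1) * 1.5 * pulse_reduced$ir_fwhm_cm
  cover[1] <- max(cover[1], 100)
  omega <- dft_omega_grid(pulse_reduced, cover)
  chi <- matrix(chi_q + 0i, 1, length(omega))
  tr1 <- traces_from_chi(chi, omega, pulse_reduced, t_fs)
  tr <- array(rep(tr1, each = grid$nx * grid$ny),
              c(grid$nx, grid$ny, length(t_fs)))
  new_interferogram_stack(tr, t_fs, rotation = 0, grid$pixel_size,
                          meta = list(reference = TRUE, chi_q = chi_q))
}
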