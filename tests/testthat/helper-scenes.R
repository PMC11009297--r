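# Shared fixtures: small ground-truth scenes and the standard analysis chain.

# a single disc domain at a chosen position, carrying one texture
single_disc_scene <- function(texture, grid = grid_spec(64, 64, 0.5),
                              centre = c(16, 16), radius = 5,
                              rho_domain = 1, rho_background = 0.35,
                              order_domain = 0.8) {
  pts <- grid_points(grid)
  labels <- matrix(0L, grid$nx, grid$ny)
  labels[(pts$x - centre[1])^2 + (pts$y - centre[2])^2 <= radius^2] <- 1L
  layout <- structure(list(labels = labels,
                           domains = data.frame(label = 1L, cx = centre[1],
                                                cy = centre[2], radius = radius),
                           grid = grid, seed = 0L), class = "domain_layout")
  synthetic_scene(grid, layout, texture, rho_domain = rho_domain,
                  rho_background = rho_background, order_domain = order_domain)
}

# noise sd for a given amplitude SNR: peak in-plane CH3 SS spectral
# amplitude inside the domains divided by SNR (per quadrature)
snr_sigma <- function(snr, model = default_band_table(), rho = 1, s = 0.8,
                      incidence = 36) {
  b <- model$bands
  i <- which(b$name == "ch3_ss")
  ff <- field_fractions(incidence)
  rho * s * ff[["f_ip"]] * abs(b$a_ip[i]) / b$gamma[i] / snr
}

# scene -> baseline-corrected series -> aligned -> components (+ director)
analyse_scene <- function(scene, model = default_band_table(), sigma = 0,
                          noise_seed = 1, estimate_centre = FALSE,
                          omega = default_omega_grid(),
                          geometry = optical_geometry(), svd = FALSE) {
  ser <- synthesize_chi2_series(scene, model, geometry, omega)
  if (sigma > 0) ser <- add_detection_noise(ser, sigma, seed = noise_seed)
  ser$stacks <- lapply(ser$stacks, correct_dark_baseline)
  al <- align_rotation_series(ser, estimate_centre = estimate_centre)
  comp <- azimuthal_decompose(al)
  dir <- if (svd) extract_director(svd_decompose(al), model)
         else extract_director(comp, model)
  list(series = ser, aligned = al, components = comp, director = dir)
}

# classification truth labels as a single string
truth_string <- function(scene) {
  tr <- attr(scene, "truth")
  paste(tr$class, tr$curvature, tr$spiral_sign, tr$boojum)
}

fit_string <- function(fit) paste(fit$class, fit$curvature, fit$spiral_sign, fit$boojum)
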