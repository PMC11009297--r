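# Spectral model: CH2/CH3 band table, complex Lorentzian evaluation,
# bounded least-squares deconvolution, band-integrated magnitude images.
#
# Line-shape convention: chi(w) = chi_NR + sum_m A_m / (w_m - w - i*Gamma_m),
# so a positive amplitude gives a positive-Im (absorptive) peak at w_m. Both
# denominator signs exist in the SFG literature; this one matches the
# SS-positive / AS-negative appearance of upright methyl groups.

#' A single Lorentzian vibrational band
#'
#' @param name unique band name.
#' @param omega0 resonance frequency, cm^-1.
#' @param gamma half-width Gamma, cm^-1 (> 0).
#' @param a_op signed out-of-plane amplitude.
#' @param a_ip signed in-plane amplitude.
#' @param assignment one of "CH3", "CH2", "unassigned".
#' @param d_offset in-plane transition-dipole azimuth of the band relative to
#'   the defined molecular direction, degrees. The CH3 symmetric stretch
#'   dipole points exactly opposite the molecular direction, hence 180 for
#'   CH3 bands by default.
#' @return one-row data.frame describing the band.
#' @export
lorentzian_band <- function(name, omega0, gamma, a_op = 0, a_ip = 0,
                            assignment = c("unassigned", "CH3", "CH2"),
                            d_offset = 0) {
  assignment <- match.arg(assignment)
  if (gamma <= 0) stopf("band '%s': gamma must be > 0", name)
  data.frame(name = name, omega0 = omega0, gamma = gamma,
             a_op = a_op, a_ip = a_ip, assignment = assignment,
             d_offset = d_offset, stringsAsFactors = FALSE)
}

#' Spectral model: a band table plus a non-resonant offset
#'
#' @param bands data.frame of bands (rows from [lorentzian_band()]).
#' @param chi_nr complex non-resonant offset.
#' @return a `spectral_model` object.
#' @export
spectral_model <- function(bands, chi_nr = 0 + 0i) {
  stopifnot(is.data.frame(bands))
  need <- c("name", "omega0", "gamma", "a_op", "a_ip", "assignment", "d_offset")
  if (!all(need %in% names(bands))) stopf("band table lacks columns: %s",
                                          paste(setdiff(need, names(bands)), collapse = ", "))
  if (anyDuplicated(bands$name)) stopf("band names must be unique")
  if (any(bands$gamma <= 0)) stopf("all gamma must be > 0")
  bands <- bands[order(bands$omega0), , drop = FALSE]
  rownames(bands) <- NULL
  structure(list(bands = bands, chi_nr = as.complex(chi_nr)),
            class = "spectral_model")
}

#' Canonical C-H stretch band table for DPPC monolayers
#'
#' Bands at 2845 (CH2 SS), 2875 (CH3 SS), 2905 (CH2 FR), 2935 (CH3 FR) and
#' 2965 (CH3 AS) cm^-1, plus two weak unassigned bands. Symmetric stretches
#' and Fermi resonances carry positive amplitudes, antisymmetric stretches
#' negative ones; CH3 groups dominate out-of-plane, CH2 groups in-plane, as
#' expected for upright, well-packed acyl tails. Half-widths and the
#' unassigned band centres are generator conventions, not measured values.
#'
#' @param chi_nr complex non-resonant offset.
#' @return a `spectral_model`.
#' @export
default_band_table <- function(chi_nr = 0.02 + 0i) {
  bands <- rbind(
    lorentzian_band("unassigned1", 2830, 9, a_op = 0.08, a_ip = 0.00, assignment = "unassigned"),
    lorentzian_band("ch2_ss",      2845, 6, a_op = 0.15, a_ip = 0.80, assignment = "CH2", d_offset = 0),
    lorentzian_band("ch3_ss",      2875, 6, a_op = 1.00, a_ip = 0.35, assignment = "CH3", d_offset = 180),
    lorentzian_band("ch2_fr",      2905, 7, a_op = 0.10, a_ip = 0.50, assignment = "CH2", d_offset = 0),
    lorentzian_band("unassigned2", 2920, 9, a_op = 0.06, a_ip = 0.00, assignment = "unassigned"),
    lorentzian_band("ch3_fr",      2935, 7, a_op = 0.80, a_ip = 0.30, assignment = "CH3", d_offset = 180),
    lorentzian_band("ch3_as",      2965, 8, a_op = -0.70, a_ip = -0.45, assignment = "CH3", d_offset = 180)
  )
  spectral_model(bands, chi_nr = chi_nr)
}

# complex Lorentzian 1/(w0 - w - i*Gamma)
lorentz <- function(omega, omega0, gamma) 1 / (omega0 - omega - 1i * gamma)

#' Evaluate a spectral model on a frequency grid
#'
#' @param model a `spectral_model`.
#' @param omega frequency grid, cm^-1.
#' @param amplitudes amplitude set: `"op"`, `"ip"`, or a numeric vector with
#'   one amplitude per band (in the model's band order).
#' @param include_nr include the non-resonant offset.
#' @return complex vector chi(omega).
#' @export
evaluate_model <- function(model, omega, amplitudes = "op", include_nr = TRUE) {
  b <- model$bands
  A <- if (is.character(amplitudes)) {
    switch(match.arg(amplitudes, c("op", "ip")), op = b$a_op, ip = b$a_ip)
  } else {
    stopifnot(length(amplitudes) == nrow(b))
    amplitudes
  }
  chi <- if (include_nr) rep(model$chi_nr, length(omega)) else complex(length(omega))
  for (m in seq_len(nrow(b))) chi <- chi + A[m] * lorentz(omega, b$omega0[m], b$gamma[m])
  chi
}

# Complex in-plane reference spectrum including the per-band dipole azimuth
# offsets: P(w) = sum_m a_ip,m * exp(i d_m) * L_m(w). Under the forward model
# the 1-fold component of an aligned pixel is (rho*s*f_ip/2) * exp(i theta) * P(w),
# so projecting F1 onto P isolates exp(i theta) directly.
inplane_reference <- function(model, omega) {
  b <- model$bands
  P <- complex(length(omega))
  for (m in seq_len(nrow(b)))
    P <- P + b$a_ip[m] * exp(1i * deg2rad(b$d_offset[m])) * lorentz(omega, b$omega0[m], b$gamma[m])
  P
}

#' Bounded Lorentzian deconvolution of a complex spectrum
#'
#' Joint least squares over the real and imaginary parts using
#' Levenberg-Marquardt with box bounds ([minpack.lm::nls.lm]). Frequencies
#' are bounded near their initial estimates (unassigned bands get the wide
#' window 2800-2940 cm^-1). On failure the fit is restarted up to
#' `max_starts` times from jittered frequencies (seeded).
#'
#' @param omega frequency grid, cm^-1.
#' @param spectrum complex spectrum (baseline-corrected).
#' @param init initial `spectral_model` (e.g. [default_band_table()]).
#' @param amplitudes which amplitude column seeds the fit: `"op"` or `"ip"`.
#' @param omega_window allowed deviation of assigned band frequencies, cm^-1.
#' @param gamma_bounds allowed half-width range, cm^-1.
#' @param max_starts jittered restarts on non-convergence.
#' @param seed RNG seed for the jitter.
#' @return fitted `spectral_model`; the chosen amplitude column is updated and
#'   diagnostics (`residual_norm`, `deviance`, `info`) attached as attributes.
#' @export
fit_bands <- function(omega, spectrum, init = default_band_table(),
                      amplitudes = "op", omega_window = 10,
                      gamma_bounds = c(2, 20), max_starts = 3, seed = 1) {
  b <- init$bands
  nb <- nrow(b)
  if (nb == 0) stopf("band table is empty")
  acol <- match.arg(amplitudes, c("op", "ip"))
  a0 <- if (acol == "op") b$a_op else b$a_ip
  unas <- b$assignment == "unassigned"
  lo_w <- ifelse(unas, 2800, b$omega0 - omega_window)
  hi_w <- ifelse(unas, 2940, b$omega0 + omega_window)
  if (any(b$omega0 < lo_w | b$omega0 > hi_w))
    stopf("initial frequencies must lie within their bounds")

  pack <- function(A, W, G, nr) c(A, W, G, Re(nr), Im(nr))
  model_of <- function(p) {
    A <- p[1:nb]; W <- p[nb + 1:nb]; G <- p[2 * nb + 1:nb]
    nr <- complex(real = p[3 * nb + 1], imaginary = p[3 * nb + 2])
    chi <- rep(nr, length(omega))
    for (m in seq_len(nb)) chi <- chi + A[m] * lorentz(omega, W[m], G[m])
    chi
  }
  resid_of <- function(p) {
    d <- model_of(p) - spectrum
    c(Re(d), Im(d))
  }
  lower <- c(rep(-1e3, nb), lo_w, rep(gamma_bounds[1], nb), -10, -10)
  upper <- c(rep(1e3, nb), hi_w, rep(gamma_bounds[2], nb), 10, 10)

  run_fit <- function(W0) {
    minpack.lm::nls.lm(par = pack(a0, W0, b$gamma, init$chi_nr), fn = resid_of,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 400))
  }
  fits <- list()
  withr::with_seed(seed, {
    fits[[1]] <- run_fit(b$omega0)
    k <- 1
    while (k < max_starts && !(fits[[k]]$info %in% 1:4)) {
      k <- k + 1
      jit <- pmin(pmax(b$omega0 + stats::runif(nb, -2, 2), lo_w), hi_w)
      fits[[k]] <- run_fit(jit)
    }
  })
  dev <- vapply(fits, function(f) f$deviance, numeric(1))
  best <- fits[[which.min(dev)]]
  if (!(best$info %in% 1:4))
    stopf("band fit did not converge (residual norm %.3g, info %d)",
          sqrt(best$deviance), best$info)
  p <- best$par
  out <- b
  if (acol == "op") out$a_op <- p[1:nb] else out$a_ip <- p[1:nb]
  out$omega0 <- p[nb + 1:nb]
  out$gamma <- p[2 * nb + 1:nb]
  fitted <- spectral_model(out, chi_nr = complex(real = p[3 * nb + 1],
                                                 imaginary = p[3 * nb + 2]))
  attr(fitted, "residual_norm") <- sqrt(best$deviance)
  attr(fitted, "deviance") <- best$deviance
  attr(fitted, "info") <- best$info
  fitted
}

# frequency windows (omega0 +/- width_factor*gamma) per assignment; errors if
# the CH2 and CH3 windows overlap. Unassigned bands are excluded.
assignment_windows <- function(model, width_factor = 2) {
  b <- model$bands[model$bands$assignment %in% c("CH2", "CH3"), , drop = FALSE]
  win <- lapply(split(b, b$assignment), function(d)
    cbind(lo = d$omega0 - width_factor * d$gamma, hi = d$omega0 + width_factor * d$gamma))
  if (all(c("CH2", "CH3") %in% names(win))) {
    for (i in seq_len(nrow(win$CH2))) for (j in seq_len(nrow(win$CH3))) {
      if (win$CH2[i, "lo"] < win$CH3[j, "hi"] && win$CH3[j, "lo"] < win$CH2[i, "hi"])
        stopf("CH2 and CH3 integration windows overlap; reduce width_factor")
    }
  }
  win
}

#' Band-integrated magnitude images
#'
#' Sums `abs()` (or signed imaginary part) of a complex spectral cube over the
#' CH2 and CH3 frequency windows, yielding one image per assignment.
#'
#' @param x complex array `(nx, ny, n_omega)`, or a `spectral_stack`, or an
#'   `azimuthal_components` field (`F0`/`F1` picked via `component`).
#' @param model `spectral_model` defining the windows.
#' @param mode `"abs"` (default) or `"imag"`.
#' @param width_factor window half-width in units of each band's gamma.
#' @param component for `azimuthal_components` input: `"F0"` or `"F1"`.
#' @return named list of `(nx, ny)` images, one per assignment present.
#' @export
integrate_band_magnitude <- function(x, model, mode = c("abs", "imag"),
                                     width_factor = 2, component = "F0") {
  mode <- match.arg(mode)
  if (inherits(x, "spectral_stack")) {
    arr <- x$data; omega <- x$omega
  } else if (inherits(x, "azimuthal_components")) {
    arr <- x[[component]]; omega <- x$omega
  } else {
    arr <- x; omega <- attr(x, "omega")
    if (is.null(omega)) stopf("supply a spectral_stack/azimuthal_components or an array with an 'omega' attribute")
  }
  win <- assignment_windows(model, width_factor)
  vals <- if (mode == "abs") abs(arr) else Im(arr)
  out <- lapply(win, function(w) {
    sel <- rep(FALSE, length(omega))
    for (i in seq_len(nrow(w))) sel <- sel | (omega >= w[i, "lo"] & omega <= w[i, "hi"])
    if (!any(sel)) return(array(0, dim(arr)[1:2]))
    if (sum(sel) == 1L) vals[, , which(sel)] else
      apply(vals[, , sel, drop = FALSE], c(1, 2), sum)
  })
  out
}
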