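# Image treatment: per-pixel FFT of interferograms to complex spectra,
# quartz-reference normalisation, dark-count / linear-baseline correction.

#' Convert an interferogram stack to a complex spectral stack
#'
#' Per-pixel discrete Fourier transform over the delay axis with the phase
#' referenced to t = 0 (the explicit delay values, including the negative
#' lead-in, enter the transform kernel), evaluated on the frequency grid
#' commensurate with the delay axis and truncated to `roi`. The forward
#' kernel is `exp(-i w t)`, so recovery uses `exp(+i w t)`; a purely
#' absorptive resonance with positive amplitude then yields a positive
#' imaginary Lorentzian peak.
#'
#' @param stack an `interferogram_stack` (uniform delay axis required).
#' @param roi frequency window `c(min, max)`, cm^-1.
#' @param omega optional explicit frequency grid; defaults to the DFT grid
#'   of the delay axis inside `roi`.
#' @return a raw, lab-frame `spectral_stack`.
#' @export
interferogram_to_spectrum <- function(stack, roi = c(2700, 3100), omega = NULL) {
  t_fs <- stack$delay_fs
  dt <- diff(t_fs)
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
    stopf("delay axis must be uniform")
  nt <- length(t_fs)
  if (is.null(omega)) {
    dw <- 1 / (.c_cm_fs * nt * dt[1])
    omega <- seq(ceiling(roi[1] / dw), floor(roi[2] / dw)) * dw
  }
  d <- stack$data
  np <- prod(dim(d)[1:2])
  dim(d) <- c(np, nt)
  E <- exp(1i * 2 * pi * .c_cm_fs * outer(t_fs, omega))
  spec <- (2 / nt) * (d %*% E)
  dim(spec) <- c(dim(stack$data)[1:2], length(omega))
  new_spectral_stack(spec, omega, frame = "lab", rotation = stack$rotation,
                     pixel_size = stack$pixel_size, flags = "raw")
}

# reduce a (possibly image-shaped) reference stack to one mean spectrum
reference_spectrum <- function(reference) {
  if (inherits(reference, "spectral_stack")) {
    spec <- apply(reference$data, 3, mean)
    list(omega = reference$omega, spec = spec)
  } else if (is.list(reference) && !is.null(reference$omega) && !is.null(reference$spec)) {
    reference
  } else stopf("reference must be a spectral_stack or list(omega=, spec=)")
}

#' Normalise a spectral stack by the quartz reference
#'
#' Complex division after interpolating the coarse reference onto the sample
#' frequency grid. Magnitude and unwrapped phase are interpolated separately
#' (cubic splines), which avoids the amplitude dips that linear complex
#' interpolation produces between coarse points. A quartz-like sample ends
#' up with unit magnitude and zero phase.
#'
#' @param sample a `spectral_stack`.
#' @param reference a spatially uniform reference `spectral_stack` (typically
#'   from [synthesize_reference()] + [interferogram_to_spectrum()]).
#' @param min_mag_frac error threshold: the interpolated reference magnitude
#'   must exceed this fraction of its maximum everywhere in the sample roi.
#' @return normalised `spectral_stack`; the interpolated reference curve is
#'   attached as attribute `"reference_interp"` so normalisation can be
#'   undone exactly.
#' @export
normalize_reference <- function(sample, reference, min_mag_frac = 0.05) {
  ref <- reference_spectrum(reference)
  if (min(sample$omega) < min(ref$omega) || max(sample$omega) > max(ref$omega))
    stopf("reference grid (%.0f-%.0f cm^-1) does not cover the sample roi (%.0f-%.0f cm^-1)",
          min(ref$omega), max(ref$omega), min(sample$omega), max(sample$omega))
  mag <- stats::spline(ref$omega, Mod(ref$spec), xout = sample$omega)$y
  ph <- stats::spline(ref$omega, unwrap_rad(Arg(ref$spec)), xout = sample$omega)$y
  refc <- mag * exp(1i * ph)
  bad <- which(mag < min_mag_frac * max(mag))
  if (length(bad))
    stopf("reference magnitude below threshold at %.1f cm^-1", sample$omega[bad[1]])
  out <- sample
  out$data <- sweep(sample$data, 3, refc, `/`)
  out$flags <- unique(c(sample$flags, "referenced"))
  attr(out, "reference_interp") <- refc
  out
}

#' Dark-count and linear-baseline correction
#'
#' Per pixel, the median complex offset over the anchor windows is removed,
#' then a complex straight line fitted over the anchor frequencies is
#' subtracted across the whole roi. Anchors default to the regions below
#' 2800 and above 3050 cm^-1, outside the resonant C-H bands; if a band
#' table is supplied, anchors overlapping any band core (omega0 +/- 2 gamma)
#' raise an error. The operation is idempotent.
#'
#' @param stack a `spectral_stack`.
#' @param anchors list of `c(lo, hi)` frequency windows, cm^-1.
#' @param model optional `spectral_model` used to verify anchor placement.
#' @return baseline-corrected `spectral_stack`.
#' @export
correct_dark_baseline <- function(stack,
                                  anchors = list(c(-Inf, 2800), c(3050, Inf)),
                                  model = NULL) {
  omega <- stack$omega
  sel <- anchor_selection(omega, anchors)
  if (sum(sel) < 3) stopf("need at least 3 anchor frequencies in the roi")
  if (!is.null(model)) {
    for (m in seq_len(nrow(model$bands))) {
      core <- model$bands$omega0[m] + c(-2, 2) * model$bands$gamma[m]
      for (w in anchors)
        if (w[1] < core[2] && core[1] < w[2])
          stopf("anchor window [%g, %g] overlaps band '%s'", w[1], w[2],
                model$bands$name[m])
    }
  }
  d <- stack$data
  np <- prod(dim(d)[1:2]); nw <- length(omega)
  dim(d) <- c(np, nw)
  d <- baseline_apply(d, omega, sel)
  dim(d) <- dim(stack$data)
  out <- stack
  out$data <- d
  out$flags <- unique(c(stack$flags, "baseline-corrected"))
  out$anchors <- anchors
  out
}

# shared dark + linear-baseline operator: rows of d are pixels, sel marks the
# anchor bins. Median complex offset, then a least-squares complex line over
# the anchors, subtracted across the whole row.
baseline_apply <- function(d, omega, sel) {
  d <- matrix(d, ncol = length(omega))
  dark <- complex(real = apply(Re(d[, sel, drop = FALSE]), 1, stats::median),
                  imaginary = apply(Im(d[, sel, drop = FALSE]), 1, stats::median))
  d <- d - dark
  X <- cbind(1, omega[sel])
  H <- solve(crossprod(X), t(X))             # 2 x n_anchor
  coefs <- d[, sel, drop = FALSE] %*% t(H)   # rows x 2
  d - coefs %*% rbind(1, omega)
}

anchor_selection <- function(omega, anchors) {
  sel <- rep(FALSE, length(omega))
  for (w in anchors) sel <- sel | (omega >= w[1] & omega <= w[2])
  sel
}

#' Full image treatment for one rotation angle
#'
#' Convenience chain: FFT, quartz normalisation, baseline correction.
#'
#' @param stack an `interferogram_stack`.
#' @param reference reference `spectral_stack` (coarse grid).
#' @param roi frequency window, cm^-1.
#' @param ... passed to [correct_dark_baseline()].
#' @return treated `spectral_stack`.
#' @export
preprocess_stack <- function(stack, reference, roi = c(2700, 3100), ...) {
  sp <- interferogram_to_spectrum(stack, roi = roi)
  sp <- normalize_reference(sp, reference)
  correct_dark_baseline(sp, ...)
}
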