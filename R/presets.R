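# Canonical texture presets and single-domain benchmark scenes.
#
# The four depicted texture classes map onto the parametric families as
#   parallel contours : linear family, non-zero gradient
#   radial contours   : boojum k = 1, q = 0 (beta = 90: concentric circles)
#   spiral            : boojum k = 1, q != 0 (sign of q = spiral sign)
# Packing curvature (CW/ACW) follows the sign of the mean directional
# derivative of theta along the director; the parameter choices below give
# unambiguous curvature over a single ~10 um domain.

#' Canonical texture preset
#'
#' @param class `"parallel"`, `"radial"` or `"spiral"`.
#' @param curvature `"CW"` or `"ACW"` packing curvature.
#' @param boojum for spirals: `"virtual"` (centre outside the domain, the
#'   homochiral configuration) or `"real"` (centre inside, the heterochiral
#'   one). Radial textures have their centre inside (real).
#' @param domain_centre domain centre (um) used to anchor the texture.
#' @param radius_um domain radius (um).
#' @param centre_dir_deg direction (deg) from the domain centre at which a
#'   virtual spiral centre is placed.
#' @return a [texture_model()] with attribute `"truth"` carrying the
#'   expected classification labels.
#' @export
texture_preset <- function(class = c("spiral", "radial", "parallel"),
                           curvature = c("CW", "ACW"),
                           boojum = c("virtual", "real"),
                           domain_centre = c(16, 16), radius_um = 5,
                           centre_dir_deg = 0) {
  class <- match.arg(class); curvature <- match.arg(curvature)
  boojum <- match.arg(boojum)
  if (class == "parallel") {
    gmag <- 1.2
    tx <- texture_model("linear", beta = 0,
                        g = if (curvature == "CW") c(-gmag, 0) else c(gmag, 0))
    truth <- list(class = "parallel", curvature = curvature,
                  spiral_sign = "n/a", boojum = "n/a")
    return(structure(tx, truth = truth))
  }
  if (class == "radial") {
    beta <- if (curvature == "ACW") 90 else -90
    tx <- texture_model("boojum", centre = domain_centre, k = 1L, beta = beta, q = 0)
    truth <- list(class = "radial", curvature = curvature,
                  spiral_sign = "n/a", boojum = "real")
    return(structure(tx, truth = truth))
  }
  # spiral: CW pairs with q > 0 ('+'), ACW with q < 0 ('-') in these presets
  # (the mirror image of one is the other)
  q <- if (curvature == "CW") 2 else -2
  beta <- if (curvature == "CW") -90 else 90
  centre <- if (boojum == "real") domain_centre else
    domain_centre + 3 * radius_um * c(cos(deg2rad(centre_dir_deg)),
                                      sin(deg2rad(centre_dir_deg)))
  tx <- texture_model("boojum", centre = centre, k = 1L, beta = beta, q = q)
  truth <- list(class = "spiral", curvature = curvature,
                spiral_sign = if (q > 0) "+" else "-", boojum = boojum)
  structure(tx, truth = truth)
}

#' Single-domain benchmark scene for texture classification
#'
#' One ~10 um condensed domain on a 64 x 64 px, 0.5 um/px field, carrying a
#' preset texture. The seed jitters the domain position, the angular offset
#' and (for spirals) the pitch and the direction of a virtual centre, so
#' repeated scenes are distinct members of the same class.
#'
#' @param class,curvature,boojum passed to [texture_preset()].
#' @param seed RNG seed for the jitter.
#' @param grid a [grid_spec()].
#' @param radius_um domain radius, um.
#' @return a [synthetic_scene()] with attribute `"truth"` (expected labels).
#' @export
make_classification_scene <- function(class = "spiral", curvature = "CW",
                                      boojum = "virtual", seed = 1,
                                      grid = grid_spec(64, 64, 0.5),
                                      radius_um = 5) {
  fov <- c((grid$nx - 1), (grid$ny - 1)) * grid$pixel_size
  jit <- withr::with_seed(seed, list(
    dc = fov / 2 + stats::runif(2, -2, 2),
    dbeta = stats::runif(1, -15, 15),
    qfac = stats::runif(1, 0.8, 1.2),
    dir = stats::runif(1, 0, 360)))
  tx <- texture_preset(class, curvature, boojum, domain_centre = jit$dc,
                       radius_um = radius_um, centre_dir_deg = jit$dir)
  truth <- attr(tx, "truth")
  if (tx$family == "boojum") {
    tx2 <- texture_model("boojum", centre = tx$centre, k = tx$k,
                         beta = wrap_deg(tx$beta + jit$dbeta), q = tx$q * jit$qfac)
  } else {
    tx2 <- texture_model("linear", beta = wrap_deg(tx$beta + jit$dbeta), g = tx$g)
  }
  layout <- list(labels = NULL, domains = data.frame(
    label = 1L, cx = jit$dc[1], cy = jit$dc[2], radius = radius_um),
    grid = grid, seed = seed)
  pts <- grid_points(grid)
  labels <- matrix(0L, grid$nx, grid$ny)
  labels[(pts$x - jit$dc[1])^2 + (pts$y - jit$dc[2])^2 <= radius_um^2] <- 1L
  layout$labels <- labels
  class(layout) <- "domain_layout"
  sc <- synthetic_scene(grid, layout, tx2, seed = seed)
  structure(sc, truth = truth)
}
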