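# Spatial mitotic-rate reduction from alternating-electric-field intensity
# maps (tumour-treating-fields style): a cubic dose-response converts field
# intensity (V/cm) to relative proliferation, which multiplies tau per voxel.

#' Dose-response curve: field intensity to relative proliferation
#'
#' A third-degree polynomial `f(E) = c0 + c1 E + c2 E^2 + c3 E^3` mapping
#' field intensity (V/cm) to the fraction of untreated proliferation, valid
#' on `range`; outputs are clamped to `[0, 1]` and `f(0)` must equal 1
#' (untreated cells proliferate at the full rate).  The default
#' coefficients are a synthetic monotone-decreasing curve through
#' (0, 1), (1, 0.70), (2, 0.30), (3, 0.10) — a stand-in with the documented
#' qualitative shape of published glioma-line dose-response data, which are
#' not distributed with this package.
#'
#' @param coef Numeric c(c0, c1, c2, c3).
#' @param range Valid intensity range in V/cm (intensities outside are
#'   clamped to the ends).
#' @return A `response_curve` object.
#' @export
response_curve <- function(coef = NULL, range = c(0, 3)) {
  if (is.null(coef)) {
    # exact cubic through the four synthetic anchor points
    E <- c(0, 1, 2, 3); f <- c(1, 0.70, 0.30, 0.10)
    coef <- solve(outer(E, 0:3, `^`), f)
  }
  if (length(coef) != 4) stop("coef must have 4 elements (c0..c3)", call. = FALSE)
  f0 <- coef[1]
  if (abs(f0 - 1) > 1e-6)
    stop("curve(0) must equal 1 (untreated proliferation)", call. = FALSE)
  structure(list(coef = as.numeric(coef), range = as.numeric(range)),
            class = "response_curve")
}

eval_curve <- function(curve, E) {
  E <- pmin(pmax(E, curve$range[1]), curve$range[2])
  cf <- curve$coef
  val <- cf[1] + cf[2] * E + cf[3] * E^2 + cf[4] * E^3
  pmin(pmax(val, 0), 1)
}

#' Combine transducer-array orientations
#'
#' The effective field intensity at each voxel is the maximum of the fields
#' generated by the left-right and front-back arrays.
#'
#' @param field_lr,field_fb Intensity maps (matrices, V/cm) on one grid.
#' @return Voxelwise maximum intensity map.
#' @export
combine_orientations <- function(field_lr, field_fb) {
  if (!same_shape(field_lr, field_fb)) stop("intensity maps differ in shape", call. = FALSE)
  pmax(field_lr, field_fb)
}

#' Convert an intensity map to a mitotic-rate reduction field
#'
#' Evaluates the dose-response curve at each voxel and clamps the result to
#' `[0, 1]`; the resulting factor multiplies the mitotic rate `tau`
#' pointwise (1 = untreated, 0 = complete mitotic arrest).
#'
#' @param intensity Intensity map (matrix, V/cm).
#' @param curve A [response_curve()].
#' @return An efficacy field (matrix of factors in `[0, 1]`).
#' @export
intensity_to_reduction <- function(intensity, curve) {
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  out <- eval_curve(curve, intensity)
  dim(out) <- dim(intensity)
  out
}

#' Synthetic electric-field intensity map
#'
#' Stand-in for head-model field computations (out of scope): a smooth
#' positive intensity field supported on the brain mask.  `"gradient"`
#' increases monotonically along the column axis; `"bifocal"` is the sum of
#' two Gaussian hot spots (two local maxima), emulating two transducer
#' array foci.
#'
#' @param geom A [brain_geometry()].
#' @param seed Integer seed (bifocal spot placement jitter).
#' @param pattern `"gradient"` or `"bifocal"`.
#' @param max_intensity Peak intensity (V/cm, default 2.5).
#' @return Intensity map (matrix, V/cm), zero outside the mask.
#' @export
synthetic_intensity_field <- function(geom, seed = 1L,
                                      pattern = c("gradient", "bifocal"),
                                      max_intensity = 2.5) {
  pattern <- match.arg(pattern)
  nr <- geom$shape[1]; nc <- geom$shape[2]
  out <- with_seed(seed, {
    if (pattern == "gradient") {
      base <- matrix(seq(0.05, 1, length.out = nc), nr, nc, byrow = TRUE)
    } else {
      ctr <- which(geom$mask, arr.ind = TRUE)
      mid <- colMeans(ctr)
      # two foci separated along the column axis; rows jittered by seed
      f1 <- c(mid[1] + runif(1, -0.08, 0.08) * nr, mid[2] - 0.25 * nc)
      f2 <- c(mid[1] + runif(1, -0.08, 0.08) * nr, mid[2] + 0.25 * nc)
      rr <- matrix(seq_len(nr), nr, nc); cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      g <- function(f) exp(-(((rr - f[1]) / (0.18 * nr))^2 + ((cc - f[2]) / (0.12 * nc))^2))
      0.15 + g(f1) + g(f2)
    }
  })
  out <- out / max(out) * max_intensity
  out * geom$mask
}

#' Build a spatially varying mitotic-rate field
#'
#' Multiplies the scalar rate `tau` by an efficacy field (see
#' [intensity_to_reduction()]); the result can be set as `params$tau` or
#' passed as `intervention = list(type = "rate_reduction", field = ...)`.
#'
#' @param tau Scalar maximal mitotic rate (/hr).
#' @param efficacy_field Matrix of factors in `[0, 1]`.
#' @param geom A [brain_geometry()] (shape check).
#' @return Matrix `tau * factor`.
#' @export
tau_field <- function(tau, efficacy_field, geom) {
  if (!same_shape(efficacy_field, geom$mask))
    stop("efficacy field shape does not match the geometry", call. = FALSE)
  if (any(efficacy_field < 0 | efficacy_field > 1))
    stop("efficacy factors must lie in [0, 1]", call. = FALSE)
  tau * efficacy_field
}
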