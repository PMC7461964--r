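#' Full width at half maximum of a peaked profile
#'
#' Locates the half-maximum crossings on either side of the (single) peak
#' by linear interpolation and returns their distance in physical units.
#' A one-sample peak (delta-like input) cannot be interpolated: the
#' one-pitch upper bound is returned with attribute \code{discrete = TRUE}.
#'
#' @param x numeric profile, or a 3-D array with \code{axis} given, in
#'   which case the 1-D profile through the global maximum along that axis
#'   is measured.
#' @param spacing_mm sample pitch along the profile.
#' @param axis axis (1-3) when \code{x} is a volume.
#' @return FWHM in mm (attribute \code{discrete} flags the degenerate case).
#' @export
measure_fwhm <- function(x, spacing_mm = 1, axis = NULL) {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (is.null(axis)) stop("measure_fwhm(): axis required for a volume")
    pk <- which(x == max(x), arr.ind = TRUE)[1, ]
    x <- switch(axis, x[, pk[2], pk[3]], x[pk[1], , pk[3]], x[pk[1], pk[2], ])
  }
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L || !any(is.finite(x))) stop("measure_fwhm(): profile too short")
  if (max(x) <= min(x)) stop("measure_fwhm(): flat profile, no peak")
  half <- max(x) / 2
  above <- x > half
  runs <- rle(above)
  if (sum(runs$values) != 1L)
    stop("measure_fwhm(): profile is not single-peaked at half maximum (",
         sum(runs$values), " above-half segments)")
  i <- range(which(above))
  if (i[1] == i[2]) {
    out <- spacing_mm
    attr(out, "discrete") <- TRUE
    return(out)
  }
  # left crossing between i[1]-1 and i[1]
  left <- if (i[1] == 1L) 1 else
    (i[1] - 1) + (half - x[i[1] - 1]) / (x[i[1]] - x[i[1] - 1])
  right <- if (i[2] == n) n else
    i[2] + (half - x[i[2]]) / (x[i[2] + 1] - x[i[2]])
  out <- (right - left) * spacing_mm
  attr(out, "discrete") <- FALSE
  out
}

#' Per-object activity recovery coefficients
#'
#' Ratio of the measured mean concentration to the true concentration per
#' object mask. With \code{normalize = "total"} the reconstruction is
#' first rescaled so its grand total matches the truth's (removes any
#' global scale mismatch before the per-object comparison).
#'
#' @param recon a \code{vq_volume} or array.
#' @param truth a \code{vq_activity} or array with constant concentration
#'   per mask.
#' @param masks named list of non-empty logical arrays.
#' @param normalize "none" or "total".
#' @return List: \code{coefficients} (named numeric),
#'   \code{true_concentration}, \code{object_voxels}.
#' @export
recovery_coefficients <- function(recon, truth, masks,
                                  normalize = c("none", "total")) {
  normalize <- match.arg(normalize)
  r <- if (inherits(recon, "vq_volume")) recon$values else recon
  t <- if (inherits(truth, "vq_activity")) truth$values else truth
  if (!identical(dim(r), dim(t)))
    stop("recovery_coefficients(): recon/truth shape mismatch")
  if (normalize == "total") r <- r * sum(t) / sum(r)
  res <- vapply(masks, function(m) {
    if (!any(m)) stop("recovery_coefficients(): empty object mask")
    tv <- t[m]
    if (max(tv) - min(tv) > 1e-6 * max(abs(tv), 1))
      stop("recovery_coefficients(): truth not constant within a mask")
    if (tv[1] <= 0) stop("recovery_coefficients(): zero truth concentration")
    mean(r[m]) / tv[1]
  }, numeric(1))
  list(coefficients = res,
       true_concentration = vapply(masks, function(m) t[m][1], numeric(1)),
       object_voxels = vapply(masks, sum, integer(1)))
}
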