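#' Tissue code table
#'
#' Per-tissue lookup used by phantoms: an 8-bit code, a name, a mass
#' density and narrow-beam linear attenuation coefficients at the two
#' photopeak energies (140 keV for Tc-99m, 190 keV for Kr-81m).
#'
#' Attenuation defaults use water-equivalent scaling by density:
#' mu(E) = (mu/rho)_water(E) * rho, with (mu/rho)_water = 0.1537 cm^2/g at
#' 140 keV and 0.1396 cm^2/g at 190 keV (NIST XCOM interpolation). This is
#' a physics-constant table, configurable by the user, not a fitted result.
#'
#' @param df a data.frame with columns \code{code}, \code{name},
#'   \code{density}, \code{mu_140}, \code{mu_190} (and optionally
#'   \code{hu_mean}, \code{hu_sd} used by the synthetic thorax generator).
#' @return A validated \code{vq_tissue_table} (a data.frame).
#' @export
tissue_table <- function(df) {
  required <- c("code", "name", "density", "mu_140", "mu_190")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("tissue_table(): missing columns: ", paste(miss, collapse = ", "))
  df$code <- as.integer(df$code)
  if (anyDuplicated(df$code))
    stop("tissue_table(): tissue codes must be unique")
  if (any(df$code < 0L | df$code > 255L))
    stop("tissue_table(): codes must fit in 8 bits (0..255)")
  if (any(df$mu_140 < 0) || any(df$mu_190 < 0))
    stop("tissue_table(): attenuation coefficients must be >= 0")
  dense <- df$density > 0
  if (any(df$mu_190[dense] >= df$mu_140[dense]))
    stop("tissue_table(): mu_190 must be < mu_140 for every tissue with density > 0")
  if (!any(df$density < 1e-2 & df$mu_140 < 1e-3))
    stop("tissue_table(): an outside-air tissue with mu ~ 0 must be present")
  class(df) <- c("vq_tissue_table", "data.frame")
  df
}

# water mass attenuation coefficients, cm^2/g
MU_RHO_WATER_140 <- 0.1537
MU_RHO_WATER_190 <- 0.1396

#' Default six-class tissue table
#'
#' Outside air, lungs, bronchi (intrathoracic airways), fat, soft tissue
#' and bone. Codes are stable and fit 8 bits. \code{hu_mean}/\code{hu_sd}
#' drive the synthetic thorax generator; bronchial air shares the HU of
#' air but is kept as a separate code because ventilation activity fills
#' it while perfusion does not.
#'
#' @return A \code{vq_tissue_table}.
#' @export
default_tissue_table <- function() {
  df <- data.frame(
    code    = c(0L, 1L, 2L, 3L, 4L, 5L),
    name    = c("outside_air", "lung", "bronchi", "fat", "soft_tissue", "bone"),
    density = c(0.0012, 0.26, 0.0012, 0.92, 1.04, 1.40),
    hu_mean = c(-1000, -800, -1000, -100, 40, 400),
    hu_sd   = c(5, 20, 5, 15, 15, 50),
    stringsAsFactors = FALSE
  )
  df$mu_140 <- MU_RHO_WATER_140 * df$density
  df$mu_190 <- MU_RHO_WATER_190 * df$density
  tissue_table(df)
}

# codes used by segmentation / the generator
TISSUE_OUTSIDE <- 0L
TISSUE_LUNG    <- 1L
TISSUE_BRONCHI <- 2L
TISSUE_FAT     <- 3L
TISSUE_SOFT    <- 4L
TISSUE_BONE    <- 5L

#' Default HU segmentation cutpoints
#'
#' Conventional CT tissue ranges: air below -950 HU, lung parenchyma
#' [-950, -400), fat [-400, -30), soft tissue [-30, 150), bone at or above
#' 150 HU. Air voxels are split into outside air vs intrathoracic airway
#' by connected-component labeling against the volume border.
#'
#' @return Named numeric vector of strictly increasing cutpoints.
#' @export
default_hu_thresholds <- function() {
  c(air = -950, lung = -400, fat = -30, soft = 150)
}
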