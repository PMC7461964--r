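#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{code} under \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so that seeded simulator calls do not disturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one root seed; keeps every derived
# seed strictly below .Machine$integer.max.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Root-mean-square deviation between two value series
#'
#' @param a,b numeric vectors of equal length.
#' @return \code{sqrt(mean((a - b)^2))}, in the units of the inputs.
#' @examples
#' rmsd(c(0, 0), c(3, 4)) # sqrt(25/2)
#' @export
rmsd <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("rmsd(): length mismatch (", length(a), " vs ", length(b), ")")
  }
  if (length(a) < 1L) stop("rmsd(): empty series")
  sqrt(mean((a - b)^2))
}

# FWHM <-> sigma conversion for Gaussians: FWHM = 2*sqrt(2*log(2)) * sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

`%||%` <- function(x, y) if (is.null(x)) y else x
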