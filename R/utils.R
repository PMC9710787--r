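# Shared constants and small helpers.

# 13C - 12C mass difference (Da); fixes the spacing of isotopic peaks at
# delta/z in the m/z dimension.
.ISOTOPE_DELTA <- 1.003355

# Mass of a proton (Da), for m/z <-> neutral mass conversion.
.PROTON_MASS <- 1.00727646688

# FWHM = 2*sqrt(2*log(2)) * sigma for a Gaussian peak.
.FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

tdStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "timsDescentError")))
}

#' Parts-per-million difference between two m/z values
#'
#' @param mz observed m/z (Th).
#' @param ref reference m/z (Th).
#' @return signed ppm difference `(mz - ref) / ref * 1e6`.
#' @export
ppmError <- function(mz, ref) (mz - ref) / ref * 1e6

# Gaussian sigma of an isotopic peak at a given m/z for a given resolving
# power: FWHM = mz / resolution.
mzPeakSigma <- function(mz, resolution = 40000) {
  (mz / resolution) / .FWHM_PER_SIGMA
}

# Half-open binning anchored at 0: bin k covers [k*w, (k+1)*w).
# The small epsilon keeps values that are exactly on a bin boundary (up to
# floating-point representation) in the upper bin.
binIndex <- function(x, width) {
  as.integer(floor(x / width + 1e-9))
}

cosineSimilarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}
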