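# Theoretical isotopic envelopes from the averagine model: the average
# amino-acid residue composition C4.9384 H7.7583 N1.3577 O1.4773 S0.0417
# (111.1254 Da) scaled to the peptide's neutral mass. Envelope shape is
# obtained by convolving the aggregated (nominal-mass) isotope
# distributions of the rounded element counts.

.AVERAGINE <- list(
  unit_mass = 111.1254,
  composition = c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
)

# Aggregated isotope abundances by nominal mass shift (index 1 = +0).
.ELEMENT_ISOTOPES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

# Truncated self-convolution p^(*n), keeping the first len terms.
convPower <- function(p, n, len) {
  out <- c(1, rep(0, len - 1))
  base <- c(p, rep(0, max(0, len - length(p))))[seq_len(len)]
  while (n > 0) {
    if (n %% 2 == 1) out <- convTrunc(out, base, len)
    base <- convTrunc(base, base, len)
    n <- n %/% 2
  }
  out
}

convTrunc <- function(a, b, len) {
  out <- numeric(len)
  for (i in seq_len(len)) {
    j <- seq_len(i)
    out[i] <- sum(a[j] * b[i - j + 1])
  }
  out
}

#' Theoretical isotopic envelope fractions for a peptide mass
#'
#' Predicts the relative abundances of the first `n_isotopes` isotopic
#' peaks of a peptide of the given neutral mass under the averagine
#' average-composition model. Fractions are normalized to sum to 1. For
#' masses below roughly 1800 Da the monoisotopic peak is the base peak;
#' for large masses the envelope maximum moves to higher isotopes.
#'
#' @param neutral_mass peptide neutral (uncharged) mass in Da; must be > 0.
#' @param n_isotopes number of envelope peaks to return (>= 2).
#' @return numeric vector of length `n_isotopes`, non-negative, summing
#'   to 1; element i is the relative abundance of isotope i - 1.
#' @examples
#' averagineEnvelope(1000, 4)
#' @export
averagineEnvelope <- function(neutral_mass, n_isotopes = 6L) {
  if (!is.numeric(neutral_mass) || length(neutral_mass) != 1 ||
      !is.finite(neutral_mass) || neutral_mass <= 0)
    tdStop("neutral_mass must be a single positive number", "domainError")
  if (n_isotopes < 2)
    tdStop("n_isotopes must be >= 2", "domainError")
  units <- neutral_mass / .AVERAGINE$unit_mass
  counts <- stats::setNames(
    pmax(0L, as.integer(round(.AVERAGINE$composition * units))),
    names(.AVERAGINE$composition))
  len <- as.integer(n_isotopes)
  dist <- c(1, rep(0, len - 1))
  for (el in names(counts)) {
    if (counts[[el]] > 0)
      dist <- convTrunc(dist,
                        convPower(.ELEMENT_ISOTOPES[[el]], counts[[el]], len),
                        len)
  }
  dist / sum(dist)
}
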