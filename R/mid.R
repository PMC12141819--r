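#' Validate and normalize a mass isotopomer distribution
#'
#' A mass isotopomer distribution (MID) is the vector of fractional
#' abundances `f[0..N]` of the isotopologues M+0 ... M+N of one metabolite
#' measurement, where M+i carries i heavy tracer atoms. Raw peak-table rows
#' arrive as intensities or approximately-normalized fractions; this
#' validates and rescales them to sum exactly to 1, recording the
#' pre-normalization sum as a QC attribute (`qc_sum`).
#'
#' @param fractions Numeric vector of isotopologue signals, M+0 first.
#' @param tolerance Negative values larger in magnitude than this are
#'   rejected as invalid measurements; smaller negatives are treated as
#'   numerical zeros. Default `1e-6`.
#' @return Numeric vector summing to 1 with attribute `qc_sum`.
#' @examples
#' validate_mid(c(1, 1, 2))
#' @export
validate_mid <- function(fractions, tolerance = 1e-6) {
  if (length(fractions) == 0L || !is.numeric(fractions)) {
    stop_empty_measurement("MID fractions must be a non-empty numeric vector.")
  }
  if (anyNA(fractions)) {
    stop_invalid_measurement("MID fractions contain missing values.")
  }
  if (any(fractions < -tolerance)) {
    stop_invalid_measurement(
      paste0("MID contains negative fraction(s) beyond tolerance: min = ",
             format(min(fractions))))
  }
  fractions <- pmax(fractions, 0)
  s <- sum(fractions)
  if (s == 0) stop_empty_measurement("All-zero MID: empty measurement.")
  out <- fractions / s
  attr(out, "qc_sum") <- s
  out
}

#' Atom fraction (L) of a mass isotopomer distribution
#'
#' The proportion of a metabolite's tracer-element atoms that carry label:
#' `L = sum(i * f[i]) / N` for a validated MID `f[0..N]`. This is the
#' labeling fraction that enters every downstream flux formula.
#'
#' @param fractions Validated MID vector `f[0..N]`.
#' @param n_atoms Number of tracer-element atoms N. Defaults to
#'   `length(fractions) - 1`, i.e. a full-length MID.
#' @return Atom fraction in `[0, 1]`.
#' @examples
#' atom_fraction(c(0.25, 0.5, 0.25))  # 0.5
#' @export
atom_fraction <- function(fractions, n_atoms = length(fractions) - 1L) {
  if (n_atoms < 1L) {
    stop_domain("Atom fraction undefined for a metabolite with no tracer atoms.")
  }
  if (length(fractions) > n_atoms + 1L) {
    stop_shape("MID longer than n_atoms + 1.")
  }
  idx <- seq_along(fractions) - 1L
  val <- sum(idx * fractions) / n_atoms
  min(max(val, 0), 1)
}

#' Binomial labeling model
#'
#' MID of a molecule whose `n` tracer atoms are each independently labeled
#' with probability `p`: `f[i] = choose(n, i) p^i (1-p)^(n-i)`. Used as the
#' forward within-molecule isotopomer model for downstream metabolites and
#' for the natural-abundance pattern of a single element. By construction
#' `atom_fraction(binomial_mid(p, n)) == p`.
#'
#' @param p Per-atom labeling probability in `[0, 1]`.
#' @param n Number of atoms (>= 1).
#' @return MID vector of length `n + 1`.
#' @export
binomial_mid <- function(p, n) {
  if (n < 1L || n != round(n)) stop_domain("`n` must be a positive integer.")
  if (p < 0 || p > 1) stop_domain("`p` must be in [0, 1].")
  dbinom(0:n, size = n, prob = p)
}

#' Convolve two mass isotopomer distributions
#'
#' Discrete convolution of fraction vectors: the MID of a molecule (or
#' moiety pair) whose label content is the independent sum of the two
#' inputs. This is how tracer-derived labeling is superposed with natural
#' abundance in the forward model.
#'
#' @param a,b MID fraction vectors.
#' @return Vector of length `length(a) + length(b) - 1`, summing to 1 when
#'   both inputs do.
#' @examples
#' convolve_mids(c(0.6, 0.4), c(0.7, 0.3))
#' @export
convolve_mids <- function(a, b) {
  if (!length(a) || !length(b)) stop_empty_measurement("Cannot convolve empty MIDs.")
  convolve_fractions(a, b)
}

# bare polynomial-product convolution, no validation (hot path)
convolve_fractions <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] != 0) {
      idx <- i:(i + length(b) - 1L)
      out[idx] <- out[idx] + a[i] * b
    }
  }
  out
}
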