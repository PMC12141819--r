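#' Build a natural-abundance correction matrix
#'
#' Column `j` (zero-based) of the matrix is the isotopologue distribution a
#' mass spectrometer is expected to measure, truncated to mass shifts
#' `0..N`, for a molecule carrying exactly `j` tracer-labeled atoms. In
#' `"high"` resolution mode only natural isotopes of the tracer element
#' contribute (a 140,000-resolution Orbitrap mass-resolves the isotopologue
#' interferences of other elements away); in `"unit"` mode the natural
#' isotope patterns of every element in the formula are convolved in.
#'
#' Multiplying a true labeling distribution by this matrix predicts the
#' measured MID; [correct_mid()] inverts that prediction.
#'
#' @param formula Chemical formula string (or named count vector).
#' @param tracer_element Element carrying the label: `"C"`, `"H"` or `"N"`.
#' @param n_tracer_atoms Number of atoms that can carry tracer label, N.
#'   Defaults to the formula's full count of `tracer_element`.
#' @param abundances Isotope abundance tibble from [isotope_abundances()].
#' @param resolution `"high"` (default) or `"unit"`.
#' @return `(N+1) x (N+1)` lower-triangular matrix.
#' @examples
#' build_correction_matrix("C2H4O2", "C")
#' @export
build_correction_matrix <- function(formula, tracer_element,
                                    n_tracer_atoms = NULL,
                                    abundances = isotope_abundances(),
                                    resolution = c("high", "unit")) {
  resolution <- match.arg(resolution)
  counts <- if (is.character(formula)) parse_chemical_formula(formula) else formula
  n_el <- element_count(counts, tracer_element)
  if (is.null(n_tracer_atoms)) n_tracer_atoms <- n_el
  if (n_el < n_tracer_atoms) {
    stop_composition(paste0(
      "Formula has ", n_el, " ", tracer_element,
      " atom(s) but n_tracer_atoms = ", n_tracer_atoms, "."))
  }
  if (n_tracer_atoms < 1L) stop_domain("n_tracer_atoms must be >= 1.")
  n <- n_tracer_atoms

  # natural pattern shared by every column in unit mode: all non-tracer elements
  base <- 1
  if (resolution == "unit") {
    for (el in setdiff(names(counts), tracer_element)) {
      base <- convolve_fractions(base, atoms_pattern(abundances, el, counts[[el]]))
    }
  }

  m <- matrix(0, nrow = n + 1L, ncol = n + 1L)
  for (j in 0:n) {
    # j atoms fixed at the labeled shift; remaining tracer-element atoms at
    # natural abundance (labeled positions carry no additional natural shift)
    free <- atoms_pattern(abundances, tracer_element, n_el - j)
    col <- convolve_fractions(base, free)
    col <- c(rep(0, j), col)                       # shift by j labeled atoms
    col <- col[seq_len(n + 1L)]                    # truncate to measured range
    col[is.na(col)] <- 0
    m[, j + 1L] <- col
  }
  m
}

#' Correct a measured MID for natural isotope abundance
#'
#' Recovers the tracer-derived labeling distribution `x` from a measured
#' MID by solving `minimize ||M x - raw||_2 subject to x >= 0`, where `M`
#' comes from [build_correction_matrix()], then renormalizing `x` to sum
#' to 1. The non-negativity constraint is the standard remedy for the
#' small negative fractions an unconstrained inversion produces on noisy
#' data; clipping after an unconstrained solve would bias low fractions.
#'
#' Measured isotopologues above M+N (more shifts than tracer atoms) are
#' dropped with a warning before the fit. The residual norm of the fit is
#' attached as attribute `qc_residual`.
#'
#' @param raw Measured MID fractions (M+0 first); shorter vectors are
#'   zero-padded to the matrix dimension.
#' @param matrix Correction matrix from [build_correction_matrix()].
#' @return Corrected MID summing to 1, attribute `qc_residual`.
#' @export
correct_mid <- function(raw, matrix) {
  n1 <- nrow(matrix)
  if (is.null(n1) || n1 != ncol(matrix)) stop_shape("Correction matrix must be square.")
  if (length(raw) > n1) {
    mf_warn(paste0("Dropping ", length(raw) - n1,
                   " measured isotopologue(s) above M+", n1 - 1L,
                   " before correction."),
            "truncated_isotopologues")
    raw <- raw[seq_len(n1)]
  }
  if (length(raw) < n1) raw <- c(raw, rep(0, n1 - length(raw)))
  raw <- as.numeric(validate_mid(raw))

  # fast path: the matrix is lower triangular with positive diagonal, so the
  # exact solve is the unconstrained least-squares solution; accept it when
  # it is already feasible
  x <- backsolve(matrix, raw, upper.tri = FALSE)
  if (min(x) < -1e-10) {
    x <- pracma::lsqnonneg(matrix, raw)$x
  }
  x <- pmax(x, 0)
  resid <- sqrt(sum((matrix %*% x - raw)^2))
  s <- sum(x)
  if (s == 0) stop_empty_measurement("Correction produced an all-zero MID.")
  out <- x / s
  attr(out, "qc_residual") <- resid
  out
}

# per-session cache of correction matrices keyed by formula/element/N/mode
.matrix_cache <- new.env(parent = emptyenv())

cached_correction_matrix <- function(formula, tracer_element, n_tracer_atoms,
                                     abundances, resolution) {
  key <- paste(formula, tracer_element, n_tracer_atoms, resolution,
               digest_abundances(abundances), sep = "|")
  m <- .matrix_cache[[key]]
  if (is.null(m)) {
    m <- build_correction_matrix(formula, tracer_element, n_tracer_atoms,
                                 abundances, resolution)
    .matrix_cache[[key]] <- m
  }
  m
}

digest_abundances <- function(abundances) {
  paste(abundances$element, abundances$mass_shift,
        signif(abundances$abundance, 12), sep = ":", collapse = ";")
}

#' Natural-abundance-correct an isotopologue table
#'
#' Data-frame-first wrapper around [correct_mid()]: takes a long
#' isotopologue table (one row per sample, metabolite and M+i), groups it
#' by `(sample, metabolite)`, assembles each measurement into a full MID
#' (missing isotopologues are zero-filled), corrects it against the
#' appropriate matrix and returns the corrected fractions in the same long
#' layout.
#'
#' @param data Tibble with columns `sample`, `metabolite`, `formula`,
#'   `tracer_element`, `isotopologue` and a value column.
#' @param value Name of the value column: `"intensity"` (raw signal,
#'   normalized internally) or `"fraction"`.
#' @param abundances Isotope abundance tibble.
#' @param resolution `"high"` or `"unit"` correction mode.
#' @return Tibble with columns `sample`, `metabolite`, `formula`,
#'   `tracer_element`, `isotopologue`, `fraction` (corrected) and
#'   `qc_residual`; other columns constant within a measurement are carried
#'   through.
#' @export
correct_isotopologues <- function(data,
                                  value = c("intensity", "fraction"),
                                  abundances = isotope_abundances(),
                                  resolution = c("high", "unit")) {
  value <- match.arg(value)
  resolution <- match.arg(resolution)
  required <- c("sample", "metabolite", "formula", "tracer_element",
                "isotopologue", value)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop_format(paste0("Isotopologue table lacks column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  data <- as_tibble(data)
  keys <- paste(data$sample, data$metabolite, sep = "\r")
  groups <- split(seq_len(nrow(data)), keys)

  n_g <- length(groups)
  first_row <- integer(n_g); lens <- integer(n_g)
  iso_out <- vector("list", n_g); frac_out <- vector("list", n_g)
  resid_out <- numeric(n_g)
  vals <- data[[value]]
  for (gi in seq_len(n_g)) {
    rows <- groups[[gi]]
    iso <- data$isotopologue[rows]
    if (anyDuplicated(iso)) {
      stop_format(paste0("Duplicate isotopologue rows for sample '",
                         data$sample[rows[1]], "', metabolite '",
                         data$metabolite[rows[1]], "'."))
    }
    n <- element_count(data$formula[rows[1]], data$tracer_element[rows[1]])
    if (n < 1L) {
      stop_composition(paste0("Metabolite '", data$metabolite[rows[1]],
                              "' has no ", data$tracer_element[rows[1]],
                              " atoms in formula '", data$formula[rows[1]], "'."))
    }
    keep <- iso <= n
    if (!all(keep)) {
      mf_warn(paste0("Dropping isotopologues above M+", n, " for '",
                     data$metabolite[rows[1]], "' in sample '",
                     data$sample[rows[1]], "'."),
              "truncated_isotopologues")
      rows <- rows[keep]; iso <- iso[keep]
    }
    vec <- numeric(n + 1L)
    vec[iso + 1L] <- vals[rows]
    m <- cached_correction_matrix(data$formula[rows[1]],
                                  data$tracer_element[rows[1]], n,
                                  abundances, resolution)
    corrected <- correct_mid(vec, m)
    first_row[gi] <- rows[1]; lens[gi] <- n + 1L
    iso_out[[gi]] <- 0:n
    frac_out[[gi]] <- as.numeric(corrected)
    resid_out[gi] <- attr(corrected, "qc_residual")
  }
  carry_cols <- setdiff(names(data), c("isotopologue", value,
                                       "fraction", "qc_residual"))
  out <- data[rep(first_row, times = lens), carry_cols, drop = FALSE]
  out$isotopologue <- unlist(iso_out, use.names = FALSE)
  out$fraction <- unlist(frac_out, use.names = FALSE)
  out$qc_residual <- rep(resid_out, times = lens)
  out
}

#' Atom fractions from a long isotopologue fraction table
#'
#' Collapses a corrected isotopologue table to one row per measurement with
#' the atom fraction `L = sum(i * f[i]) / N`.
#'
#' @param data Tibble as returned by [correct_isotopologues()] (columns
#'   `sample`, `metabolite`, `formula`, `tracer_element`, `isotopologue`,
#'   `fraction`).
#' @return Tibble with one row per `(sample, metabolite)` and columns
#'   `n_atoms`, `atom_fraction`, plus carried-through constants.
#' @export
atom_fractions <- function(data) {
  required <- c("sample", "metabolite", "formula", "tracer_element",
                "isotopologue", "fraction")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop_format(paste0("Fraction table lacks column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  data <- as_tibble(data)
  keys <- paste(data$sample, data$metabolite, sep = "\r")
  groups <- split(seq_len(nrow(data)), keys)
  first_row <- unname(vapply(groups, `[`, integer(1), 1L))
  n_atoms <- vapply(first_row, function(r) {
    element_count(data$formula[r], data$tracer_element[r])
  }, integer(1))
  af <- vapply(seq_along(groups), function(gi) {
    rows <- groups[[gi]]
    min(max(sum(data$isotopologue[rows] * data$fraction[rows]) / n_atoms[gi],
            0), 1)
  }, numeric(1))
  carry_cols <- setdiff(names(data), c("isotopologue", "fraction", "intensity"))
  out <- data[first_row, carry_cols, drop = FALSE]
  out$n_atoms <- unname(n_atoms)
  out$atom_fraction <- unname(af)
  out
}
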