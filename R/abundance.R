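#' Natural isotope abundance table
#'
#' Per-element natural isotope distributions used to build correction
#' matrices. Each element maps to mass shifts (0 = lightest isotope) and
#' their natural abundances; abundances per element sum to 1. Defaults are
#' standard IUPAC terrestrial values: 13C 0.0107, 2H 0.000115, 15N 0.00364,
#' plus O and S minor isotopes for unit-resolution work.
#'
#' @param overrides Optional tibble/data frame with columns `element`,
#'   `mass_shift`, `abundance`; listed elements replace the defaults wholesale.
#' @return A tibble with columns `element`, `mass_shift`, `abundance`.
#' @examples
#' isotope_abundances()
#' @export
isotope_abundances <- function(overrides = NULL) {
  tab <- tibble(
    element = c("C", "C",
                "H", "H",
                "N", "N",
                "O", "O", "O",
                "S", "S", "S", "S"),
    mass_shift = c(0L, 1L,
                   0L, 1L,
                   0L, 1L,
                   0L, 1L, 2L,
                   0L, 1L, 2L, 4L),
    abundance = c(1 - 0.0107, 0.0107,
                  1 - 0.000115, 0.000115,
                  1 - 0.00364, 0.00364,
                  1 - 0.00038 - 0.00205, 0.00038, 0.00205,
                  1 - 0.0075 - 0.0425 - 0.0001, 0.0075, 0.0425, 0.0001)
  )
  if (!is.null(overrides)) {
    overrides <- as_tibble(overrides)
    validate_abundance_table(overrides)
    tab <- dplyr::bind_rows(
      dplyr::filter(tab, !(.data$element %in% overrides$element)),
      overrides
    )
  }
  validate_abundance_table(tab)
  tab
}

#' Read an isotope abundance override file
#'
#' Delimited text with header `element,mass_shift,abundance`. Elements present
#' in the file replace the built-in defaults for that element.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @return A full abundance tibble (defaults merged with the overrides).
#' @export
read_isotope_abundances <- function(path, delim = ",") {
  if (!file.exists(path)) stop_format(paste0("Abundance file not found: ", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  needed <- c("element", "mass_shift", "abundance")
  if (!all(needed %in% names(raw))) {
    stop_format("Abundance file must have columns element, mass_shift, abundance.")
  }
  isotope_abundances(overrides = raw[needed])
}

validate_abundance_table <- function(tab) {
  if (any(tab$abundance < 0)) stop_domain("Isotope abundances must be >= 0.")
  if (any(tab$mass_shift < 0 | tab$mass_shift != round(tab$mass_shift))) {
    stop_domain("Isotope mass shifts must be non-negative integers.")
  }
  sums <- tapply(tab$abundance, tab$element, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-6]
  if (length(bad)) {
    stop_domain(paste0("Isotope abundances must sum to 1 per element; off for: ",
                       paste(bad, collapse = ", ")))
  }
  invisible(tab)
}

# natural isotope pattern of one element as a fraction vector over mass shifts
element_pattern <- function(abundances, element) {
  rows <- abundances[abundances$element == element, ]
  if (!nrow(rows)) return(1)  # element with no entry: treated as monoisotopic
  v <- numeric(max(rows$mass_shift) + 1L)
  v[rows$mass_shift + 1L] <- rows$abundance
  v
}

# pattern of k atoms of an element: k-fold self-convolution
atoms_pattern <- function(abundances, element, k) {
  if (k <= 0L) return(1)
  p <- element_pattern(abundances, element)
  out <- 1
  for (i in seq_len(k)) out <- convolve_fractions(out, p)
  out
}
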