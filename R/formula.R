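#' Parse a chemical formula into element counts
#'
#' Turns a Hill-style molecular formula such as `"C6H12O6"` into a named
#' integer vector of element counts. Only plain element-count pairs are
#' supported (no parentheses, charges or isotope prefixes), which covers the
#' formulas found in peak-table exports for polar metabolites and saponified
#' fatty acids.
#'
#' @param formula Character scalar, e.g. `"C5H10N2O3"`.
#' @return Named integer vector of counts, names are element symbols.
#' @examples
#' parse_chemical_formula("C6H12O6")
#' @export
parse_chemical_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop_composition("`formula` must be a single non-empty string.")
  }
  matches <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  pieces <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(pieces)) != nchar(formula)) {
    stop_composition(paste0("Cannot parse chemical formula: '", formula, "'"))
  }
  elements <- sub("[0-9]*$", "", pieces)
  counts <- as.integer(ifelse(grepl("[0-9]+$", pieces),
                              sub("^[A-Za-z]+", "", pieces), "1"))
  out <- tapply(counts, elements, sum)
  setNames(as.integer(out), names(out))
}

.formula_cache <- new.env(parent = emptyenv())

element_count <- function(formula, element) {
  counts <- if (is.character(formula)) {
    cached <- .formula_cache[[formula]]
    if (is.null(cached)) {
      cached <- parse_chemical_formula(formula)
      .formula_cache[[formula]] <- cached
    }
    cached
  } else formula
  n <- counts[element]
  if (is.na(n)) 0L else as.integer(n)
}
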