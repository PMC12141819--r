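# Shared fixtures: all inputs are built in code at test time.

# pure-13C abundance table with a chosen heavy fraction, other elements
# monoisotopic -- keeps hand arithmetic in oracles simple
carbon_only_abundances <- function(p13 = 0.011) {
  isotope_abundances(tibble::tibble(
    element = c("C", "C", "H", "N", "O", "S"),
    mass_shift = c(0L, 1L, 0L, 0L, 0L, 0L),
    abundance = c(1 - p13, p13, 1, 1, 1, 1)))
}

# compact experiment configuration for pipeline tests
small_config <- function(...) {
  args <- list(tissues = "liver", diets = "AA", methionine_arms = FALSE,
               water_arm = FALSE, bootstrap_draws = 0L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(flux_config, args)
}

# long-format isotopologue tibble from a named list of fraction vectors
mid_table <- function(mids, metabolite, formula, tracer_element,
                      value = "intensity", scale = 1) {
  purrr::map_dfr(names(mids), function(s) {
    f <- mids[[s]]
    out <- tibble::tibble(
      sample = s, metabolite = metabolite, formula = formula,
      tracer_element = tracer_element,
      isotopologue = seq_along(f) - 1L)
    out[[value]] <- f * scale
    out
  })
}
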