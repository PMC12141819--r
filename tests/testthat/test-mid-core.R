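test_that("validate_mid normalizes and records the pre-normalization sum", {
  v <- validate_mid(c(0.5, 0.5))
  expect_equal(as.numeric(v), c(0.5, 0.5))
  expect_equal(attr(v, "qc_sum"), 1)

  v <- validate_mid(c(1, 1, 2))
  expect_equal(as.numeric(v), c(0.25, 0.25, 0.5))
  expect_equal(attr(v, "qc_sum"), 4)
})

test_that("validate_mid rejects degenerate measurements", {
  expect_error(validate_mid(c(0, 0, 0)), class = "midflux_empty_measurement")
  expect_error(validate_mid(numeric(0)), class = "midflux_empty_measurement")
  expect_error(validate_mid(c(0.9, -0.2)), class = "midflux_invalid_measurement")
  # sub-tolerance negatives are numerical zeros, not errors
  expect_silent(validate_mid(c(1, -1e-9)))
})

test_that("atom fraction is the labeled-atom proportion", {
  expect_equal(atom_fraction(c(0, 0, 1)), 1)
  expect_equal(atom_fraction(c(0.5, 0.5)), 0.5)
  # (0*0.25 + 1*0.5 + 2*0.25) / 2
  expect_equal(atom_fraction(c(0.25, 0.5, 0.25)), 0.5)
  expect_error(atom_fraction(1, n_atoms = 0), class = "midflux_domain_error")
})

test_that("binomial labeling model matches expansion and inverts to p", {
  expect_equal(binomial_mid(0.5, 2), c(0.25, 0.5, 0.25))
  expect_equal(binomial_mid(0, 3), c(1, 0, 0, 0))
  expect_equal(binomial_mid(0.011, 2), c(0.978121, 0.021758, 0.000121),
               tolerance = 1e-12)
  expect_error(binomial_mid(0.5, 0), class = "midflux_domain_error")
  expect_error(binomial_mid(1.2, 3), class = "midflux_domain_error")

  for (p in seq(0, 1, by = 0.1)) {
    for (n in 1:10) {
      expect_equal(atom_fraction(binomial_mid(p, n)), p, tolerance = 1e-12)
    }
  }
})

test_that("MID convolution is polynomial multiplication", {
  expect_equal(convolve_mids(c(1, 0), c(0.9, 0.1)), c(0.9, 0.1, 0))
  expect_equal(convolve_mids(c(0.5, 0.5), c(0.5, 0.5)), c(0.25, 0.5, 0.25))
  expect_equal(convolve_mids(c(0.6, 0.4), c(0.7, 0.3)), c(0.42, 0.46, 0.12))
  # mass conservation and atom-count additivity
  withr::with_seed(11, {
    for (i in 1:20) {
      a <- validate_mid(runif(sample(2:6, 1)))
      b <- validate_mid(runif(sample(2:6, 1)))
      out <- convolve_mids(a, b)
      expect_equal(sum(out), 1, tolerance = 1e-12)
      expect_equal(length(out), length(a) + length(b) - 1L)
    }
  })
})

test_that("natural label only adds to tracer labeling under convolution", {
  tracer <- binomial_mid(0.3, 4)
  natural <- binomial_mid(0.0107, 6)
  n_total <- 10L
  combined <- convolve_mids(tracer, natural)
  expect_gte(atom_fraction(combined, n_total) * n_total,
             atom_fraction(tracer) * 4)
})

test_that("chemical formulas parse to element counts", {
  expect_equal(parse_chemical_formula("C6H12O6"),
               c(C = 6L, H = 12L, O = 6L))
  expect_equal(parse_chemical_formula("C5H10N2O3"),
               c(C = 5L, H = 10L, N = 2L, O = 3L))
  # two-letter elements and implicit count of 1
  expect_equal(parse_chemical_formula("C2H3NaO2"),
               c(C = 2L, H = 3L, Na = 1L, O = 2L))
  expect_error(parse_chemical_formula("C6H12-O6"),
               class = "midflux_composition_error")
  expect_error(parse_chemical_formula(""), class = "midflux_composition_error")
})

test_that("isotope abundance tables validate and accept overrides", {
  tab <- isotope_abundances()
  sums <- tapply(tab$abundance, tab$element, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_equal(tab$abundance[tab$element == "C" & tab$mass_shift == 1], 0.0107)
  expect_equal(tab$abundance[tab$element == "H" & tab$mass_shift == 1], 0.000115)
  expect_equal(tab$abundance[tab$element == "N" & tab$mass_shift == 1], 0.00364)

  over <- isotope_abundances(tibble::tibble(
    element = "C", mass_shift = c(0L, 1L), abundance = c(0.98, 0.02)))
  expect_equal(over$abundance[over$element == "C" & over$mass_shift == 1], 0.02)
  # untouched elements keep defaults
  expect_equal(over$abundance[over$element == "N" & over$mass_shift == 1], 0.00364)

  expect_error(
    isotope_abundances(tibble::tibble(
      element = "C", mass_shift = c(0L, 1L), abundance = c(0.9, 0.2))),
    class = "midflux_domain_error")
})
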