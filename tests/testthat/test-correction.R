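test_that("correction matrix columns enumerate single-atom labeling", {
  ab <- carbon_only_abundances(0.011)
  m <- build_correction_matrix("CH4O", "C", abundances = ab)
  expect_equal(m, rbind(c(0.989, 0), c(0.011, 1)), tolerance = 1e-12)

  # no natural label: identity
  m0 <- build_correction_matrix("C3H6O3", "C",
                                abundances = carbon_only_abundances(0))
  expect_equal(m0, diag(4))

  # unlabeled column of a two-carbon molecule is the binomial pattern
  m2 <- build_correction_matrix(c(C = 2L), "C", abundances = ab)
  expect_equal(m2[, 1], binomial_mid(0.011, 2), tolerance = 1e-12)
})

test_that("unit-resolution matrix folds in other elements (hand arithmetic)", {
  pc <- 0.0107; ph <- 0.000115
  po1 <- 0.00038; po2 <- 0.00205
  ab <- isotope_abundances()
  m <- build_correction_matrix("CH4O", "C", abundances = ab,
                               resolution = "unit")
  # methanol M+0 measured from an unlabeled molecule: every atom light
  expect_equal(m[1, 1], (1 - pc) * (1 - ph)^4 * (1 - po1 - po2),
               tolerance = 1e-12)
  # M+1: exactly one heavy atom among C, 4 H, O(+1)
  m1_expected <- pc * (1 - ph)^4 * (1 - po1 - po2) +
    (1 - pc) * 4 * ph * (1 - ph)^3 * (1 - po1 - po2) +
    (1 - pc) * (1 - ph)^4 * po1
  expect_equal(m[2, 1], m1_expected, tolerance = 1e-12)
  # labeled column: the single carbon is already heavy
  expect_equal(m[1, 2], 0)
  expect_equal(m[2, 2], (1 - ph)^4 * (1 - po1 - po2), tolerance = 1e-12)

  # high mode ignores H/O for the same molecule
  mh <- build_correction_matrix("CH4O", "C", abundances = ab)
  expect_equal(mh[, 1], c(1 - pc, pc), tolerance = 1e-12)
})

test_that("matrix construction rejects impossible compositions", {
  expect_error(build_correction_matrix("C2H4O2", "C", n_tracer_atoms = 3),
               class = "midflux_composition_error")
  expect_error(build_correction_matrix("H2O", "C"),
               class = "midflux_domain_error")
})

test_that("correction inverts the forward convolution", {
  ab <- carbon_only_abundances(0.011)
  m <- build_correction_matrix(c(C = 2L), "C", abundances = ab)

  # a pure unlabeled molecule measured at natural abundance
  corrected <- correct_mid(binomial_mid(0.011, 2), m)
  expect_equal(as.numeric(corrected), c(1, 0, 0), tolerance = 1e-9)

  # identity matrix passes fractions through
  expect_equal(as.numeric(correct_mid(c(0.3, 0.7), diag(2))), c(0.3, 0.7))

  # synthetic-truth round trip
  truth <- c(0.2, 0.5, 0.3)
  expect_equal(as.numeric(correct_mid(as.numeric(m %*% truth), m)), truth,
               tolerance = 1e-9)
})

test_that("round trip recovers random truths across random formulas", {
  ab <- isotope_abundances()
  withr::with_seed(42, {
    for (i in 1:25) {
      n_c <- sample(2:20, 1)
      formula <- paste0("C", n_c, "H", sample(4:40, 1), "O", sample(1:8, 1))
      mode <- sample(c("high", "unit"), 1)
      m <- build_correction_matrix(formula, "C", abundances = ab,
                                   resolution = mode)
      truth <- validate_mid(runif(n_c + 1))
      corrected <- correct_mid(as.numeric(m %*% as.numeric(truth)), m)
      expect_lt(max(abs(corrected - truth)), 1e-8)
    }
  })
})

test_that("corrected unlabeled standard is at least 99.9% M+0", {
  ab <- isotope_abundances()
  for (formula in c("C6H12O6", "C5H10N2O3", "C18H34O2")) {
    m <- build_correction_matrix(formula, "C", abundances = ab)
    n <- ncol(m) - 1L
    standard <- as.numeric(m %*% c(1, rep(0, n)))
    corrected <- correct_mid(standard, m)
    expect_gte(corrected[1], 0.999)
  }
})

test_that("constrained correction never returns negative fractions", {
  ab <- isotope_abundances()
  m <- build_correction_matrix("C6H12O6", "C", abundances = ab)
  withr::with_seed(7, {
    for (i in 1:50) {
      truth <- validate_mid(runif(7)^4)
      noisy <- pmax(as.numeric(m %*% as.numeric(truth)) + rnorm(7, 0, 0.01), 0)
      if (sum(noisy) == 0) next
      corrected <- correct_mid(noisy, m)
      expect_true(all(corrected >= 0))
      expect_equal(sum(corrected), 1, tolerance = 1e-12)
    }
  })
})

test_that("measured isotopologues beyond M+N are dropped with a warning", {
  m <- build_correction_matrix(c(C = 2L), "C",
                               abundances = carbon_only_abundances(0.011))
  expect_warning(out <- correct_mid(c(0.9, 0.05, 0.03, 0.02), m),
                 class = "midflux_truncated_isotopologues")
  expect_length(out, 3)
  expect_error(correct_mid(c(0.5, 0.5), cbind(1, 2)),
               class = "midflux_shape_error")
})

test_that("table-level correction matches vector-level correction", {
  ab <- isotope_abundances()
  m <- build_correction_matrix("C3H6O3", "C", abundances = ab)
  truth <- c(0.6, 0.3, 0.08, 0.02)
  raw <- as.numeric(m %*% truth)
  tab <- mid_table(list(s1 = raw), "lactate", "C3H6O3", "C", scale = 2e5)
  out <- correct_isotopologues(tab)
  expect_equal(out$fraction, as.numeric(correct_mid(raw, m)), tolerance = 1e-10)
  expect_equal(out$isotopologue, 0:3)

  dup <- dplyr::bind_rows(tab, tab[2, ])
  expect_error(correct_isotopologues(dup), class = "midflux_format_error")

  bad <- tab
  bad$tracer_element <- "N"
  expect_error(correct_isotopologues(bad),
               class = "midflux_composition_error")
})

test_that("atom_fractions collapses corrected tables per measurement", {
  tab <- mid_table(list(a = c(0.25, 0.5, 0.25), b = c(0, 0, 1)),
                   "glycine-frag", "C2H5NO2", "C", value = "fraction")
  out <- atom_fractions(tab)
  out <- out[order(out$sample), ]
  expect_equal(out$atom_fraction, c(0.5, 1))
  expect_equal(out$n_atoms, c(2L, 2L))
})
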