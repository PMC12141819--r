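test_that("serum labeling is the closed-form dilution of the tracer", {
  expect_equal(simulate_serum_labeling(50, 150), 0.25)
  expect_equal(simulate_serum_labeling(50, 0), 1)
  expect_lt(simulate_serum_labeling(1e-6, 100), 1e-7)
  expect_error(simulate_serum_labeling(-1, 10), class = "midflux_domain_error")
})

test_that("tissue labeling is the contribution-weighted cross sum", {
  cross <- rbind(glucose = c(glucose = 1, glutamine = 0.2),
                 glutamine = c(glucose = 0.05, glutamine = 1))
  expect_equal(
    simulate_tissue_labeling(c(glucose = 1, glutamine = 0), cross, "glucose"),
    1)
  expect_equal(
    simulate_tissue_labeling(c(glucose = 0.6, glutamine = 0.1), cross,
                             "glucose"),
    0.62)
  expect_equal(simulate_tissue_labeling(c(0, 0), cross, "glutamine"), 0)
  expect_error(simulate_tissue_labeling(c(0.5), cross, 1),
               class = "midflux_shape_error")
})

test_that("sampled truths satisfy their own invariants", {
  cfg <- flux_config()
  withr::with_seed(21, {
    for (i in 1:5) {
      truth <- sample_truth(cfg)
      expect_true(all(truth$f_circ$f_circ > 0))
      sums <- tapply(truth$contributions$contribution,
                     paste(truth$contributions$tissue,
                           truth$contributions$target,
                           truth$contributions$diet),
                     sum)
      expect_true(all(sums <= 1 + 1e-12))
      expect_true(all(diag(truth$cross) == 1))
      expect_true(all(truth$lipogenesis$new_fraction >= 0 &
                        truth$lipogenesis$new_fraction <= 1))
    }
  })
})

test_that("noise-free emission reproduces the natural-abundance pattern", {
  plan <- tibble::tibble(
    sample = "s1", metabolite = "glucose", formula = "C6H12O6",
    tracer_element = "C", model = "binomial", labeling = 0,
    n_label = NA_integer_, p_label = NA_real_)
  out <- emit_mids(plan, mid_sd = 0, intensity_cv = 0, detection_lod = 0)
  expect_equal(out$fraction, binomial_mid(0.0107, 6), tolerance = 1e-12)
  expect_error(emit_mids(plan, mid_sd = -1), class = "midflux_domain_error")
})

test_that("detection censoring drops only sub-limit peaks and never M+0", {
  plan <- tibble::tibble(
    sample = "s1", metabolite = "glucose", formula = "C6H12O6",
    tracer_element = "C", model = "tracer", labeling = 0.25,
    n_label = NA_integer_, p_label = NA_real_)
  out <- emit_mids(plan, mid_sd = 0, intensity_cv = 0, detection_lod = 0.005)
  # unlabeled/fully-labeled mixture: M+0, its M+1 natural satellite, M+6
  expect_true(all(c(0L, 1L, 6L) %in% out$isotopologue))
  expect_false(any(c(3L, 4L) %in% out$isotopologue))
  expect_equal(sum(out$fraction), 1, tolerance = 1e-12)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_config(animals_per_arm = 2L)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  generate_experiment(cfg, seed = 11, dir = d1)
  generate_experiment(cfg, seed = 11, dir = d2)
  for (f in c("serum.csv", "tissue.csv", "manifest.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the data
  d3 <- file.path(withr::local_tempdir(), "c")
  generate_experiment(cfg, seed = 12, dir = d3)
  expect_false(identical(readLines(file.path(d1, "serum.csv")),
                         readLines(file.path(d3, "serum.csv"))))
})

test_that("generator demands a non-empty design", {
  expect_error(flux_config(tissues = character(0)),
               class = "midflux_config_error")
  expect_error(flux_config(nutrients = character(0)),
               class = "midflux_config_error")
})

test_that("recovery error grows monotonically with measurement noise", {
  errs <- vapply(c(0, 0.005, 0.05), function(sd) {
    cfg <- small_config(mid_sd = sd, intensity_cv = 0, animal_cv = 0,
                        animals_per_arm = 2L)
    reps <- vapply(1:4, function(r) {
      exp <- generate_experiment(cfg, seed = 300 + r)
      rec <- suppressWarnings(recover_experiment(exp))
      median(rec$abs_error[rec$quantity == "contribution"])
    }, numeric(1))
    median(reps)
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})
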