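test_that("infusion rate converts protocol units to nmol/min/g", {
  expect_equal(infusion_rate(500, 0.1), 50)
  expect_equal(infusion_rate(15, 0.1), 1.5)
  expect_equal(infusion_rate(150, 0.1), 15)
  expect_error(infusion_rate(-1, 0.1), class = "midflux_domain_error")
})

test_that("F_circ follows the tracer-dilution formula with guards", {
  expect_equal(f_circ(50, 0.5), 50)
  expect_equal(f_circ(50, 1), 0)
  expect_equal(f_circ(1.5, 0.1), 13.5)
  expect_error(f_circ(50, 0.004), class = "midflux_unreliable_labeling")
  expect_error(f_circ(50, 1.1), class = "midflux_domain_error")
  expect_error(f_circ(0, 0.5), class = "midflux_domain_error")
})

test_that("F_circ inverts the steady-state dilution exactly and is monotone", {
  withr::with_seed(5, {
    R <- runif(200, 0.5, 100)
    F <- runif(200, 1, 500)
    L <- simulate_serum_labeling(R, F)
    expect_equal(f_circ(R, L, l_min = 0), F, tolerance = 1e-12)
  })
  L_grid <- seq(0.01, 1, by = 0.01)
  vals <- f_circ(50, L_grid)
  expect_true(all(diff(vals) < 0))
})

test_that("normalized labeling is a guarded ratio", {
  expect_equal(normalized_labeling(0.2, 0.4), 0.5)
  expect_equal(normalized_labeling(0.3, 0.3), 1)
  expect_error(normalized_labeling(0.05, 0.005),
               class = "midflux_division_unstable")
})

test_that("direct contributions solve the worked cross-tracer system", {
  # decoupled system: identity map
  fit <- direct_contributions(diag(2), c(0.5, 0.3))
  expect_equal(unname(fit$contributions), c(0.5, 0.3))

  # 2x2 elimination: f1 + 0.2 f2 = 0.5 ; 0.3 f1 + f2 = 0.4
  fit <- direct_contributions(rbind(c(1, 0.2), c(0.3, 1)), c(0.5, 0.4))
  expect_equal(unname(fit$contributions), c(0.44680851, 0.26595745),
               tolerance = 1e-6)
  # substituting back reproduces both measured labelings
  expect_equal(as.numeric(rbind(c(1, 0.2), c(0.3, 1)) %*% fit$contributions),
               c(0.5, 0.4), tolerance = 1e-9)

  expect_error(direct_contributions(matrix(1, 2, 2), c(0.5, 0.5)),
               class = "midflux_singular_system")
  expect_error(direct_contributions(diag(2), c(0.5, 0.3, 0.1)),
               class = "midflux_shape_error")
  expect_error(direct_contributions(rbind(c(0.9, 0.5), c(0.2, 1)), c(0.5, 0.4)),
               class = "midflux_shape_error")
  expect_error(direct_contributions(rbind(c(1, 0.5), c(2, 1)), c(0.5, 0.4)),
               class = "midflux_domain_error")
})

test_that("constrained solve clips infeasible estimates and flags them", {
  cross <- rbind(c(1, 0.2), c(0.3, 1))
  # measured vector chosen so the exact solution has a negative component
  measured <- c(0.02, 0.5)
  fit <- direct_contributions(cross, measured)
  expect_true(all(fit$contributions >= 0 & fit$contributions <= 1))
  expect_true(fit$clipped[1])
  expect_lt(fit$unconstrained[1], 0)
  # the unconstrained exact solve is reported alongside
  expect_equal(as.numeric(cross %*% fit$unconstrained), measured,
               tolerance = 1e-9)
  # unconstrained mode returns the exact solution
  fit_u <- direct_contributions(cross, measured, constrain = FALSE)
  expect_equal(fit_u$contributions, fit_u$unconstrained)
})

test_that("raising a measured labeling never lowers its nutrient's estimate", {
  withr::with_seed(9, {
    for (i in 1:20) {
      off <- runif(2, 0, 0.3)
      cross <- rbind(c(1, off[1]), c(off[2], 1))
      measured <- runif(2, 0.1, 0.6)
      f0 <- direct_contributions(cross, measured)$contributions
      bumped <- measured + c(0.05, 0)
      f1 <- direct_contributions(cross, bumped)$contributions
      expect_gte(f1[1], f0[1] - 1e-9)
    }
  })
})

test_that("tidy and glance summarize a contribution fit", {
  fit <- direct_contributions(rbind(c(1, 0.2), c(0.3, 1)), c(0.5, 0.4),
                              nutrients = c("glucose", "glutamine"))
  td <- tidy(fit)
  expect_equal(td$nutrient, c("glucose", "glutamine"))
  expect_equal(td$contribution, unname(fit$contributions))
  gl <- glance(fit)
  expect_equal(gl$n_clipped, 0L)
  expect_lt(gl$residual, 1e-9)
  expect_equal(gl$total_contribution, sum(td$contribution))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("lipogenesis enrichment normalizes labeled hydrogens to body water", {
  # fully synthesized pool: 0.44 labeled H over 22 exchangeable at 2% water
  mid <- c(0.56, 0.44)  # mean labeled H = 0.44
  out <- lipogenesis_enrichment(mid, 0.02, 22)
  expect_equal(out$mean_labeled_H, 0.44)
  expect_equal(out$normalized_value, 1)

  out0 <- lipogenesis_enrichment(c(1, 0, 0), 0.02, 22)
  expect_equal(out0$normalized_value, 0)

  out25 <- lipogenesis_enrichment(c(0.89, 0.11), 0.02, 22)
  expect_equal(out25$normalized_value, 0.25)

  # default mode: plain water-normalized labeling (n_exchangeable_H = 1)
  out1 <- lipogenesis_enrichment(c(0.89, 0.11), 0.02)
  expect_equal(out1$normalized_value, 5.5)

  expect_error(lipogenesis_enrichment(mid, 0), class = "midflux_domain_error")
  expect_error(lipogenesis_enrichment(mid, 1), class = "midflux_domain_error")
})

test_that("lipogenesis value is linear in labeling, inverse in water", {
  base <- lipogenesis_enrichment(c(0.8, 0.2), 0.02, 22)$normalized_value
  doubled <- lipogenesis_enrichment(c(0.6, 0.4), 0.02, 22)$normalized_value
  expect_equal(doubled, 2 * base)
  halved_w <- lipogenesis_enrichment(c(0.8, 0.2), 0.04, 22)$normalized_value
  expect_equal(halved_w, base / 2)
})

test_that("protein synthesis rate scales content by labeling ratio", {
  expect_equal(protein_synthesis_rate(100, 0.02, 0.2, control_mean = 10), 1)
  expect_equal(protein_synthesis_rate(100, 0, 0.2, control_mean = 10), 0)
  expect_equal(protein_synthesis_rate(80, 0.03, 0.2, control_mean = 10), 1.2)
  expect_error(protein_synthesis_rate(100, 0.02, 0.005),
               class = "midflux_division_unstable")
})

test_that("protein synthesis table normalizes to the control diet", {
  tab <- tibble::tibble(
    tissue = rep(c("liver", "muscle"), each = 4),
    diet = rep(c("AA", "AA", "SAAR", "SAAR"), 2),
    protein_content = c(100, 120, 90, 95, 200, 210, 190, 185),
    tissue_met_L = c(0.020, 0.024, 0.015, 0.016, 0.010, 0.011, 0.009, 0.008),
    serum_met_L = 0.2)
  out <- protein_synthesis_pipeline(tab, control_diet = "AA")
  # control group mean relative rate is 1 by construction
  ctrl <- out[out$diet == "AA", ]
  means <- tapply(ctrl$relative_rate, ctrl$tissue, mean)
  expect_equal(as.numeric(means), c(1, 1))
  expect_true(all(out$relative_rate >= 0))
  expect_error(protein_synthesis_pipeline(tab, control_diet = "chow"),
               class = "midflux_incomplete_design")
})

test_that("HOMA-IR and OGTT area follow the printed formulas", {
  expect_equal(homa_ir(5, 90), 20)
  expect_equal(homa_ir(0, 90), 0)
  expect_equal(homa_ir(22.5, 1), 1)
  expect_error(homa_ir(-1, 90), class = "midflux_domain_error")

  expect_equal(auc_trapezoid(c(0, 15, 30), c(5, 10, 5)), 225)
  expect_equal(auc_trapezoid(c(0, 30, 60, 120), rep(7, 4)), 7 * 120)
  expect_equal(auc_trapezoid(c(0, 10), c(0, 10)), 50)
  expect_error(auc_trapezoid(c(0, 10, 5), c(1, 2, 3)),
               class = "midflux_ordering_error")
  expect_error(auc_trapezoid(c(0, 10), c(1, 2, 3)),
               class = "midflux_shape_error")
})
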