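#' Molar tracer infusion rate from the infusion protocol
#'
#' Converts the infusion protocol (tracer concentration in mmol/L, syringe
#' pump rate in uL/min per g body weight) to the molar infusion rate R in
#' nmol/min per g body weight. Since 1 mmol/L is 1 nmol/uL, the conversion
#' is a plain product: 500 mmol/L glucose at 0.1 uL/min/g gives
#' R = 50 nmol/min/g.
#'
#' @param concentration Tracer concentration in the infusate, mmol/L.
#' @param pump_rate Pump rate, uL/min per g body weight (default 0.1, the
#'   standard jugular-vein infusion setting).
#' @return Infusion rate R in nmol/min per g body weight.
#' @export
infusion_rate <- function(concentration, pump_rate = 0.1) {
  if (any(concentration <= 0) || any(pump_rate <= 0)) {
    stop_domain("Concentration and pump rate must be positive.")
  }
  concentration * pump_rate
}

#' Circulatory turnover flux from serum tracer dilution
#'
#' At isotopic pseudo-steady state, the infused tracer is diluted in the
#' circulation by endogenous production: `F_circ = R * (1 - L) / L`, where
#' R is the molar infusion rate and L the atom (labeling) fraction of the
#' metabolite in venous serum. `L = 1` means no endogenous turnover
#' (`F_circ = 0`); as `L` approaches 0 the estimate diverges, so labeling
#' below `l_min` is rejected as unreliable.
#'
#' @param R Infusion rate, nmol/min per g body weight.
#' @param L Serum atom fraction of the infused metabolite, in `(0, 1]`.
#' @param l_min Guard threshold below which `L` is considered too small for
#'   a reliable estimate (default 0.005).
#' @return F_circ in nmol/min per g body weight (vectorized over inputs).
#' @examples
#' f_circ(50, 0.25)  # 150 nmol/min/g
#' @export
f_circ <- function(R, L, l_min = 0.005) {
  if (any(R <= 0)) stop_domain("Infusion rate R must be positive.")
  if (any(L > 1)) stop_domain("Labeling fraction L cannot exceed 1.")
  if (any(L <= l_min)) {
    stop_unreliable_labeling(paste0(
      "Serum labeling L <= ", l_min,
      ": F_circ diverges as L approaches 0; measurement too dilute."))
  }
  R * (1 - L) / L
}

#' Normalized labeling of a downstream metabolite
#'
#' Carbon-transfer efficiency from an infused tracer X to a metabolite Y:
#' `L_{Y<-X} = L_Y / L_X`, the atom fraction of Y divided by the atom
#' fraction of the circulating tracer. Values slightly above 1 can occur
#' with measurement noise.
#'
#' @param l_y Atom fraction of the downstream metabolite.
#' @param l_x Atom fraction of the infused tracer in serum.
#' @param threshold Minimum denominator (default 0.01); below it the ratio
#'   is numerically unstable and an error is raised.
#' @return Ratio `L_Y / L_X` (vectorized).
#' @export
normalized_labeling <- function(l_y, l_x, threshold = 0.01) {
  if (any(l_x <= threshold)) {
    stop_division_unstable(paste0(
      "Tracer labeling below ", threshold, ": normalized labeling unstable."))
  }
  l_y / l_x
}

#' De novo lipogenesis enrichment from deuterated-water labeling
#'
#' Summarizes the 2H-corrected MID of a saponified fatty acid into the mean
#' number of labeled hydrogens per molecule, `sum(i * f[i])`, and normalizes
#' it to body-water 2H enrichment:
#' `normalized = mean_labeled_H / (n_exchangeable_H * water_enrichment)`.
#' With `n_exchangeable_H = 1` (the default) this is the plain
#' water-normalized 2H labeling fraction; with `n_exchangeable_H` set to the
#' number of water-derived hydrogens incorporated during synthesis (e.g. 22
#' for C18:1) the value is interpretable as the newly synthesized fraction
#' of the fatty-acid pool.
#'
#' @param fractions 2H-corrected MID of the fatty acid (M+0 first).
#' @param water_enrichment Body-water 2H enrichment, in `(0, 1)`.
#' @param n_exchangeable_H Water-derived hydrogens per molecule (default 1).
#' @return A tibble with `mean_labeled_H`, `water_enrichment`,
#'   `n_exchangeable_H` and `normalized_value`.
#' @export
lipogenesis_enrichment <- function(fractions, water_enrichment,
                                   n_exchangeable_H = 1L) {
  if (water_enrichment <= 0 || water_enrichment >= 1) {
    stop_domain("Body-water enrichment must lie strictly between 0 and 1.")
  }
  if (n_exchangeable_H < 1L) stop_domain("n_exchangeable_H must be >= 1.")
  mean_h <- sum((seq_along(fractions) - 1L) * fractions)
  tibble(
    mean_labeled_H = mean_h,
    water_enrichment = water_enrichment,
    n_exchangeable_H = as.integer(n_exchangeable_H),
    normalized_value = mean_h / (n_exchangeable_H * water_enrichment)
  )
}

#' Relative protein synthesis rate from heavy amino-acid incorporation
#'
#' After a 13C-methionine infusion, the labeling of methionine liberated
#' from hydrolyzed tissue protein, relative to serum methionine labeling
#' and scaled by the organ's protein content, indexes protein synthesis:
#' `raw = protein_content * tissue_protein_met_L / serum_met_L`, reported
#' relative to the mean of a control group
#' (`relative = raw / control_mean`).
#'
#' @param protein_content Organ protein content, mg.
#' @param tissue_protein_met_L Atom fraction of methionine in hydrolyzed
#'   tissue protein.
#' @param serum_met_L Atom fraction of serum methionine (must exceed
#'   `threshold`).
#' @param control_mean Mean raw rate of the control group used for
#'   normalization (default 1, i.e. report the raw rate).
#' @param threshold Minimum serum labeling (default 0.01).
#' @return Relative synthesis rate (vectorized).
#' @export
protein_synthesis_rate <- function(protein_content, tissue_protein_met_L,
                                   serum_met_L, control_mean = 1,
                                   threshold = 0.01) {
  if (any(serum_met_L <= threshold)) {
    stop_division_unstable("Serum methionine labeling below threshold.")
  }
  if (any(control_mean <= 0)) stop_domain("control_mean must be positive.")
  protein_content * tissue_protein_met_L / serum_met_L / control_mean
}

#' Homeostasis model assessment of insulin resistance
#'
#' `HOMA-IR = insulin (uU/mL) * glucose (mg/dL) / 22.5`, implemented
#' verbatim as used with mass-unit glucose. Note the common variant of this
#' index divides mmol/L glucose by 22.5 (equivalently mg/dL by 405); this
#' function reproduces the mass-unit/22.5 form as printed, so values are
#' directly comparable with that convention only.
#'
#' @param insulin Fasting insulin, uU/mL.
#' @param glucose Fasting glucose, mg/dL.
#' @return HOMA-IR index (vectorized).
#' @examples
#' homa_ir(5, 90)  # 20
#' @export
homa_ir <- function(insulin, glucose) {
  if (any(insulin < 0) || any(glucose < 0)) {
    stop_domain("Insulin and glucose must be non-negative.")
  }
  insulin * glucose / 22.5
}

#' Trapezoidal area under a glucose-tolerance curve
#'
#' Standard trapezoidal integration of measured values over time, as used
#' to summarize an oral glucose tolerance test.
#'
#' @param times Measurement times (minutes), strictly increasing.
#' @param values Measured values (e.g. blood glucose, mg/dL).
#' @return Area under the curve.
#' @export
auc_trapezoid <- function(times, values) {
  if (length(times) != length(values) || length(times) < 2L) {
    stop_shape("times and values must have equal length >= 2.")
  }
  if (any(diff(times) <= 0)) {
    stop_ordering("times must be strictly increasing.")
  }
  sum(diff(times) * (head(values, -1) + tail(values, -1)) / 2)
}
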