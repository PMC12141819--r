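#' Atom fractions of an isotopologue table, joined to the sample manifest
#'
#' Convenience step shared by the estimators: natural-abundance-correct a
#' long isotopologue table, collapse to atom fractions and join the sample
#' manifest (`sample`, `animal`, `arm`, `tissue`, `diet`, `state`, ...).
#'
#' @param data Long isotopologue tibble.
#' @param manifest Sample manifest tibble keyed by `sample`.
#' @param config A [flux_config()] object (correction mode, value column).
#' @return Tibble of per-sample, per-metabolite atom fractions with
#'   manifest columns attached.
#' @export
labeling_summary <- function(data, manifest, config = flux_config()) {
  corrected <- correct_isotopologues(data, value = config$value_col,
                                     resolution = config$resolution_mode)
  af <- atom_fractions(corrected)
  dplyr::inner_join(af, manifest, by = "sample")
}

#' Estimate circulatory turnover fluxes from serum labeling
#'
#' For every infusion arm present in the manifest, corrects the serum MIDs
#' of the infused metabolite, averages the per-animal atom fractions within
#' each diet/state group, converts the protocol to a molar infusion rate R
#' and applies `F_circ = R (1 - L) / L`.
#'
#' @param serum Serum isotopologue tibble.
#' @param manifest Sample manifest.
#' @param config A [flux_config()] object.
#' @return Tibble with one row per `(metabolite, diet, state)`:
#'   `n_animals`, `serum_L`, `R`, `f_circ`.
#' @export
estimate_f_circ <- function(serum, manifest, config = flux_config()) {
  lab <- labeling_summary(serum, manifest, config)
  lab <- lab[lab$tissue == "serum" & lab$metabolite == lab$arm, ]
  if (!nrow(lab)) stop_incomplete_design("No serum measurements of an infused tracer.")
  keys <- paste(lab$metabolite, lab$diet, lab$state, sep = "\r")
  dplyr::bind_rows(lapply(split(seq_len(nrow(lab)), keys), function(rows) {
    g <- lab[rows, ]
    l_mean <- mean(g$atom_fraction)
    R <- infusion_rate(
      tracer_concentration(config, g$metabolite[1], g$state[1]),
      config$pump_rate)
    tibble(
      metabolite = g$metabolite[1], diet = g$diet[1], state = g$state[1],
      n_animals = length(unique(g$animal)), serum_L = l_mean, R = R,
      f_circ = f_circ(R, l_mean, l_min = config$l_min))
  }))
}

# per-animal serum atom fractions of all system nutrients, one group
arm_serum_labelings <- function(lab, config, diet, state) {
  nutrients <- config$nutrients
  out <- list()
  for (arm in nutrients) {
    g <- lab[lab$arm == arm & lab$diet == diet & lab$state == state &
             lab$tissue == "serum" & lab$metabolite %in% nutrients, ]
    if (!nrow(g) || !any(g$metabolite == arm)) {
      stop_incomplete_design(paste0(
        "Missing serum data for tracer arm '", arm, "' (diet ", diet,
        ", state ", state, ")."))
    }
    wide <- tidyr::pivot_wider(g[c("animal", "metabolite", "atom_fraction")],
                               names_from = "metabolite",
                               values_from = "atom_fraction")
    out[[arm]] <- wide
  }
  out
}

# group-mean cross matrix from per-animal serum labelings (mean L before ratio)
cross_from_serum <- function(serum_by_arm, config, idx = NULL) {
  nutrients <- config$nutrients
  k <- length(nutrients)
  cross <- diag(k)
  dimnames(cross) <- list(nutrients, nutrients)
  for (j in seq_len(k)) {
    arm <- nutrients[j]
    wide <- serum_by_arm[[arm]]
    rows <- if (is.null(idx)) seq_len(nrow(wide)) else idx[[arm]]
    l_tracer <- mean(wide[[arm]][rows])
    for (i in seq_len(k)) {
      if (i != j) {
        nut <- nutrients[i]
        l_nut <- if (nut %in% names(wide)) mean(wide[[nut]][rows]) else {
          stop_incomplete_design(paste0(
            "Serum panel of arm '", arm, "' lacks nutrient '", nut, "'."))
        }
        cross[j, i] <- normalized_labeling(l_nut, l_tracer,
                                           threshold = config$ratio_threshold)
      }
    }
  }
  cross
}

#' Direct contributions of circulating nutrients to tissue metabolites
#'
#' End-to-end cross-tracer analysis: corrects serum and tissue isotopologue
#' tables, computes per-animal atom fractions, averages within each
#' diet/state group (mean labeling before ratios), assembles the serum
#' cross-labeling matrix and the measured tissue vector for every tissue
#' and target metabolite, and solves the constrained linear system for the
#' direct contribution of each nutrient. Uncertainty comes from a
#' nonparametric bootstrap that resamples animals within each arm and
#' re-runs the whole group-mean-and-solve procedure.
#'
#' @param serum,tissue Long isotopologue tibbles.
#' @param manifest Sample manifest.
#' @param config A [flux_config()] object (`bootstrap_draws = 0` skips the
#'   bootstrap; `per_animal = TRUE` solves one system per matched animal
#'   index and summarizes across animals instead).
#' @param seed Seed for the bootstrap resampling.
#' @return Tibble with one row per
#'   `(diet, state, tissue, target, nutrient)`: `contribution`,
#'   `ci_lower`/`ci_upper` (percentile bootstrap), `unconstrained`,
#'   `clipped`, `residual`, `n_animals`.
#' @export
tca_contribution_pipeline <- function(serum, tissue, manifest,
                                      config = flux_config(),
                                      seed = config$seed) {
  lab_serum <- labeling_summary(serum, manifest, config)
  lab_tissue <- labeling_summary(tissue, manifest, config)
  lab_tissue <- lab_tissue[lab_tissue$arm %in% config$nutrients &
                           lab_tissue$metabolite %in% config$targets, ]
  if (!nrow(lab_tissue)) {
    stop_incomplete_design("No tissue target measurements under a nutrient arm.")
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  groups <- unique(lab_tissue[c("diet", "state")])
  dplyr::bind_rows(lapply(seq_len(nrow(groups)), function(gi) {
    diet <- groups$diet[gi]; state <- groups$state[gi]
    serum_by_arm <- arm_serum_labelings(lab_serum, config, diet, state)
    tis_g <- lab_tissue[lab_tissue$diet == diet & lab_tissue$state == state, ]
    if (isTRUE(config$per_animal)) {
      per_animal_solve(serum_by_arm, tis_g, config, diet, state)
    } else {
      group_mean_solve(serum_by_arm, tis_g, config, diet, state)
    }
  }))
}

# measured vector for one tissue x target: mean tissue L / mean serum tracer L
measured_vector <- function(tis_g, serum_by_arm, config, tissue, target,
                            idx_serum = NULL, idx_tissue = NULL) {
  vapply(config$nutrients, function(arm) {
    g <- tis_g[tis_g$arm == arm & tis_g$tissue == tissue &
               tis_g$metabolite == target, ]
    if (!nrow(g)) {
      stop_incomplete_design(paste0(
        "Missing tracer arm '", arm, "' for tissue '", tissue,
        "', target '", target, "'."))
    }
    rows_t <- if (is.null(idx_tissue)) seq_len(nrow(g)) else {
      match(idx_tissue[[arm]], g$animal)
    }
    wide <- serum_by_arm[[arm]]
    rows_s <- if (is.null(idx_serum)) seq_len(nrow(wide)) else idx_serum[[arm]]
    normalized_labeling(mean(g$atom_fraction[rows_t], na.rm = TRUE),
                        mean(wide[[arm]][rows_s]),
                        threshold = config$ratio_threshold)
  }, numeric(1))
}

group_mean_solve <- function(serum_by_arm, tis_g, config, diet, state) {
  cross <- cross_from_serum(serum_by_arm, config)
  combos <- unique(tis_g[c("tissue", "metabolite")])
  draws <- as.integer(config$bootstrap_draws)

  # one joint animal resampling per draw, reused across tissues/targets so
  # resampled cross terms and measured vectors stay internally consistent
  boot_idx <- NULL
  if (draws > 0) {
    boot_idx <- purrr::map(seq_len(draws), function(d) {
      purrr::map(config$nutrients, function(arm) {
        wide <- serum_by_arm[[arm]]
        animals <- wide$animal
        sample(animals, length(animals), replace = TRUE)
      }) |> setNames(config$nutrients)
    })
  }

  dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(ci) {
    tissue <- combos$tissue[ci]; target <- combos$metabolite[ci]
    measured <- measured_vector(tis_g, serum_by_arm, config, tissue, target)
    fit <- direct_contributions(cross, measured, nutrients = config$nutrients,
                                constrain = config$constrain)
    td <- tidy(fit)
    ci_lo <- rep(NA_real_, nrow(td)); ci_hi <- rep(NA_real_, nrow(td))
    if (draws > 0) {
      boot <- matrix(NA_real_, draws, length(config$nutrients))
      for (d in seq_len(draws)) {
        idx <- purrr::map(config$nutrients, function(arm) {
          match(boot_idx[[d]][[arm]], serum_by_arm[[arm]]$animal)
        }) |> setNames(config$nutrients)
        idx_animals <- purrr::map(boot_idx[[d]], identity)
        cross_b <- tryCatch(cross_from_serum(serum_by_arm, config, idx),
                            midflux_error = function(e) NULL)
        if (is.null(cross_b)) next
        measured_b <- tryCatch(
          measured_vector(tis_g, serum_by_arm, config, tissue, target,
                          idx_serum = idx, idx_tissue = idx_animals),
          midflux_error = function(e) NULL)
        if (is.null(measured_b)) next
        fit_b <- tryCatch(
          direct_contributions(cross_b, pmin(pmax(measured_b, 0), 1.5),
                               nutrients = config$nutrients,
                               constrain = config$constrain),
          midflux_error = function(e) NULL)
        if (!is.null(fit_b)) boot[d, ] <- fit_b$contributions
      }
      ok <- stats::complete.cases(boot)
      if (any(ok)) {
        ci_lo <- apply(boot[ok, , drop = FALSE], 2, quantile, 0.025)
        ci_hi <- apply(boot[ok, , drop = FALSE], 2, quantile, 0.975)
      }
    }
    n_animals <- min(vapply(config$nutrients, function(arm) {
      length(unique(tis_g$animal[tis_g$arm == arm & tis_g$tissue == tissue &
                                 tis_g$metabolite == target]))
    }, numeric(1)))
    tibble(
      diet = diet, state = state, tissue = tissue, target = target,
      nutrient = td$nutrient, contribution = td$contribution,
      ci_lower = as.numeric(ci_lo), ci_upper = as.numeric(ci_hi),
      unconstrained = td$unconstrained, clipped = td$clipped,
      residual = fit$residual, n_animals = n_animals)
  }))
}

per_animal_solve <- function(serum_by_arm, tis_g, config, diet, state) {
  counts <- vapply(serum_by_arm, nrow, numeric(1))
  if (length(unique(counts)) != 1L) {
    stop_incomplete_design(
      "per_animal solving requires equal animal counts across arms.")
  }
  combos <- unique(tis_g[c("tissue", "metabolite")])
  dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(ci) {
    tissue <- combos$tissue[ci]; target <- combos$metabolite[ci]
    per <- lapply(seq_len(counts[1]), function(k) {
      idx <- purrr::map(serum_by_arm, function(w) k)
      idx_animals <- purrr::map(serum_by_arm, function(w) w$animal[k])
      cross_k <- cross_from_serum(serum_by_arm, config, idx)
      measured_k <- measured_vector(tis_g, serum_by_arm, config, tissue,
                                    target, idx_serum = idx,
                                    idx_tissue = idx_animals)
      direct_contributions(cross_k, pmin(pmax(measured_k, 0), 1.5),
                           nutrients = config$nutrients,
                           constrain = config$constrain)$contributions
    })
    mat <- do.call(rbind, per)
    tibble(
      diet = diet, state = state, tissue = tissue, target = target,
      nutrient = config$nutrients,
      contribution = as.numeric(colMeans(mat)),
      ci_lower = as.numeric(apply(mat, 2, quantile, 0.025)),
      ci_upper = as.numeric(apply(mat, 2, quantile, 0.975)),
      unconstrained = NA_real_, clipped = NA,
      residual = NA_real_, n_animals = unname(counts[1]))
  }))
}

#' Deuterated-water lipogenesis analysis
#'
#' Corrects the 2H MIDs of saponified fatty acids from the drinking-water
#' arm, computes each animal's mean labeled hydrogens per molecule, divides
#' by the animal's measured body-water enrichment (the
#' `water_enrichment` manifest column), and summarizes per tissue and diet.
#' Two normalizations are reported: `water_normalized_labeling`
#' (`n_exchangeable_H = 1`, the plain water-normalized 2H labeling
#' fraction) and `new_synthesis_fraction` (dividing additionally by the
#' fatty acid's configured number of water-derived hydrogens, interpretable
#' as the newly synthesized fraction of the pool).
#'
#' @param tissue Long isotopologue tibble containing the fatty-acid rows.
#' @param manifest Sample manifest with a `water_enrichment` column for the
#'   water-arm samples.
#' @param config A [flux_config()] object.
#' @return Tibble per `(diet, tissue, fatty_acid)` with group means, SEM
#'   and `n_animals`.
#' @export
lipogenesis_pipeline <- function(tissue, manifest, config = flux_config()) {
  lab <- labeling_summary_lipo(tissue, manifest, config)
  if (!nrow(lab)) stop_incomplete_design("No deuterated-water arm measurements.")
  keys <- paste(lab$diet, lab$tissue, lab$metabolite, sep = "\r")
  dplyr::bind_rows(lapply(split(seq_len(nrow(lab)), keys), function(rows) {
    g <- lab[rows, ]
    n_ex <- n_exchangeable_for(config, g$metabolite[1])
    norm1 <- g$mean_labeled_H / g$water_enrichment
    gfrac <- norm1 / n_ex
    tibble(
      diet = g$diet[1], tissue = g$tissue[1], fatty_acid = g$metabolite[1],
      n_animals = nrow(g),
      mean_labeled_H = mean(g$mean_labeled_H),
      water_normalized_labeling = mean(norm1),
      water_normalized_sem = stats::sd(norm1) / sqrt(nrow(g)),
      new_synthesis_fraction = mean(gfrac),
      new_synthesis_sem = stats::sd(gfrac) / sqrt(nrow(g)))
  }))
}

# per-sample mean labeled hydrogens for water-arm fatty acids
labeling_summary_lipo <- function(tissue, manifest, config) {
  man <- manifest[manifest$arm == "2H2O", ]
  if (!nrow(man)) return(tibble())
  data <- tissue[tissue$sample %in% man$sample, ]
  if (!nrow(data)) return(tibble())
  corrected <- correct_isotopologues(data, value = config$value_col,
                                     resolution = config$resolution_mode)
  keys <- paste(corrected$sample, corrected$metabolite, sep = "\r")
  per <- dplyr::bind_rows(lapply(split(seq_len(nrow(corrected)), keys),
                                 function(rows) {
    g <- corrected[rows, ]
    tibble(sample = g$sample[1], metabolite = g$metabolite[1],
           mean_labeled_H = sum(g$isotopologue * g$fraction))
  }))
  dplyr::inner_join(per, man, by = "sample")
}

#' Corrected-MID summaries for bolus readouts
#'
#' Bolus tracer readouts (2-deoxyglucose phosphorylation, labeled palmitate
#' oxidation products) are reported as corrected labeled fractions and
#' labeled signal totals rather than model-derived fluxes: this collapses a
#' corrected table to the fraction of a chosen isotopologue and the total
#' labeled (M+1 and above) fraction per measurement.
#'
#' @param data Long isotopologue tibble.
#' @param shift Isotopologue of interest (default 2, e.g. M+2 from
#'   13C-palmitate-derived acetyl units).
#' @param config A [flux_config()] object.
#' @return Tibble per `(sample, metabolite)` with `fraction_m_shift` and
#'   `labeled_fraction`.
#' @export
labeled_fraction_summary <- function(data, shift = 2L, config = flux_config()) {
  corrected <- correct_isotopologues(data, value = config$value_col,
                                     resolution = config$resolution_mode)
  keys <- paste(corrected$sample, corrected$metabolite, sep = "\r")
  dplyr::bind_rows(lapply(split(seq_len(nrow(corrected)), keys),
                          function(rows) {
    g <- corrected[rows, ]
    tibble(sample = g$sample[1], metabolite = g$metabolite[1],
           fraction_m_shift = sum(g$fraction[g$isotopologue == shift]),
           labeled_fraction = sum(g$fraction[g$isotopologue > 0]))
  }))
}

#' Relative protein synthesis rates for a table of organs
#'
#' Applies [protein_synthesis_rate()] row-wise to a table of per-animal
#' organ measurements from a 13C-methionine infusion and normalizes each
#' tissue to the mean raw rate of the control diet group.
#'
#' @param data Tibble with columns `tissue`, `diet`, `protein_content`
#'   (mg), `tissue_met_L` and `serum_met_L` (atom fractions), one row per
#'   animal and organ.
#' @param control_diet Diet label of the normalization group (default
#'   `"AA"`).
#' @param threshold Minimum serum methionine labeling.
#' @return Input tibble with `raw_rate` and `relative_rate` columns added.
#' @export
protein_synthesis_pipeline <- function(data, control_diet = "AA",
                                       threshold = 0.01) {
  needed <- c("tissue", "diet", "protein_content", "tissue_met_L",
              "serum_met_L")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop_format(paste0("Protein table lacks column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (!any(data$diet == control_diet)) {
    stop_incomplete_design(paste0("No rows for control diet '",
                                  control_diet, "'."))
  }
  data <- as_tibble(data)
  data$raw_rate <- protein_synthesis_rate(
    data$protein_content, data$tissue_met_L, data$serum_met_L,
    control_mean = 1, threshold = threshold)
  ctrl <- data[data$diet == control_diet, ]
  ctrl_means <- tapply(ctrl$raw_rate, ctrl$tissue, mean)
  cm <- ctrl_means[data$tissue]
  if (anyNA(cm)) {
    stop_incomplete_design("Some tissues have no control-diet rows.")
  }
  data$relative_rate <- data$raw_rate / as.numeric(cm)
  data
}

#' Compare estimates from a synthetic experiment against its ground truth
#'
#' Runs the full analysis (circulatory fluxes, direct contributions,
#' lipogenesis) on a synthetic experiment and joins each estimate to the
#' truth record, giving one row per recoverable quantity with absolute and
#' relative error.
#'
#' @param experiment A `synthetic_experiment` (in memory or from
#'   [read_experiment()]); must carry a truth record.
#' @param config Configuration (defaults to the experiment's own).
#' @param bootstrap_draws Bootstrap draws for the contribution solve
#'   (default 0 here: recovery needs point estimates).
#' @return Tibble with columns `quantity`, `metabolite`, `tissue`, `diet`,
#'   `state`, `nutrient`, `truth`, `estimate`, `abs_error`, `rel_error`.
#' @export
recover_experiment <- function(experiment, config = experiment$config,
                               bootstrap_draws = 0L) {
  if (is.null(experiment$truth)) {
    stop_config("Experiment carries no truth record to recover against.")
  }
  truth <- experiment$truth
  cfg <- config
  cfg$bootstrap_draws <- as.integer(bootstrap_draws)

  fc <- estimate_f_circ(experiment$serum, experiment$manifest, cfg)
  fc_cmp <- dplyr::inner_join(
    fc, truth$f_circ,
    by = c("metabolite", "diet", "state"), suffix = c("_est", "_true"))
  out_fc <- tibble(
    quantity = "f_circ", metabolite = fc_cmp$metabolite,
    tissue = "serum", diet = fc_cmp$diet, state = fc_cmp$state,
    nutrient = NA_character_,
    truth = fc_cmp$f_circ_true, estimate = fc_cmp$f_circ_est)

  contrib <- tca_contribution_pipeline(experiment$serum, experiment$tissue,
                                       experiment$manifest, cfg)
  contrib_cmp <- dplyr::inner_join(
    contrib, truth$contributions,
    by = c("tissue", "diet", "nutrient", "target"),
    suffix = c("_est", "_true"))
  out_ct <- tibble(
    quantity = "contribution", metabolite = contrib_cmp$target,
    tissue = contrib_cmp$tissue, diet = contrib_cmp$diet,
    state = contrib_cmp$state, nutrient = contrib_cmp$nutrient,
    truth = contrib_cmp$contribution_true,
    estimate = contrib_cmp$contribution_est)

  out_lp <- tibble()
  if (any(experiment$manifest$arm == "2H2O")) {
    lipo <- lipogenesis_pipeline(experiment$tissue, experiment$manifest, cfg)
    lipo_cmp <- dplyr::inner_join(lipo, truth$lipogenesis,
                                  by = c("diet", "tissue", "fatty_acid"))
    out_lp <- tibble(
      quantity = "lipogenesis", metabolite = lipo_cmp$fatty_acid,
      tissue = lipo_cmp$tissue, diet = lipo_cmp$diet, state = NA_character_,
      nutrient = NA_character_,
      truth = lipo_cmp$new_fraction,
      estimate = lipo_cmp$new_synthesis_fraction)
  }

  out <- dplyr::bind_rows(out_fc, out_ct, out_lp)
  out$abs_error <- abs(out$estimate - out$truth)
  out$rel_error <- ifelse(out$truth != 0, out$abs_error / abs(out$truth), NA)
  out
}
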