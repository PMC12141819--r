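#' Serum labeling of an infused tracer at pseudo-steady state
#'
#' Closed-form inverse of the circulatory-flux relation: a tracer infused at
#' molar rate R into a pool turning over at F_circ plateaus at atom fraction
#' `L = R / (R + F_circ)`. With no endogenous production (`F_circ = 0`) the
#' circulation becomes fully labeled.
#'
#' @param R Infusion rate, nmol/min per g.
#' @param f_circ True circulatory turnover flux, nmol/min per g.
#' @return Atom fraction in `[0, 1]` (vectorized).
#' @examples
#' simulate_serum_labeling(50, 150)  # 0.25
#' @export
simulate_serum_labeling <- function(R, f_circ) {
  if (any(R < 0) || any(f_circ < 0)) stop_domain("R and f_circ must be >= 0.")
  ifelse(f_circ == 0, 1, R / (R + f_circ))
}

#' Tissue labeling implied by true direct contributions
#'
#' Forward form of the cross-tracer system: under infusion arm j the
#' normalized labeling of a tissue target is
#' `sum_i contributions[i] * cross[j, i]` (the infused nutrient contributes
#' with weight 1 on the diagonal).
#'
#' @param contributions Named vector of true direct contributions.
#' @param cross Arm-by-nutrient matrix of true serum cross-labelings
#'   (diagonal 1).
#' @param arm Arm name or row index.
#' @return Normalized labeling of the target under that arm.
#' @examples
#' cross <- rbind(glucose = c(glucose = 1, glutamine = 0.2),
#'                glutamine = c(glucose = 0.05, glutamine = 1))
#' simulate_tissue_labeling(c(glucose = 0.6, glutamine = 0.1), cross, "glucose")
#' @export
simulate_tissue_labeling <- function(contributions, cross, arm) {
  cross <- as.matrix(cross)
  if (length(contributions) != ncol(cross)) {
    stop_shape("contributions length must match the cross matrix columns.")
  }
  sum(contributions * cross[arm, ])
}

#' Sample a ground-truth record for a synthetic experiment
#'
#' Draws the quantities the estimators must recover: circulatory fluxes per
#' metabolite, diet and state; the serum cross-labeling matrix; per-tissue
#' and per-target direct-contribution vectors (with total contribution of
#' the modeled nutrients capped at 0.9); and newly-synthesized fatty-acid
#' fractions for the deuterated-water arm. Base turnover magnitudes (150,
#' 60 and 20 nmol/min per g for glucose, glutamine and methionine) are
#' typical of refed mice and give serum enrichments in the 10-25% range the
#' single-tracer infusion design is calibrated for; each diet/state draws a
#' seeded multiplier around its base so recovery is tested on varied values.
#' Uses the current RNG state; seed via [generate_experiment()].
#'
#' @param config A [flux_config()] object.
#' @return A list of class `synthetic_truth` with elements `f_circ`,
#'   `cross`, `contributions`, `lipogenesis`, `noise`.
#' @export
sample_truth <- function(config = flux_config()) {
  base <- c(glucose = 150, glutamine = 60, methionine = 20)
  n_nut <- length(config$nutrients)

  arms <- tidyr::expand_grid(metabolite = config$nutrients,
                             diet = config$diets, state = config$states)
  if (isTRUE(config$methionine_arms)) {
    arms <- dplyr::bind_rows(
      arms,
      tidyr::expand_grid(metabolite = "methionine", diet = config$diets,
                         state = c("fast", "refed")))
  }
  arms$f_circ <- vapply(seq_len(nrow(arms)), function(i) {
    b <- base[arms$metabolite[i]]
    if (is.na(b)) b <- runif(1, 40, 200)
    unname(b * runif(1, 0.8, 1.25))
  }, numeric(1))

  cross <- diag(n_nut)
  dimnames(cross) <- list(config$nutrients, config$nutrients)
  defaults <- matrix(NA_real_, n_nut, n_nut, dimnames = dimnames(cross))
  if (all(c("glucose", "glutamine") %in% config$nutrients)) {
    defaults["glucose", "glutamine"] <- 0.15  # serum gln labeling under glc arm
    defaults["glutamine", "glucose"] <- 0.05
  }
  for (j in seq_len(n_nut)) for (i in seq_len(n_nut)) {
    if (i != j) {
      cross[j, i] <- if (!is.na(defaults[j, i])) defaults[j, i]
                     else runif(1, 0.03, 0.2)
    }
  }

  contrib <- tidyr::expand_grid(tissue = config$tissues,
                                target = config$targets, diet = config$diets)
  contrib_rows <- purrr::map_dfr(seq_len(nrow(contrib)), function(i) {
    f <- c(runif(1, 0.25, 0.65), runif(n_nut - 1L, 0.05, 0.25))
    if (sum(f) > 0.9) f <- f * 0.9 / sum(f)
    tibble(tissue = contrib$tissue[i], target = contrib$target[i],
           diet = contrib$diet[i], nutrient = config$nutrients,
           contribution = f)
  })

  lipo <- tidyr::expand_grid(tissue = config$tissues, diet = config$diets)
  lipo$new_fraction <- runif(nrow(lipo), 0.1, 0.6)
  lipo$fatty_acid <- config$fatty_acid

  structure(
    list(
      f_circ = arms,
      cross = cross,
      contributions = contrib_rows,
      lipogenesis = lipo,
      water_enrichment = config$body_water_enrichment,
      noise = list(mid_sd = config$mid_sd, intensity_cv = config$intensity_cv,
                   animal_cv = config$animal_cv,
                   detection_lod = effective_lod(config)),
      animals_per_arm = as.integer(config$animals_per_arm)
    ),
    class = "synthetic_truth"
  )
}

# multiplicative inter-animal jitter, clamped to a valid fraction
jitter_fraction <- function(x, cv, lo = 1e-6, hi = 0.999999) {
  if (cv == 0) return(x)
  pmin(pmax(x * (1 + rnorm(length(x), 0, cv)), lo), hi)
}

# Emit one measured MID: true distribution -> forward natural-abundance
# convolution -> detection-limit censoring -> additive fraction noise ->
# renormalization -> intensity scaling.
emit_one_mid <- function(true_mid, formula, tracer_element, abundances,
                         resolution, mid_sd, lod, intensity_cv) {
  n <- length(true_mid) - 1L
  m <- cached_correction_matrix(formula, tracer_element, n, abundances,
                                resolution)
  meas <- as.numeric(m %*% true_mid)
  keep <- which(meas >= lod | seq_along(meas) == 1L)
  f <- meas[keep]
  if (mid_sd > 0) f <- pmax(f + rnorm(length(f), 0, mid_sd), 0)
  f <- f / sum(f)
  tic <- 1e6 * exp(rnorm(1, 0, intensity_cv))
  list(isotopologue = keep - 1L, fraction = f, intensity = f * tic)
}

# true within-molecule distributions for the three forward models
true_mid_tracer <- function(L, n) {
  x <- numeric(n + 1L); x[1] <- 1 - L; x[n + 1L] <- L; x
}
true_mid_binomial <- function(L, n) dbinom(0:n, n, L)
true_mid_lipid <- function(g, n_total, n_label, w) {
  x <- numeric(n_total + 1L)
  x[1] <- 1 - g
  b <- dbinom(0:n_label, n_label, w)
  x[seq_len(n_label + 1L)] <- x[seq_len(n_label + 1L)] + g * b
  x
}

#' Emit measured isotopologue tables from true labeling states
#'
#' Forward measurement model of the simulator, exposed on a labeling plan
#' table: each row names a sample/metabolite and its true labeling, the
#' within-molecule model (`"tracer"` = unlabeled/fully-labeled mixture for
#' the infused nutrient itself, `"binomial"` = per-atom labeling for
#' downstream metabolites, `"lipid"` = unlabeled/newly-synthesized mixture
#' with `n_label` water-derived hydrogens at enrichment `p_label`). The
#' true MID is convolved with natural abundance, isotopologues whose
#' expected fraction falls below the detection limit are censored (never
#' M+0), additive Gaussian noise is applied to the retained fractions,
#' which are renormalized and scaled to intensities.
#'
#' @param plan Tibble with columns `sample`, `metabolite`, `formula`,
#'   `tracer_element`, `model`, `labeling` (atom fraction, or newly
#'   synthesized fraction for `"lipid"`), and for lipid rows `n_label`,
#'   `p_label`.
#' @param abundances Isotope abundance tibble.
#' @param mid_sd Additive fraction noise sd (>= 0).
#' @param intensity_cv Per-sample total-signal CV.
#' @param detection_lod Censoring threshold on expected fractions.
#' @param resolution Correction/convolution mode.
#' @return Long isotopologue tibble (`sample`, `metabolite`, `formula`,
#'   `tracer_element`, `isotopologue`, `fraction`, `intensity`).
#' @export
emit_mids <- function(plan, abundances = isotope_abundances(),
                      mid_sd = 0.005, intensity_cv = 0.05,
                      detection_lod = mid_sd,
                      resolution = c("high", "unit")) {
  resolution <- match.arg(resolution)
  if (mid_sd < 0) stop_domain("Noise sd must be >= 0.")
  n_rows <- nrow(plan)
  iso <- vector("list", n_rows); frac <- vector("list", n_rows)
  inten <- vector("list", n_rows); lens <- integer(n_rows)
  for (i in seq_len(n_rows)) {
    n <- element_count(plan$formula[i], plan$tracer_element[i])
    x <- switch(plan$model[i],
      tracer = true_mid_tracer(plan$labeling[i], n),
      binomial = true_mid_binomial(plan$labeling[i], n),
      lipid = true_mid_lipid(plan$labeling[i], n, plan$n_label[i],
                             plan$p_label[i]),
      stop_config(paste0("Unknown forward model '", plan$model[i], "'."))
    )
    out <- emit_one_mid(x, plan$formula[i], plan$tracer_element[i], abundances,
                        resolution, mid_sd, detection_lod, intensity_cv)
    iso[[i]] <- out$isotopologue; frac[[i]] <- out$fraction
    inten[[i]] <- out$intensity; lens[i] <- length(out$isotopologue)
  }
  rep_idx <- rep(seq_len(n_rows), times = lens)
  tibble(
    sample = plan$sample[rep_idx], metabolite = plan$metabolite[rep_idx],
    formula = plan$formula[rep_idx],
    tracer_element = plan$tracer_element[rep_idx],
    isotopologue = unlist(iso, use.names = FALSE),
    fraction = unlist(frac, use.names = FALSE),
    intensity = unlist(inten, use.names = FALSE))
}

#' Generate a complete synthetic infusion experiment
#'
#' Forward-simulates the full reference design with known ground truth:
#' single-tracer 13C infusion arms for each configured nutrient (serum
#' labeling of the infused tracer and of the other nutrients, tissue
#' labeling of each target in each tissue), optional fasted/refed
#' 13C-methionine arms, and an optional 2H2O drinking-water arm measuring a
#' saponified fatty acid per tissue. Outputs use the same delimited table
#' dialect the readers consume, so every estimator can be run against the
#' result and compared with the truth record.
#'
#' @param config A [flux_config()] object.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   tables.
#' @param truth Optional `synthetic_truth` record; by default sampled via
#'   [sample_truth()] under `seed`.
#' @param dir Optional directory; when given, writes `serum.csv`,
#'   `tissue.csv`, `manifest.csv`, `truth.json` and `config.yaml` there.
#' @return A list of class `synthetic_experiment` with elements `serum`,
#'   `tissue`, `manifest`, `truth`, `config`.
#' @export
generate_experiment <- function(config = flux_config(), seed = config$seed,
                                truth = NULL, dir = NULL) {
  validate_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  if (is.null(truth)) truth <- sample_truth(config)
  abund <- isotope_abundances()
  lod <- effective_lod(config)
  a_count <- as.integer(config$animals_per_arm)
  reg <- metabolite_registry()

  manifest <- list(); serum_plan <- list(); tissue_plan <- list()
  counter <- 0L
  next_sample <- function() {
    counter <<- counter + 1L
    sprintf("S%04d", counter)
  }
  lookup_truth_f <- function(met, diet, state) {
    row <- truth$f_circ[truth$f_circ$metabolite == met &
                        truth$f_circ$diet == diet &
                        truth$f_circ$state == state, ]
    if (!nrow(row)) stop_config(paste0("Truth lacks F_circ for ", met,
                                       "/", diet, "/", state))
    row$f_circ[1]
  }

  # 13C nutrient arms: serum panel + tissue targets per animal
  for (diet in config$diets) for (state in config$states) {
    for (arm in config$nutrients) {
      R <- infusion_rate(tracer_concentration(config, arm, state),
                         config$pump_rate)
      l_arm <- simulate_serum_labeling(R, lookup_truth_f(arm, diet, state))
      for (k in seq_len(a_count)) {
        animal <- paste(arm, diet, state, k, sep = "_")
        l_animal <- jitter_fraction(l_arm, config$animal_cv)
        s_serum <- next_sample()
        manifest[[length(manifest) + 1L]] <- list(
          sample = s_serum, animal = animal, arm = arm, tissue = "serum",
          diet = diet, state = state, water_enrichment = NA_real_)
        for (nut in config$nutrients) {
          info <- registry_lookup(nut)
          if (nut == arm) {
            serum_plan[[length(serum_plan) + 1L]] <- list(
              sample = s_serum, metabolite = nut, formula = info$formula,
              tracer_element = info$tracer_element, model = "tracer",
              labeling = l_animal, n_label = NA_integer_, p_label = NA_real_)
          } else {
            l_nut <- l_animal *
              jitter_fraction(truth$cross[arm, nut], config$animal_cv, lo = 0)
            serum_plan[[length(serum_plan) + 1L]] <- list(
              sample = s_serum, metabolite = nut, formula = info$formula,
              tracer_element = info$tracer_element, model = "binomial",
              labeling = min(l_nut, 0.999999), n_label = NA_integer_,
              p_label = NA_real_)
          }
        }
        for (tis in config$tissues) {
          s_tis <- next_sample()
          manifest[[length(manifest) + 1L]] <- list(
            sample = s_tis, animal = animal, arm = arm, tissue = tis,
            diet = diet, state = state, water_enrichment = NA_real_)
          for (target in config$targets) {
            f_true <- truth$contributions$contribution[
              truth$contributions$tissue == tis &
              truth$contributions$target == target &
              truth$contributions$diet == diet]
            norm_lab <- sum(f_true * truth$cross[arm, ])
            l_target <- l_animal *
              jitter_fraction(norm_lab, config$animal_cv, lo = 0)
            info <- registry_lookup(target)
            tissue_plan[[length(tissue_plan) + 1L]] <- list(
              sample = s_tis, metabolite = target, formula = info$formula,
              tracer_element = info$tracer_element, model = "binomial",
              labeling = min(l_target, 0.999999), n_label = NA_integer_,
              p_label = NA_real_)
          }
        }
      }
    }
  }

  # methionine F_circ arms (serum only)
  if (isTRUE(config$methionine_arms)) {
    info <- registry_lookup("methionine")
    for (diet in config$diets) for (state in c("fast", "refed")) {
      R <- infusion_rate(tracer_concentration(config, "methionine", state),
                         config$pump_rate)
      l_arm <- simulate_serum_labeling(R, lookup_truth_f("methionine", diet, state))
      for (k in seq_len(a_count)) {
        animal <- paste("methionine", diet, state, k, sep = "_")
        s_serum <- next_sample()
        manifest[[length(manifest) + 1L]] <- list(
          sample = s_serum, animal = animal, arm = "methionine",
          tissue = "serum", diet = diet, state = state,
          water_enrichment = NA_real_)
        serum_plan[[length(serum_plan) + 1L]] <- list(
          sample = s_serum, metabolite = "methionine", formula = info$formula,
          tracer_element = info$tracer_element, model = "tracer",
          labeling = jitter_fraction(l_arm, config$animal_cv),
          n_label = NA_integer_, p_label = NA_real_)
      }
    }
  }

  # 2H2O drinking-water arm: saponified fatty acid per tissue
  if (isTRUE(config$water_arm)) {
    fa <- config$fatty_acid
    info <- registry_lookup(fa)
    n_label <- n_exchangeable_for(config, fa)
    for (diet in config$diets) {
      for (k in seq_len(a_count)) {
        animal <- paste("water", diet, k, sep = "_")
        w_animal <- jitter_fraction(truth$water_enrichment, config$animal_cv)
        for (tis in config$tissues) {
          g_true <- truth$lipogenesis$new_fraction[
            truth$lipogenesis$tissue == tis & truth$lipogenesis$diet == diet]
          g_animal <- if (g_true == 0) 0 else
            jitter_fraction(g_true, config$animal_cv, lo = 0)
          s_tis <- next_sample()
          manifest[[length(manifest) + 1L]] <- list(
            sample = s_tis, animal = animal, arm = "2H2O", tissue = tis,
            diet = diet, state = "refed", water_enrichment = w_animal)
          tissue_plan[[length(tissue_plan) + 1L]] <- list(
            sample = s_tis, metabolite = fa, formula = info$formula,
            tracer_element = info$tracer_element, model = "lipid",
            labeling = g_animal, n_label = n_label, p_label = w_animal)
        }
      }
    }
  }

  manifest <- dplyr::bind_rows(manifest)
  serum_plan <- dplyr::bind_rows(serum_plan)
  tissue_plan <- dplyr::bind_rows(tissue_plan)
  serum <- emit_mids(serum_plan, abund, config$mid_sd, config$intensity_cv,
                     lod, config$resolution_mode)
  tissue <- emit_mids(tissue_plan, abund, config$mid_sd, config$intensity_cv,
                      lod, config$resolution_mode)
  if (config$value_col == "fraction") {
    serum$intensity <- NULL
    tissue$intensity <- NULL
  } else {
    serum$fraction <- NULL
    tissue$fraction <- NULL
  }
  truth$seed <- as.integer(seed)

  exp <- structure(
    list(serum = serum, tissue = tissue, manifest = manifest,
         truth = truth, config = config),
    class = "synthetic_experiment")
  if (!is.null(dir)) write_experiment(exp, dir)
  exp
}

n_exchangeable_for <- function(config, fatty_acid) {
  n <- config$n_exchangeable[fatty_acid]
  if (is.na(n)) {
    stop_config(paste0("No n_exchangeable entry configured for '",
                       fatty_acid, "'."))
  }
  as.integer(n)
}
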