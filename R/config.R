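#' Analysis and simulation configuration
#'
#' Builds the validated flat configuration shared by the simulator, the
#' analysis pipelines and the command-line interface. Every option has a
#' default matching the reference infusion protocol (0.1 uL/min per g pump
#' rate; 500 mmol/L U-13C glucose and 150 mmol/L U-13C,15N glutamine in the
#' refed state; 15/30 mmol/L U-13C methionine fasted/refed; 2H2O drinking
#' water); unknown keys are rejected so a typo cannot silently fall back to
#' a default.
#'
#' @param nutrients Circulating nutrients forming the cross-tracer system
#'   (each is also a single-tracer infusion arm).
#' @param tissues Tissues sampled.
#' @param targets Tissue target metabolites for the contribution system.
#' @param diets Diet groups.
#' @param states Nutritional state for the 13C nutrient arms.
#' @param methionine_arms Include fasted + refed 13C-methionine F_circ arms.
#' @param water_arm Include the 2H2O drinking-water lipogenesis arm.
#' @param fatty_acid Saponified fatty acid measured in the water arm.
#' @param animals_per_arm Animals per infusion arm and diet group.
#' @param pump_rate Pump rate, uL/min per g body weight.
#' @param concentrations Named vector of tracer concentrations (mmol/L);
#'   state-dependent entries use `<tracer>_<state>` names.
#' @param mid_sd Additive Gaussian measurement noise on MID fractions.
#' @param intensity_cv Log-normal coefficient of variation of per-sample
#'   total signal (scales all isotopologues of a sample together, so it
#'   cancels in fractions).
#' @param animal_cv Relative inter-animal biological variation of true
#'   labeling quantities.
#' @param detection_lod Smallest noise-free expected fraction emitted by the
#'   simulator; peaks below it are censored as undetected. `NA` (default)
#'   ties the limit to `mid_sd`, so noise-free simulations censor nothing.
#' @param body_water_enrichment Body-water 2H enrichment in the water arm.
#' @param n_exchangeable Named integer vector: water-derived hydrogens per
#'   newly synthesized molecule, per fatty acid.
#' @param l_min Minimum serum labeling for an F_circ estimate.
#' @param ratio_threshold Minimum denominator for normalized labeling.
#' @param bootstrap_draws Bootstrap resamples for contribution CIs.
#' @param resolution_mode Correction mode, `"high"` or `"unit"`.
#' @param constrain Constrain contributions to `[0, 1]`.
#' @param per_animal Solve the contribution system per matched animal
#'   instead of on group means.
#' @param value_col Value column of input tables: `"intensity"` or
#'   `"fraction"`.
#' @param delim Field delimiter for tables.
#' @param seed Default seed for seeded operations.
#' @return A named list of class `flux_config`.
#' @export
flux_config <- function(nutrients = c("glucose", "glutamine"),
                        tissues = c("liver", "BAT", "gWAT", "iWAT",
                                    "muscle", "heart", "brain", "lung"),
                        targets = c("lactate", "citrate", "malate"),
                        diets = c("AA", "SAAR"),
                        states = "refed",
                        methionine_arms = TRUE,
                        water_arm = TRUE,
                        fatty_acid = "C18:1",
                        animals_per_arm = 5L,
                        pump_rate = 0.1,
                        concentrations = c(glucose = 500, glutamine = 150,
                                           methionine_fast = 15,
                                           methionine_refed = 30),
                        mid_sd = 0.005,
                        intensity_cv = 0.05,
                        animal_cv = 0.05,
                        detection_lod = NA_real_,
                        body_water_enrichment = 0.02,
                        n_exchangeable = c("C18:1" = 22L, "C18:0" = 22L,
                                           "C16:0" = 20L),
                        l_min = 0.005,
                        ratio_threshold = 0.01,
                        bootstrap_draws = 1000L,
                        resolution_mode = "high",
                        constrain = TRUE,
                        per_animal = FALSE,
                        value_col = "intensity",
                        delim = ",",
                        seed = 1L) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "flux_config")
}

config_keys <- function() names(formals(flux_config))

validate_config <- function(cfg) {
  if (!length(cfg$nutrients)) stop_config("Config must name at least one nutrient arm.")
  if (!length(cfg$tissues)) stop_config("Config must name at least one tissue.")
  if (!length(cfg$targets)) stop_config("Config must name at least one target metabolite.")
  num_pos <- c("animals_per_arm", "pump_rate")
  for (k in num_pos) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0) {
      stop_config(paste0("Config key '", k, "' must be a positive number."))
    }
  }
  num_nonneg <- c("mid_sd", "intensity_cv", "animal_cv", "bootstrap_draws")
  for (k in num_nonneg) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] < 0) {
      stop_config(paste0("Config key '", k, "' must be a non-negative number."))
    }
  }
  if (!is.na(cfg$detection_lod) && cfg$detection_lod < 0) {
    stop_config("detection_lod must be non-negative (or NA for automatic).")
  }
  if (cfg$body_water_enrichment <= 0 || cfg$body_water_enrichment >= 1) {
    stop_config("body_water_enrichment must lie strictly between 0 and 1.")
  }
  if (!cfg$resolution_mode %in% c("high", "unit")) {
    stop_config("resolution_mode must be 'high' or 'unit'.")
  }
  if (!cfg$value_col %in% c("intensity", "fraction")) {
    stop_config("value_col must be 'intensity' or 'fraction'.")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L ||
      cfg$seed != round(cfg$seed)) {
    stop_config("seed must be a single integer.")
  }
  invisible(cfg)
}

# detection limit actually applied by the simulator
effective_lod <- function(cfg) {
  if (is.na(cfg$detection_lod)) cfg$mid_sd else cfg$detection_lod
}

#' Read a run configuration file
#'
#' Flat YAML of `key: value` pairs; any key not understood by
#' [flux_config()] is rejected, and omitted keys take their defaults.
#'
#' @param path Path to the YAML configuration.
#' @return A `flux_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config(paste0("Config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown)) {
    stop_config(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (k in c("concentrations", "n_exchangeable")) {
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  }
  do.call(flux_config, raw)
}

#' Write a run configuration file
#'
#' @param config A `flux_config` object.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "flux_config"))
  out <- unclass(config)
  out$concentrations <- as.list(out$concentrations)
  out$n_exchangeable <- as.list(out$n_exchangeable)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Built-in metabolite registry for the simulator and pipelines
#'
#' Formulas and tracer elements for the metabolites of the reference
#' infusion design. Input tables may carry any metabolite, since they
#' include their own `formula` and `tracer_element` columns; this registry
#' is what the simulator and default pipelines use.
#'
#' @return Tibble with columns `metabolite`, `formula`, `tracer_element`.
#' @export
metabolite_registry <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cache <<- tibble(
    metabolite = c("glucose", "glutamine", "methionine",
                   "lactate", "citrate", "malate",
                   "C18:1", "C18:0", "C16:0"),
    formula = c("C6H12O6", "C5H10N2O3", "C5H11NO2S",
                "C3H6O3", "C6H8O7", "C4H6O5",
                "C18H34O2", "C18H36O2", "C16H32O2"),
    tracer_element = c("C", "C", "C", "C", "C", "C", "H", "H", "H")
    )
    cache
  }
})

registry_lookup <- function(metabolite) {
  reg <- metabolite_registry()
  row <- reg[reg$metabolite == metabolite, ]
  if (!nrow(row)) {
    stop_config(paste0("Metabolite '", metabolite,
                       "' is not in the built-in registry."))
  }
  row
}

# infusate concentration for a tracer in a given state (mmol/L)
tracer_concentration <- function(cfg, tracer, state) {
  conc <- cfg$concentrations
  key_state <- paste0(tracer, "_", state)
  if (key_state %in% names(conc)) return(unname(conc[key_state]))
  if (tracer %in% names(conc)) return(unname(conc[tracer]))
  stop_config(paste0("No infusate concentration configured for '", tracer,
                     "' (state '", state, "')."))
}
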