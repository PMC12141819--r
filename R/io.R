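#' Read a delimited isotopologue table
#'
#' Reads peak-table exports with header columns
#' `sample,metabolite,formula,tracer_element,isotopologue,intensity` (or a
#' pre-normalized `fraction` column), where `isotopologue` is the integer i
#' of M+i (M+0 is 0). Duplicate `(sample, metabolite, isotopologue)` rows
#' are an error; missing intermediate isotopologues are filled with zero
#' signal and flagged with a warning.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma; mass-spec exports vary).
#' @param value Expected value column, `"intensity"` or `"fraction"`.
#' @return Long isotopologue tibble.
#' @export
read_isotopologue_table <- function(path, delim = ",",
                                    value = c("intensity", "fraction")) {
  value <- match.arg(value)
  if (!file.exists(path)) stop_format(paste0("Table not found: ", path))
  header <- strsplit(readr::read_lines(path, n_max = 1L), delim, fixed = TRUE)[[1]]
  needed <- c("sample", "metabolite", "formula", "tracer_element",
              "isotopologue", value)
  if (!all(needed %in% header)) {
    stop_format(paste0("Malformed header in ", path, ": need columns ",
                       paste(needed, collapse = ", "), "."))
  }
  df <- suppressWarnings(readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())))
  df$isotopologue <- suppressWarnings(as.integer(df$isotopologue))
  vals <- suppressWarnings(as.numeric(df[[value]]))
  bad <- which(is.na(vals) | is.na(df$isotopologue))
  if (length(bad)) {
    stop_parse(paste0("Non-numeric ", value, "/isotopologue at data row(s): ",
                      paste(head(bad, 5), collapse = ", "), " of ", path))
  }
  df[[value]] <- vals

  key <- paste(df$sample, df$metabolite, df$isotopologue, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), ][1, ]
    stop_format(paste0("Duplicate isotopologue row: sample '", dup$sample,
                       "', metabolite '", dup$metabolite, "', M+",
                       dup$isotopologue, "."))
  }
  fill_isotopologue_gaps(as_tibble(df), value)
}

# add explicit zero rows for missing intermediate M+i and warn
fill_isotopologue_gaps <- function(df, value) {
  keys <- paste(df$sample, df$metabolite, sep = "\r")
  groups <- split(seq_len(nrow(df)), keys)
  filled <- dplyr::bind_rows(lapply(groups, function(rows) {
    g <- df[rows, ]
    have <- sort(g$isotopologue)
    need <- setdiff(seq(0L, max(have)), have)
    if (!length(need)) return(g)
    mf_warn(paste0("Missing intermediate isotopologue(s) M+",
                   paste(need, collapse = ", M+"), " for '", g$metabolite[1],
                   "' in sample '", g$sample[1], "'; filled with 0."),
            "filled_gaps")
    add <- g[rep(1, length(need)), ]
    add$isotopologue <- need
    add[[value]] <- 0
    dplyr::arrange(dplyr::bind_rows(g, add), isotopologue)
  }))
  filled
}

#' Write an isotopologue table
#'
#' @param data Long isotopologue tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_isotopologue_table <- function(data, path, delim = ",") {
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

#' Write a synthetic experiment to a directory
#'
#' Writes `serum.csv`, `tissue.csv`, `manifest.csv`, `truth.json` and
#' `config.yaml` in the dialect the readers and the command-line interface
#' consume.
#'
#' @param experiment A `synthetic_experiment` from [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  delim <- experiment$config$delim
  write_isotopologue_table(experiment$serum, file.path(dir, "serum.csv"), delim)
  write_isotopologue_table(experiment$tissue, file.path(dir, "tissue.csv"), delim)
  readr::write_delim(experiment$manifest, file.path(dir, "manifest.csv"),
                     delim = delim)
  jsonlite::write_json(truth_to_list(experiment$truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(experiment$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a synthetic experiment directory
#'
#' @param dir Directory written by [write_experiment()] (or the `simulate`
#'   CLI subcommand).
#' @return A `synthetic_experiment` list.
#' @export
read_experiment <- function(dir) {
  cfg_path <- file.path(dir, "config.yaml")
  if (!file.exists(cfg_path)) {
    stop_format(paste0("Not an experiment directory (no config.yaml): ", dir))
  }
  config <- read_run_config(cfg_path)
  serum <- read_isotopologue_table(file.path(dir, "serum.csv"),
                                   config$delim, config$value_col)
  tissue <- read_isotopologue_table(file.path(dir, "tissue.csv"),
                                    config$delim, config$value_col)
  manifest <- readr::read_delim(file.path(dir, "manifest.csv"),
                                delim = config$delim, show_col_types = FALSE,
                                progress = FALSE)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    truth_from_list(jsonlite::read_json(truth_path, simplifyVector = TRUE))
  }
  structure(list(serum = serum, tissue = tissue, manifest = manifest,
                 truth = truth, config = config),
            class = "synthetic_experiment")
}

truth_to_list <- function(truth) {
  cross_df <- as.data.frame(truth$cross)
  cross_df <- cbind(arm = rownames(truth$cross), cross_df)
  list(
    f_circ = as.data.frame(truth$f_circ),
    cross = cross_df,
    contributions = as.data.frame(truth$contributions),
    lipogenesis = as.data.frame(truth$lipogenesis),
    water_enrichment = truth$water_enrichment,
    noise = truth$noise,
    animals_per_arm = truth$animals_per_arm,
    seed = truth$seed
  )
}

truth_from_list <- function(x) {
  cross_df <- as.data.frame(x$cross)
  rn <- cross_df$arm
  cross <- as.matrix(cross_df[setdiff(names(cross_df), "arm")])
  rownames(cross) <- rn
  structure(
    list(
      f_circ = as_tibble(x$f_circ),
      cross = cross,
      contributions = as_tibble(x$contributions),
      lipogenesis = as_tibble(x$lipogenesis),
      water_enrichment = x$water_enrichment,
      noise = x$noise,
      animals_per_arm = x$animals_per_arm,
      seed = x$seed
    ),
    class = "synthetic_truth"
  )
}
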