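#' Read a long-format screen table
#'
#' Reads a tidy CSV of well-level confluency observations (one row per well
#' per time point). Header matching is case-insensitive. Required columns:
#' `plate`, `well`, `cell_line`, `drug`, `time_h`, `confluency_pct`;
#' `dose_uM`, `bio_rep`, `tech_rep` are filled with defaults when absent.
#' Lines starting with `#` are treated as comments.
#'
#' Validation fails closed: missing required columns, non-numeric time or
#' confluency, confluency outside \[0, 100\] (offending rows are listed), or
#' duplicate `(plate, well, time_h)` keys are errors. A cell line without a
#' vehicle control triggers a warning (downstream normalization will error).
#'
#' @param path Path to the CSV file.
#' @param vehicle Vehicle drug label used for the control check.
#' @return A validated tibble.
#' @export
read_screen_table <- function(path, vehicle = "DMSO") {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  canonical <- c("plate", "well", "cell_line", "drug", "dose_uM",
                 "bio_rep", "tech_rep", "time_h", "confluency_pct")
  idx <- match(tolower(names(raw)), tolower(canonical))
  names(raw)[!is.na(idx)] <- canonical[idx[!is.na(idx)]]
  required <- c("plate", "well", "cell_line", "drug", "time_h", "confluency_pct")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "cin_schema_error")
  }
  if (!"dose_uM" %in% names(raw)) raw$dose_uM <- 0
  if (!"bio_rep" %in% names(raw)) raw$bio_rep <- 1L
  if (!"tech_rep" %in% names(raw)) raw$tech_rep <- 1L
  for (col in c("time_h", "confluency_pct", "dose_uM")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    if (any(is.na(vals) & !is.na(raw[[col]]))) {
      abort(sprintf("column `%s` contains non-numeric values", col),
            class = "cin_schema_error")
    }
    raw[[col]] <- vals
  }
  bad <- which(raw$confluency_pct < 0 | raw$confluency_pct > 100)
  if (length(bad)) {
    abort(sprintf("confluency outside [0, 100] in data row(s): %s",
                  paste(head(bad, 10), collapse = ", ")),
          class = "cin_schema_error")
  }
  dup <- duplicated(raw[c("plate", "well", "time_h")])
  if (any(dup)) {
    abort(sprintf("duplicate (plate, well, time_h) keys in data row(s): %s",
                  paste(head(which(dup), 10), collapse = ", ")),
          class = "cin_schema_error")
  }
  no_ctrl <- setdiff(unique(raw$cell_line),
                     raw$cell_line[raw$drug == vehicle])
  if (length(no_ctrl)) {
    warn(sprintf("cell line(s) without a %s control: %s",
                 vehicle, paste(no_ctrl, collapse = ", ")))
  }
  as_tibble(raw[c(canonical, setdiff(names(raw), canonical))])
}

#' Write a stage output CSV with a provenance header
#'
#' Every pipeline output carries a comment header naming the producing stage
#' and a hash of the configuration, so results can be traced to the settings
#' that made them.
#'
#' @param x Table to write.
#' @param path Output path.
#' @param stage Stage name (e.g. `"simulate"`, `"metrics"`).
#' @param config Configuration object hashed into the header (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_stage_csv <- function(x, path, stage, config = NULL) {
  hash <- if (is.null(config)) "none" else rlang::hash(config)
  header <- sprintf("# cinsynergy stage: %s; config_hash: %s", stage, hash)
  writeLines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the analysis (not generative) parameters of the end-to-end
#' pipeline and validates their ranges. Serializes to YAML round-trip stably
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param auc_method `"sum"` or `"trapezoid"`.
#' @param r2_min,min_points Exponential-cutoff parameters.
#' @param window_boundaries Day boundaries for windowed synergy (or `NULL`).
#' @param alpha Significance level on adjusted p-values.
#' @param effect_min Minimum |log2 effect| for a volcano hit.
#' @param alternative Test sidedness (`"two.sided"`, `"greater"`, `"less"`).
#' @param family_size Bonferroni family size (`NULL` = number of drugs).
#' @param replicate_unit `"bio"` or `"well"` for the differential test.
#' @param synergy_method `"t"` or `"bootstrap"`.
#' @param vehicle Vehicle drug label.
#' @param reference_line,perturbation_line Cell lines for the synergy stage
#'   (`NULL` = infer from the table: first line is the reference).
#' @param seed Integer seed for any stochastic stage (bootstrap).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(auc_method = "sum", r2_min = 0.99, min_points = 4,
                            window_boundaries = 4, alpha = 0.05,
                            effect_min = 1, alternative = "two.sided",
                            family_size = NULL, replicate_unit = "bio",
                            synergy_method = "t", vehicle = "DMSO",
                            reference_line = NULL, perturbation_line = NULL,
                            seed = 1L) {
  stopifnot(auc_method %in% c("sum", "trapezoid"),
            r2_min > 0, r2_min <= 1, min_points >= 2,
            alpha >= 0, alpha <= 1, effect_min >= 0,
            alternative %in% c("two.sided", "greater", "less"),
            replicate_unit %in% c("bio", "well"),
            synergy_method %in% c("t", "bootstrap"))
  if (!is.null(family_size) && family_size < 1) {
    abort("`family_size` must be >= 1", class = "cin_parameter_error")
  }
  structure(
    list(auc_method = auc_method, r2_min = r2_min, min_points = min_points,
         window_boundaries = window_boundaries, alpha = alpha,
         effect_min = effect_min, alternative = alternative,
         family_size = family_size, replicate_unit = replicate_unit,
         synergy_method = synergy_method, vehicle = vehicle,
         reference_line = reference_line,
         perturbation_line = perturbation_line, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[!vapply(vals, is.null, logical(1))])
}

#' Run the end-to-end screen analysis pipeline
#'
#' From a screen table (or CSV path) computes per-well growth metrics,
#' per-drug differential sensitivity between the reference and perturbation
#' lines with volcano annotation, and Bliss synergy per drug (full run and,
#' when configured, per time window). Outputs are deterministic: re-running
#' with the same inputs and configuration reproduces byte-identical files.
#'
#' @param screen A screen table or path to one (see [read_screen_table()]).
#' @param config A [pipeline_config()].
#' @param out_dir If non-`NULL`, writes `metrics.csv`, `differential.csv`,
#'   `synergy.csv` (each with a provenance header) and `run_log.txt` there.
#' @return A list with `metrics`, `differential`, `volcano`, `synergy`,
#'   `config`, invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(screen, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(screen)) screen <- read_screen_table(screen, config$vehicle)
  lines <- unique(screen$cell_line)
  ref <- config$reference_line %||% lines[1]
  pert <- config$perturbation_line %||% setdiff(lines, ref)[1]
  if (is.na(pert) || is.null(pert)) {
    abort("pipeline needs two cell lines (reference and perturbation)",
          class = "cin_design_error")
  }

  metrics <- screen_metrics(screen, auc_method = config$auc_method,
                            r2_min = config$r2_min,
                            min_points = config$min_points,
                            vehicle = config$vehicle)
  differential <- differential_screen(
    metrics, line_a = pert, line_b = ref,
    replicate_unit = config$replicate_unit,
    alternative = config$alternative,
    family_size = config$family_size, vehicle = config$vehicle)
  volcano <- build_volcano_table(differential,
                                 effect_min = config$effect_min,
                                 alpha = config$alpha)
  synergy <- withr::with_seed(config$seed, {
    full <- synergy_screen(screen, pert, ref, vehicle = config$vehicle,
                           auc_method = config$auc_method,
                           method = config$synergy_method,
                           alternative = config$alternative)
    if (!is.null(config$window_boundaries)) {
      windowed <- synergy_screen(screen, pert, ref, vehicle = config$vehicle,
                                 window_boundaries = config$window_boundaries,
                                 auc_method = config$auc_method,
                                 method = config$synergy_method,
                                 alternative = config$alternative)
      bind_rows(full, windowed)
    } else full
  })

  result <- list(metrics = metrics, differential = differential,
                 volcano = volcano, synergy = synergy, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stage_csv(metrics, file.path(out_dir, "metrics.csv"),
                    "metrics", config)
    write_stage_csv(volcano, file.path(out_dir, "differential.csv"),
                    "differential", config)
    write_stage_csv(synergy, file.path(out_dir, "synergy.csv"),
                    "synergy", config)
    log_lines <- c(
      "cinsynergy pipeline run",
      sprintf("package_version: %s",
              as.character(utils::packageVersion("cinsynergy"))),
      sprintf("r_version: %s", R.version.string),
      sprintf("config_hash: %s", rlang::hash(config)),
      sprintf("seed: %d", config$seed),
      sprintf("reference_line: %s", ref),
      sprintf("perturbation_line: %s", pert),
      "config:",
      strsplit(yaml::as.yaml(unclass(config)), "\n")[[1]]
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    return(invisible(result))
  }
  result
}

`%||%` <- function(x, y) if (is.null(x)) y else x
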