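# CSV series I/O. A series file has header `x,absorbance`; an optional JSON
# sidecar (same path, .json extension) carries method_kind, design, seed and
# noise_sd so that a round trip preserves the metadata.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a titration series from CSV
#'
#' Expects a CSV with header `x,absorbance`. Rows are validated (numeric
#' cells, absorbance not below minus three times the noise floor) with
#' offending row numbers named in errors. Points are sorted by `x`
#' (duplicates allowed, treated as replicates); the original row order is
#' kept in the `original_order` attribute. If a JSON sidecar written by
#' [write_series()] sits next to the file, its metadata are restored.
#'
#' @param path CSV file path.
#' @param noise_floor Noise scale (AU) used for the negative-absorbance
#'   sanity check; overridden by the sidecar's `noise_sd` when present.
#' @return A [titration_series()].
#' @export
read_series <- function(path, noise_floor = 0.002) {
  if (!file.exists(path)) {
    ligex_error("ligex_parse_error", sprintf("file not found: %s", path))
  }
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   ligex_error("ligex_parse_error",
                               sprintf("cannot parse %s: %s", path, conditionMessage(e)))
                 })
  if (nrow(df) == 0L) {
    ligex_error("ligex_parse_error", sprintf("%s contains no data rows", path))
  }
  if (!all(c("x", "absorbance") %in% names(df))) {
    ligex_error("ligex_parse_error",
                sprintf("%s must have columns `x` and `absorbance` (found: %s)",
                        path, paste(names(df), collapse = ", ")))
  }
  xv <- suppressWarnings(as.numeric(df$x))
  av <- suppressWarnings(as.numeric(df$absorbance))
  bad <- which(is.na(xv) | is.na(av))
  if (length(bad)) {
    ligex_error("ligex_parse_error",
                sprintf("non-numeric cells in %s at data row(s) %s",
                        path, paste(bad, collapse = ", ")))
  }
  meta <- list(method_kind = "unknown", design = list(), seed = NULL,
               noise_sd = noise_floor)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    got <- tryCatch(jsonlite::read_json(sc, simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.list(got)) meta <- modifyList(meta, got[!vapply(got, is.null, TRUE)])
  }
  neg <- which(av < -3 * meta$noise_sd)
  if (length(neg)) {
    ligex_error("ligex_parse_error",
                sprintf("absorbance below -3 x noise floor in %s at data row(s) %s",
                        path, paste(neg, collapse = ", ")))
  }
  ord <- order(xv)
  out <- titration_series(xv[ord], av[ord],
                          method_kind = meta$method_kind,
                          design = as.list(meta$design),
                          seed = if (is.null(meta$seed)) NULL else as.integer(meta$seed),
                          noise_sd = as.numeric(meta$noise_sd))
  attr(out, "original_order") <- ord
  out
}

#' Write a titration series to CSV (plus JSON sidecar)
#'
#' @param series A [titration_series()].
#' @param path Output CSV path; metadata go to the matching `.json` sidecar.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  if (!inherits(series, "titration_series")) {
    ligex_error("ligex_invalid_argument", "`series` must be a titration_series")
  }
  write.csv(as.data.frame(series), path, row.names = FALSE)
  jsonlite::write_json(
    list(method_kind = series$method_kind, design = series$design,
         seed = series$seed, noise_sd = series$noise_sd),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

RUN_COMMANDS <- c("simulate", "exchange", "job", "moleratio", "compare")
DESIGN_PRESETS <- c("paper_calibration", "paper_exchange", "paper_job",
                    "paper_moleratio")

run_config_defaults <- function() {
  list(command = NULL, input = NULL, calibration = NULL, output = NULL,
       out_prefix = "ligex_run",
       preset = NULL,
       n = 1, log_beta_MX = 8, log_beta_MLn = 14,
       eps_MX = 1600, eps_MLn = 0, eps_M = 0, eps_L = 0, path_length = 1,
       noise_sd = 0, seed = NULL, boot_reps = 2000,
       locator = "tangent", normalize = FALSE, fraction = "metal",
       log_beta_grid = c(4, 5, 14), medium_shift = 6, n_seeds = 25)
}

#' Read a run configuration file
#'
#' Flat key-value YAML; keys mirror the arguments of the pipeline commands
#' (see [run_pipeline()]). Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) {
    ligex_error("ligex_config_error", "config file must be a YAML mapping")
  }
  build_run_config(cfg)
}

#' Assemble and validate a run configuration
#'
#' @param ... Configuration fields overriding the defaults; see
#'   [run_pipeline()] for their meaning.
#' @return A `run_config` list.
#' @export
run_config <- function(...) build_run_config(list(...))

build_run_config <- function(cfg) {
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    ligex_error("ligex_config_error",
                sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, cfg[!vapply(cfg, is.null, TRUE)])
  if (is.null(cfg$command) || !cfg$command %in% RUN_COMMANDS) {
    ligex_error("ligex_config_error",
                sprintf("`command` must be one of: %s", paste(RUN_COMMANDS, collapse = ", ")))
  }
  if (!is.null(cfg$preset) && !cfg$preset %in% DESIGN_PRESETS) {
    ligex_error("ligex_config_error",
                sprintf("unknown preset `%s`; valid presets: %s",
                        cfg$preset, paste(DESIGN_PRESETS, collapse = ", ")))
  }
  if (cfg$noise_sd > 0 && is.null(cfg$seed)) {
    ligex_error("ligex_config_error", "`seed` is required whenever `noise_sd` > 0")
  }
  structure(cfg, class = "run_config")
}

config_system <- function(cfg) {
  complex_system(n = cfg$n, log_beta_MX = cfg$log_beta_MX,
                 log_beta_MLn = cfg$log_beta_MLn,
                 eps_MX = cfg$eps_MX, eps_MLn = cfg$eps_MLn,
                 eps_M = cfg$eps_M, eps_L = cfg$eps_L,
                 path_length = cfg$path_length)
}
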