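REPORT_SCHEMA_VERSION <- "1.0"

write_report <- function(report, path) {
  report <- c(list(schema_version = REPORT_SCHEMA_VERSION), report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

line_fit_report <- function(fit) {
  list(slope = fit$slope, intercept = fit$intercept, r = fit$r,
       residual_sd = fit$residual_sd, n_points = fit$n_points,
       x_range = fit$x_range)
}

#' Execute a configured pipeline
#'
#' Commands:
#' \describe{
#'   \item{simulate}{Generate a design (one of the `paper_*` presets, which
#'     encode the bench designs the package validates against) and write the
#'     series CSV + sidecar. `paper_exchange` also writes the companion
#'     calibration series.}
#'   \item{exchange}{Read `calibration` and `input` CSVs, run
#'     [estimate_n_exchange()], write a JSON report.}
#'   \item{job}{Read `input`, run [job_analysis()], write a JSON report.}
#'   \item{moleratio}{Read `input`, run [moleratio_analysis()], write a JSON
#'     report.}
#'   \item{compare}{Run [compare_methods()] over `log_beta_grid` and write a
#'     CSV table plus a JSON report.}
#' }
#' All outputs are pure functions of the configuration (fixed seeds, no
#' timestamps), so identical configurations yield byte-identical reports.
#'
#' @param config A `run_config` from [run_config()] or [read_run_config()].
#' @return Invisibly, a list with the report and the paths written.
#' @examples
#' \donttest{
#' td <- tempdir()
#' cfg <- run_config(command = "simulate", preset = "paper_exchange",
#'                   noise_sd = 0.002, seed = 1,
#'                   out_prefix = file.path(td, "demo"))
#' run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- build_run_config(config)
  system <- config_system(config)
  prefix <- config$out_prefix
  artifacts <- character(0)
  report <- list(command = config$command,
                 parameters = unclass(config)[c("n", "log_beta_MX", "log_beta_MLn",
                                                "eps_MX", "eps_MLn", "eps_M", "eps_L",
                                                "path_length", "noise_sd", "seed")])

  if (config$command == "simulate") {
    if (is.null(config$preset)) {
      ligex_error("ligex_config_error", "simulate requires a `preset`")
    }
    series_list <- switch(
      config$preset,
      paper_calibration = list(
        calibration = simulate_calibration_design(system, noise_sd = config$noise_sd,
                                                  seed = config$seed)),
      paper_exchange = list(
        calibration = simulate_calibration_design(system, noise_sd = config$noise_sd,
                                                  seed = add_seed(config$seed, 1L)),
        exchange = simulate_exchange_design(system, noise_sd = config$noise_sd,
                                            seed = add_seed(config$seed, 2L))),
      paper_job = list(
        job = simulate_job_design(system, noise_sd = config$noise_sd,
                                  seed = config$seed)),
      paper_moleratio = list(
        mole_ratio = simulate_moleratio_design(system, noise_sd = config$noise_sd,
                                               seed = config$seed))
    )
    for (nm in names(series_list)) {
      p <- sprintf("%s_%s.csv", prefix, nm)
      write_series(series_list[[nm]], p)
      artifacts <- c(artifacts, p, sidecar_path(p))
    }
    report$preset <- config$preset
    report$files <- as.list(setNames(sprintf("%s_%s.csv", prefix, names(series_list)),
                                     names(series_list)))
  } else if (config$command == "exchange") {
    if (is.null(config$calibration) || is.null(config$input)) {
      ligex_error("ligex_config_error",
                  "exchange requires `calibration` and `input` CSV paths")
    }
    cal <- read_series(config$calibration)
    ex <- read_series(config$input)
    res <- withCallingHandlers(
      estimate_n_exchange(cal, ex, boot_reps = config$boot_reps,
                          boot_seed = config$seed %||% 1L),
      ligex_warning = function(w) invokeRestart("muffleWarning")
    )
    report <- c(report, list(
      method = res$method, n_hat = res$n_hat, n_hat_slope = res$n_hat_slope,
      n_rounded = res$n_rounded, ratio = res$ratio,
      ci = list(low = res$ci_low, high = res$ci_high),
      geometry = res$geometry[c("x_star", "y_star", "delta", "alpha", "beta",
                                "metal_per_ligand", "ligand_per_metal")],
      fits = list(direct = line_fit_report(res$direct),
                  inverse = line_fit_report(res$inverse)),
      linear_mask = res$linear_mask,
      warnings = as.list(res$warnings)
    ))
  } else if (config$command == "job") {
    if (is.null(config$input)) {
      ligex_error("ligex_config_error", "job requires an `input` CSV path")
    }
    res <- job_analysis(read_series(config$input), locator = config$locator,
                        normalize = isTRUE(config$normalize),
                        fraction = config$fraction)
    report <- c(report, list(
      method = res$method, x_max = res$x_max, fraction = res$fraction,
      n_hat = res$n_hat, locator = res$locator, normalized = res$normalized,
      fits = if (res$locator == "tangent")
        list(left = line_fit_report(res$fits$left),
             right = line_fit_report(res$fits$right))
      else list(quadratic = res$fits$quadratic)
    ))
  } else if (config$command == "moleratio") {
    if (is.null(config$input)) {
      ligex_error("ligex_config_error", "moleratio requires an `input` CSV path")
    }
    res <- withCallingHandlers(
      moleratio_analysis(read_series(config$input)),
      ligex_warning = function(w) invokeRestart("muffleWarning")
    )
    report <- c(report, list(
      method = res$method, break_x = res$break_x, n_hat = res$n_hat,
      split_index = res$split_index, sse = res$sse,
      fits = list(rise = line_fit_report(res$fits$rise),
                  plateau = line_fit_report(res$fits$plateau)),
      warnings = as.list(res$warnings)
    ))
  } else if (config$command == "compare") {
    tab <- compare_methods(system, log_beta_grid = config$log_beta_grid,
                           noise_sd = config$noise_sd,
                           seeds = seq_len(config$n_seeds) + (config$seed %||% 0L),
                           medium_shift = config$medium_shift)
    tab_path <- sprintf("%s_compare.csv", prefix)
    write.csv(tab, tab_path, row.names = FALSE)
    artifacts <- c(artifacts, tab_path)
    report$table <- tab
    report$table_csv <- tab_path
  }

  report_path <- sprintf("%s_report.json", prefix)
  write_report(report, report_path)
  artifacts <- c(artifacts, report_path)
  invisible(list(report = report, artifacts = artifacts))
}

add_seed <- function(seed, k) if (is.null(seed)) NULL else seed + k

cli_option_list <- function() {
  list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "YAML config file (CLI flags override it)"),
    optparse::make_option("--input", type = "character", default = NULL),
    optparse::make_option("--calibration", type = "character", default = NULL),
    optparse::make_option("--out-prefix", type = "character", default = NULL,
                          dest = "out_prefix"),
    optparse::make_option("--preset", type = "character", default = NULL),
    optparse::make_option("--n", type = "double", default = NULL),
    optparse::make_option("--log-beta-mx", type = "double", default = NULL,
                          dest = "log_beta_MX"),
    optparse::make_option("--log-beta-mln", type = "double", default = NULL,
                          dest = "log_beta_MLn"),
    optparse::make_option("--eps-mx", type = "double", default = NULL,
                          dest = "eps_MX"),
    optparse::make_option("--eps-mln", type = "double", default = NULL,
                          dest = "eps_MLn"),
    optparse::make_option("--noise-sd", type = "double", default = NULL,
                          dest = "noise_sd"),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--boot-reps", type = "integer", default = NULL,
                          dest = "boot_reps"),
    optparse::make_option("--locator", type = "character", default = NULL),
    optparse::make_option("--normalize", action = "store_true", default = NULL),
    optparse::make_option("--ligand-fraction", action = "store_true",
                          default = NULL, dest = "ligand_fraction",
                          help = "treat the Job abscissa as ligand mole fraction"),
    optparse::make_option("--log-beta-grid", type = "character", default = NULL,
                          dest = "log_beta_grid",
                          help = "comma-separated grid for `compare`"),
    optparse::make_option("--medium-shift", type = "double", default = NULL,
                          dest = "medium_shift"),
    optparse::make_option("--n-seeds", type = "integer", default = NULL,
                          dest = "n_seeds")
  )
}

#' Command-line entry point
#'
#' Thin wrapper used by the `inst/cli/ligex` script:
#' `ligex <command> [flags]` with commands `simulate`, `exchange`, `job`,
#' `moleratio`, `compare`. Flags mirror the [run_config()] fields; a
#' `--config` YAML file supplies defaults and explicit flags override it.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly. Errors print their
#'   condition class and message on stderr and return 1.
#' @export
ligex_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1L || !args[1] %in% RUN_COMMANDS) {
      ligex_error("ligex_config_error",
                  sprintf("usage: ligex <%s> [flags]", paste(RUN_COMMANDS, collapse = "|")))
    }
    parser <- optparse::OptionParser(option_list = cli_option_list())
    opts <- optparse::parse_args(parser, args = args[-1])
    opts$help <- NULL
    cfg <- list()
    if (!is.null(opts$config)) {
      cfg <- yaml::read_yaml(opts$config)
      opts$config <- NULL
    }
    if (isTRUE(opts$ligand_fraction)) opts$fraction <- "ligand"
    opts$ligand_fraction <- NULL
    if (!is.null(opts$log_beta_grid) && is.character(opts$log_beta_grid)) {
      opts$log_beta_grid <- as.numeric(strsplit(opts$log_beta_grid, ",")[[1]])
    }
    cfg <- modifyList(cfg, opts[!vapply(opts, is.null, TRUE)])
    cfg$command <- args[1]
    out <- run_pipeline(build_run_config(cfg))
    message(sprintf("wrote: %s", paste(out$artifacts, collapse = ", ")))
    0L
  }, error = function(e) {
    cls <- setdiff(class(e), c("error", "condition"))[1]
    cat(sprintf("%s: %s\n", cls %||% "error", conditionMessage(e)),
        file = stderr())
    1L
  })
  invisible(status)
}
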