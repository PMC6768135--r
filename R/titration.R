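#' Construct a titration series
#'
#' An ordered set of (x, absorbance) measurements from one spectrophotometric
#' design, with the metadata needed to interpret the abscissa:
#' concentrations in mol/L for the calibration, exchange and mole-ratio
#' designs (the latter re-expressed as a metal/ligand mole ratio), a
#' dimensionless metal mole fraction for Job's design.
#'
#' @param x Abscissa values, sorted non-decreasing (duplicates = replicates).
#' @param absorbance Measured absorbances (AU), same length as `x`.
#' @param method_kind One of `"exchange"`, `"job"`, `"mole_ratio"`,
#'   `"calibration"`, `"unknown"`.
#' @param design Optional list describing the fixed totals and varied
#'   quantity of the design (free-form metadata).
#' @param seed Integer RNG seed used to generate the series, or `NULL`.
#' @param noise_sd Gaussian noise standard deviation (AU) used, or 0.
#' @return An object of class `titration_series`.
#' @examples
#' titration_series(c(1e-4, 2e-4), c(0.16, 0.32), "calibration")
#' @export
titration_series <- function(x, absorbance,
                             method_kind = c("unknown", "exchange", "job",
                                             "mole_ratio", "calibration"),
                             design = list(), seed = NULL, noise_sd = 0) {
  method_kind <- match.arg(method_kind)
  if (!is.numeric(x) || !is.numeric(absorbance) ||
      length(x) != length(absorbance) || length(x) < 1L) {
    ligex_error("ligex_invalid_argument",
                "`x` and `absorbance` must be numeric vectors of equal positive length")
  }
  if (any(!is.finite(x)) || any(!is.finite(absorbance))) {
    ligex_error("ligex_invalid_argument", "non-finite values in series")
  }
  if (is.unsorted(x)) {
    ligex_error("ligex_invalid_argument", "`x` must be sorted non-decreasing")
  }
  if (method_kind == "job" && (any(x < 0) || any(x > 1))) {
    ligex_error("ligex_invalid_argument", "Job mole fractions must lie in [0, 1]")
  }
  structure(
    list(x = as.numeric(x), absorbance = as.numeric(absorbance),
         method_kind = method_kind, design = design,
         seed = seed, noise_sd = noise_sd),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %s, %d points, x in [%g, %g], noise_sd = %g AU%s\n",
              x$method_kind, length(x$x), min(x$x), max(x$x), x$noise_sd,
              if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  invisible(x)
}

#' @export
as.data.frame.titration_series <- function(x, ...) {
  data.frame(x = x$x, absorbance = x$absorbance)
}

#' @export
length.titration_series <- function(x) length(x$x)

add_noise <- function(a, noise_sd, seed, n) {
  if (noise_sd < 0) ligex_error("ligex_invalid_argument", "`noise_sd` must be >= 0")
  if (noise_sd == 0) return(a)
  if (is.null(seed)) {
    ligex_error("ligex_invalid_argument",
                "`seed` is required whenever `noise_sd` > 0 (reproducibility contract)")
  }
  a + with_seed(seed, rnorm(n, mean = 0, sd = noise_sd))
}

simulate_series <- function(system, totals_list, x, method_kind, design,
                            noise_sd, seed) {
  a <- vapply(totals_list, function(tt) {
    absorbance(system, solve_speciation(system, tt))
  }, numeric(1))
  titration_series(x, add_noise(a, noise_sd, seed, length(a)),
                   method_kind = method_kind, design = design,
                   seed = seed, noise_sd = noise_sd)
}

#' Simulate a ligand-exchange (displacement) design
#'
#' A fixed nominal concentration of the indicator complex MX (equimolar total
#' metal and indicator ligand) is challenged with increasing amounts of the
#' test ligand L; absorbance is read at the MX wavelength. The default grid
#' reproduces the bench design of 0.2-1.8 umol ligand added to 3 umol of
#' indicator complex in 10 mL (1 umol / 10 mL = 1e-4 M).
#'
#' @param system A [complex_system()].
#' @param indicator_conc Nominal MX concentration in M (`C_M = C_X`).
#' @param ligand_amounts Total test-ligand concentrations in M.
#' @param noise_sd Additive Gaussian noise sd in AU.
#' @param seed RNG seed; required when `noise_sd > 0`.
#' @return A [titration_series()] with `x` = ligand concentration (M).
#' @examples
#' sys <- demo_system("exchange")
#' simulate_exchange_design(sys, noise_sd = 0.002, seed = 1)
#' @export
simulate_exchange_design <- function(system, indicator_conc = 3e-4,
                                     ligand_amounts = seq(2e-5, 1.8e-4, by = 2e-5),
                                     noise_sd = 0, seed = NULL) {
  check_number(indicator_conc, "indicator_conc", min = 0)
  if (indicator_conc <= 0) {
    ligex_error("ligex_invalid_argument", "`indicator_conc` must be > 0")
  }
  ligand_amounts <- sort(as.numeric(ligand_amounts))
  totals <- lapply(ligand_amounts, function(cl) {
    mixture_totals(C_M = indicator_conc, C_X = indicator_conc, C_L = cl)
  })
  simulate_series(system, totals, ligand_amounts, "exchange",
                  design = list(varies = "C_L", C_M = indicator_conc,
                                C_X = indicator_conc),
                  noise_sd, seed)
}

#' Simulate an indicator-complex calibration design
#'
#' Standard solutions of the indicator complex alone (`C_M = C_X`, no test
#' ligand). Default levels reproduce the bench design of 0.1-0.6 mM.
#'
#' @inheritParams simulate_exchange_design
#' @param conc_levels Nominal MX concentrations in M.
#' @return A [titration_series()] with `x` = nominal MX concentration (M).
#' @examples
#' simulate_calibration_design(demo_system("exchange"))
#' @export
simulate_calibration_design <- function(system,
                                        conc_levels = seq(1e-4, 6e-4, by = 1e-4),
                                        noise_sd = 0, seed = NULL) {
  conc_levels <- sort(as.numeric(conc_levels))
  totals <- lapply(conc_levels, function(cc) {
    mixture_totals(C_M = cc, C_X = cc, C_L = 0)
  })
  simulate_series(system, totals, conc_levels, "calibration",
                  design = list(varies = "C_M = C_X", C_L = 0),
                  noise_sd, seed)
}

#' Simulate a Job's continuous-variations design
#'
#' Mixtures of metal and test ligand at constant total concentration and
#' varying metal mole fraction, no indicator ligand. The default reproduces
#' the bench design of nine mixtures totalling 10 umol in 10 mL (1 mM) at
#' metal mole fractions 0.1-0.9.
#'
#' @inheritParams simulate_exchange_design
#' @param total_conc Constant total `C_M + C_L` in M.
#' @param k_points Number of mole-fraction levels (>= 3), equally spaced on
#'   \[0.1, 0.9\].
#' @return A [titration_series()] with `x` = metal mole fraction.
#' @examples
#' simulate_job_design(demo_system("classical"))
#' @export
simulate_job_design <- function(system, total_conc = 1e-3, k_points = 9L,
                                noise_sd = 0, seed = NULL) {
  check_number(total_conc, "total_conc", min = 0)
  check_number(k_points, "k_points", min = 3)
  frac <- seq(0.1, 0.9, length.out = as.integer(k_points))
  totals <- lapply(frac, function(f) {
    mixture_totals(C_M = f * total_conc, C_X = 0, C_L = (1 - f) * total_conc)
  })
  simulate_series(system, totals, frac, "job",
                  design = list(varies = "metal mole fraction",
                                total_conc = total_conc),
                  noise_sd, seed)
}

#' Simulate a mole-ratio (Yoe-Jones) design
#'
#' Fixed total test-ligand concentration, varying total metal, no indicator.
#' The abscissa is the metal/ligand mole ratio. The default grid reproduces
#' the bench design of 0.4-30 umol metal against 5 umol ligand in 10 mL
#' (ligand 0.5 mM, metal 0.04-3 mM).
#'
#' @inheritParams simulate_exchange_design
#' @param ligand_conc Fixed total ligand concentration in M.
#' @param metal_range Total metal concentrations in M.
#' @return A [titration_series()] with `x` = metal/ligand mole ratio
#'   (dimensionless).
#' @examples
#' simulate_moleratio_design(demo_system("classical"))
#' @export
simulate_moleratio_design <- function(system, ligand_conc = 5e-4,
                                      metal_range = c(0.4, 1, 2, 3, 4, 5, 6,
                                                      7.5, 10, 15, 20, 30) * 1e-4,
                                      noise_sd = 0, seed = NULL) {
  check_number(ligand_conc, "ligand_conc", min = 0)
  if (ligand_conc <= 0) {
    ligex_error("ligex_invalid_argument", "`ligand_conc` must be > 0")
  }
  metal_range <- sort(as.numeric(metal_range))
  totals <- lapply(metal_range, function(cm) {
    mixture_totals(C_M = cm, C_X = 0, C_L = ligand_conc)
  })
  simulate_series(system, totals, metal_range / ligand_conc, "mole_ratio",
                  design = list(varies = "C_M", C_L = ligand_conc,
                                x_axis = "metal_per_ligand"),
                  noise_sd, seed)
}
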