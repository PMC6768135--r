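#' Define a competitive complexation system
#'
#' Describes the chemical model underlying all simulations: a metal M, an
#' indicator ligand X forming a 1:1 colored complex MX, and a test ligand L
#' forming a (usually colorless) complex MLn with `n` ligands per metal.
#' Overall formation constants are given on the log10 scale:
#' \eqn{[MX] = \beta_{MX} [M][X]} and \eqn{[ML_n] = \beta_{MLn} [M][L]^n}.
#' Absorbance at the working wavelength is additive Beer-Lambert over the
#' species with non-zero molar absorptivities.
#'
#' The displacement assay requires MX to be appreciably less stable than MLn
#' (so the test ligand strips the metal) and MLn to be transparent at the MX
#' wavelength; neither is enforced here, so the same type also describes the
#' Job / mole-ratio designs where the MLn complex itself is the chromophore.
#'
#' @param n Integer >= 1, ligands per metal in MLn.
#' @param log_beta_MX log10 overall formation constant of MX (M^-1).
#' @param log_beta_MLn log10 overall formation constant of MLn (M^-n).
#' @param eps_MX,eps_MLn,eps_M,eps_L Molar absorptivities (M^-1 cm^-1) of MX,
#'   MLn, free metal and free ligand at the working wavelength.
#' @param path_length Optical path length in cm.
#' @return An object of class `complex_system`.
#' @examples
#' sys <- complex_system(n = 1, log_beta_MX = 8, log_beta_MLn = 14, eps_MX = 1600)
#' sys
#' @seealso [demo_system()] for ready-made illustrative parameter sets.
#' @export
complex_system <- function(n = 1L, log_beta_MX = 0, log_beta_MLn = 0,
                           eps_MX = 0, eps_MLn = 0, eps_M = 0, eps_L = 0,
                           path_length = 1) {
  check_number(n, "n", min = 1)
  if (n != round(n)) {
    ligex_error("ligex_invalid_argument", "`n` must be a positive integer")
  }
  check_number(log_beta_MX, "log_beta_MX")
  check_number(log_beta_MLn, "log_beta_MLn")
  for (nm in c("eps_MX", "eps_MLn", "eps_M", "eps_L")) {
    check_number(get(nm), nm, min = 0)
  }
  check_number(path_length, "path_length", min = 0)
  structure(
    list(n = as.integer(round(n)),
         log_beta_MX = log_beta_MX, log_beta_MLn = log_beta_MLn,
         eps_MX = eps_MX, eps_MLn = eps_MLn, eps_M = eps_M, eps_L = eps_L,
         path_length = path_length),
    class = "complex_system"
  )
}

#' @export
print.complex_system <- function(x, ...) {
  cat("<complex_system>\n")
  cat(sprintf("  MX : log10(beta) = %g, eps = %g M^-1 cm^-1\n",
              x$log_beta_MX, x$eps_MX))
  cat(sprintf("  ML%s: log10(beta) = %g, eps = %g M^-1 cm^-1\n",
              if (x$n > 1) x$n else "", x$log_beta_MLn, x$eps_MLn))
  cat(sprintf("  free species eps: M = %g, L = %g; path = %g cm\n",
              x$eps_M, x$eps_L, x$path_length))
  invisible(x)
}

#' Illustrative demonstration systems
#'
#' Ready-made `complex_system` parameter sets loosely modelled on the
#' Fe(III)-salicylate / Fe(III)-bisphosphonate chemistry that motivates the
#' package. The formation constants are *illustrative placeholders*, not
#' fitted or literature values: published stability constants for these
#' systems are conditional on medium, pH and ionic strength, and the methods
#' implemented here do not require them. The `"exchange"` view represents
#' measurement at the indicator absorption maximum (colored MX, transparent
#' MLn); the `"classical"` view represents the Job / mole-ratio designs where
#' the MLn complex is the absorbing species and no indicator is present.
#'
#' @param view `"exchange"` or `"classical"` (see Details).
#' @param n Ligands per metal in MLn.
#' @param log_beta_MLn log10 formation constant of MLn. The default `14 * n`
#'   puts the system deep in the strong-binding regime at sub-millimolar
#'   concentrations, giving near-triangular Job plots and sharp mole-ratio
#'   breaks.
#' @param log_beta_MX log10 formation constant of the indicator complex
#'   (ignored by the `"classical"` view, which contains no indicator).
#' @param eps Molar absorptivity of the chromophore (MX in the exchange view,
#'   MLn in the classical view).
#' @return A [complex_system()].
#' @examples
#' demo_system("exchange")
#' demo_system("classical", n = 2)
#' @export
demo_system <- function(view = c("exchange", "classical"), n = 1L,
                        log_beta_MLn = 14 * n, log_beta_MX = 8, eps = 1600) {
  view <- match.arg(view)
  if (view == "exchange") {
    complex_system(n = n, log_beta_MX = log_beta_MX,
                   log_beta_MLn = log_beta_MLn, eps_MX = eps)
  } else {
    complex_system(n = n, log_beta_MX = 0, log_beta_MLn = log_beta_MLn,
                   eps_MX = 0, eps_MLn = eps)
  }
}

#' Analytical (total) concentrations of one mixture
#'
#' @param C_M,C_X,C_L Total (analytical) concentrations in mol/L of metal,
#'   indicator ligand and test ligand.
#' @return An object of class `mixture_totals`.
#' @examples
#' mixture_totals(C_M = 3e-4, C_X = 3e-4, C_L = 1e-4)
#' @export
mixture_totals <- function(C_M = 0, C_X = 0, C_L = 0) {
  check_number(C_M, "C_M", min = 0)
  check_number(C_X, "C_X", min = 0)
  check_number(C_L, "C_L", min = 0)
  structure(list(C_M = C_M, C_X = C_X, C_L = C_L), class = "mixture_totals")
}

#' @export
print.mixture_totals <- function(x, ...) {
  cat(sprintf("<mixture_totals> C_M = %g M, C_X = %g M, C_L = %g M\n",
              x$C_M, x$C_X, x$C_L))
  invisible(x)
}
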