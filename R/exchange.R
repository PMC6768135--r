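# Ligand-exchange estimator: overlay of the indicator calibration line
# (the "direct" line, slope ~ eps_MX * path) and the attenuation line of the
# displacement series (the "inverse" line). The vertical segment delta from
# their intersection to the abscissa and the x-axis segments alpha (left of
# the foot, measured from the direct line's x-intercept) and beta (from the
# foot to the inverse line's x-intercept) satisfy
#   alpha = delta / slope_direct,   beta = delta / |slope_inverse|
# so alpha/beta = |slope_inverse| / slope_direct estimates the metal-per-
# ligand ratio; its reciprocal is the ligand-per-metal stoichiometry n of
# MLn (one mole of L displaces 1/n mole of the 1:1 indicator complex).

PARALLEL_TOL <- 1e-9

series_xy <- function(series) {
  if (inherits(series, "titration_series")) {
    list(x = series$x, y = series$absorbance)
  } else if (is.data.frame(series)) {
    if (!all(c("x", "absorbance") %in% names(series))) {
      ligex_error("ligex_invalid_argument",
                  "data frame must have columns `x` and `absorbance`")
    }
    list(x = series$x, y = series$absorbance)
  } else {
    ligex_error("ligex_invalid_argument",
                "expected a titration_series or data frame")
  }
}

#' Fit a straight line to titration points
#'
#' Ordinary least squares through a set of (x, absorbance) points, optionally
#' restricted to an abscissa window. Exact through any two distinct points.
#'
#' @param series A [titration_series()] or data frame with columns `x` and
#'   `absorbance`.
#' @param x_window Optional length-2 numeric; only points with
#'   `x_window[1] <= x <= x_window[2]` are fitted.
#' @return An object of class `line_fit` with elements `slope`, `intercept`,
#'   `r` (Pearson correlation, 0 when the response is constant),
#'   `residual_sd` (AU, 0 for a 2-point fit), `n_points`, `x_range`.
#' @examples
#' fit_line(data.frame(x = c(0, 1), absorbance = c(0, 2)))
#' @export
fit_line <- function(series, x_window = NULL) {
  p <- series_xy(series)
  x <- p$x; y <- p$y
  if (!is.null(x_window)) {
    keep <- x >= x_window[1] & x <= x_window[2]
    x <- x[keep]; y <- y[keep]
  }
  if (length(unique(x)) < 2L) {
    ligex_error("ligex_degenerate_fit",
                "need at least 2 distinct x values to fit a line")
  }
  fit <- lm(y ~ x)
  cf <- coef(fit)
  n <- length(x)
  rss <- sum(fit$residuals^2)
  r <- if (sd(y) == 0) 0 else suppressWarnings(stats::cor(x, y))
  structure(
    list(slope = unname(cf[2]), intercept = unname(cf[1]), r = r,
         residual_sd = if (n > 2) sqrt(rss / (n - 2)) else 0,
         n_points = n, x_range = range(x)),
    class = "line_fit"
  )
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("<line_fit> A = %.6g %+.6g x  (r = %.4f, s = %.3g AU, n = %d)\n",
              x$intercept, x$slope, x$r, x$residual_sd, x$n_points))
  invisible(x)
}

#' Intersection of two fitted lines
#'
#' @param direct,inverse `line_fit` objects.
#' @return Named numeric `c(x_star, y_star)` satisfying both line equations.
#' @examples
#' d <- fit_line(data.frame(x = 0:1, absorbance = c(0, 2)))
#' i <- fit_line(data.frame(x = 0:1, absorbance = c(3, 2)))
#' intersect_lines(d, i)
#' @export
intersect_lines <- function(direct, inverse) {
  s1 <- direct$slope; s2 <- inverse$slope
  if (abs(s1 - s2) <= PARALLEL_TOL * max(abs(s1), abs(s2), 1e-300)) {
    ligex_error("ligex_parallel_lines",
                "lines are (near-)parallel: no usable intersection")
  }
  x_star <- (inverse$intercept - direct$intercept) / (s1 - s2)
  c(x_star = x_star, y_star = s1 * x_star + direct$intercept)
}

#' Overlay geometry of the ligand-exchange plot
#'
#' Computes the intersection of the direct (calibration) and inverse
#' (attenuation) lines, the vertical segment `delta` from the intersection
#' down to the abscissa, and the abscissa segments `alpha` (from the direct
#' line's x-intercept to the foot of the vertical) and `beta` (from the foot
#' to the inverse line's x-intercept). Using the actual x-intercept of the
#' direct line (rather than the origin) makes `alpha = delta / slope_direct`
#' an exact identity even when the calibration line has a small intercept.
#'
#' @param direct `line_fit` of the calibration line (positive slope).
#' @param inverse `line_fit` of the attenuation line (negative slope).
#' @return An object of class `exchange_geometry` with `x_star`, `y_star`,
#'   `delta`, `alpha`, `beta`, `metal_per_ligand` (= alpha/beta) and
#'   `ligand_per_metal` (= beta/alpha).
#' @examples
#' d <- structure(list(slope = 1600, intercept = 0), class = "line_fit")
#' i <- structure(list(slope = -3200, intercept = 0.96), class = "line_fit")
#' exchange_geometry(d, i)
#' @export
exchange_geometry <- function(direct, inverse) {
  pt <- intersect_lines(direct, inverse)
  if (pt[["y_star"]] <= 0) {
    ligex_error("ligex_geometry_undefined",
                "lines intersect at or below the abscissa: geometry undefined")
  }
  x0_direct <- -direct$intercept / direct$slope
  x0_inverse <- -inverse$intercept / inverse$slope
  alpha <- pt[["x_star"]] - x0_direct
  beta <- x0_inverse - pt[["x_star"]]
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    ligex_error("ligex_geometry_undefined",
                "degenerate overlay: alpha and beta must both be positive")
  }
  structure(
    list(x_star = pt[["x_star"]], y_star = pt[["y_star"]],
         delta = pt[["y_star"]], alpha = alpha, beta = beta,
         metal_per_ligand = alpha / beta, ligand_per_metal = beta / alpha),
    class = "exchange_geometry"
  )
}

#' @export
print.exchange_geometry <- function(x, ...) {
  cat("<exchange_geometry>\n")
  cat(sprintf("  intersection (%.6g, %.6g), delta = %.6g AU\n",
              x$x_star, x$y_star, x$delta))
  cat(sprintf("  alpha = %.6g, beta = %.6g, alpha/beta = %.6g (metal per ligand)\n",
              x$alpha, x$beta, x$metal_per_ligand))
  invisible(x)
}

#' Select the linear (pre-equivalence) region of an exchange series
#'
#' The displacement series is linear only while indicator complex remains to
#' be consumed; past the equivalence level the absorbance flattens. Starting
#' from the full series, the fit is re-estimated and trailing points whose
#' absolute residual exceeds `k` times the fit's residual standard deviation
#' are trimmed one at a time, never below 3 points. Deterministic.
#'
#' @param exchange A [titration_series()] of kind `"exchange"`.
#' @param direct Optional calibration `line_fit`; its residual sd is used as
#'   a noise-floor estimate for the trimming threshold.
#' @param k Trimming threshold in residual-sd units.
#' @return Logical mask over the series points (`TRUE` = keep).
#' @examples
#' sys <- demo_system("exchange")
#' ex <- simulate_exchange_design(sys)
#' linear_region_mask(ex)
#' @export
linear_region_mask <- function(exchange, direct = NULL, k = 3) {
  p <- series_xy(exchange)
  n <- length(p$x)
  if (n < 3L) {
    ligex_error("ligex_insufficient_linear_region",
                "need at least 3 points to identify a linear region")
  }
  mask <- rep(TRUE, n)
  # Threshold scale: an independent noise estimate (the calibration fit's
  # residual sd) with a small floor, NOT the current fit's residual sd --
  # the latter is inflated by the very curvature being trimmed.
  s <- max(if (!is.null(direct)) direct$residual_sd else 0,
           1e-6 * max(abs(p$y), 1e-300))
  repeat {
    df <- data.frame(x = p$x[mask], absorbance = p$y[mask])
    fit <- fit_line(df)
    last <- max(which(mask))
    resid_last <- abs(p$y[last] - (fit$intercept + fit$slope * p$x[last]))
    if (resid_last <= k * s || sum(mask) <= 3L) break
    mask[last] <- FALSE
  }
  mask
}

# Nearest simple ratio by relative distance; ties go to the smaller ratio.
round_ratio <- function(n_hat, candidates = c(1/3, 1/2, 1, 2, 3, 4)) {
  d <- abs(n_hat - candidates) / candidates
  i <- which(d <= min(d) + 1e-15)
  candidates[i[which.min(candidates[i])]]
}

ratio_label <- function(n) {
  # metal:ligand display for a ligand-per-metal ratio n
  if (n >= 1) sprintf("1:%g", n) else sprintf("%g:1", 1 / n)
}

#' Estimate complex stoichiometry by the ligand-exchange method
#'
#' Fits the calibration (direct) line and the attenuation (inverse) line,
#' restricted to its linear pre-equivalence region, overlays them and reads
#' the stoichiometry from the abscissa segments: `alpha/beta` estimates the
#' metal-per-ligand ratio and its reciprocal the ligand-per-metal ratio `n`
#' of MLn, which is reported as the primary estimate. The equivalent
#' slope-ratio form (`slope_direct / |slope_inverse|`) is reported alongside.
#' Uncertainty is quantified by case-resampling bootstrap within each series.
#'
#' @param calibration A [titration_series()] of kind `"calibration"` (or
#'   `"unknown"`).
#' @param exchange A [titration_series()] of kind `"exchange"` (or
#'   `"unknown"`).
#' @param k_trim Trimming threshold for [linear_region_mask()].
#' @param boot_reps Bootstrap replicates for the percentile CI (0 disables).
#' @param boot_seed RNG seed for the bootstrap.
#' @return An object of class `stoichiometry_result` with `n_hat` (ligand per
#'   metal), `n_rounded` (nearest simple ratio), `ratio` (metal:ligand display
#'   string), `ci_low`/`ci_high`, `geometry`, the two line fits, and any
#'   warnings raised.
#' @examples
#' sys <- demo_system("exchange")
#' cal <- simulate_calibration_design(sys, noise_sd = 0.002, seed = 11)
#' ex <- simulate_exchange_design(sys, noise_sd = 0.002, seed = 12)
#' estimate_n_exchange(cal, ex, boot_reps = 200)
#' @export
estimate_n_exchange <- function(calibration, exchange, k_trim = 3,
                                boot_reps = 2000L, boot_seed = 1L) {
  check_kind(calibration, "calibration")
  check_kind(exchange, "exchange")
  warnings_out <- character(0)

  direct <- fit_line(calibration)
  thr <- 3 * direct$residual_sd + 1e-8 * max(abs(calibration$absorbance))
  if (abs(direct$intercept) > thr) {
    msg <- sprintf(paste0("calibration intercept (%.3g AU) exceeds 3 x residual sd: ",
                          "the origin assumption of the exchange algebra is strained"),
                   direct$intercept)
    warnings_out <- c(warnings_out, msg)
    ligex_warn("ligex_origin_violation", msg)
  }

  mask <- linear_region_mask(exchange, direct, k = k_trim)
  inv_df <- data.frame(x = exchange$x[mask], absorbance = exchange$absorbance[mask])
  if (nrow(inv_df) < 2L) {
    ligex_error("ligex_insufficient_linear_region",
                "fewer than 2 points in the linear region of the exchange series")
  }
  inverse <- fit_line(inv_df)
  geom <- exchange_geometry(direct, inverse)

  n_hat <- geom$ligand_per_metal
  n_slope <- direct$slope / abs(inverse$slope)
  n_rounded <- round_ratio(n_hat)

  ci <- c(NA_real_, NA_real_)
  if (boot_reps > 0) {
    ci <- boot_ci_exchange(calibration$x, calibration$absorbance,
                           inv_df$x, inv_df$absorbance,
                           reps = boot_reps, seed = boot_seed)
  }

  structure(
    list(method = "ligand_exchange",
         n_hat = n_hat, n_hat_slope = n_slope, n_rounded = n_rounded,
         ratio = ratio_label(n_rounded),
         ci_low = ci[1], ci_high = ci[2],
         geometry = geom, direct = direct, inverse = inverse,
         linear_mask = mask,
         diagnostics = list(direct_r = direct$r, inverse_r = inverse$r,
                            direct_residual_sd = direct$residual_sd,
                            inverse_residual_sd = inverse$residual_sd),
         warnings = warnings_out),
    class = "stoichiometry_result"
  )
}

check_kind <- function(series, kind) {
  if (!inherits(series, "titration_series")) {
    ligex_error("ligex_invalid_argument", "expected a titration_series")
  }
  if (!series$method_kind %in% c(kind, "unknown")) {
    ligex_error("ligex_invalid_argument",
                sprintf("series of kind `%s` supplied where `%s` expected",
                        series$method_kind, kind))
  }
  invisible(series)
}

# Vectorized case-resampling bootstrap of the slope-ratio estimator
# (identical to the geometric alpha/beta route; see exchange_geometry).
boot_ci_exchange <- function(cx, cy, ex, ey, reps, seed,
                             probs = c(0.025, 0.975)) {
  ols_slopes <- function(x, y, idx) {
    # idx: n x reps matrix of resampled row indices
    xs <- matrix(x[idx], nrow = nrow(idx))
    ys <- matrix(y[idx], nrow = nrow(idx))
    n <- nrow(idx)
    sx <- colSums(xs); sy <- colSums(ys)
    sxx <- colSums(xs * xs); sxy <- colSums(xs * ys)
    denom <- n * sxx - sx^2
    slope <- (n * sxy - sx * sy) / denom
    slope[abs(denom) < 1e-300] <- NA_real_
    slope
  }
  with_seed(seed, {
    i1 <- matrix(sample.int(length(cx), length(cx) * reps, replace = TRUE),
                 nrow = length(cx))
    i2 <- matrix(sample.int(length(ex), length(ex) * reps, replace = TRUE),
                 nrow = length(ex))
    s1 <- ols_slopes(cx, cy, i1)
    s2 <- ols_slopes(ex, ey, i2)
    n_boot <- s1 / abs(s2)
    n_boot[!is.finite(n_boot) | s2 >= 0 | s1 <= 0] <- NA_real_
    unname(quantile(n_boot, probs = probs, na.rm = TRUE))
  })
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  cat(sprintf("<stoichiometry_result> method = %s\n", x$method))
  cat(sprintf("  n_hat (ligand per metal) = %.4f  -> metal:ligand %s\n",
              x$n_hat, x$ratio))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  bootstrap 95%% CI: [%.4f, %.4f]\n", x$ci_low, x$ci_high))
  }
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n   - ")
  invisible(x)
}
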