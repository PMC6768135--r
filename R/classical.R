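#' Job's method of continuous variations
#'
#' Locates the maximum of the continuous-variations curve (absorbance vs
#' metal mole fraction at constant total concentration). In `"tangent"` mode
#' straight lines are fitted to the two monotone branches, excluding the
#' curved apex region (points within 5\% of the maximum absorbance), and
#' intersected; in `"quadratic"` mode a parabola is fitted to the 3-5 points
#' bracketing the empirical maximum and its vertex returned. For a complex
#' MLn the apex lies at metal mole fraction `1/(1+n)`, so the ligand-per-metal
#' ratio is `(1 - x_max)/x_max`.
#'
#' @param series A [titration_series()] of kind `"job"` (or `"unknown"`),
#'   >= 5 points.
#' @param locator `"tangent"` or `"quadratic"`.
#' @param normalize If `TRUE`, absorbances are scaled by their maximum
#'   (A/A_max) before analysis; this affects neither locator's `x_max`.
#' @param fraction Which component the abscissa mole fraction refers to;
#'   `"metal"` (the default convention) or `"ligand"` (flipped axis).
#' @return An object of class `job_result` with `x_max`, `n_hat` (ligand per
#'   metal), the branch/parabola fits and diagnostics.
#' @examples
#' sys <- demo_system("classical")
#' job_analysis(simulate_job_design(sys))
#' @export
job_analysis <- function(series, locator = c("tangent", "quadratic"),
                         normalize = FALSE, fraction = c("metal", "ligand")) {
  locator <- match.arg(locator)
  fraction <- match.arg(fraction)
  check_kind(series, "job")
  x <- series$x
  a <- series$absorbance
  if (length(x) < 5L) {
    ligex_error("ligex_invalid_argument", "Job analysis needs at least 5 points")
  }
  if (normalize) a <- a / max(a)
  i_max <- which.max(a)
  if (i_max == 1L || i_max == length(x)) {
    ligex_error("ligex_no_interior_maximum",
                "curve maximum lies at an endpoint: no interior maximum to locate")
  }

  if (locator == "tangent") {
    apex_region <- a >= 0.95 * max(a)
    left <- x < x[i_max] & !apex_region
    right <- x > x[i_max] & !apex_region
    if (sum(left) < 2L || sum(right) < 2L) {
      ligex_error("ligex_insufficient_branch",
                  "fewer than 2 points on a monotone branch after apex exclusion")
    }
    fit_left <- fit_line(data.frame(x = x[left], absorbance = a[left]))
    fit_right <- fit_line(data.frame(x = x[right], absorbance = a[right]))
    pt <- intersect_lines(fit_left, fit_right)
    x_max <- pt[["x_star"]]
    fits <- list(left = fit_left, right = fit_right)
  } else {
    half <- 2L
    idx <- max(1L, i_max - half):min(length(x), i_max + half)
    if (length(idx) < 3L) {
      ligex_error("ligex_insufficient_branch",
                  "fewer than 3 points bracket the maximum for the quadratic fit")
    }
    xi <- x[idx]; ai <- a[idx]
    qf <- lm(ai ~ xi + I(xi^2))
    cf <- coef(qf)
    if (!is.finite(cf[3]) || cf[3] >= 0) {
      ligex_error("ligex_no_interior_maximum",
                  "quadratic fit around the apex is not concave")
    }
    x_max <- unname(-cf[2] / (2 * cf[3]))
    fits <- list(quadratic = unname(cf))
  }
  if (!is.finite(x_max) || x_max <= 0 || x_max >= 1) {
    ligex_error("ligex_no_interior_maximum",
                sprintf("located apex %.4g lies outside (0, 1)", x_max))
  }
  x_metal <- if (fraction == "metal") x_max else 1 - x_max
  structure(
    list(method = "job", x_max = x_max, fraction = fraction,
         n_hat = (1 - x_metal) / x_metal,
         locator = locator, normalized = normalize, fits = fits,
         i_max = i_max),
    class = "job_result"
  )
}

#' @export
print.job_result <- function(x, ...) {
  cat(sprintf("<job_result> apex at %s mole fraction %.4f (%s locator)\n",
              x$fraction, x$x_max, x$locator))
  cat(sprintf("  n_hat (ligand per metal) = %.4f -> metal:ligand %s\n",
              x$n_hat, ratio_label(round_ratio(x$n_hat))))
  invisible(x)
}

#' Mole-ratio (Yoe-Jones) tangent method
#'
#' Fits the classic two-segment (rising line / plateau) model by exhaustive
#' search over split points: for every admissible split both segments are fit
#' by ordinary least squares and the split minimizing the total squared
#' residual is kept (ties resolved toward the smaller split index, so the
#' procedure is deterministic). The reported breakpoint is the abscissa of
#' the tangent intersection.
#'
#' @param series A [titration_series()] of kind `"mole_ratio"` (or
#'   `"unknown"`), >= 5 points, abscissa = metal/ligand mole ratio.
#' @return An object of class `moleratio_result` with `break_x` (on the
#'   series' metal-per-ligand axis), `n_hat` (ligand per metal, `1/break_x`),
#'   the two segment fits, `split_index` and `sse`.
#' @examples
#' sys <- demo_system("classical")
#' moleratio_analysis(simulate_moleratio_design(sys))
#' @export
moleratio_analysis <- function(series) {
  check_kind(series, "mole_ratio")
  x <- series$x
  a <- series$absorbance
  n <- length(x)
  if (n < 5L) {
    ligex_error("ligex_invalid_argument",
                "mole-ratio analysis needs at least 5 points")
  }
  best <- NULL
  for (s in 2:(n - 2)) {
    i1 <- seq_len(s); i2 <- (s + 1):n
    if (length(unique(x[i1])) < 2L || length(unique(x[i2])) < 2L) next
    f1 <- fit_line(data.frame(x = x[i1], absorbance = a[i1]))
    f2 <- fit_line(data.frame(x = x[i2], absorbance = a[i2]))
    sse <- sum((a[i1] - f1$intercept - f1$slope * x[i1])^2) +
      sum((a[i2] - f2$intercept - f2$slope * x[i2])^2)
    # strict improvement required, so SSE ties keep the smaller split index
    if (is.null(best) || sse < best$sse) {
      best <- list(split = s, f1 = f1, f2 = f2, sse = sse)
    }
  }
  if (is.null(best)) {
    ligex_error("ligex_insufficient_segment",
                "no split leaves 2 distinct x values in both segments")
  }
  pt <- intersect_lines(best$f1, best$f2)
  break_x <- pt[["x_star"]]
  warn <- character(0)
  if (break_x < min(x) || break_x > max(x)) {
    warn <- sprintf("tangent intersection %.4g lies outside the data range", break_x)
    ligex_warn("ligex_break_outside_range", warn)
  }
  structure(
    list(method = "mole_ratio", break_x = break_x,
         n_hat = 1 / break_x,
         split_index = best$split, fits = list(rise = best$f1, plateau = best$f2),
         sse = best$sse, warnings = warn),
    class = "moleratio_result"
  )
}

#' @export
print.moleratio_result <- function(x, ...) {
  cat(sprintf("<moleratio_result> tangents intersect at metal/ligand ratio %.4f\n",
              x$break_x))
  cat(sprintf("  n_hat (ligand per metal) = %.4f, split after point %d, SSE = %.3g\n",
              x$n_hat, x$split_index, x$sse))
  invisible(x)
}

#' Compare the three stoichiometry estimators across binding strengths
#'
#' Runs matched simulations of all three experimental designs over a grid of
#' formation constants and reports bias and spread of the ligand-per-metal
#' estimate for each method. The grid `log_beta_grid` is the conditional
#' log10 formation constant of MLn *in the strongly acidic medium of the
#' classical designs*; the exchange design, run in a mildly acidic medium
#' where the ligand is far less protonated, sees a conditional constant
#' larger by `medium_shift` log units (see the methods vignette for the
#' chemistry behind this default).
#'
#' @param system Base [complex_system()] (exchange view: colored MX).
#' @param log_beta_grid Conditional log10 beta(MLn) values for the classical
#'   designs.
#' @param noise_sd Absorbance noise sd (AU) applied to every design.
#' @param seeds Integer vector; one full set of matched simulations per seed.
#' @param medium_shift Log-unit increase of the MLn conditional constant in
#'   the exchange medium relative to the classical medium.
#' @param eps_classical Molar absorptivity of MLn in the classical designs.
#' @return A data frame with columns `log_beta`, `method`, `bias`, `sd`,
#'   `n_fail` (failed replicates, excluded from bias/sd).
#' @examples
#' tab <- compare_methods(demo_system("exchange"), log_beta_grid = c(4, 14),
#'                        seeds = 1:5)
#' tab
#' @export
compare_methods <- function(system, log_beta_grid = c(4, 5, 14),
                            noise_sd = 0.002, seeds = 1:25,
                            medium_shift = 6, eps_classical = NULL) {
  if (!inherits(system, "complex_system")) {
    ligex_error("ligex_invalid_argument", "`system` must be a complex_system")
  }
  eps_classical <- eps_classical %||% max(system$eps_MX, system$eps_MLn)
  n_true <- system$n
  rows <- list()
  for (lb in log_beta_grid) {
    sys_ex <- system
    sys_ex$log_beta_MLn <- lb + medium_shift
    sys_cl <- complex_system(n = system$n, log_beta_MX = 0, log_beta_MLn = lb,
                             eps_MX = 0, eps_MLn = eps_classical,
                             eps_M = system$eps_M, eps_L = system$eps_L,
                             path_length = system$path_length)
    est <- matrix(NA_real_, nrow = length(seeds), ncol = 3,
                  dimnames = list(NULL, c("ligand_exchange", "job", "mole_ratio")))
    for (i in seq_along(seeds)) {
      s <- seeds[i]
      est[i, "ligand_exchange"] <- tryCatch({
        cal <- simulate_calibration_design(sys_ex, noise_sd = noise_sd,
                                           seed = s * 10L + 1L)
        ex <- simulate_exchange_design(sys_ex, noise_sd = noise_sd,
                                       seed = s * 10L + 2L)
        suppressWarnings(
          estimate_n_exchange(cal, ex, boot_reps = 0L)$n_hat
        )
      }, error = function(e) NA_real_)
      est[i, "job"] <- tryCatch({
        jb <- simulate_job_design(sys_cl, noise_sd = noise_sd,
                                  seed = s * 10L + 3L)
        job_analysis(jb, locator = "tangent")$n_hat
      }, error = function(e) NA_real_)
      est[i, "mole_ratio"] <- tryCatch({
        mr <- simulate_moleratio_design(sys_cl, noise_sd = noise_sd,
                                        seed = s * 10L + 4L)
        suppressWarnings(moleratio_analysis(mr)$n_hat)
      }, error = function(e) NA_real_)
    }
    for (m in colnames(est)) {
      v <- est[, m]
      rows[[length(rows) + 1L]] <- data.frame(
        log_beta = lb, method = m,
        bias = mean(v, na.rm = TRUE) - n_true,
        sd = sd(v, na.rm = TRUE),
        n_fail = sum(is.na(v))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
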