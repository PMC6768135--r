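# Competitive complexation equilibrium:
#   M + X  <-> MX    [MX]  = beta_MX  [M][X]
#   M + nL <-> MLn   [MLn] = beta_MLn [M][L]^n
# subject to the analytical mass balances
#   [M] + [MX] + [MLn]  = C_M
#   [X] + [MX]          = C_X
#   [L] + n [MLn]       = C_L

SPECIATION_TOL <- 1e-12      # relative mass-balance residual target
SPECIATION_CONTRACT <- 1e-9  # hard contract: worse than this is a failure
SPECIATION_MAX_ITER <- 200L

beta_lin <- function(log_beta) 10^log_beta

speciation_residuals <- function(system, totals, m, x, l) {
  bMX <- beta_lin(system$log_beta_MX)
  bML <- beta_lin(system$log_beta_MLn)
  n <- system$n
  a <- bMX * m * x
  b <- bML * m * l^n
  c(M = (m + a + b - totals$C_M) / max(totals$C_M, 1e-300),
    X = (x + a - totals$C_X) / max(totals$C_X, 1e-300),
    L = (l + n * b - totals$C_L) / max(totals$C_L, 1e-300))
}

build_state <- function(system, totals, m, x, l, method, iterations) {
  bMX <- beta_lin(system$log_beta_MX)
  bML <- beta_lin(system$log_beta_MLn)
  structure(
    list(free_M = m, free_X = x, free_L = l,
         conc_MX = bMX * m * x, conc_MLn = bML * m * l^system$n,
         residuals = speciation_residuals(system, totals, m, x, l),
         totals = totals, method = method, iterations = iterations),
    class = "speciation_state"
  )
}

#' @export
print.speciation_state <- function(x, ...) {
  cat("<speciation_state>\n")
  cat(sprintf("  free:  [M] = %.6g  [X] = %.6g  [L] = %.6g  (mol/L)\n",
              x$free_M, x$free_X, x$free_L))
  cat(sprintf("  bound: [MX] = %.6g  [MLn] = %.6g  (mol/L)\n",
              x$conc_MX, x$conc_MLn))
  cat(sprintf("  max |relative mass-balance residual| = %.3g (%s, %d iter)\n",
              max(abs(x$residuals)), x$method, x$iterations))
  invisible(x)
}

# Trivial/degenerate reductions shared by solver and oracle. Returns a state
# or NULL when a genuine solve is needed, plus activity flags.
speciation_setup <- function(system, totals) {
  if (!inherits(system, "complex_system")) {
    ligex_error("ligex_invalid_argument", "`system` must be a complex_system")
  }
  if (!inherits(totals, "mixture_totals")) totals <- do.call(mixture_totals, as.list(totals))
  bMX <- beta_lin(system$log_beta_MX)
  bML <- beta_lin(system$log_beta_MLn)
  mx_active <- bMX > 0 && totals$C_M > 0 && totals$C_X > 0
  ml_active <- bML > 0 && totals$C_M > 0 && totals$C_L > 0
  state <- NULL
  if (!mx_active && !ml_active) {
    state <- build_state(system, totals, totals$C_M, totals$C_X, totals$C_L,
                         method = "trivial", iterations = 0L)
  }
  list(totals = totals, mx_active = mx_active, ml_active = ml_active,
       state = state)
}

# Free ligand concentration solving l + n b m l^n = C_L for fixed free metal m.
free_L_given_M <- function(m, C_L, bML, n) {
  if (C_L <= 0 || bML <= 0 || m <= 0) return(C_L)
  if (n == 1L) return(C_L / (1 + bML * m))
  g <- function(l) l + n * bML * m * l^n - C_L
  lo <- log(1e-300); hi <- log(C_L)
  if (g(C_L) <= 0) return(C_L)
  while (hi - lo > 1e-14) {
    mid <- (lo + hi) / 2
    if (g(exp(mid)) > 0) hi <- mid else lo <- mid
  }
  exp((lo + hi) / 2)
}

#' Solve a competitive complexation equilibrium
#'
#' Computes the unique positive equilibrium concentrations of free M, X and L
#' (and the complexes MX, MLn) satisfying mass action and the three mass
#' balances. The solver is a damped Newton iteration on log concentrations
#' (which keeps every iterate strictly positive); if it fails to reach the
#' residual tolerance it falls back to the bracketing bisection scheme of
#' [speciation_oracle()].
#'
#' @param system A [complex_system()].
#' @param totals A [mixture_totals()] (or a list with elements `C_M`, `C_X`,
#'   `C_L`).
#' @param tol Relative mass-balance residual tolerance.
#' @param max_iter Newton iteration cap before falling back.
#' @return A `speciation_state` with elements `free_M`, `free_X`, `free_L`,
#'   `conc_MX`, `conc_MLn` and the per-balance relative `residuals`.
#' @examples
#' sys <- demo_system("exchange")
#' solve_speciation(sys, mixture_totals(C_M = 3e-4, C_X = 3e-4, C_L = 1e-4))
#' @export
solve_speciation <- function(system, totals, tol = SPECIATION_TOL,
                             max_iter = SPECIATION_MAX_ITER) {
  setup <- speciation_setup(system, totals)
  if (!is.null(setup$state)) return(setup$state)
  totals <- setup$totals
  bMX <- beta_lin(system$log_beta_MX)
  bML <- beta_lin(system$log_beta_MLn)
  n <- system$n
  C_M <- totals$C_M; C_X <- totals$C_X; C_L <- totals$C_L
  mx <- setup$mx_active; ml <- setup$ml_active

  # initial guess: free metal damped by total binding capacity
  m0 <- C_M / (1 + bMX * C_X + bML * C_L^n)
  m0 <- max(m0, C_M * 1e-200)
  x0 <- if (mx) max(C_X / (1 + bMX * m0), C_X * 1e-200) else C_X
  l0 <- if (ml) max(free_L_given_M(m0, C_L, bML, n), C_L * 1e-200) else C_L

  # unknown vector: log m always; log x if MX active; log l if MLn active
  unknowns <- c(TRUE, mx, ml)
  t_cur <- log(c(m0, x0, l0))[unknowns]

  eval_point <- function(t_vec) {
    full <- log(c(m0, x0, l0))
    full[unknowns] <- t_vec
    v <- exp(full)
    m <- v[1]
    x <- if (mx) v[2] else C_X
    l <- if (ml) v[3] else C_L
    a <- if (mx) bMX * m * x else 0
    b <- if (ml) bML * m * l^n else 0
    FM <- (m + a + b - C_M) / C_M
    FX <- if (mx) (x + a - C_X) / C_X else NULL
    FL <- if (ml) (l + n * b - C_L) / C_L else NULL
    Fv <- c(FM, FX, FL)
    # Jacobian wrt the log-unknowns
    J <- matrix(0, length(Fv), length(Fv))
    J[1, 1] <- (m + a + b) / C_M
    idx <- 1L
    if (mx) {
      idx <- idx + 1L
      J[1, idx] <- a / C_M
      J[idx, 1] <- a / C_X
      J[idx, idx] <- (x + a) / C_X
    }
    if (ml) {
      idx_l <- idx + 1L
      J[1, idx_l] <- n * b / C_M
      J[idx_l, 1] <- n * b / C_L
      J[idx_l, idx_l] <- (l + n * n * b) / C_L
    }
    list(F = Fv, J = J, m = m, x = x, l = l)
  }

  ep <- eval_point(t_cur)
  res <- max(abs(ep$F))
  iter <- 0L
  ok <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    if (res <= tol) { ok <- TRUE; break }
    step <- tryCatch(solve(ep$J, -ep$F), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    step <- pmin(pmax(step, -30), 30)
    improved <- FALSE
    lam <- 1
    for (k in 0:12) {
      cand <- t_cur + lam * step
      epc <- tryCatch(eval_point(cand), error = function(e) NULL)
      if (!is.null(epc) && all(is.finite(epc$F)) && max(abs(epc$F)) < res) {
        t_cur <- cand; ep <- epc; res <- max(abs(epc$F)); improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  if (ok || res <= tol) {
    return(build_state(system, totals, ep$m, ep$x, ep$l,
                       method = "newton", iterations = iter))
  }
  # Newton stalled: fall back to the guaranteed bracketing scheme.
  st <- speciation_oracle(system, totals)
  st$method <- "newton+bisection_fallback"
  if (max(abs(st$residuals)) > SPECIATION_CONTRACT) {
    ligex_error("ligex_speciation_failure",
                sprintf("speciation solver failed to converge (best residual %.3g)",
                        max(abs(st$residuals))),
                best_residual = max(abs(st$residuals)))
  }
  st
}

#' Reference speciation solver by nested bracketing bisection
#'
#' Independent implementation of the [solve_speciation()] contract, used as a
#' cross-check: an outer bisection on the free metal concentration (in log
#' space over \[0, C_M\]), with the free indicator ligand obtained in closed
#' form and the free test ligand by an inner monotone bisection. Slower but
#' unconditionally convergent, since the total-metal balance is strictly
#' increasing in free M.
#'
#' @inheritParams solve_speciation
#' @return A `speciation_state`; see [solve_speciation()].
#' @examples
#' sys <- demo_system("exchange")
#' speciation_oracle(sys, mixture_totals(C_M = 3e-4, C_X = 3e-4, C_L = 1e-4))
#' @export
speciation_oracle <- function(system, totals) {
  setup <- speciation_setup(system, totals)
  if (!is.null(setup$state)) {
    setup$state$method <- "bisection"
    return(setup$state)
  }
  totals <- setup$totals
  bMX <- beta_lin(system$log_beta_MX)
  bML <- beta_lin(system$log_beta_MLn)
  n <- system$n
  C_M <- totals$C_M; C_X <- totals$C_X; C_L <- totals$C_L
  mx <- setup$mx_active; ml <- setup$ml_active

  f <- function(m) {
    x <- if (mx) C_X / (1 + bMX * m) else C_X
    l <- if (ml) free_L_given_M(m, C_L, bML, n) else C_L
    a <- if (mx) bMX * m * x else 0
    b <- if (ml) bML * m * l^n else 0
    m + a + b - C_M
  }
  lo <- log(1e-300); hi <- log(C_M)
  if (f(C_M) <= 0) {
    m <- C_M
  } else {
    iters <- 0L
    while (hi - lo > 1e-14 && iters < 5000L) {
      mid <- (lo + hi) / 2
      if (f(exp(mid)) > 0) hi <- mid else lo <- mid
      iters <- iters + 1L
    }
    m <- exp((lo + hi) / 2)
  }
  x <- if (mx) C_X / (1 + bMX * m) else C_X
  l <- if (ml) free_L_given_M(m, C_L, bML, n) else C_L
  build_state(system, totals, m, x, l, method = "bisection", iterations = 0L)
}

#' Beer-Lambert absorbance of an equilibrium mixture
#'
#' Additive absorbance over all species with non-zero molar absorptivity:
#' \eqn{A = b\,(\varepsilon_{MX}[MX] + \varepsilon_{MLn}[ML_n] +
#' \varepsilon_M[M] + \varepsilon_L[L])} with path length \eqn{b}.
#'
#' @param system A [complex_system()].
#' @param state A `speciation_state` from [solve_speciation()].
#' @return Absorbance in AU (non-negative).
#' @examples
#' sys <- demo_system("exchange")
#' st <- solve_speciation(sys, mixture_totals(C_M = 3e-4, C_X = 3e-4))
#' absorbance(sys, st)
#' @export
absorbance <- function(system, state) {
  if (!inherits(state, "speciation_state")) {
    ligex_error("ligex_invalid_argument", "`state` must be a speciation_state")
  }
  system$path_length * (
    system$eps_MX * state$conc_MX + system$eps_MLn * state$conc_MLn +
      system$eps_M * state$free_M + system$eps_L * state$free_L
  )
}
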