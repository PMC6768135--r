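# Shared fixtures and small independent oracles, built in code.

# Strong-binding regime: indicator complex essentially fully formed at
# calibration concentrations and displacement essentially quantitative.
strong_exchange_system <- function(n = 1L) {
  demo_system("exchange", n = n, log_beta_MX = 10, log_beta_MLn = 14 * n)
}

# Even harder limit for machine-precision linearity checks.
ultra_exchange_system <- function(n = 1L) {
  demo_system("exchange", n = n, log_beta_MX = 16, log_beta_MLn = 26)
}

strong_classical_system <- function(n = 1L) demo_system("classical", n = n)

rel_diff <- function(a, b) {
  abs(a - b) / pmax(abs(a), abs(b), 1e-300)
}

# Closed-form 1:1 binding: [MX] from the quadratic mass-action equation
# beta (C_M - c)(C_X - c) = c, smaller root.
quadratic_mx <- function(beta, C_M, C_X) {
  S <- C_M + C_X + 1 / beta
  (S - sqrt(S^2 - 4 * C_M * C_X)) / 2
}

# Closed-form OLS via the normal equations, independent of lm().
normal_eq_line <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  c(intercept = (sy - slope * sx) / n, slope = slope)
}

make_line_fit <- function(slope, intercept) {
  structure(list(slope = slope, intercept = intercept, r = 1,
                 residual_sd = 0, n_points = 2L, x_range = c(0, 1)),
            class = "line_fit")
}

random_totals <- function() {
  mixture_totals(C_M = 10^runif(1, -6, -2),
                 C_X = 10^runif(1, -6, -2),
                 C_L = 10^runif(1, -6, -2))
}

random_system <- function() {
  complex_system(n = sample(1:3, 1),
                 log_beta_MX = runif(1, 2, 16),
                 log_beta_MLn = runif(1, 2, 16),
                 eps_MX = 1600)
}
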