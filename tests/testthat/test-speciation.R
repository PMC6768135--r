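test_that("without binding, free concentrations equal the analytical totals", {
  # log beta -1000 underflows to beta == 0: no binding at all
  sys <- complex_system(n = 1, log_beta_MX = -1000, log_beta_MLn = -1000)
  st <- solve_speciation(sys, mixture_totals(C_M = 1e-3, C_X = 2e-3, C_L = 5e-4))
  expect_equal(st$free_M, 1e-3)
  expect_equal(st$free_X, 2e-3)
  expect_equal(st$free_L, 5e-4)
  expect_equal(st$conc_MX, 0)
  expect_equal(st$conc_MLn, 0)
})

test_that("1:1 binding without test ligand matches the closed-form quadratic", {
  sys <- complex_system(n = 1, log_beta_MX = 8, log_beta_MLn = 0, eps_MX = 1600)
  tt <- mixture_totals(C_M = 3e-4, C_X = 3e-4, C_L = 0)
  st <- solve_speciation(sys, tt)
  expect_lt(rel_diff(st$conc_MX, quadratic_mx(1e8, 3e-4, 3e-4)), 1e-10)
  # strong-binding limit: complex concentration within 1% of total metal
  expect_lt(abs(st$conc_MX - 3e-4) / 3e-4, 0.01)
})

test_that("competitive n = 2 equilibrium matches frozen nested-bisection values", {
  sys <- complex_system(n = 2, log_beta_MX = 6, log_beta_MLn = 14, eps_MX = 1600)
  tt <- mixture_totals(C_M = 3e-4, C_X = 3e-4, C_L = 2e-4)
  expected <- list(free_M = 1.9528801149e-06, free_X = 1.0159572632e-04,
                   free_L = 7.1430759931e-07, conc_MX = 1.9840427368e-04,
                   conc_MLn = 9.9642846200e-05)
  for (solver in list(solve_speciation, speciation_oracle)) {
    st <- solver(sys, tt)
    for (nm in names(expected)) {
      expect_lt(rel_diff(st[[nm]], expected[[nm]]), 1e-6)
    }
  }
  expect_lt(rel_diff(absorbance(sys, solve_speciation(sys, tt)), 0.3174468379), 1e-6)
})

test_that("Newton solver and bisection oracle agree to 6 significant figures", {
  set.seed(2024)
  worst <- 0
  for (i in 1:200) {
    sys <- random_system()
    tt <- random_totals()
    a <- solve_speciation(sys, tt)
    b <- speciation_oracle(sys, tt)
    for (nm in c("free_M", "free_X", "free_L", "conc_MX", "conc_MLn")) {
      scale <- max(tt$C_M, tt$C_X, tt$C_L)
      # compare relatively, except for concentrations utterly negligible
      # against the totals (both solvers agree they are ~0)
      if (max(a[[nm]], b[[nm]]) > 1e-290 * scale) {
        worst <- max(worst, rel_diff(a[[nm]], b[[nm]]))
      }
    }
    expect_lte(max(abs(a$residuals)), 1e-9)
    expect_lte(max(abs(b$residuals)), 1e-9)
  }
  expect_lt(worst, 1e-6)
})

test_that("every returned state is non-negative with tiny mass-balance residuals", {
  set.seed(7)
  for (i in 1:50) {
    st <- solve_speciation(random_system(), random_totals())
    expect_true(all(unlist(st[c("free_M", "free_X", "free_L",
                                "conc_MX", "conc_MLn")]) >= 0))
    expect_lte(max(abs(st$residuals)), 1e-9)
  }
})

test_that("absorbance is additive Beer-Lambert over the species", {
  sys <- complex_system(n = 1, log_beta_MX = 8, log_beta_MLn = 0, eps_MX = 1600)
  zero <- solve_speciation(sys, mixture_totals(0, 0, 0))
  expect_identical(absorbance(sys, zero), 0)
  # direct product: [MX] = 3e-4 M at eps 1600 -> A = 0.48
  st <- solve_speciation(complex_system(n = 1, log_beta_MX = 16, eps_MX = 1600),
                         mixture_totals(C_M = 3e-4, C_X = 3e-4))
  expect_equal(1600 * st$conc_MX, 0.48, tolerance = 1e-6)
  # free-species terms and path length contribute too
  sys2 <- complex_system(n = 1, log_beta_MX = 8, eps_MX = 1600, eps_M = 10,
                         eps_L = 5, path_length = 2)
  st2 <- solve_speciation(sys2, mixture_totals(3e-4, 3e-4, 1e-4))
  expect_equal(absorbance(sys2, st2),
               2 * (1600 * st2$conc_MX + 10 * st2$free_M + 5 * st2$free_L))
})

test_that("invalid systems and totals are rejected", {
  expect_error(complex_system(n = 0), class = "ligex_invalid_argument")
  expect_error(complex_system(n = 1.5), class = "ligex_invalid_argument")
  expect_error(complex_system(eps_MX = -1), class = "ligex_invalid_argument")
  expect_error(mixture_totals(C_M = -1e-4), class = "ligex_invalid_argument")
})
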