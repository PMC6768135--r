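test_that("Job apex sits at metal mole fraction 1/(1+n) in the strong limit", {
  for (n in 1:3) {
    jb <- simulate_job_design(strong_classical_system(n))
    res <- job_analysis(jb, locator = "tangent")
    expect_lt(abs(res$x_max - 1 / (1 + n)), 1e-3)
    expect_lt(abs(res$n_hat - n), 1e-2)
  }
})

test_that("quadratic apex locator returns the parabola vertex", {
  x <- seq(0.1, 0.9, by = 0.1)
  a <- 1 - (x - 0.45)^2
  res <- job_analysis(titration_series(x, a, "job"), locator = "quadratic")
  expect_equal(res$x_max, 0.45, tolerance = 1e-9)
})

test_that("normalization does not move the located Job apex", {
  jb <- simulate_job_design(strong_classical_system(1), noise_sd = 0.002, seed = 17)
  for (loc in c("tangent", "quadratic")) {
    raw <- job_analysis(jb, locator = loc, normalize = FALSE)
    nrm <- job_analysis(jb, locator = loc, normalize = TRUE)
    expect_lt(abs(raw$x_max - nrm$x_max), 1e-12)
    expect_true(nrm$normalized)
  }
})

test_that("a monotone series has no interior maximum to locate", {
  s <- titration_series(seq(0.1, 0.9, by = 0.1), seq(0.1, 0.9, by = 0.1), "job")
  expect_error(job_analysis(s), class = "ligex_no_interior_maximum")
  expect_error(job_analysis(titration_series(c(0.2, 0.5, 0.8), c(0, 1, 0), "job")),
               class = "ligex_invalid_argument")  # too few points
})

test_that("the flipped abscissa convention gives a consistent stoichiometry", {
  jb <- simulate_job_design(strong_classical_system(2))
  # re-express on the ligand mole-fraction axis
  flipped <- titration_series(rev(1 - jb$x), rev(jb$absorbance), "job")
  res <- job_analysis(flipped, fraction = "ligand")
  expect_lt(abs(res$x_max - 2 / 3), 1e-3)   # ligand fraction n/(1+n)
  expect_lt(abs(res$n_hat - 2), 1e-2)       # still ligand-per-metal
})

test_that("two-segment search solves the piecewise-linear toy exactly", {
  s <- titration_series(c(0, 0.5, 1, 2, 3), c(0, 0.5, 1, 1, 1), "mole_ratio")
  res <- moleratio_analysis(s)
  expect_equal(res$break_x, 1, tolerance = 1e-12)
  expect_lt(res$sse, 1e-24)
  expect_gte(res$split_index, 2L)
  expect_lte(res$split_index, 3L)
})

test_that("segmentation recovers randomized exact breakpoints", {
  set.seed(404)
  for (i in 1:20) {
    brk <- runif(1, 0.8, 2.2)
    s1 <- runif(1, 0.5, 2); s2 <- runif(1, -0.1, 0.2)
    x <- seq(0.1, 4, by = 0.3)
    y <- ifelse(x < brk, s1 * x, s1 * brk + s2 * (x - brk))
    res <- moleratio_analysis(titration_series(x, y, "mole_ratio"))
    expect_lt(abs(res$break_x - brk), 1e-9)
  }
})

test_that("strong-limit bench mole-ratio design breaks at ratio 1", {
  res <- moleratio_analysis(simulate_moleratio_design(strong_classical_system(1)))
  expect_lt(abs(res$break_x - 1), 1e-2)
  expect_lt(abs(res$n_hat - 1), 1e-2)
})

test_that("weak complexes curve the mole-ratio plot and bias the tangents", {
  weak <- moleratio_analysis(simulate_moleratio_design(
    demo_system("classical", log_beta_MLn = 4)))
  strong <- moleratio_analysis(simulate_moleratio_design(
    demo_system("classical", log_beta_MLn = 14)))
  expect_gt(abs(weak$break_x - 1), 10 * abs(strong$break_x - 1))
  expect_gt(abs(weak$break_x - 1), 0.05)
})

test_that("method comparison table is complete and seed-deterministic", {
  sys <- demo_system("exchange")
  t1 <- compare_methods(sys, log_beta_grid = c(5, 14), seeds = 1:3)
  t2 <- compare_methods(sys, log_beta_grid = c(5, 14), seeds = 1:3)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 6L)
  expect_setequal(unique(t1$method), c("ligand_exchange", "job", "mole_ratio"))
  # all three estimators recover the truth in the strong regime
  expect_true(all(abs(t1$bias[t1$log_beta == 14]) < 0.05))
  expect_true(all(t1$n_fail == 0))
})
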