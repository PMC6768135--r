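test_that("fit_line reproduces exact and constant lines and matches the normal equations", {
  f <- fit_line(data.frame(x = c(0, 1), absorbance = c(0, 2)))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$r, 1)
  expect_equal(f$residual_sd, 0)

  f2 <- fit_line(data.frame(x = 0:2, absorbance = c(1, 1, 1)))
  expect_equal(f2$slope, 0)
  expect_equal(f2$intercept, 1)

  set.seed(31)
  for (i in 1:10) {
    x <- runif(50); y <- 0.3 + 2.5 * x + rnorm(50, sd = 0.1)
    f3 <- fit_line(data.frame(x = x, absorbance = y))
    ref <- normal_eq_line(x, y)
    expect_lt(abs(f3$slope - ref["slope"]), 1e-10)
    expect_lt(abs(f3$intercept - ref["intercept"]), 1e-10)
  }

  expect_error(fit_line(data.frame(x = c(1, 1), absorbance = c(0, 1))),
               class = "ligex_degenerate_fit")
  # x_window restricts the fitted points
  fw <- fit_line(data.frame(x = 0:5, absorbance = c(0, 1, 2, 10, 11, 12)),
                 x_window = c(0, 2))
  expect_equal(fw$slope, 1)
  expect_equal(fw$n_points, 3L)
})

test_that("line intersection solves both equations and flags parallels", {
  d <- make_line_fit(2, 0); i <- make_line_fit(-1, 3)
  expect_equal(intersect_lines(d, i), c(x_star = 1, y_star = 2))
  expect_error(intersect_lines(make_line_fit(1, 0), make_line_fit(1, 1)),
               class = "ligex_parallel_lines")
  pt <- intersect_lines(make_line_fit(1600, 0), make_line_fit(-3200, 0.96))
  expect_equal(pt, c(x_star = 2e-4, y_star = 0.32))
})

test_that("overlay geometry reproduces the hand-computed alpha, beta, delta", {
  g <- exchange_geometry(make_line_fit(1600, 0), make_line_fit(-3200, 0.96))
  expect_equal(g$delta, 0.32)
  expect_equal(g$alpha, 2e-4)
  expect_equal(g$beta, 1e-4)
  expect_equal(g$metal_per_ligand, 2)
  # symmetric slopes (1:1 complex): alpha equals beta
  g1 <- exchange_geometry(make_line_fit(1600, 0), make_line_fit(-1600, 0.96))
  expect_equal(g1$alpha, g1$beta)
  # steeper inverse slope (-3 eps): abscissa ratio 3
  g3 <- exchange_geometry(make_line_fit(1600, 0), make_line_fit(-4800, 0.96))
  expect_equal(g3$metal_per_ligand, 3, tolerance = 1e-12)
  # intersection at/below the abscissa is rejected
  expect_error(exchange_geometry(make_line_fit(1600, 0), make_line_fit(-3200, -0.1)),
               class = "ligex_geometry_undefined")
})

test_that("alpha/beta equals the slope ratio for any intersecting line pair", {
  set.seed(55)
  for (i in 1:50) {
    s1 <- runif(1, 100, 5000)
    s2 <- -runif(1, 100, 5000)
    b1 <- runif(1, -0.05, 0.05)
    b2 <- runif(1, 0.5, 2)
    g <- exchange_geometry(make_line_fit(s1, b1), make_line_fit(s2, b2))
    expect_lt(rel_diff(g$metal_per_ligand, abs(s2) / s1), 1e-12)
    expect_lt(rel_diff(g$alpha, g$delta / s1), 1e-12)
    expect_lt(rel_diff(g$beta, g$delta / abs(s2)), 1e-12)
  }
})

test_that("linear-region mask keeps pre-equivalence points and trims the floor", {
  sys <- ultra_exchange_system()
  ex <- simulate_exchange_design(sys)  # fully pre-equivalence
  expect_true(all(linear_region_mask(ex)))
  ext <- simulate_exchange_design(sys, ligand_amounts = seq(5e-5, 6e-4, by = 5e-5))
  m <- linear_region_mask(ext)
  expect_true(all(m[ext$x < 2.9e-4]))
  expect_false(any(m[ext$x > 3.1e-4]))
  expect_error(
    linear_region_mask(titration_series(c(0, 1e-4), c(0.4, 0.2), "exchange")),
    class = "ligex_insufficient_linear_region")
})

test_that("exchange estimator recovers n = 1, 2, 3 from noiseless simulations", {
  r1 <- suppressWarnings(estimate_n_exchange(
    simulate_calibration_design(ultra_exchange_system()),
    simulate_exchange_design(ultra_exchange_system()), boot_reps = 0))
  expect_lt(abs(r1$n_hat - 1), 1e-6)
  for (n in 2:3) {
    sys <- strong_exchange_system(n)
    r <- suppressWarnings(estimate_n_exchange(
      simulate_calibration_design(sys), simulate_exchange_design(sys),
      boot_reps = 0))
    expect_lt(abs(r$n_hat - n), 1e-3)
    expect_equal(r$n_rounded, n)
  }
})

test_that("noisy bench-design estimate rounds to 1:1 with a covering CI", {
  sys <- demo_system("exchange")
  cal <- simulate_calibration_design(sys, noise_sd = 0.002, seed = 101)
  ex <- simulate_exchange_design(sys, noise_sd = 0.002, seed = 102)
  r <- estimate_n_exchange(cal, ex, boot_reps = 500, boot_seed = 1)
  expect_equal(r$n_rounded, 1)
  expect_identical(r$ratio, "1:1")
  expect_lte(r$ci_low, r$n_hat)
  expect_gte(r$ci_high, r$n_hat)
  expect_true(r$ci_low <= 1 && 1 <= r$ci_high)
})

test_that("mean recovery over 100 noisy runs is within 0.05 of truth for n = 1..3", {
  for (n in 1:3) {
    sys <- strong_exchange_system(n)
    n_hats <- vapply(1:100, function(s) {
      cal <- simulate_calibration_design(sys, noise_sd = 0.002, seed = 2 * s)
      ex <- simulate_exchange_design(sys, noise_sd = 0.002, seed = 2 * s + 1)
      suppressWarnings(estimate_n_exchange(cal, ex, boot_reps = 0))$n_hat
    }, numeric(1))
    expect_lt(abs(mean(n_hats) - n), 0.05)
  }
})

test_that("the estimate is invariant to a common rescaling of the abscissa", {
  sys <- demo_system("exchange")
  cal <- simulate_calibration_design(sys, noise_sd = 0.002, seed = 7)
  ex <- simulate_exchange_design(sys, noise_sd = 0.002, seed = 8)
  scale_x <- function(s, c) titration_series(s$x * c, s$absorbance,
                                             s$method_kind, s$design,
                                             s$seed, s$noise_sd)
  r1 <- suppressWarnings(estimate_n_exchange(cal, ex, boot_reps = 0))
  r2 <- suppressWarnings(estimate_n_exchange(scale_x(cal, 10), scale_x(ex, 10),
                                             boot_reps = 0))
  expect_equal(r1$n_hat, r2$n_hat, tolerance = 1e-12)
})

test_that("bootstrap confidence intervals are seed-deterministic", {
  sys <- demo_system("exchange")
  cal <- simulate_calibration_design(sys, noise_sd = 0.002, seed = 301)
  ex <- simulate_exchange_design(sys, noise_sd = 0.002, seed = 302)
  r1 <- estimate_n_exchange(cal, ex, boot_reps = 400, boot_seed = 5)
  r2 <- estimate_n_exchange(cal, ex, boot_reps = 400, boot_seed = 5)
  r3 <- estimate_n_exchange(cal, ex, boot_reps = 400, boot_seed = 6)
  expect_identical(c(r1$ci_low, r1$ci_high), c(r2$ci_low, r2$ci_high))
  expect_false(identical(c(r1$ci_low, r1$ci_high), c(r3$ci_low, r3$ci_high)))
})

test_that("a visibly non-zero calibration intercept raises the origin warning", {
  cal <- titration_series(seq(1e-4, 6e-4, by = 1e-4),
                          0.1 + 1600 * seq(1e-4, 6e-4, by = 1e-4),
                          "calibration")
  ex <- simulate_exchange_design(demo_system("exchange"))
  expect_warning(estimate_n_exchange(cal, ex, boot_reps = 0),
                 class = "ligex_origin_violation")
})
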