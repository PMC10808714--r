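# Mechanics of the sweep/search machinery on deliberately small problem
# sizes; the quantitative spacing claims run at study scale in the
# acceptance suite.

tiny_cfg <- function() estimator_config(2, epochs = 4)
tiny_cfg3 <- function() estimator_config(3, epochs = 4)

test_that("two-component sweeps cover the grid and reproduce bit-for-bit", {
  inst <- fast_instrument(n_photons = 2000)
  sw <- sweep_spacing_two(4, c(0.1, 5), instrument = inst,
                          config = tiny_cfg(), n_train = 600, n_test = 120,
                          n_seeds = 2, seed = 3)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw$stats), 2 * 2)  # grid points x components
  expect_equal(nrow(sw$replicates), 2 * 2 * 2)
  expect_true(all(is.finite(as.matrix(sw$stats[-(1:2)]))))
  sw2 <- sweep_spacing_two(4, c(0.1, 5), instrument = inst,
                           config = tiny_cfg(), n_train = 600, n_test = 120,
                           n_seeds = 2, seed = 3)
  expect_identical(sw$stats, sw2$stats)
  # precision improves from near-degenerate to well-spaced lifetimes
  sig <- sw$stats$offset_std_abs[sw$stats$component == 1]
  expect_lt(sig[2], sig[1])
  # bracketed by zero and the constant-predictor plateau
  expect_true(all(sig > 0 & sig < 0.16))
})

test_that("three-component sweeps validate the lifetime ordering", {
  expect_error(
    sweep_middle_lifetime_three(4, 10, c(1, 6.5), seed = 1),
    "tau_A < tau_B < tau_C")
  inst <- fast_instrument(n_photons = 2000)
  sw <- sweep_middle_lifetime_three(4, 10, c(1, 3), instrument = inst,
                                    config = tiny_cfg3(), n_train = 500,
                                    n_test = 100, n_seeds = 1, seed = 2)
  expect_equal(sort(unique(sw$stats$component)), 1:3)
})

test_that("snr sweep attaches the grid to the instrument", {
  inst <- fast_instrument(n_photons = 2000)
  sw <- snr_sweep(c(10, 1000), lifetimes = c(4, 9), instrument = inst,
                  config = tiny_cfg(), n_train = 600, n_test = 120,
                  n_seeds = 1, seed = 5)
  expect_equal(sw$grid_name, "snr")
  expect_equal(length(sw$grid), 2L)
  expect_equal(nrow(sw$stats), 4L)
})

test_that("min-spacing search honours its bisection contract", {
  inst <- fast_instrument(n_photons = 20000)
  found <- find_min_spacing(2, sigma_target = 0.1, tol_ns = 0.5,
                            bracket = c(0.1, 6.4), instrument = inst,
                            config = estimator_config(2, epochs = 10),
                            n_train = 1500, n_test = 300, n_seeds = 1,
                            seed = 4)
  ev <- attr(found, "evaluations")
  expect_true(all(diff(ev$delta_ns) > 0))
  # the returned spacing meets the target; spacings that failed lie
  # strictly below it
  expect_lte(ev$sigma[which.min(abs(ev$delta_ns - found))], 0.1)
  failed <- ev$delta_ns[ev$sigma > 0.1]
  if (length(failed) > 0) expect_true(all(failed < found))
  # unreachable targets produce a clear bracket error
  expect_error(
    find_min_spacing(2, sigma_target = 1e-6, tol_ns = 0.5,
                     bracket = c(0.1, 0.2), instrument = inst,
                     config = tiny_cfg(), n_train = 300, n_test = 100,
                     n_seeds = 1, seed = 4),
    "bracket")
})

test_that("the spacing-law fit recovers exact log-linear relations", {
  n <- 2:5
  law <- fit_spacing_law(n, 10^(0.41 * n - 1.1))
  expect_equal(law$slope, 0.41, tolerance = 1e-9)
  expect_equal(law$intercept, -1.1, tolerance = 1e-9)
  expect_equal(law$fit_r_squared, 1, tolerance = 1e-9)
  expect_equal(fit_spacing_law(c(2, 4), c(0.5, 3))$fit_r_squared, 1)
  expect_error(fit_spacing_law(2, 0.5), "at least two")
  expect_error(fit_spacing_law(c(2, 3), c(0.5, -1)), "positive")
  expect_equal(predict(law, 3), 10^(0.41 * 3 - 1.1))
})

test_that("the lifetime budget caps the distinguishable fluorophore count", {
  law <- fit_spacing_law(2:5, 10^(0.41 * (2:5) - 1.1))
  expect_equal(max_distinguishable(law, 20), 4L)
  expect_equal(max_distinguishable(law, 0.6), 2L)
  # never below the two-fluorophore floor, even for absurd budgets
  expect_gte(max_distinguishable(law, 1e-6), 2L)
})
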