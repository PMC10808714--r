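test_that("instrument configuration enforces its geometry", {
  cfg <- instrument_config()
  expect_equal(n_bins(cfg), 4096L)
  expect_equal(bin_times(cfg)[1:3], c(0, 0.3125, 0.625))
  expect_error(instrument_config(bin_width_ns = 0.3, window_ns = 1280),
               "integer multiple")
  expect_error(instrument_config(snr = 0.5), "snr")
})

test_that("expected histogram matches exact exponential bin integrals without IRF", {
  cfg <- bare_instrument(n_photons = 1e4)
  mx <- mixture_sample(10, fractions = 1)
  h <- expected_histogram(mx, cfg, background = FALSE)
  # independent closed form: integral of (1/tau) exp(-t/tau) over each bin
  edges <- c(bin_times(cfg), cfg$window_ns)
  expected <- 1e4 * (exp(-edges[-length(edges)] / 10) - exp(-edges[-1] / 10))
  expect_equal(as.numeric(h), expected, tolerance = 1e-12)
  # conservation: in-window expectation equals the non-escaped probability
  expect_equal(sum(h), 1e4 * (1 - exp(-1280 / 10)), tolerance = 1e-9)
})

test_that("background level realises the configured peak-to-noise SNR", {
  cfg <- instrument_config(snr = 100, n_photons = 5e4)
  mx <- mixture_sample(c(4, 9), fractions = c(0.5, 0.5))
  h <- expected_histogram(mx, cfg)
  level <- attr(h, "background_level")
  expect_equal(max(h - level) / level, 100, tolerance = 1e-9)
})

test_that("IRF-convolved expectation still conserves in-window probability", {
  # with laser shape and jitter on, bin integrals must still total the
  # probability of arriving inside the window
  cfg <- instrument_config(snr = NULL, n_photons = 1)
  mx <- mixture_sample(c(4, 9), fractions = c(0.3, 0.7))
  h <- expected_histogram(mx, cfg, background = FALSE)
  total <- sum(vapply(seq_along(mx$lifetimes_ns), function(i) {
    mx$fractions[i] * diff(flimmix:::arrival_cdf(c(0, cfg$window_ns),
                                                 mx$lifetimes_ns[i], cfg))
  }, numeric(1)))
  expect_equal(sum(h), total, tolerance = 1e-12)
  expect_true(all(h >= 0))
})

test_that("simulated curves are reproducible and respect the photon budget", {
  cfg <- fast_instrument()
  mx <- mixture_sample(c(4, 9), fractions = c(0.4, 0.6))
  cv1 <- simulate_decay(mx, cfg, seed = 3)
  cv2 <- simulate_decay(mx, cfg, seed = 3)
  expect_identical(cv1$counts, cv2$counts)
  expect_error(simulate_decay(mx, cfg), "seed")

  off <- instrument_config(n_photons = 0, snr = NULL)
  cv0 <- simulate_decay(mx, off, seed = 1)
  expect_true(all(cv0$counts == 0L))

  nobg <- bare_instrument(n_photons = 2e4, window_ns = 1280)
  cvs <- simulate_decay(mixture_sample(5, fractions = 1), nobg, seed = 2)
  expect_lte(sum(cvs$counts), 2e4)
  # window >> tau: essentially no photon escapes
  expect_gte(sum(cvs$counts), 2e4 * (1 - exp(-1280 / 5)) - 3 * sqrt(2e4))
})

test_that("mean arrival time of an ideal mono-exponential curve equals tau", {
  cfg <- bare_instrument(n_photons = 1e5)
  cv <- simulate_decay(mixture_sample(10, fractions = 1), cfg, seed = 9)
  centres <- cv$time_ns + cfg$bin_width_ns / 2
  m <- sum(centres * cv$counts) / sum(cv$counts)
  se <- 10 / sqrt(sum(cv$counts))
  expect_lt(abs(m - 10), 3 * se)
})

test_that("Monte-Carlo histogram agrees with the closed-form expectation", {
  cfg <- instrument_config(snr = NULL, n_photons = 1e6)
  mx <- mixture_sample(c(4, 9), fractions = c(0.3, 0.7))
  cv <- simulate_decay(mx, cfg, seed = 11)
  e <- expected_histogram(mx, cfg, background = FALSE)
  keep <- e > 5
  chi2 <- sum((cv$counts[keep] - e[keep])^2 / e[keep])
  p <- pchisq(chi2, df = sum(keep), lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("maximum-likelihood lifetime recovery from ideal curves is unbiased", {
  # multinomial ML fit of tau on the binned counts; Fisher information of
  # the exponential gives se(tau) ~ tau/sqrt(n)
  for (tau in c(1, 5, 20)) {
    cfg <- bare_instrument(n_photons = 1e5)
    cv <- simulate_decay(mixture_sample(tau, fractions = 1), cfg, seed = 17)
    nll <- function(th) {
      p <- flimmix:::component_bin_probs(th, cfg)
      p <- p / sum(p)
      -sum(cv$counts[cv$counts > 0] * log(p[cv$counts > 0]))
    }
    tau_hat <- optimize(nll, c(tau / 3, tau * 3))$minimum
    expect_lt(abs(tau_hat - tau), 3 * tau / sqrt(1e5))
  }
})

test_that("doubling the photon budget shrinks relative bin error by sqrt(2)", {
  cfg1 <- instrument_config(n_photons = 5000, snr = NULL, window_ns = 320)
  cfg2 <- instrument_config(n_photons = 10000, snr = NULL, window_ns = 320)
  mx <- mixture_sample(5, fractions = 1)
  rel_err <- function(cfg, bin = 4L, reps = 120) {
    e <- expected_histogram(mx, cfg, background = FALSE)[bin]
    counts <- vapply(seq_len(reps),
                     function(s) simulate_decay(mx, cfg, seed = 800 + s)$counts[bin],
                     integer(1))
    sd(counts) / e
  }
  ratio <- rel_err(cfg2) / rel_err(cfg1)
  expect_gt(ratio, 1 / sqrt(2) - 0.18)
  expect_lt(ratio, 1 / sqrt(2) + 0.18)
})

test_that("generated datasets are labelled, reproducible and prior-faithful", {
  cfg <- fast_instrument(n_photons = 200)
  ds <- generate_dataset(10, c(4, 9), cfg, seed = 21)
  expect_equal(dim(ds$counts), c(10L, 4096L))
  expect_equal(rowSums(ds$labels), rep(1, 10), tolerance = 1e-9)
  ds2 <- generate_dataset(10, c(4, 9), cfg, seed = 21)
  expect_identical(ds$counts, ds2$counts)
  expect_identical(ds$labels, ds2$labels)
  expect_error(generate_dataset(10, c(4, 9), cfg, prior = c(1, -1), seed = 1),
               "prior")
  expect_error(generate_dataset(10, c(4, 9), cfg), "seed")

  # flat prior: uniform marginal, mean 1/2, sd 1/sqrt(12)
  big <- generate_dataset(10000, c(4, 9), instrument_config(n_photons = 0),
                          seed = 33)
  se <- sqrt(1 / 12) / sqrt(10000)
  expect_lt(abs(mean(big$labels[, 1]) - 0.5), 3 * se)

  # single curves can be regenerated in isolation via the sub-seed
  cv <- get_curve(ds, 4)
  expect_identical(cv$counts, as.integer(ds$counts[4, ]))
})

test_that("snr_of estimates the configured peak-to-background ratio", {
  cv <- decay_curve(c(1000, rep(10, 99)), seq(0, 99))
  expect_equal(snr_of(cv, tail_fraction = 0.1), 100)
  flat <- decay_curve(rep(7, 50), seq_len(50))
  expect_equal(snr_of(flat), 1)
  expect_warning(
    expect_equal(snr_of(decay_curve(c(5, rep(0, 49)), seq_len(50))), Inf),
    "unbounded")

  cfg <- instrument_config(snr = 100, n_photons = 5e4)
  mx <- mixture_sample(10, fractions = 1)
  est <- vapply(1:50,
                function(s) snr_of(simulate_decay(mx, cfg, seed = 100 + s)),
                numeric(1))
  expect_lt(abs(mean(est) - 100) / 100, 0.2)
})
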