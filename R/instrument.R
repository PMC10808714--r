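#' TCSPC acquisition settings
#'
#' Bundles the acquisition parameters of a time-correlated single-photon
#' counting (TCSPC) measurement: histogram binning, laser pulse shape,
#' detector timing jitter, background level and photon budget. Defaults
#' describe a SPAD-array setup with a 1.28 us window at 312.5 ps
#' resolution (4096 bins), a laser pulse of 1.25 ns FWHM with a 600 ps
#' exponential turn-off, 150 ps detector jitter and a peak-signal to
#' background ratio (SNR) of 100.
#'
#' @param bin_width_ns Histogram bin width in ns.
#' @param window_ns Acquisition window length in ns; must be an integer
#'   multiple of `bin_width_ns`.
#' @param laser_fwhm_ns Full width at half maximum of the Gaussian core of
#'   the laser pulse, ns. Zero disables the Gaussian component.
#' @param laser_turnoff_ns Characteristic lifetime of the laser's
#'   exponential turn-off decay, ns. Zero disables the tail.
#' @param jitter_sigma_ns Standard deviation of the Gaussian SPAD timing
#'   jitter, ns. Zero disables jitter.
#' @param snr Peak expected signal divided by the constant background
#'   level, or `NULL` for no background.
#' @param n_photons Expected number of signal photons per curve.
#' @return An object of class `"instrument_config"`.
#' @examples
#' cfg <- instrument_config()
#' n_bins(cfg)
#' @export
instrument_config <- function(bin_width_ns = 0.3125,
                              window_ns = 1280,
                              laser_fwhm_ns = 1.25,
                              laser_turnoff_ns = 0.6,
                              jitter_sigma_ns = 0.15,
                              snr = 100,
                              n_photons = 5e4) {
  stopifnot(bin_width_ns > 0, window_ns > 0,
            laser_fwhm_ns >= 0, laser_turnoff_ns >= 0, jitter_sigma_ns >= 0,
            n_photons >= 0)
  nb <- window_ns / bin_width_ns
  if (abs(nb - round(nb)) > 1e-9) {
    stop("window_ns must be an integer multiple of bin_width_ns")
  }
  if (!is.null(snr) && snr < 1) stop("snr must be >= 1 when set")
  structure(list(bin_width_ns = bin_width_ns,
                 window_ns = window_ns,
                 laser_fwhm_ns = laser_fwhm_ns,
                 laser_turnoff_ns = laser_turnoff_ns,
                 jitter_sigma_ns = jitter_sigma_ns,
                 snr = snr,
                 n_photons = n_photons),
            class = "instrument_config")
}

#' @rdname instrument_config
#' @param instrument An `instrument_config`.
#' @export
n_bins <- function(instrument) {
  as.integer(round(instrument$window_ns / instrument$bin_width_ns))
}

#' @rdname instrument_config
#' @export
bin_times <- function(instrument) {
  (seq_len(n_bins(instrument)) - 1L) * instrument$bin_width_ns
}

#' @export
print.instrument_config <- function(x, ...) {
  cat("TCSPC instrument configuration\n")
  cat(sprintf("  window: %g ns in %d bins of %g ns\n",
              x$window_ns, n_bins(x), x$bin_width_ns))
  cat(sprintf("  laser: FWHM %g ns, turn-off %g ns; jitter sigma %g ns\n",
              x$laser_fwhm_ns, x$laser_turnoff_ns, x$jitter_sigma_ns))
  cat(sprintf("  photons/curve: %g; SNR: %s\n", x$n_photons,
              if (is.null(x$snr)) "none (no background)" else format(x$snr)))
  invisible(x)
}

# Combined Gaussian sigma of laser core + detector jitter.
irf_sigma <- function(instrument) {
  sqrt((instrument$laser_fwhm_ns / (2 * sqrt(2 * log(2))))^2 +
         instrument$jitter_sigma_ns^2)
}

# CDF of Exp(tau) + N(0, sigma) (exponentially modified Gaussian),
# evaluated in log space so the exp(sigma^2/(2 tau^2)) factor cannot
# overflow before the complementary normal tail damps it.
emg_cdf <- function(t, tau, sigma) {
  if (sigma <= 0) {
    return(ifelse(t < 0, 0, 1 - exp(-t / tau)))
  }
  u <- t / sigma
  r <- sigma / tau
  pnorm(u) - exp(r^2 / 2 - t / tau + pnorm(u - r, log.p = TRUE))
}

# CDF of the photon arrival time for one fluorophore: fluorescence delay
# Exp(tau) + laser turn-off Exp(theta) + Gaussian blur (laser core and
# detector jitter). The two-exponential case is a signed combination of
# EMG CDFs; near-equal time constants are nudged apart (the Erlang limit).
arrival_cdf <- function(t, tau, instrument) {
  sigma <- irf_sigma(instrument)
  theta <- instrument$laser_turnoff_ns
  if (theta <= 0) {
    return(emg_cdf(t, tau, sigma))
  }
  if (abs(tau - theta) < 1e-9 * max(tau, theta)) {
    theta <- theta * (1 + 1e-6)
  }
  (tau * emg_cdf(t, tau, sigma) - theta * emg_cdf(t, theta, sigma)) /
    (tau - theta)
}

# Per-bin arrival probabilities for one component over the whole window.
component_bin_probs <- function(tau, instrument) {
  edges <- c(bin_times(instrument),
             n_bins(instrument) * instrument$bin_width_ns)
  cdf <- arrival_cdf(edges, tau, instrument)
  p <- diff(cdf)
  pmax(p, 0)
}

#' Expected (noise-free) decay histogram of a mixture
#'
#' Computes the expectation of the binned photon counts for a fluorophore
#' mixture under an instrument configuration: per-component exponential
#' decay convolved with the laser pulse and jitter kernel, integrated over
#' each bin, scaled by the photon budget and the component's fractional
#' contribution, plus (optionally) the constant background level implied
#' by the configured SNR. Photons arriving outside the window are lost,
#' so the in-window expectation can total less than `n_photons`.
#'
#' @param mixture A [mixture_sample()].
#' @param instrument An [instrument_config()].
#' @param background If `FALSE`, return the signal expectation only.
#' @return Numeric vector of expected counts, one per bin, with the
#'   background level (counts/bin) attached as attribute
#'   `"background_level"`.
#' @examples
#' mx <- mixture_sample(lifetimes_ns = c(4, 9), fractions = c(0.5, 0.5))
#' h <- expected_histogram(mx, instrument_config(n_photons = 1e4))
#' @export
expected_histogram <- function(mixture, instrument, background = TRUE) {
  stopifnot(inherits(mixture, "mixture_sample"),
            inherits(instrument, "instrument_config"))
  probs <- vapply(mixture$lifetimes_ns, component_bin_probs,
                  numeric(n_bins(instrument)), instrument = instrument)
  signal <- instrument$n_photons * as.numeric(probs %*% mixture$fractions)
  level <- background_level(signal, instrument)
  out <- if (background) signal + level else signal
  attr(out, "background_level") <- level
  out
}

# Constant background (counts per bin) from the configured SNR, defined
# as peak expected signal over background level.
background_level <- function(signal, instrument) {
  if (is.null(instrument$snr) || max(signal) <= 0) return(0)
  max(signal) / instrument$snr
}

#' Estimate the signal-to-noise ratio of a decay curve
#'
#' SNR is defined as the maximum histogram intensity divided by the noise
#' level, estimated as the mean count over the final `tail_fraction` of
#' the window, where the fluorescence has decayed away.
#'
#' @param curve A [decay_curve()].
#' @param tail_fraction Fraction of the window (from the end) used to
#'   estimate the background level.
#' @return Estimated SNR; `Inf` (with a warning) if the tail is all zero.
#' @export
snr_of <- function(curve, tail_fraction = 0.1) {
  stopifnot(inherits(curve, "decay_curve"),
            tail_fraction > 0, tail_fraction < 1)
  counts <- curve$counts
  n <- length(counts)
  if (n == 0L) stop("empty curve")
  tail_n <- max(1L, floor(tail_fraction * n))
  noise <- mean(counts[(n - tail_n + 1L):n])
  if (noise <= 0) {
    warning("zero noise level in tail; SNR is unbounded")
    return(Inf)
  }
  max(counts) / noise
}
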