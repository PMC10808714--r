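#' Specify a fluorophore mixture
#'
#' A mixture is defined by its component lifetimes together with any one
#' of: fractional contributions, decay amplitudes, or pipetted volumes
#' plus per-volume intensity factors (from which reference fractions
#' follow). Whichever is given, the other representations are derived so
#' that fractions and amplitudes are always mutually consistent.
#'
#' @param lifetimes_ns Positive component lifetimes in ns.
#' @param fractions Fractional contributions (sum to 1), or `NULL`.
#' @param amplitudes Pre-exponential amplitudes, or `NULL`.
#' @param volumes_ul Pipetted volumes in ul, or `NULL`.
#' @param intensity_factors Per-volume intensity factors (required with
#'   `volumes_ul`).
#' @return An object of class `"mixture_sample"` with elements
#'   `lifetimes_ns`, `fractions`, `amplitudes`.
#' @examples
#' mixture_sample(c(10.6, 5.6), volumes_ul = c(100, 100),
#'                intensity_factors = c(1, 1))
#' @export
mixture_sample <- function(lifetimes_ns, fractions = NULL, amplitudes = NULL,
                           volumes_ul = NULL, intensity_factors = NULL) {
  if (any(!is.finite(lifetimes_ns)) || any(lifetimes_ns <= 0)) {
    stop("lifetimes_ns must be positive")
  }
  if (is.null(fractions) && !is.null(volumes_ul)) {
    if (is.null(intensity_factors)) stop("intensity_factors required with volumes_ul")
    fractions <- reference_fractions(volumes_ul, intensity_factors)
  }
  if (is.null(fractions) && !is.null(amplitudes)) {
    fractions <- fractional_contributions(amplitudes, lifetimes_ns)
  }
  if (is.null(fractions)) {
    stop("one of fractions, amplitudes, or volumes_ul + intensity_factors is required")
  }
  if (length(fractions) != length(lifetimes_ns)) {
    stop("fractions and lifetimes_ns must have equal length")
  }
  check_fraction_vector(fractions)
  if (is.null(amplitudes)) {
    amplitudes <- amplitudes_from_fractions(fractions, lifetimes_ns)
  } else if (max(abs(fractional_contributions(amplitudes, lifetimes_ns) -
                       fractions)) > 1e-9) {
    stop("amplitudes and fractions are inconsistent")
  }
  structure(list(lifetimes_ns = as.numeric(lifetimes_ns),
                 fractions = as.numeric(fractions),
                 amplitudes = as.numeric(amplitudes)),
            class = "mixture_sample")
}

#' @export
print.mixture_sample <- function(x, ...) {
  cat(sprintf("Fluorophore mixture (%d components)\n", length(x$lifetimes_ns)))
  print(data.frame(lifetime_ns = x$lifetimes_ns,
                   fraction = round(x$fractions, 4),
                   amplitude = signif(x$amplitudes, 4)))
  invisible(x)
}

#' Binned TCSPC decay curve
#'
#' @param counts Non-negative integer photon counts, one per time bin.
#' @param time_ns Bin start times; strictly increasing with constant step.
#' @param meta Optional list of provenance (mixture, instrument, seed).
#' @return An object of class `"decay_curve"`.
#' @export
decay_curve <- function(counts, time_ns, meta = list()) {
  if (length(counts) != length(time_ns)) {
    stop("counts and time_ns must have equal length")
  }
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9)) {
    stop("counts must be non-negative integers")
  }
  if (length(time_ns) > 1L) {
    steps <- diff(time_ns)
    if (any(steps <= 0) || max(steps) - min(steps) > 1e-9 * steps[1]) {
      stop("time_ns must be strictly increasing with constant step")
    }
  }
  structure(list(counts = as.integer(round(counts)),
                 time_ns = as.numeric(time_ns), meta = meta),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("TCSPC decay curve: %d bins of %g ns, %d photons, peak %d\n",
              length(x$counts),
              if (length(x$time_ns) > 1) diff(x$time_ns[1:2]) else NA,
              sum(x$counts), max(x$counts)))
  invisible(x)
}

#' @export
plot.decay_curve <- function(x, log = "y", ...) {
  y <- pmax(x$counts, if (grepl("y", log)) 0.5 else 0)
  graphics::plot(x$time_ns, y, type = "s", log = log,
                 xlab = "time (ns)", ylab = "counts", ...)
  invisible(x)
}

#' Monte-Carlo simulation of one TCSPC decay curve
#'
#' Samples `n_photons` signal photons: the emitting fluorophore is chosen
#' with probability equal to its fractional contribution, the fluorescence
#' delay is exponential with that component's lifetime, the laser emission
#' offset follows the pulse model (Gaussian core plus exponential
#' turn-off) and detector jitter adds a further Gaussian offset. Arrivals
#' outside the acquisition window (including negative times) are dropped.
#' Independent Poisson background counts are added per bin at the level
#' implied by the configured SNR.
#'
#' @param mixture A [mixture_sample()].
#' @param instrument An [instrument_config()].
#' @param seed Integer seed; mandatory, so every curve is reproducible.
#' @return A [decay_curve()] with provenance in `meta`.
#' @examples
#' mx <- mixture_sample(c(4, 9), fractions = c(0.3, 0.7))
#' cv <- simulate_decay(mx, instrument_config(n_photons = 1e4), seed = 1)
#' @export
simulate_decay <- function(mixture, instrument, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory: every simulated curve must be reproducible")
  }
  stopifnot(inherits(mixture, "mixture_sample"),
            inherits(instrument, "instrument_config"))
  set.seed(seed)
  counts <- sample_signal_counts(mixture$fractions, mixture$lifetimes_ns,
                                 instrument)
  counts <- add_background(counts, mixture, instrument)
  decay_curve(counts, bin_times(instrument),
              meta = list(mixture = mixture, instrument = instrument,
                          seed = seed))
}

# The photon kernel uses its own fast RNG; its seed is drawn from R's
# RNG stream so that set.seed() fully determines the curve.
sample_signal_counts <- function(fractions, lifetimes, instrument) {
  kernel_seed <- floor(runif(1) * 2^31)
  photon_mc(as.integer(instrument$n_photons), fractions, lifetimes,
            irf_sigma(instrument), instrument$laser_turnoff_ns,
            instrument$bin_width_ns, n_bins(instrument), kernel_seed)
}

# Adds Poisson background at the SNR-implied level. `peak_signal` can be
# supplied to avoid recomputing the expected histogram per curve.
add_background <- function(counts, mixture, instrument, peak_signal = NULL) {
  if (is.null(instrument$snr) || instrument$n_photons == 0) return(counts)
  if (is.null(peak_signal)) {
    sig <- expected_histogram(mixture, instrument, background = FALSE)
    peak_signal <- max(sig)
  }
  level <- peak_signal / instrument$snr
  counts + rpois(length(counts), level)
}

# Order-independent per-curve sub-seed: a counter-based affine map into
# the 32-bit range, so curve i of a dataset is reproducible in isolation.
sub_seed <- function(seed, i) {
  s <- (abs(as.numeric(seed)) %% 2147483629) * 48271 + 7919 * as.numeric(i)
  as.integer(s %% 2147483629 + 1)
}

#' Generate a labelled dataset of simulated decay curves
#'
#' Draws a reference fraction vector per curve from a prior over the
#' simplex (flat Dirichlet by default), converts it to amplitudes, and
#' simulates each curve with a per-curve sub-seed derived from `seed` by
#' a counter-based scheme, so the dataset is bit-reproducible and each
#' curve can be regenerated independently.
#'
#' @param n_curves Number of curves.
#' @param lifetimes Component lifetimes in ns.
#' @param instrument An [instrument_config()].
#' @param prior `"flat"` for the uniform Dirichlet, or a numeric vector of
#'   Dirichlet concentration parameters (one per component).
#' @param seed Integer seed (mandatory).
#' @return An object of class `"labeled_dataset"`: integer count matrix
#'   `counts` (curves in rows), fraction matrix `labels`, plus
#'   `lifetimes_ns`, `instrument`, `prior`, `seed`.
#' @examples
#' ds <- generate_dataset(10, c(4, 9),
#'                        instrument_config(n_photons = 2000), seed = 7)
#' rowSums(ds$labels)
#' @export
generate_dataset <- function(n_curves, lifetimes, instrument,
                             prior = "flat", seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_curves >= 1, inherits(instrument, "instrument_config"))
  k <- length(lifetimes)
  if (k < 1L) stop("at least one lifetime required")
  alpha <- if (identical(prior, "flat")) rep(1, k) else as.numeric(prior)
  if (length(alpha) != k || any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("invalid prior: need 'flat' or positive concentration per component")
  }

  set.seed(seed)
  g <- matrix(stats::rgamma(n_curves * k, shape = rep(alpha, each = n_curves)),
              nrow = n_curves)
  labels <- g / rowSums(g)

  # Shared per-component bin shapes: used only to price the background
  # level per curve without re-deriving the expected histogram each time.
  probs <- vapply(lifetimes, component_bin_probs,
                  numeric(n_bins(instrument)), instrument = instrument)

  nb <- n_bins(instrument)
  counts <- matrix(0L, nrow = n_curves, ncol = nb)
  for (i in seq_len(n_curves)) {
    mx <- mixture_sample(lifetimes, fractions = labels[i, ])
    peak <- instrument$n_photons * max(probs %*% labels[i, ])
    set.seed(sub_seed(seed, i))
    ci <- sample_signal_counts(mx$fractions, mx$lifetimes_ns, instrument)
    counts[i, ] <- add_background(ci, mx, instrument, peak_signal = peak)
  }
  structure(list(counts = counts, labels = labels,
                 lifetimes_ns = as.numeric(lifetimes),
                 instrument = instrument,
                 prior = list(type = "dirichlet", alpha = alpha),
                 seed = as.integer(seed)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labelled TCSPC dataset: %d curves x %d bins, %d components\n",
              nrow(x$counts), ncol(x$counts), ncol(x$labels)))
  cat(sprintf("  lifetimes (ns): %s; seed %d\n",
              paste(x$lifetimes_ns, collapse = ", "), x$seed))
  invisible(x)
}

#' @rdname generate_dataset
#' @param dataset A `labeled_dataset`.
#' @param i Curve index.
#' @export
get_curve <- function(dataset, i) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            i >= 1, i <= nrow(dataset$counts))
  decay_curve(dataset$counts[i, ], bin_times(dataset$instrument),
              meta = list(label = dataset$labels[i, ],
                          seed = sub_seed(dataset$seed, i)))
}
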