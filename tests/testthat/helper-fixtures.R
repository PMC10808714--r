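# Shared lightweight fixtures. Unit tests use a reduced photon budget and
# a short window where the full-scale defaults are not the point of the
# test; the acceptance suite runs the full study conditions.

fast_instrument <- function(n_photons = 5000, snr = 100, ...) {
  instrument_config(n_photons = n_photons, snr = snr, ...)
}

# Instrument with the ideal-decay settings: no laser shape, no jitter,
# no background.
bare_instrument <- function(n_photons = 1e5, window_ns = 1280) {
  instrument_config(laser_fwhm_ns = 0, laser_turnoff_ns = 0,
                    jitter_sigma_ns = 0, snr = NULL,
                    n_photons = n_photons, window_ns = window_ns)
}

# Small two-component training setup used across estimator tests.
small_two_comp <- function(n_train = 2000, n_test = 300, taus = c(4, 9),
                           seed = 5, instrument = fast_instrument()) {
  list(train = generate_dataset(n_train, taus, instrument, seed = seed),
       test = generate_dataset(n_test, taus, instrument, seed = seed + 1000),
       taus = taus, instrument = instrument)
}
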