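#' Fixed-lifetime least-squares fraction fit
#'
#' Classical reference method: with the component lifetimes known and
#' held fixed, the decay histogram is modelled as a non-negative linear
#' combination of the per-component expected bin shapes (each component's
#' exponential decay convolved with the laser/jitter kernel and
#' integrated over the bins) plus a constant background. Amplitudes are
#' obtained by non-negativity-constrained linear least squares
#' (Lawson-Hanson) and converted to fractional contributions.
#'
#' Non-negativity is enforced because unconstrained multi-exponential
#' amplitude fitting is notoriously unstable when lifetimes are close;
#' the constrained fixed-lifetime fit is the fair baseline.
#'
#' @param curve A [decay_curve()], or a bare numeric vector of bin
#'   contents (useful for noise-free expectations).
#' @param lifetimes Known component lifetimes in ns (distinct).
#' @param instrument The [instrument_config()] the curve was recorded
#'   with; defines binning and the IRF used for the basis shapes.
#' @param weighting `"none"` for ordinary least squares or `"poisson"`
#'   to weight each bin by the reciprocal square root of its count.
#' @return An object of class `"flim_ls"`: `fractions`, `amplitudes`
#'   (common arbitrary scale), `background` (counts/bin),
#'   `residual_norm`, `fitted`, plus inputs.
#' @examples
#' mx <- mixture_sample(c(10.6, 5.6), amplitudes = c(2, 1) / 26.8)
#' cfg <- instrument_config(n_photons = 1e4)
#' fit <- ls_fixed_tau_fit(expected_histogram(mx, cfg), c(10.6, 5.6), cfg)
#' fit$fractions
#' @export
ls_fixed_tau_fit <- function(curve, lifetimes, instrument,
                             weighting = c("none", "poisson")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(instrument, "instrument_config"))
  y <- if (inherits(curve, "decay_curve")) as.numeric(curve$counts)
       else as.numeric(curve)
  if (length(y) != n_bins(instrument)) {
    stop(sprintf("curve has %d bins but instrument defines %d",
                 length(y), n_bins(instrument)))
  }
  if (any(lifetimes <= 0)) stop("lifetimes must be positive")
  if (anyDuplicated(lifetimes)) {
    stop("degenerate basis: duplicate lifetimes give a rank-deficient design")
  }
  shapes <- vapply(lifetimes, component_bin_probs,
                   numeric(n_bins(instrument)), instrument = instrument)
  A <- cbind(shapes, background = 1)
  w <- if (weighting == "poisson") 1 / sqrt(pmax(y, 1)) else rep(1, length(y))
  sol <- pracma::lsqnonneg(A * w, y * w)
  k <- length(lifetimes)
  coefs <- sol$x[seq_len(k)]        # per-component signal photons in shape units
  background <- sol$x[k + 1L]
  total <- sum(coefs)
  if (total <= 0) {
    stop("degenerate fit: no signal attributed to any component")
  }
  fitted <- as.numeric(A %*% sol$x)
  structure(list(fractions = coefs / total,
                 amplitudes = coefs / lifetimes,
                 background = background,
                 residual_norm = sqrt(sum((y - fitted)^2)),
                 fitted = fitted,
                 lifetimes_ns = lifetimes,
                 weighting = weighting,
                 counts = y),
            class = "flim_ls")
}

#' @export
print.flim_ls <- function(x, ...) {
  cat("Fixed-lifetime least-squares fit\n")
  print(data.frame(lifetime_ns = x$lifetimes_ns,
                   fraction = round(x$fractions, 4)))
  cat(sprintf("  background %.3g counts/bin; residual norm %.4g\n",
              x$background, x$residual_norm))
  invisible(x)
}

#' @export
coef.flim_ls <- function(object, ...) {
  c(stats::setNames(object$amplitudes,
                    paste0("alpha_", seq_along(object$amplitudes))),
    background = object$background)
}

#' @export
fitted.flim_ls <- function(object, ...) object$fitted

#' @export
residuals.flim_ls <- function(object, ...) object$counts - object$fitted

#' Predict fractions for many curves with the LS baseline
#'
#' Convenience wrapper applying [ls_fixed_tau_fit()] to each curve of a
#' dataset; returns a fraction matrix comparable to
#' [predict.flim_ann()].
#'
#' @param dataset A `labeled_dataset` (or count matrix).
#' @param lifetimes,instrument,weighting As in [ls_fixed_tau_fit()].
#' @return Matrix of fitted fractions, one row per curve.
#' @export
ls_predict <- function(dataset, lifetimes, instrument,
                       weighting = c("none", "poisson")) {
  weighting <- match.arg(weighting)
  counts <- if (inherits(dataset, "labeled_dataset")) dataset$counts
            else as.matrix(dataset)
  t(apply(counts, 1, function(y) {
    ls_fixed_tau_fit(as.numeric(y), lifetimes, instrument,
                     weighting = weighting)$fractions
  }))
}
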