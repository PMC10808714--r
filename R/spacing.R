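#' Train and evaluate one unmixing experiment
#'
#' One end-to-end replicate of the simulation study design: generate a
#' training and a disjoint held-out test set of simulated curves (flat
#' fraction prior), fit the neural-network estimator on the training set,
#' predict on the test set, and score the predictions. All three stages
#' draw their seeds from `seed` by the counter-based scheme, so a
#' replicate is fully reproducible from one integer.
#'
#' @param lifetimes Component lifetimes in ns.
#' @param instrument An [instrument_config()].
#' @param config An [estimator_config()] or `NULL` for the default
#'   architecture of the component count (its `seed` is re-derived from
#'   `seed`).
#' @param n_train,n_test Training and held-out curve counts.
#' @param seed Integer master seed.
#' @return An [evaluate_fractions()] report for the held-out set.
#' @export
run_unmixing_experiment <- function(lifetimes, instrument, config = NULL,
                                    n_train = 10000, n_test = 2000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  k <- length(lifetimes)
  if (is.null(config)) {
    config <- estimator_config(
      k, input_bins = auto_input_bins(lifetimes, instrument))
  }
  config$seed <- sub_seed(seed, 303L)
  train_ds <- generate_dataset(n_train, lifetimes, instrument,
                               seed = sub_seed(seed, 101L))
  test_ds <- generate_dataset(n_test, lifetimes, instrument,
                              seed = sub_seed(seed, 202L))
  fit <- flim_ann(train_ds, config)
  pred <- predict(fit, test_ds)
  evaluate_fractions(pred, test_ds$labels)
}

# Network input window for auto-configured experiments: enough leading
# bins to cover ~8x the longest lifetime (so essentially all decay
# information is inside), rounded up to multiples of 256 and capped at
# the acquisition window.
auto_input_bins <- function(lifetimes, instrument) {
  needed <- ceiling(8 * max(lifetimes) / instrument$bin_width_ns / 256) * 256
  as.integer(min(n_bins(instrument), max(256, needed)))
}

# Shared sweep driver: runs n_seeds replicates per grid value, where
# `lifetimes_of` maps a grid value to the component lifetimes and
# `instrument_of` to the acquisition settings.
run_sweep <- function(grid, grid_name, lifetimes_of, instrument_of,
                      config, n_train, n_test, n_seeds, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_seeds >= 1, length(grid) >= 1, !is.unsorted(grid, strictly = TRUE))
  reps <- list()
  for (gi in seq_along(grid)) {
    for (r in seq_len(n_seeds)) {
      rep_seed <- sub_seed(seed, gi * 1000L + r)
      rpt <- run_unmixing_experiment(lifetimes_of(grid[gi]),
                                     instrument_of(grid[gi]),
                                     config, n_train, n_test, rep_seed)
      rpt <- as.data.frame(rpt)
      rpt$grid_value <- grid[gi]
      rpt$replicate <- r
      reps[[length(reps) + 1L]] <- rpt
    }
  }
  replicates <- do.call(rbind, reps)
  stat_cols <- c("mean_offset_signed", "mean_offset_abs",
                 "offset_std_signed", "offset_std_abs", "r_squared")
  agg <- stats::aggregate(replicates[stat_cols],
                          by = replicates[c("grid_value", "component")],
                          FUN = mean)
  agg <- agg[order(agg$grid_value, agg$component), ]
  rownames(agg) <- NULL
  structure(list(grid = grid, grid_name = grid_name,
                 stats = agg, replicates = replicates,
                 n_seeds = n_seeds,
                 settings = list(n_train = n_train, n_test = n_test,
                                 seed = seed)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d points, %d seeds/point)\n",
              x$grid_name, length(x$grid), x$n_seeds))
  df <- x$stats
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, statistic = "offset_std_abs", ...) {
  s <- x$stats
  comps <- sort(unique(s$component))
  graphics::matplot(x$grid,
                    sapply(comps, function(k)
                      s[[statistic]][s$component == k]),
                    type = "b", pch = comps, xlab = x$grid_name,
                    ylab = statistic, ...)
  graphics::legend("topright", legend = paste("component", comps),
                   pch = comps, lty = seq_along(comps), col = seq_along(comps))
  invisible(x)
}

#' Two-fluorophore lifetime-spacing sweep
#'
#' Accuracy, precision and linear correlation of the estimator as a
#' function of the lifetime spacing for a mixture of two fluorophores
#' with lifetimes \eqn{\tau_A} and \eqn{\tau_A + \Delta\tau}. A fresh
#' estimator is trained per grid point and replicate; statistics are
#' averaged over replicates.
#'
#' @param tau_a_ns Base lifetime (ns).
#' @param delta_grid Increasing lifetime spacings (ns).
#' @param instrument An [instrument_config()].
#' @param config Optional [estimator_config()].
#' @param n_train,n_test,n_seeds Curve counts per replicate and number of
#'   replicates per grid point.
#' @param seed Integer master seed.
#' @return A `"sweep_result"`: aggregated `stats` (mean over replicates,
#'   per grid value and component), the raw `replicates`, and settings.
#' @export
sweep_spacing_two <- function(tau_a_ns = 4, delta_grid,
                              instrument = instrument_config(),
                              config = NULL, n_train = 10000, n_test = 2000,
                              n_seeds = 3, seed) {
  stopifnot(all(delta_grid > 0))
  run_sweep(delta_grid, "delta_tau_ns",
            lifetimes_of = function(d) c(tau_a_ns, tau_a_ns + d),
            instrument_of = function(d) instrument,
            config = config, n_train = n_train, n_test = n_test,
            n_seeds = n_seeds, seed = seed)
}

#' Three-fluorophore middle-lifetime sweep
#'
#' Two lifetimes are fixed (\eqn{\tau_A}, \eqn{\tau_C}) and the middle
#' lifetime \eqn{\tau_B = \tau_A + \Delta\tau} moves between them. As the
#' middle component approaches either neighbour, that pair becomes hard
#' to separate: the per-component precision curves cross near the uniform
#' spacing point.
#'
#' @param tau_a_ns,tau_c_ns Fixed shortest and longest lifetimes (ns).
#' @param delta_grid Spacings \eqn{\tau_B - \tau_A}; every value must
#'   keep \eqn{\tau_A < \tau_B < \tau_C}.
#' @inheritParams sweep_spacing_two
#' @return A `"sweep_result"` with per-component statistics.
#' @export
sweep_middle_lifetime_three <- function(tau_a_ns = 4, tau_c_ns = 10,
                                        delta_grid,
                                        instrument = instrument_config(),
                                        config = NULL, n_train = 10000,
                                        n_test = 2000, n_seeds = 3, seed) {
  if (any(delta_grid <= 0) || any(tau_a_ns + delta_grid >= tau_c_ns)) {
    stop("grid must satisfy tau_A < tau_B < tau_C")
  }
  run_sweep(delta_grid, "delta_tau_ns",
            lifetimes_of = function(d) c(tau_a_ns, tau_a_ns + d, tau_c_ns),
            instrument_of = function(d) instrument,
            config = config, n_train = n_train, n_test = n_test,
            n_seeds = n_seeds, seed = seed)
}

#' SNR sensitivity sweep
#'
#' Re-runs the two-fluorophore experiment across a grid of
#' signal-to-noise ratios at fixed lifetimes, to locate the point beyond
#' which more signal no longer buys precision.
#'
#' @param snr_grid Increasing SNR values.
#' @param lifetimes Mixture lifetimes (ns).
#' @inheritParams sweep_spacing_two
#' @return A `"sweep_result"` with `grid_name = "snr"`.
#' @export
snr_sweep <- function(snr_grid, lifetimes = c(4, 9),
                      instrument = instrument_config(),
                      config = NULL, n_train = 10000, n_test = 2000,
                      n_seeds = 3, seed) {
  stopifnot(all(snr_grid >= 1))
  run_sweep(snr_grid, "snr",
            lifetimes_of = function(s) lifetimes,
            instrument_of = function(s) {
              instrument$snr <- s
              instrument
            },
            config = config, n_train = n_train, n_test = n_test,
            n_seeds = n_seeds, seed = seed)
}

#' Minimal lifetime spacing reaching a precision target
#'
#' For `n_fluorophores` components on an equally spaced lifetime ladder
#' starting at `base_tau_ns`, finds by bisection the smallest spacing
#' whose seed-averaged precision (absolute-offset standard deviation on
#' held-out curves, aggregated over fluorophores per `aggregate`) meets
#' `sigma_target`. Precision improves with spacing, which makes
#' bisection valid; the evaluations performed are returned for
#' inspection.
#'
#' The default aggregation is the mean over fluorophores. The
#' conservative alternative `"worst"` (max over fluorophores) guarantees
#' every component individually meets the target, but at the photon
#' budgets typical of a single acquisition the middle components of
#' ladders with four or more fluorophores cannot reach a 5% target at
#' any spacing — their precision is information-limited, not
#' spacing-limited — so a worst-component search fails by construction
#' there (see the methods vignette).
#'
#' @param n_fluorophores Number of components (>= 2).
#' @param sigma_target Precision target as a fraction (default 0.05).
#' @param tol_ns Bisection tolerance on the spacing (ns).
#' @param bracket Search interval for the spacing (ns); errors if the
#'   target is not reached at its upper end. If the true minimum lies
#'   below the lower end, the lower end is returned (to within `tol_ns`).
#' @param base_tau_ns Shortest lifetime of the ladder (ns).
#' @param aggregate How to combine the per-fluorophore standard
#'   deviations: `"mean"` or `"worst"`.
#' @param escalate_margin Replicate-escalation band: an evaluation runs
#'   one replicate first and adds replicates (up to `n_seeds`) only while
#'   its running mean lies within this distance of `sigma_target`.
#'   Evaluations far from the threshold are decided cheaply; boundary
#'   ones get the full seed average. Set to `Inf` to always run
#'   `n_seeds` replicates.
#' @inheritParams sweep_spacing_two
#' @return The minimal spacing in ns (numeric scalar), with the
#'   evaluation table attached as attribute `"evaluations"`.
#' @export
find_min_spacing <- function(n_fluorophores, sigma_target = 0.05,
                             tol_ns = 0.1, bracket = c(0.05, 12.8),
                             base_tau_ns = 4,
                             aggregate = c("mean", "worst"),
                             escalate_margin = 0.01,
                             instrument = instrument_config(),
                             config = NULL, n_train = 10000, n_test = 2000,
                             n_seeds = 3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  aggregate <- match.arg(aggregate)
  stopifnot(n_fluorophores >= 2, sigma_target > 0, tol_ns > 0,
            length(bracket) == 2, bracket[1] > 0, bracket[2] > bracket[1])
  agg_fun <- if (aggregate == "worst") max else mean
  evals <- data.frame(delta_ns = numeric(0), sigma = numeric(0),
                      n_replicates = integer(0))
  sigma_at <- function(delta) {
    taus <- base_tau_ns + (seq_len(n_fluorophores) - 1L) * delta
    sig <- numeric(0)
    for (r in seq_len(n_seeds)) {
      rpt <- run_unmixing_experiment(
        taus, instrument, config, n_train, n_test,
        seed = sub_seed(seed, round(delta * 1e4) + r))
      sig <- c(sig, agg_fun(rpt$offset_std_abs))
      if (abs(mean(sig) - sigma_target) > escalate_margin) break
    }
    s <- mean(sig)
    evals[nrow(evals) + 1L, ] <<- list(delta, s, length(sig))
    s
  }
  lo <- bracket[1]
  hi <- bracket[2]
  if (sigma_at(hi) > sigma_target) {
    stop(sprintf(paste0("precision target %.3g not reached at the bracket ",
                        "top (spacing %.3g ns): widen the bracket or relax ",
                        "the target"), sigma_target, hi))
  }
  while (hi - lo > tol_ns) {
    mid <- (lo + hi) / 2
    if (sigma_at(mid) <= sigma_target) hi <- mid else lo <- mid
  }
  attr(hi, "evaluations") <- evals[order(evals$delta_ns), ]
  hi
}

#' Fit the minimal-spacing design law
#'
#' Ordinary least-squares line through \eqn{(N, \log_{10}
#' \Delta\tau_{\min})}: the fitted law is \eqn{\Delta\tau_{\min} =
#' 10^{a N + b}} with slope \eqn{a} and intercept \eqn{b}.
#'
#' @param n_values Fluorophore counts.
#' @param min_spacings_ns Minimal spacings (ns), one per count.
#' @return An object of class `"spacing_law"` with `slope`, `intercept`,
#'   `fit_r_squared` and the input points.
#' @examples
#' law <- fit_spacing_law(2:5, 10^(0.41 * (2:5) - 1.1))
#' law$slope
#' @export
fit_spacing_law <- function(n_values, min_spacings_ns) {
  if (length(n_values) != length(min_spacings_ns) || length(n_values) < 2) {
    stop("need at least two (N, spacing) points of equal length")
  }
  if (any(min_spacings_ns <= 0)) stop("spacings must be positive")
  y <- log10(min_spacings_ns)
  fit <- lm(y ~ n_values)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 fit_r_squared = r2,
                 n_values = n_values,
                 min_spacings_ns = min_spacings_ns),
            class = "spacing_law")
}

#' @export
print.spacing_law <- function(x, ...) {
  cat(sprintf("Minimal-spacing law: delta_tau_min = 10^(%.3f N %+.3f) ns\n",
              x$slope, x$intercept))
  cat(sprintf("  fit R^2 = %.3f over N = %s\n", x$fit_r_squared,
              paste(x$n_values, collapse = ", ")))
  invisible(x)
}

#' @export
predict.spacing_law <- function(object, n_fluorophores, ...) {
  10^(object$slope * n_fluorophores + object$intercept)
}

#' Largest fluorophore count fitting a lifetime budget
#'
#' Given a fitted [fit_spacing_law()] and a usable lifetime range (most
#' common fluorophores stay under 20 ns), returns the largest number of
#' fluorophores whose equally spaced ladder, at the minimal spacing the
#' law requires, still spans no more than the budget:
#' the largest \eqn{N} with \eqn{(N-1)\,10^{aN+b} \le} budget.
#'
#' @param spacing_law A `"spacing_law"`.
#' @param lifetime_budget_ns Usable lifetime span in ns.
#' @return Integer count, always at least 2.
#' @export
max_distinguishable <- function(spacing_law, lifetime_budget_ns = 20) {
  stopifnot(inherits(spacing_law, "spacing_law"))
  best <- 2L
  for (n in 2:100) {
    span <- (n - 1) * predict(spacing_law, n)
    if (span <= lifetime_budget_ns) best <- as.integer(n)
  }
  best
}
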