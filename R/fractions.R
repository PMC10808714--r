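#' Fractional contributions of mixture components
#'
#' In a multi-exponential decay \eqn{I(t) = \sum_i \alpha_i e^{-t/\tau_i}},
#' the share of the total emitted signal contributed by component \eqn{i} is
#' \deqn{P_i = \frac{\alpha_i \tau_i}{\sum_j \alpha_j \tau_j},}
#' since the time-integral of each component's decay is \eqn{\alpha_i\tau_i}.
#'
#' @param amplitudes Non-negative pre-exponential amplitude factors
#'   \eqn{\alpha_i}, one per component.
#' @param lifetimes Positive lifetimes \eqn{\tau_i} in ns, same length.
#' @return Numeric vector of fractions, non-negative and summing to 1.
#' @seealso [amplitudes_from_fractions()] for the inverse map,
#'   [reference_fractions()] for fractions from pipetted volumes.
#' @examples
#' fractional_contributions(c(2, 1), c(10.6, 5.6))
#' @export
fractional_contributions <- function(amplitudes, lifetimes) {
  check_components(amplitudes, lifetimes)
  products <- amplitudes * lifetimes
  total <- sum(products)
  if (total <= 0) {
    stop("degenerate mixture: all amplitude-lifetime products are zero")
  }
  products / total
}

#' Reference fractions from volumes and intensity factors
#'
#' Ground-truth fractional contributions of a pipetted mixture: each
#' component contributes in proportion to its per-volume emission intensity
#' \eqn{I_{0,i}} times the volume \eqn{v_i} added,
#' \deqn{P_{\mathrm{ref},i} = \frac{I_{0,i} v_i}{\sum_j I_{0,j} v_j}.}
#'
#' @param volumes_ul Non-negative volumes in microlitres.
#' @param intensity_factors Non-negative per-volume intensity factors,
#'   same length.
#' @return Numeric fraction vector summing to 1.
#' @examples
#' reference_fractions(c(100, 25), c(1, 1))
#' @export
reference_fractions <- function(volumes_ul, intensity_factors) {
  check_components(volumes_ul, intensity_factors,
                   names = c("volumes_ul", "intensity_factors"))
  products <- volumes_ul * intensity_factors
  total <- sum(products)
  if (total <= 0) {
    stop("degenerate mixture: all volume-intensity products are zero")
  }
  products / total
}

#' Amplitudes realising prescribed fractional contributions
#'
#' Inverts [fractional_contributions()]: given target fractions and known
#' lifetimes, returns amplitudes \eqn{\alpha_i \propto P_i/\tau_i},
#' normalised so that \eqn{\sum_i \alpha_i\tau_i = 1}. Used to simulate
#' curves label-first: draw the fractions, derive the amplitudes, simulate.
#'
#' @param fractions Fraction vector (non-negative, sums to 1).
#' @param lifetimes Positive lifetimes in ns, same length.
#' @return Amplitude vector; round-trips through
#'   [fractional_contributions()] to `fractions` to machine precision.
#' @export
amplitudes_from_fractions <- function(fractions, lifetimes) {
  check_components(fractions, lifetimes, names = c("fractions", "lifetimes"))
  if (any(lifetimes <= 0)) stop("lifetimes must be positive")
  check_fraction_vector(fractions)
  fractions / lifetimes
}

# Shared argument validation for component-wise vectors.
check_components <- function(x, y, names = c("amplitudes", "lifetimes")) {
  if (length(x) != length(y)) {
    stop(sprintf("%s and %s must have equal length", names[1], names[2]))
  }
  if (length(x) < 1L) stop("at least one component required")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite component values")
  }
  if (any(x < 0) || any(y < 0)) {
    stop(sprintf("%s and %s must be non-negative", names[1], names[2]))
  }
  invisible(TRUE)
}

check_fraction_vector <- function(p, tol = 1e-9) {
  if (any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop("fractions must be non-negative and sum to 1")
  }
  invisible(TRUE)
}
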