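#' Mean offset between predicted and reference fractions
#'
#' Accuracy statistic \eqn{\langle\Delta P\rangle = \frac{1}{N}\sum
#' (P_{\mathrm{pred}} - P_{\mathrm{ref}})}. The `"signed"` convention is
#' the plain mean difference; `"absolute"` averages the magnitudes
#' \eqn{|P_{\mathrm{pred}} - P_{\mathrm{ref}}|} instead, which is the
#' convention under which the uninformative-limit plateau of a
#' two-component mixture sits at 25%.
#'
#' @param pred,ref Numeric vectors of equal length (one component's
#'   fraction across curves).
#' @param convention `"signed"` or `"absolute"`.
#' @return A single number.
#' @export
mean_offset <- function(pred, ref, convention = c("signed", "absolute")) {
  convention <- match.arg(convention)
  check_paired(pred, ref, min_n = 1L)
  d <- offsets(pred, ref, convention)
  mean(d)
}

#' Standard deviation of fraction offsets
#'
#' Precision statistic: the population standard deviation of the offsets
#' about their own mean,
#' \eqn{\sigma = \sqrt{\frac{1}{N}\sum |(\Delta P) - \langle\Delta
#' P\rangle|^2}}, with \eqn{\Delta P} taken signed or absolute per
#' `convention`.
#'
#' @inheritParams mean_offset
#' @return A non-negative number.
#' @export
offset_std <- function(pred, ref, convention = c("signed", "absolute")) {
  convention <- match.arg(convention)
  check_paired(pred, ref, min_n = 2L)
  d <- offsets(pred, ref, convention)
  sqrt(mean((d - mean(d))^2))
}

offsets <- function(pred, ref, convention) {
  d <- pred - ref
  if (convention == "absolute") abs(d) else d
}

check_paired <- function(pred, ref, min_n) {
  if (length(pred) != length(ref)) stop("pred and ref must have equal length")
  if (length(pred) < min_n) {
    stop(sprintf("at least %d paired values required", min_n))
  }
  invisible(TRUE)
}

#' Coefficient of determination of predicted vs reference fractions
#'
#' By default the squared Pearson correlation between predictions and
#' references (scale- and offset-invariant, as read off a
#' prediction-vs-truth scatter). A constant prediction is defined to have
#' R-squared 0; a constant reference leaves the correlation undefined and
#' errors. `method = "identity"` instead scores agreement with the
#' identity line, \eqn{1 - \sum(pred-ref)^2 / \sum(ref-\bar{ref})^2}
#' (can be negative).
#'
#' @inheritParams mean_offset
#' @param method `"pearson"` or `"identity"`.
#' @return A number (in \[0, 1\] for `"pearson"`).
#' @export
r_squared <- function(pred, ref, method = c("pearson", "identity")) {
  method <- match.arg(method)
  check_paired(pred, ref, min_n = 2L)
  ss_ref <- sum((ref - mean(ref))^2)
  if (ss_ref == 0) stop("undefined correlation: reference values are constant")
  if (method == "identity") {
    return(1 - sum((pred - ref)^2) / ss_ref)
  }
  if (sd(pred) == 0) return(0)
  stats::cor(pred, ref)^2
}

#' Per-fluorophore accuracy and precision report
#'
#' Compares a matrix of predicted fractions against the reference matrix
#' column by column, reporting the mean offset and offset standard
#' deviation under both the signed and absolute conventions, plus the
#' squared Pearson correlation.
#'
#' @param pred,ref Fraction matrices of identical shape (curves in rows,
#'   components in columns).
#' @return An object of class `"eval_report"`: a data frame with one row
#'   per component and columns `component`, `n`, `mean_offset_signed`,
#'   `mean_offset_abs`, `offset_std_signed`, `offset_std_abs`,
#'   `r_squared`.
#' @examples
#' p <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, byrow = TRUE)
#' evaluate_fractions(p, p)
#' @export
evaluate_fractions <- function(pred, ref) {
  pred <- as.matrix(pred)
  ref <- as.matrix(ref)
  if (!all(dim(pred) == dim(ref))) stop("pred and ref shapes differ")
  if (nrow(pred) < 2L) stop("at least two curves required")
  rows <- lapply(seq_len(ncol(pred)), function(j) {
    data.frame(component = j,
               n = nrow(pred),
               mean_offset_signed = mean_offset(pred[, j], ref[, j], "signed"),
               mean_offset_abs = mean_offset(pred[, j], ref[, j], "absolute"),
               offset_std_signed = offset_std(pred[, j], ref[, j], "signed"),
               offset_std_abs = offset_std(pred[, j], ref[, j], "absolute"),
               r_squared = r_squared(pred[, j], ref[, j]))
  })
  structure(do.call(rbind, rows), class = c("eval_report", "data.frame"))
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat("Fraction-recovery report (per fluorophore)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
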