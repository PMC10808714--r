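#' Estimator architecture and training hyperparameters
#'
#' Default architectures follow the component count: three hidden layers
#' (40, 20, 10) for two fluorophores and four hidden layers
#' (70, 50, 30, 10) for three or more, with rectified-linear activations,
#' minibatch size 500, 20 epochs and learning rate 1e-3 under the Adam
#' optimiser with mean-squared-error loss. The network reads the leading
#' `input_bins` histogram bins of each curve, normalised by their total
#' counts (so predictions are invariant to overall intensity).
#'
#' @param n_components Number of fluorophores (>= 2; single-component
#'   unmixing is trivial and rejected).
#' @param hidden Hidden-layer widths; `NULL` selects the default for the
#'   component count.
#' @param input_bins Number of leading histogram bins fed to the network.
#'   The default 256 bins cover 80 ns at the default 312.5 ps binning,
#'   several times the longest lifetime of interest.
#' @param learning_rate,batch_size,epochs Optimiser hyperparameters.
#' @param seed Integer seed controlling weight initialisation and
#'   minibatch shuffling.
#' @return An object of class `"estimator_config"`.
#' @examples
#' estimator_config(3)
#' @export
estimator_config <- function(n_components, hidden = NULL, input_bins = 256L,
                             learning_rate = 1e-3, batch_size = 500L,
                             epochs = 20L, seed = 1L) {
  if (n_components < 2) {
    stop("n_components must be >= 2: a single component always has fraction 1")
  }
  if (is.null(hidden)) {
    hidden <- if (n_components == 2) c(40L, 20L, 10L) else c(70L, 50L, 30L, 10L)
  }
  stopifnot(all(hidden >= 1), input_bins >= 1, learning_rate >= 0,
            batch_size >= 1, epochs >= 1)
  structure(list(n_components = as.integer(n_components),
                 hidden = as.integer(hidden),
                 activation = "relu", loss = "mse",
                 input_bins = as.integer(input_bins),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "estimator_config")
}

#' @export
print.estimator_config <- function(x, ...) {
  cat(sprintf(
    "Fraction-estimator config: %d -> %s -> %d (ReLU, MSE)\n",
    x$input_bins, paste(x$hidden, collapse = " -> "), x$n_components))
  cat(sprintf("  Adam lr %g, batch %d, %d epochs, seed %d\n",
              x$learning_rate, x$batch_size, x$epochs, x$seed))
  invisible(x)
}

# Normalised network input from curves. Accepts a labeled_dataset, a
# count matrix (curves in rows), a single decay_curve or a list of them.
# Each row is truncated to the leading input_bins bins and divided by its
# total count over those bins.
curves_to_input <- function(curves, input_bins) {
  counts <- if (inherits(curves, "labeled_dataset")) {
    curves$counts
  } else if (inherits(curves, "decay_curve")) {
    matrix(curves$counts, nrow = 1)
  } else if (is.list(curves)) {
    do.call(rbind, lapply(curves, function(cv) {
      stopifnot(inherits(cv, "decay_curve"))
      cv$counts
    }))
  } else if (is.matrix(curves)) {
    curves
  } else {
    stop("unsupported curve container")
  }
  if (ncol(counts) < input_bins) {
    stop(sprintf("bin mismatch: estimator expects >= %d bins, curves have %d",
                 input_bins, ncol(counts)))
  }
  X <- counts[, seq_len(input_bins), drop = FALSE]
  storage.mode(X) <- "double"
  totals <- rowSums(X)
  totals[totals == 0] <- 1
  # Normalise away the intensity scale, then rescale so bin values are
  # O(1) (mean 1): keeps the fixed short Adam schedule well conditioned.
  X / totals * input_bins
}

#' Fit the neural-network fraction estimator
#'
#' Trains a fully connected feed-forward network to regress the
#' fractional contributions of each fluorophore directly from the binned
#' decay histogram, using minibatch Adam on mean-squared error for a
#' fixed number of epochs. Training is deterministic given
#' `config$seed`.
#'
#' @param dataset A [generate_dataset()] result (or any
#'   `labeled_dataset`) whose label matrix has `config$n_components`
#'   columns.
#' @param config An [estimator_config()]; defaults to the standard
#'   architecture for the dataset's component count.
#' @return An object of class `"flim_ann"` with elements `config`,
#'   `weights`, `normalization` and `loss_history` (one mean training
#'   loss per epoch).
#' @seealso [predict.flim_ann()], [fine_tune()], [evaluate_fractions()]
#' @examples
#' ds <- generate_dataset(200, c(4, 9),
#'                        instrument_config(n_photons = 2000), seed = 11)
#' fit <- flim_ann(ds, estimator_config(2, epochs = 2))
#' fit$loss_history
#' @export
flim_ann <- function(dataset, config = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (is.null(config)) config <- estimator_config(ncol(dataset$labels))
  stopifnot(inherits(config, "estimator_config"))
  if (ncol(dataset$labels) != config$n_components) {
    stop(sprintf("dataset has %d label columns but config expects %d",
                 ncol(dataset$labels), config$n_components))
  }
  if (nrow(dataset$counts) < 1L) stop("empty dataset")
  X <- curves_to_input(dataset, config$input_bins)
  Y <- dataset$labels
  set.seed(config$seed)
  params <- mlp_init(c(config$input_bins, config$hidden, config$n_components))
  tr <- mlp_train(params, X, Y, config$epochs, config$batch_size,
                  config$learning_rate)
  structure(list(config = config,
                 weights = tr$params,
                 normalization = list(
                   input_bins = config$input_bins,
                   scale = "per-curve total counts, times input_bins"),
                 loss_history = tr$loss_history),
            class = "flim_ann")
}

#' Fine-tune a trained estimator on new labelled curves
#'
#' Continues training from the existing weights on a second labelled set
#' — the mechanism by which an estimator pre-trained on simulated curves
#' is adapted to measured (or domain-shifted) data. The original model is
#' left unmodified; optimiser moments are restarted.
#'
#' @param model A fitted [flim_ann()].
#' @param dataset A `labeled_dataset` with matching component count and
#'   binning.
#' @param epochs,learning_rate Training schedule for the adaptation pass.
#' @param seed Seed for minibatch shuffling; defaults to the model's.
#' @return A new `"flim_ann"` object with concatenated loss history.
#' @export
fine_tune <- function(model, dataset, epochs = 20L,
                      learning_rate = model$config$learning_rate,
                      seed = model$config$seed) {
  stopifnot(inherits(model, "flim_ann"), inherits(dataset, "labeled_dataset"),
            epochs >= 1, learning_rate >= 0)
  if (ncol(dataset$labels) != model$config$n_components) {
    stop("component count of dataset does not match the model")
  }
  X <- curves_to_input(dataset, model$normalization$input_bins)
  Y <- dataset$labels
  set.seed(seed)
  tr <- mlp_train(model$weights, X, Y, epochs, model$config$batch_size,
                  learning_rate)
  model$weights <- tr$params
  model$loss_history <- c(model$loss_history, tr$loss_history)
  model
}

#' Predict fractional contributions for decay curves
#'
#' Applies the trained network to the normalised leading bins of each
#' curve. Raw network outputs are clipped to \[0, 1\] and renormalised to
#' sum to one (recorded post-processing, not part of the training loss).
#'
#' @param object A fitted [flim_ann()].
#' @param newdata Curves: a `labeled_dataset`, a count matrix (curves in
#'   rows), a [decay_curve()] or a list of them.
#' @param ... Unused.
#' @return Matrix of fractions, one row per curve, rows summing to 1.
#' @export
predict.flim_ann <- function(object, newdata, ...) {
  X <- curves_to_input(newdata, object$normalization$input_bins)
  if (nrow(X) == 0L) {
    return(matrix(numeric(0), ncol = object$config$n_components))
  }
  raw <- mlp_forward(object$weights, X)
  clipped <- pmin(pmax(raw, 0), 1)
  totals <- rowSums(clipped)
  degenerate <- totals <= 0
  clipped[degenerate, ] <- 1
  totals[degenerate] <- object$config$n_components
  clipped / totals
}

#' @export
print.flim_ann <- function(x, ...) {
  cat(sprintf("Neural-network lifetime unmixer (%d components)\n",
              x$config$n_components))
  cat(sprintf("  architecture: %d -> %s -> %d (ReLU)\n",
              x$config$input_bins, paste(x$config$hidden, collapse = " -> "),
              x$config$n_components))
  cat(sprintf("  trained %d epochs; final MSE %.3g\n",
              length(x$loss_history), tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
summary.flim_ann <- function(object, ...) {
  n_par <- sum(vapply(object$weights$W, length, numeric(1))) +
    sum(vapply(object$weights$b, length, numeric(1)))
  cat(sprintf("Neural-network lifetime unmixer: %d parameters\n", n_par))
  print(object$config)
  cat(sprintf("  input normalisation: leading %d bins / %s\n",
              object$normalization$input_bins, object$normalization$scale))
  cat(sprintf("  training MSE: first epoch %.3g, last epoch %.3g\n",
              object$loss_history[1], tail(object$loss_history, 1)))
  invisible(object)
}

#' @export
coef.flim_ann <- function(object, ...) object$weights

#' @export
plot.flim_ann <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "b",
                 xlab = "epoch", ylab = "training MSE", log = "y", ...)
  invisible(x)
}

#' Save / restore a trained estimator
#'
#' The checkpoint is a single archive holding the configuration, weights
#' and input-normalisation spec; [read_estimator()] restores an object
#' that is `identical()` to the saved one.
#'
#' @param model A fitted [flim_ann()].
#' @param path File path for the checkpoint.
#' @return `write_estimator` returns `path` invisibly; `read_estimator`
#'   the restored model.
#' @export
write_estimator <- function(model, path) {
  stopifnot(inherits(model, "flim_ann"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_estimator
#' @export
read_estimator <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "flim_ann")) stop("not a flim_ann checkpoint")
  model
}
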