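#' Read and write decay curves as CSV
#'
#' A curve is stored as plain CSV with header `time_ns,counts`, one row
#' per bin — the lingua franca for generic TCSPC exports.
#'
#' @param curve A [decay_curve()].
#' @param path CSV file path.
#' @return `write_curve_csv` returns `path` invisibly; `read_curve_csv`
#'   a `decay_curve`.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "decay_curve"))
  write.csv(data.frame(time_ns = curve$time_ns, counts = curve$counts),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_ns", "counts") %in% names(df))) {
    stop("curve CSV must have columns time_ns and counts")
  }
  decay_curve(df$counts, df$time_ns, meta = list(source = path))
}

FORMAT_VERSION <- "1"

#' Write / read a labelled dataset directory
#'
#' On-disk layout: `curves/curve_<i>.csv` (one CSV per curve),
#' `labels.csv` with columns `curve_id,P_1..P_n`, and `manifest.json`
#' recording the instrument configuration, lifetimes, fraction prior,
#' seed and format version — enough provenance to regenerate the dataset
#' exactly.
#'
#' @param dataset A `labeled_dataset`.
#' @param dir Target directory (created if missing).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` a
#'   `labeled_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  dir.create(file.path(dir, "curves"), recursive = TRUE, showWarnings = FALSE)
  n <- nrow(dataset$counts)
  ids <- sprintf("curve_%04d", seq_len(n))
  for (i in seq_len(n)) {
    write_curve_csv(get_curve(dataset, i),
                    file.path(dir, "curves", paste0(ids[i], ".csv")))
  }
  labels <- as.data.frame(dataset$labels)
  names(labels) <- paste0("P_", seq_len(ncol(labels)))
  write.csv(cbind(curve_id = ids, labels),
            file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  manifest <- list(format_version = FORMAT_VERSION,
                   instrument = unclass(dataset$instrument),
                   lifetimes_ns = dataset$lifetimes_ns,
                   prior = dataset$prior,
                   seed = dataset$seed,
                   n_curves = n)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(as.character(manifest$format_version), FORMAT_VERSION)) {
    stop(sprintf("incompatible dataset format version %s (expected %s)",
                 manifest$format_version, FORMAT_VERSION))
  }
  inst <- manifest$instrument
  instrument <- instrument_config(
    bin_width_ns = inst$bin_width_ns, window_ns = inst$window_ns,
    laser_fwhm_ns = inst$laser_fwhm_ns,
    laser_turnoff_ns = inst$laser_turnoff_ns,
    jitter_sigma_ns = inst$jitter_sigma_ns,
    snr = inst$snr, n_photons = inst$n_photons)
  labels_df <- read.csv(file.path(dir, "labels.csv"))
  label_cols <- grep("^P_", names(labels_df), value = TRUE)
  labels <- as.matrix(labels_df[label_cols])
  dimnames(labels) <- NULL
  counts <- t(vapply(labels_df$curve_id, function(id) {
    as.integer(read_curve_csv(
      file.path(dir, "curves", paste0(id, ".csv")))$counts)
  }, integer(n_bins(instrument))))
  dimnames(counts) <- NULL
  structure(list(counts = counts, labels = labels,
                 lifetimes_ns = manifest$lifetimes_ns,
                 instrument = instrument,
                 prior = manifest$prior,
                 seed = as.integer(manifest$seed)),
            class = "labeled_dataset")
}

#' Write predicted fractions as CSV
#'
#' @param pred Fraction matrix (curves in rows).
#' @param path CSV path; columns `curve_id,P_1..P_n`.
#' @param curve_ids Optional identifiers; defaults to `curve_<i>`.
#' @export
write_predictions_csv <- function(pred, path, curve_ids = NULL) {
  pred <- as.matrix(pred)
  if (is.null(curve_ids)) curve_ids <- sprintf("curve_%04d", seq_len(nrow(pred)))
  df <- as.data.frame(pred)
  names(df) <- paste0("P_", seq_len(ncol(df)))
  write.csv(cbind(curve_id = curve_ids, df), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize reports and experiment results to JSON / CSV
#'
#' `write_report_json` works for [evaluate_fractions()] reports,
#' `"sweep_result"` objects, `"spacing_law"` objects and
#' [ls_fixed_tau_fit()] results. `write_report_csv` writes an
#' [evaluate_fractions()] report or a sweep's statistics as a flat CSV
#' (one row per component and statistic).
#'
#' @param x The object to serialize.
#' @param path Output path.
#' @export
write_report_json <- function(x, path) {
  payload <- if (inherits(x, "eval_report")) {
    list(kind = "eval_report", per_fluorophore = as.data.frame(x))
  } else if (inherits(x, "sweep_result")) {
    list(kind = "sweep_result", grid_name = x$grid_name, grid = x$grid,
         n_seeds = x$n_seeds, stats = x$stats, replicates = x$replicates,
         settings = x$settings)
  } else if (inherits(x, "spacing_law")) {
    list(kind = "spacing_law", slope = x$slope, intercept = x$intercept,
         fit_r_squared = x$fit_r_squared, n_values = x$n_values,
         min_spacings_ns = x$min_spacings_ns)
  } else if (inherits(x, "flim_ls")) {
    list(kind = "ls_fit", amplitudes = x$amplitudes, fractions = x$fractions,
         residual_norm = x$residual_norm, background = x$background)
  } else {
    stop("unsupported report type")
  }
  payload$format_version <- FORMAT_VERSION
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_csv <- function(x, path) {
  df <- if (inherits(x, "eval_report")) {
    long_stats(as.data.frame(x), id_cols = c("component", "n"))
  } else if (inherits(x, "sweep_result")) {
    long_stats(x$stats, id_cols = c("grid_value", "component"))
  } else {
    stop("unsupported report type")
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

long_stats <- function(df, id_cols) {
  stat_cols <- setdiff(names(df), id_cols)
  out <- do.call(rbind, lapply(stat_cols, function(s) {
    cbind(df[id_cols], statistic = s, value = df[[s]])
  }))
  out[do.call(order, out[id_cols]), ]
}
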