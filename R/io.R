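# Plain-text artifact formats: I/Q CSV + JSON sidecar, envelope CSV,
# feature CSV, model JSON, cohort manifest CSV.

#' Write an I/Q signal to CSV with a JSON sidecar
#'
#' The CSV has columns `t,i,q`; the sidecar `<path>.json` records
#' subject id, label, carrier and sampling frequency, and seed.
#'
#' @param signal an [iq_signal()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_iq_csv <- function(signal, path) {
  stopifnot(inherits(signal, "iq_signal"))
  n <- length(signal$samples)
  df <- data.frame(t = (seq_len(n) - 1) / signal$fs,
                   i = Re(signal$samples), q = Im(signal$samples))
  write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = signal$subject_id,
               label = signal$label,
               f0_hz = signal$f0, fs_hz = signal$fs,
               seed = signal$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an I/Q signal written by [write_iq_csv()]
#'
#' @param path CSV path (the `<path>.json` sidecar is read if present).
#' @return an [iq_signal()].
#' @export
read_iq_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("i", "q") %in% names(df))) stop("expected columns t,i,q")
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  fs <- meta$fs_hz
  if (is.null(fs)) {
    if (nrow(df) < 2 || is.null(df$t)) stop("no sampling frequency available")
    fs <- 1 / (df$t[2] - df$t[1])
  }
  iq_signal(complex(real = df$i, imaginary = df$q), fs = fs,
            subject_id = meta$subject_id %||% "subject",
            label = meta$label,
            seed = meta$seed %||% NA_integer_,
            f0 = meta$f0_hz %||% 24e9)
}

#' Write a cohort of signals plus a manifest
#'
#' @param signals list of [iq_signal()] (e.g. from [generate_cohort()]).
#' @param dir output directory (created if needed).
#' @return path to `manifest.csv`, invisibly.
#' @export
write_cohort <- function(signals, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(signals, function(s) {
    p <- file.path(dir, paste0(s$subject_id, ".csv"))
    write_iq_csv(s, p)
    p
  }, character(1))
  manifest <- data.frame(
    subject_id = vapply(signals, `[[`, character(1), "subject_id"),
    label = vapply(signals, function(s) s$label %||% NA_character_,
                   character(1)),
    path = paths, stringsAsFactors = FALSE)
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Write envelopes to CSV (columns t, v_u, v_l, v_m)
#'
#' @param env an `envelope_set`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_envelopes_csv <- function(env, path) {
  stopifnot(inherits(env, "envelope_set"))
  write.csv(data.frame(t = env$frame_times, v_u = env$v_u, v_l = env$v_l,
                       v_m = env$v_m),
            path, row.names = FALSE)
  invisible(path)
}

#' Write / read a gait-feature table
#'
#' Columns: subject_id, label, v_m_mean, v_u_mean, v_u_std, v_l_std.
#'
#' @param features data.frame as produced by [cohort_features()].
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_features_csv <- function(features, path) {
  .check_feature_table(features)
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_feature_table(df)
  df
}

#' Serialize / restore a trained SVM model as JSON
#'
#' The JSON stores hyperparameters, standardization statistics and the
#' support data, which is sufficient for bit-reproducible prediction.
#'
#' @param model an `svm_gait_model`.
#' @param path JSON path.
#' @return `path` (write) or the model (read).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "svm_gait_model"))
  payload <- list(
    type = "svm_gait_model",
    C = model$C, gamma = model$gamma, objective = model$objective,
    feature_columns = model$feature_columns,
    standardization = list(mean = as.numeric(model$standardization$mean),
                           sd = as.numeric(model$standardization$sd)),
    alpha = model$alpha, rho = model$rho,
    support_y = model$support_y,
    support_x = apply(model$support_x, 1, identity, simplify = FALSE),
    validation_metrics = model$validation_metrics,
    validation_confusion = model$validation_confusion)
  # I(17) significant digits: doubles survive the text round trip
  # exactly, so restored models predict bit-identically
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$type, "svm_gait_model")) stop("not an svm_gait_model file")
  sx <- do.call(rbind, lapply(p$support_x, as.numeric))
  std <- list(mean = p$standardization$mean, sd = p$standardization$sd)
  names(std$mean) <- p$feature_columns
  names(std$sd) <- p$feature_columns
  structure(
    list(C = p$C, gamma = p$gamma, objective = p$objective,
         standardization = std,
         alpha = p$alpha, rho = p$rho,
         support_x = sx, support_y = p$support_y,
         feature_columns = p$feature_columns,
         validation_metrics = as.list(p$validation_metrics),
         validation_confusion = as.list(p$validation_confusion)),
    class = "svm_gait_model"
  )
}
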