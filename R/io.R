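#' Serialize and restore parameter presets
#'
#' Cell parameter sets and analysis/experiment configurations persist as
#' structured JSON (or YAML when the `yaml` package is available). The
#' named presets `"tc_default"` and `"ctx_default"` mirror the published
#' parameter table.
#'
#' @param params a [membrane_params()] object or a named list of them.
#' @param path output file (`.json` or `.yaml`/`.yml`).
#' @export
write_params <- function(params, path) {
  if (inherits(params, "membrane_params")) params <- list(preset = params)
  lst <- lapply(params, function(p) unclass(p))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML output")
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_params
#' @return `read_params`: named list of `membrane_params` objects.
#' @export
read_params <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML input")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(lst, function(p) {
    type <- p$type
    p$type <- NULL
    do.call(membrane_params, c(list(type = type), p))
  })
}

#' Built-in parameter presets
#'
#' @return named list with `tc_default` and `ctx_default`
#'   [membrane_params()] objects.
#' @export
default_presets <- function() {
  list(tc_default = membrane_params("tc"),
       ctx_default = membrane_params("ctx"))
}

#' Persist a conductance trace as CSV
#'
#' Columns `time_ms`, `g_exc_ns`, `g_inh_ns`.
#'
#' @param trace a [conductance_trace()].
#' @param path CSV path.
#' @export
write_conductance_csv <- function(trace, path) {
  stopifnot(inherits(trace, "conductance_trace"))
  df <- data.frame(time_ms = (seq_along(trace$g_exc) - 1) * trace$dt,
                   g_exc_ns = trace$g_exc, g_inh_ns = trace$g_inh)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conductance_csv
#' @param e_exc,e_inh reversal potentials to stamp on the loaded trace.
#' @export
read_conductance_csv <- function(path, e_exc = 0, e_inh = -75) {
  df <- read.csv(path)
  dt <- diff(df$time_ms[1:2])
  conductance_trace(df$g_exc_ns, df$g_inh_ns, dt, e_exc, e_inh)
}

#' Tidy export of transfer results
#'
#' One row per result: analysis settings, information values and
#' diagnostics, ready for CSV.
#'
#' @param results a `transfer_result` or list of them.
#' @param condition optional vector of condition labels.
#' @return data frame.
#' @export
transfer_table <- function(results, condition = NULL) {
  if (inherits(results, "transfer_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(window_ms = r$settings$window_ms,
               bin_ms = r$settings$bin_ms, lag_ms = r$settings$lag_ms,
               mi_raw = r$mi_raw, bias = r$bias,
               mi_corrected = r$mi_corrected, te = r$te,
               n_windows = r$n_windows, n_words_s = r$n_words_s,
               n_words_r = r$n_words_r,
               flags = paste(r$flags, collapse = ";"))))
  if (!is.null(condition)) df <- cbind(condition = condition, df)
  df
}
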