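#' Write a diffusion trace as delimited text
#'
#' Two-column CSV with header `time_s,signal`, '.' decimal separator, UTF-8.
#'
#' @param trace A [diffusion_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "diffusion_trace"))
  df <- data.frame(time_s = trace$times, signal = trace$signal)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a diffusion trace from delimited text
#'
#' Expects the dialect written by [write_trace()]: a `time_s,signal` header
#' followed by numeric rows with strictly increasing times.  Malformed rows
#' are reported with their line numbers.
#'
#' @param path Input path.
#' @param x_m Observation height to attach to the trace, cm.
#' @param calibrated Whether the signal column is in concentration units.
#' @return A [diffusion_trace()].
#' @export
read_trace <- function(path, x_m = 0.51, calibrated = FALSE) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("trace file is empty: ", path)
  header <- trimws(strsplit(lines[1], ",")[[1]])
  if (length(header) < 2L || header[1] != "time_s" || header[2] != "signal") {
    stop("missing or malformed header (expected 'time_s,signal') in ", path)
  }
  fields <- strsplit(lines[-1], ",")
  bad_shape <- which(lengths(fields) < 2L)
  if (length(bad_shape)) {
    stop("malformed row at line ", bad_shape[1] + 1L, " of ", path)
  }
  times <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  signal <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad_num <- which(is.na(times) | is.na(signal))
  if (length(bad_num)) {
    stop("non-numeric cell at line ", bad_num[1] + 1L, " of ", path)
  }
  bad_order <- which(diff(times) <= 0)
  if (length(bad_order)) {
    stop("times not strictly increasing at line ", bad_order[1] + 2L,
         " of ", path)
  }
  diffusion_trace(times, signal, x_m = x_m, calibrated = calibrated)
}

#' Read a permeation sampling table
#'
#' CSV with header `time_h,acceptor_conc` (hours; nmol/mL).
#'
#' @param path Input path.
#' @param ... Experiment fields passed to [permeation_experiment()]
#'   (`C_d` is required).
#' @return A [permeation_experiment()].
#' @export
read_permeation <- function(path, ...) {
  if (!file.exists(path)) stop("sampling table not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("time_h", "acceptor_conc") %in% names(df))) {
    stop("expected columns 'time_h' and 'acceptor_conc' in ", path)
  }
  permeation_experiment(df$time_h, df$acceptor_conc, ...)
}

#' Write an analysis report
#'
#' Emits a machine-readable CSV of the result fields plus a short
#' human-readable summary with provenance (seed, package version).
#'
#' @param result A `fick_fit`, `papp_result` or data.frame.
#' @param path Output CSV path; the summary goes to `<path>.txt`.
#' @param seed Seed used for the run, recorded in the summary.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, seed = NA) {
  if (inherits(result, "fick_fit")) {
    df <- data.frame(A = result$params$A, sigma = result$params$sigma,
                     D = result$params$D,
                     se_A = result$std_errors[["A"]],
                     se_sigma = result$std_errors[["sigma"]],
                     se_D = result$std_errors[["D"]],
                     fit_error_pct = result$fit_error_pct,
                     rmse = result$rmse, r2 = result$r2,
                     n_used = result$n_used, converged = result$converged)
  } else if (inherits(result, "papp_result")) {
    df <- data.frame(dQdt_nmol_s = result$dQdt, Papp_cm_s = result$Papp,
                     r2_window = result$r2_window,
                     n_window = length(result$window),
                     sink_ok = result$sink_ok)
  } else if (is.data.frame(result)) {
    df <- result
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"))
  }
  utils::write.csv(df, path, row.names = FALSE)
  summary_path <- paste0(path, ".txt")
  con <- file(summary_path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("mucodiff %s", as.character(utils::packageVersion("mucodiff"))),
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %s", seed),
    "",
    utils::capture.output(print(df))), con)
  invisible(path)
}
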