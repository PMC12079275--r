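#' Read and write multichannel trace CSV
#'
#' Plain comma-separated files with a `time_s` header column followed by one
#' column per channel (values in mV). On read, the time base is checked for
#' uniformity (1e-6 relative tolerance) and ragged or header-less files are
#' rejected with the offending line where detectable.
#'
#' @param path File path.
#' @param trace Multichannel trace tibble.
#' @return `read_trace_csv()`: the trace tibble; `write_trace_csv()`: `path`,
#'   invisibly.
#' @export
read_trace_csv <- function(path) {
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) abort(sprintf("cannot parse '%s': %s", path,
                                      conditionMessage(e)),
                              class = "protoelec_format_error")
  )
  if (!"time_s" %in% names(raw)) {
    abort("trace CSV must have a `time_s` header column.",
          class = "protoelec_format_error")
  }
  if (nrow(raw) < 2) {
    abort("trace CSV needs at least two rows.", class = "protoelec_format_error")
  }
  if (anyNA(raw)) {
    bad <- which(rowSums(is.na(raw)) > 0)[1]
    abort(sprintf("ragged or non-numeric row at data line %d.", bad),
          class = "protoelec_format_error")
  }
  out <- as_tibble(raw)
  trace_dt(out) # validates uniform time base
  out
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  if (!"time_s" %in% names(trace)) {
    abort("trace must have a `time_s` column.", class = "protoelec_format_error")
  }
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Read and write impedance spectrum CSV
#'
#' Header `freq_hz,z_real_ohm,z_imag_ohm`; frequencies must be positive and
#' are sorted ascending on read (stable for ties).
#'
#' @param path File path.
#' @param spectrum Spectrum tibble.
#' @return `read_spectrum_csv()`: the spectrum tibble, sorted by frequency;
#'   `write_spectrum_csv()`: `path`, invisibly.
#' @export
read_spectrum_csv <- function(path) {
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("cannot parse '%s': %s", path,
                                      conditionMessage(e)),
                              class = "protoelec_format_error")
  )
  need <- c("freq_hz", "z_real_ohm", "z_imag_ohm")
  if (!all(need %in% names(raw))) {
    abort("spectrum CSV must have header freq_hz,z_real_ohm,z_imag_ohm.",
          class = "protoelec_format_error")
  }
  if (anyNA(raw[need])) {
    abort("spectrum CSV contains missing values.",
          class = "protoelec_format_error")
  }
  if (any(raw$freq_hz <= 0)) {
    bad <- which(raw$freq_hz <= 0)[1]
    abort(sprintf("non-positive frequency at data line %d.", bad),
          class = "protoelec_format_error")
  }
  out <- as_tibble(raw[need])
  out[order(out$freq_hz), ]
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spectrum, path) {
  check_spectrum(spectrum)
  utils::write.csv(spectrum[, c("freq_hz", "z_real_ohm", "z_imag_ohm")],
                   path, row.names = FALSE)
  invisible(path)
}
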