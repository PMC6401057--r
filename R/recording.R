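#' Recording header metadata
#'
#' Builds the header object stored at the front of a `.ppd` file (or in the
#' companion `.json` settings file of a CSV export). The header is a JSON
#' object holding the subject ID, start date/time and the acquisition
#' parameters needed to interpret the stored counts.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param start_datetime ISO-8601 character timestamp. The default is a
#'   fixed epoch value so that programmatically generated recordings are
#'   byte-reproducible; pass e.g. `format(Sys.time(), "%Y-%m-%dT%H:%M:%S")`
#'   for wall-clock stamps.
#' @param acquisition_mode `"2-colour time-division"` (signals 1 and 2 come
#'   from detectors 1 and 2) or `"1-colour time-division"` (both signals
#'   from detector 1).
#' @param sampling_rate Per-channel sampling rate in Hz; must be positive.
#' @param led_currents Numeric pair, LED 1 and LED 2 drive current in mA.
#'   Each must lie in the driver's 0--100 mA output range.
#' @param volts_per_division Volts represented by one 15-bit count
#'   (default `3.3 / 2^15`, approximately 1.007e-4 V).
#' @param ... Further scalar metadata fields (e.g. a simulation seed); kept
#'   verbatim through JSON round trips.
#'
#' @return A `recording_header` object (named list).
#' @seealso [photometry_recording()], [write_ppd()]
#' @export
recording_header <- function(subject_id = "unknown",
                             start_datetime = "1970-01-01T00:00:00",
                             acquisition_mode = c("2-colour time-division",
                                                  "1-colour time-division"),
                             sampling_rate = 130,
                             led_currents = c(0, 0),
                             volts_per_division = 3.3 / 2^15,
                             ...) {
  acquisition_mode <- match.arg(acquisition_mode)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  if (length(led_currents) != 2L || !is.numeric(led_currents) ||
      any(!is.finite(led_currents)) ||
      any(led_currents < 0) || any(led_currents > 100)) {
    abort("`led_currents` must be two values in [0, 100] mA",
          class = "photomux_config_error")
  }
  stopifnot_scalar(volts_per_division, "volts_per_division", positive = TRUE)
  header <- list(
    subject_id = as.character(subject_id)[1],
    start_datetime = as.character(start_datetime)[1],
    acquisition_mode = acquisition_mode,
    sampling_rate = sampling_rate,
    led_currents = as.numeric(led_currents),
    volts_per_division = volts_per_division
  )
  extra <- list(...)
  if (length(extra)) {
    if (is.null(names(extra)) || any(names(extra) == "")) {
      abort("extra header fields must be named",
            class = "photomux_config_error")
    }
    header[names(extra)] <- extra
  }
  structure(header, class = "recording_header")
}

# Rebuild a header from a parsed JSON list, preserving unknown keys.
header_from_list <- function(x) {
  known <- c("subject_id", "start_datetime", "acquisition_mode",
             "sampling_rate", "led_currents", "volts_per_division")
  args <- x[intersect(known, names(x))]
  extra <- x[setdiff(names(x), known)]
  do.call(recording_header, c(args, extra))
}

#' Serialize a recording header to JSON text
#'
#' @param header A [recording_header()] object.
#' @return A single JSON string.
#' @export
header_to_json <- function(header) {
  as.character(jsonlite::toJSON(unclass(header), auto_unbox = TRUE,
                                digits = NA))
}

#' Parse a recording header from JSON text
#'
#' Unknown keys are retained so files written by newer producers still load.
#'
#' @param json JSON text as produced by [header_to_json()].
#' @return A [recording_header()] object.
#' @export
header_from_json <- function(json) {
  parsed <- tryCatch(
    jsonlite::fromJSON(json, simplifyVector = TRUE),
    error = function(e) {
      abort(paste0("malformed header JSON: ", conditionMessage(e)),
            class = "photomux_format_error")
    }
  )
  header_from_list(parsed)
}

#' @export
print.recording_header <- function(x, ...) {
  cat("<recording_header>\n")
  for (k in names(x)) {
    cat(sprintf("  %-18s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}

#' Photometry recording container
#'
#' A recording is a tibble with one row per time point and integer columns
#' `analog_1`, `analog_2` (15-bit baseline-subtracted counts, 0--32767) and
#' `digital_1`, `digital_2` (0/1), carrying a [recording_header()] as an
#' attribute. All tidyverse verbs apply to the data columns; the header is
#' retrieved with [rec_header()].
#'
#' @param analog_1,analog_2 Integer-valued vectors in `[0, 32767]`.
#' @param digital_1,digital_2 Vectors of 0/1 (or logical), same length as
#'   the analog series.
#' @param header A [recording_header()].
#'
#' @return A `photometry_recording` tibble.
#' @examples
#' rec <- photometry_recording(
#'   analog_1 = c(100L, 200L), analog_2 = c(5L, 6L),
#'   digital_1 = c(0L, 1L), digital_2 = c(0L, 0L)
#' )
#' rec
#' @export
photometry_recording <- function(analog_1 = integer(),
                                 analog_2 = integer(),
                                 digital_1 = integer(),
                                 digital_2 = integer(),
                                 header = recording_header()) {
  if (!inherits(header, "recording_header")) {
    abort("`header` must be a recording_header object",
          class = "photomux_config_error")
  }
  check_analog <- function(x, name) {
    if (length(x) && (!is.numeric(x) || any(!is.finite(x)) ||
                      any(x != trunc(x)) || any(x < 0) || any(x > 32767))) {
      abort(sprintf("`%s` values must be integers in [0, 32767]", name),
            class = "photomux_range_error")
    }
    as.integer(x)
  }
  check_digital <- function(x, name) {
    if (is.logical(x)) x <- as.integer(x)
    if (length(x) && (!is.numeric(x) || any(!(x %in% c(0, 1))))) {
      abort(sprintf("`%s` values must be 0 or 1", name),
            class = "photomux_range_error")
    }
    as.integer(x)
  }
  analog_1 <- check_analog(analog_1, "analog_1")
  analog_2 <- check_analog(analog_2, "analog_2")
  digital_1 <- check_digital(digital_1, "digital_1")
  digital_2 <- check_digital(digital_2, "digital_2")
  n <- unique(c(length(analog_1), length(analog_2),
                length(digital_1), length(digital_2)))
  if (length(n) != 1L) {
    abort("all four series must have equal length",
          class = "photomux_range_error")
  }
  out <- tibble::tibble(analog_1 = analog_1, analog_2 = analog_2,
                        digital_1 = digital_1, digital_2 = digital_2)
  attr(out, "header") <- header
  class(out) <- c("photometry_recording", class(out))
  out
}

#' Extract the header of a recording
#'
#' @param recording A [photometry_recording()].
#' @return The [recording_header()] attribute.
#' @export
rec_header <- function(recording) {
  h <- attr(recording, "header", exact = TRUE)
  if (is.null(h)) {
    abort("object carries no recording header",
          class = "photomux_format_error")
  }
  h
}

#' @export
print.photometry_recording <- function(x, ...) {
  h <- attr(x, "header", exact = TRUE)
  cat(sprintf("<photometry_recording: %d samples at %g Hz, %s>\n",
              nrow(x), h$sampling_rate, h$acquisition_mode))
  NextMethod()
}

assert_recording <- function(recording) {
  if (!inherits(recording, "photometry_recording")) {
    abort("expected a photometry_recording object",
          class = "photomux_config_error")
  }
  invisible(recording)
}
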