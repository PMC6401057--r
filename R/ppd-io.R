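#' Pack an analog sample and a digital bit into one 16-bit chunk
#'
#' Each stored chunk is a 16-bit word holding one 15-bit analog count and
#' one digital bit. The analog count occupies the high 15 bits and the
#' digital bit the least significant bit, so unpacking is a single shift
#' and mask.
#'
#' @param analog Integer vector of counts in `[0, 32767]`.
#' @param digital Integer (or logical) vector of 0/1, recycled against
#'   `analog` if scalar.
#' @return Integer vector of 16-bit words in `[0, 65535]`.
#' @seealso [unpack_chunk()]
#' @examples
#' pack_chunk(32767, 1) # 65535, i.e. 0xFFFF
#' unpack_chunk(pack_chunk(1234, 1))
#' @export
pack_chunk <- function(analog, digital) {
  if (is.logical(digital)) digital <- as.integer(digital)
  if (!is.numeric(analog) || any(!is.finite(analog)) ||
      any(analog != trunc(analog)) || any(analog < 0) || any(analog > 32767)) {
    abort("`analog` must contain integers in [0, 32767]",
          class = "photomux_range_error")
  }
  if (!is.numeric(digital) || any(!(digital %in% c(0, 1)))) {
    abort("`digital` must contain only 0 or 1",
          class = "photomux_range_error")
  }
  as.integer(analog) * 2L + as.integer(digital)
}

#' Unpack a 16-bit chunk into its analog count and digital bit
#'
#' Exact inverse of [pack_chunk()].
#'
#' @param word Integer vector of 16-bit words in `[0, 65535]`.
#' @return A list with integer vectors `analog` and `digital`.
#' @export
unpack_chunk <- function(word) {
  if (!is.numeric(word) || any(!is.finite(word)) ||
      any(word != trunc(word)) || any(word < 0) || any(word > 65535)) {
    abort("`word` must contain integers in [0, 65535]",
          class = "photomux_range_error")
  }
  word <- as.integer(word)
  list(analog = word %/% 2L, digital = word %% 2L)
}

# 16-bit little-endian writer: writeBin(size = 2) expects signed values.
write_u16 <- function(con, values) {
  v <- as.integer(values)
  v <- ifelse(v > 32767L, v - 65536L, v)
  writeBin(v, con, size = 2L, endian = "little")
}

read_u16 <- function(con, n) {
  readBin(con, what = "integer", n = n, size = 2L, signed = FALSE,
          endian = "little")
}

#' Write a recording as a .ppd binary file
#'
#' File layout: a 2-byte little-endian unsigned integer giving the byte
#' length of the UTF-8 JSON header, the header itself, then the data
#' section -- one pair of 16-bit little-endian chunks per time point
#' (signal 1 chunk first, then signal 2), 4 bytes per time point. A one
#' hour recording at 130 Hz therefore has a 1,872,000-byte data section
#' (~1.9 MB).
#'
#' @param recording A [photometry_recording()].
#' @param path Output file path (written atomically).
#' @return Invisibly, the total number of bytes written.
#' @seealso [read_ppd()]
#' @export
write_ppd <- function(recording, path) {
  assert_recording(recording)
  json <- header_to_json(rec_header(recording))
  json_raw <- charToRaw(enc2utf8(json))
  if (length(json_raw) > 65535L) {
    abort("header JSON exceeds the 2-byte length prefix",
          class = "photomux_format_error")
  }
  n <- nrow(recording)
  words <- integer(2L * n)
  if (n > 0) {
    words[seq(1L, 2L * n, by = 2L)] <-
      pack_chunk(recording$analog_1, recording$digital_1)
    words[seq(2L, 2L * n, by = 2L)] <-
      pack_chunk(recording$analog_2, recording$digital_2)
  }
  atomic_write(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    write_u16(con, length(json_raw))
    writeBin(json_raw, con)
    if (n > 0) write_u16(con, words)
  })
  invisible(2L + length(json_raw) + 4L * n)
}

#' Size in bytes of the data section a recording would occupy on disk
#'
#' Exactly `4 * nrow(recording)`: two 2-byte chunks per time point.
#'
#' @param recording A [photometry_recording()].
#' @return Integer byte count.
#' @export
ppd_data_bytes <- function(recording) {
  assert_recording(recording)
  4L * nrow(recording)
}

#' Read a .ppd binary file
#'
#' Exact inverse of [write_ppd()]. Unknown header keys are preserved.
#'
#' @param path Path to a `.ppd` file.
#' @return A [photometry_recording()].
#' @export
read_ppd <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist", path),
          class = "photomux_io_error")
  }
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (size < 2) {
    abort("file too short to hold a header length prefix",
          class = "photomux_format_error")
  }
  hlen <- read_u16(con, 1L)
  if (size < 2 + hlen) {
    abort(sprintf("truncated header: expected %d bytes at offset 2", hlen),
          class = "photomux_truncation_error")
  }
  json <- rawToChar(readBin(con, "raw", n = hlen))
  Encoding(json) <- "UTF-8"
  header <- header_from_json(json)
  data_bytes <- size - 2 - hlen
  if (data_bytes %% 4 != 0) {
    abort(sprintf(
      "truncated data section: %d bytes after byte offset %d is not a multiple of 4",
      data_bytes, 2 + hlen),
      class = "photomux_truncation_error")
  }
  words <- read_u16(con, data_bytes / 2)
  n <- length(words) %/% 2L
  c1 <- unpack_chunk(words[seq_len(n) * 2L - 1L])
  c2 <- unpack_chunk(words[seq_len(n) * 2L])
  photometry_recording(c1$analog, c2$analog, c1$digital, c2$digital, header)
}

#' Write a recording as CSV plus a JSON settings file
#'
#' Each line holds one time point as four comma-separated decimal integers:
#' `analog_1,analog_2,digital_1,digital_2` (raw 15-bit counts, no header
#' row, LF line endings). The acquisition settings are saved as a JSON
#' object in a separate text file. The CSV is roughly 4 times larger than
#' the equivalent binary data section.
#'
#' @param recording A [photometry_recording()].
#' @param path CSV output path.
#' @param settings_path Path for the JSON settings file; default replaces
#'   the extension of `path` with `.json`.
#' @return Invisibly, the number of data lines written.
#' @seealso [read_ppd_csv()]
#' @export
write_ppd_csv <- function(recording, path,
                          settings_path = sub("\\.[^.]*$", ".json", path)) {
  assert_recording(recording)
  lines <- sprintf("%d,%d,%d,%d", recording$analog_1, recording$analog_2,
                   recording$digital_1, recording$digital_2)
  atomic_write(path, function(tmp) {
    con <- file(tmp, "wb") # binary mode: LF endings on every platform
    on.exit(close(con))
    if (length(lines)) writeLines(lines, con, sep = "\n")
  })
  atomic_write(settings_path, function(tmp) {
    writeLines(header_to_json(rec_header(recording)), tmp)
  })
  invisible(length(lines))
}

#' Read a CSV recording and its JSON settings file
#'
#' Exact inverse of [write_ppd_csv()].
#'
#' @param path CSV path.
#' @param settings_path JSON settings path; default as in [write_ppd_csv()].
#' @return A [photometry_recording()].
#' @export
read_ppd_csv <- function(path,
                         settings_path = sub("\\.[^.]*$", ".json", path)) {
  for (p in c(path, settings_path)) {
    if (!file.exists(p)) {
      abort(sprintf("file '%s' does not exist", p),
            class = "photomux_io_error")
    }
  }
  header <- header_from_json(paste(readLines(settings_path, warn = FALSE),
                                   collapse = "\n"))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) {
    return(photometry_recording(header = header))
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) {
    abort(sprintf("line %d has %d fields, expected 4",
                  bad[1], lengths(fields)[bad[1]]),
          class = "photomux_format_error")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 4L, byrow = TRUE)
  bad <- which(apply(m, 1L, function(r) any(is.na(r) | r != trunc(r))))
  if (length(bad)) {
    abort(sprintf("line %d contains a non-integer field", bad[1]),
          class = "photomux_format_error")
  }
  bad <- which(m[, 1] > 32767 | m[, 2] > 32767 | m[, 1] < 0 | m[, 2] < 0)
  if (length(bad)) {
    abort(sprintf("line %d: analog count outside [0, 32767]", bad[1]),
          class = "photomux_range_error")
  }
  bad <- which(!(m[, 3] %in% c(0, 1)) | !(m[, 4] %in% c(0, 1)))
  if (length(bad)) {
    abort(sprintf("line %d: digital value not 0/1", bad[1]),
          class = "photomux_range_error")
  }
  photometry_recording(m[, 1], m[, 2], m[, 3], m[, 4], header)
}
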