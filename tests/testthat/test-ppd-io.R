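test_that("chunk packing and unpacking are mutually inverse over the full 16-bit space", {
  expect_identical(pack_chunk(0, 0), 0L)
  expect_identical(pack_chunk(32767, 1), 65535L)

  analog <- rep(0:32767, each = 2)
  digital <- rep_len(c(0L, 1L), length(analog))
  words <- pack_chunk(analog, digital)
  expect_identical(sort(words), 0:65535) # bijection
  back <- unpack_chunk(words)
  expect_identical(back$analog, analog)
  expect_identical(back$digital, digital)

  # and the other direction
  rt <- unpack_chunk(0:65535)
  expect_identical(pack_chunk(rt$analog, rt$digital), 0:65535)
})

test_that("chunk packing rejects out-of-range inputs", {
  expect_error(pack_chunk(32768, 0), class = "photomux_range_error")
  expect_error(pack_chunk(-1, 0), class = "photomux_range_error")
  expect_error(pack_chunk(10, 2), class = "photomux_range_error")
  expect_error(unpack_chunk(65536), class = "photomux_range_error")
})

test_that("header serializes to JSON and round-trips losslessly, keeping unknown keys", {
  h <- recording_header(subject_id = "m42", sampling_rate = 130,
                        led_currents = c(30, 45), custom_field = "abc")
  h2 <- header_from_json(header_to_json(h))
  expect_equal(h2$subject_id, "m42")
  expect_equal(h2$led_currents, c(30, 45))
  expect_equal(h2$custom_field, "abc")
  expect_equal(unclass(h2)[names(h)], unclass(h)[names(h)])

  expect_error(recording_header(sampling_rate = -1),
               class = "photomux_config_error")
  expect_error(recording_header(led_currents = c(50, 120)),
               class = "photomux_config_error")
  expect_error(header_from_json("{not json"),
               class = "photomux_format_error")
})

test_that("recording container validates its series", {
  expect_error(photometry_recording(analog_1 = 40000, analog_2 = 0,
                                    digital_1 = 0, digital_2 = 0),
               class = "photomux_range_error")
  expect_error(photometry_recording(analog_1 = c(1, 2), analog_2 = 1,
                                    digital_1 = c(0, 0), digital_2 = c(0, 0)),
               class = "photomux_range_error")
  empty <- photometry_recording()
  expect_identical(nrow(empty), 0L)
})

test_that(".ppd round trip is lossless and the data section is 4 bytes per time point", {
  for (n in c(0L, 1L, 997L)) {
    rec <- random_recording(n, seed = n + 1)
    path <- withr_tempfile(".ppd")
    bytes <- write_ppd(rec, path)
    expect_identical(ppd_data_bytes(rec), 4L * n)
    expect_identical(as.integer(file.info(path)$size), bytes)
    rec2 <- read_ppd(path)
    expect_identical(rec2$analog_1, rec$analog_1)
    expect_identical(rec2$analog_2, rec$analog_2)
    expect_identical(rec2$digital_1, rec$digital_1)
    expect_identical(rec2$digital_2, rec$digital_2)
    h2 <- rec_header(rec2)
    expect_equal(h2$extra_key, "kept") # forward-compatible extras
    expect_equal(h2$sampling_rate, rec_header(rec)$sampling_rate)
  }
})

test_that("a file truncated mid-chunk raises a truncation error naming the offset", {
  rec <- random_recording(10)
  path <- withr_tempfile(".ppd")
  write_ppd(rec, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw[1:(length(raw) - 1)], path)
  err <- expect_error(read_ppd(path), class = "photomux_truncation_error")
  expect_match(conditionMessage(err), "offset")
  # corrupt header JSON
  hlen <- as.integer(raw[1]) + 256L * as.integer(raw[2])
  raw2 <- raw
  raw2[3:(2 + hlen)] <- as.raw(0x7b)
  writeBin(raw2, path)
  expect_error(read_ppd(path), class = "photomux_format_error")
})

test_that("CSV export formats one line per time point and round-trips", {
  rec <- photometry_recording(100L, 200L, 0L, 1L)
  path <- withr_tempfile(".csv")
  n_lines <- write_ppd_csv(rec, path)
  expect_identical(n_lines, 1L)
  expect_identical(readLines(path), "100,200,0,1")
  expect_true(file.exists(sub("\\.csv$", ".json", path)))

  rec <- random_recording(512)
  path <- withr_tempfile(".csv")
  write_ppd_csv(rec, path)
  rec2 <- read_ppd_csv(path)
  expect_identical(rec2$analog_1, rec$analog_1)
  expect_identical(rec2$analog_2, rec$analog_2)
  expect_identical(rec2$digital_1, rec$digital_1)
  expect_identical(rec2$digital_2, rec$digital_2)
})

test_that("CSV reader reports malformed lines with their line number", {
  path <- withr_tempfile(".csv")
  settings <- sub("\\.csv$", ".json", path)
  writeLines(header_to_json(recording_header()), settings)

  writeLines(c("1,2,0,0", "1,2,0"), path)
  err <- expect_error(read_ppd_csv(path), class = "photomux_format_error")
  expect_match(conditionMessage(err), "line 2")

  writeLines(c("1,2,0,0", "1,x,0,1"), path)
  err <- expect_error(read_ppd_csv(path), class = "photomux_format_error")
  expect_match(conditionMessage(err), "line 2")

  writeLines(c("1,40000,0,0"), path)
  expect_error(read_ppd_csv(path), class = "photomux_range_error")
})

test_that("CSV is about four times larger than the binary data section", {
  # one minute at 130 Hz, counts uniform over the full 15-bit range
  rec <- random_recording(60 * 130, seed = 7)
  ppd <- withr_tempfile(".ppd")
  csv <- withr_tempfile(".csv")
  write_ppd(rec, ppd)
  write_ppd_csv(rec, csv)
  ratio <- file.info(csv)$size / ppd_data_bytes(rec)
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.5)
})
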