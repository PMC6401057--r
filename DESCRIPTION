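Package: photomux
Title: Time-Division Multiplexed Fiber Photometry: Acquisition Emulation
    and Signal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for time-division multiplexed fiber photometry
    acquisition and analysis. Implements the compact .ppd binary recording
    format (15-bit analog counts plus digital events packed in 16-bit
    chunks behind a JSON header) and its CSV companion; a desk-scale
    emulator of an acquisition board that alternates LED excitation pulses
    with oversampled, baseline-subtracted ADC reads; offline lock-in
    amplification for sinusoidally modulated excitation; numerical
    evaluation of the normalized overlap noise that limits the bandwidth
    of frequency-division multiplexing; and post-acquisition utilities
    (recency-weighted event-triggered averaging, zero-phase photometry
    filtering, sync-pulse clock alignment, coefficient-of-variation noise
    metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
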