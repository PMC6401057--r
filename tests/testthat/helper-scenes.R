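# Shared fixtures, all built in code.

# Two detectors, each dominated by its own LED (a 2-colour bench scene).
two_colour_scene <- function(noise_sd = 0, ambient = 0) {
  fluorescent_scene(
    responsivity = matrix(c(0.02, 0, 0, 0.02), 2, 2),
    ambient = ambient,
    noise_sd_additive = noise_sd
  )
}

# Single detector that sees both LEDs (used for crosstalk checks).
shared_detector_scene <- function(r1 = 0.02, r2 = 0.02, ambient = 0,
                                  noise_sd = 0) {
  fluorescent_scene(
    responsivity = matrix(c(r1, r2), 1, 2),
    ambient = ambient,
    noise_sd_additive = noise_sd
  )
}

# A random but valid recording for round-trip tests.
random_recording <- function(n, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    photometry_recording(
      analog_1 = sample.int(32768, n, replace = TRUE) - 1L,
      analog_2 = sample.int(32768, n, replace = TRUE) - 1L,
      digital_1 = sample(0:1, n, replace = TRUE),
      digital_2 = sample(0:1, n, replace = TRUE),
      header = recording_header(subject_id = "fixture", extra_key = "kept")
    )
  })
}

withr_tempfile <- function(ext) withr::local_tempfile(fileext = ext,
                                                      .local_envir = parent.frame())
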