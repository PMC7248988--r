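# Synthetic session generator and spectral utilities.

test_that("simulated sessions have the full suite at the right length", {
  rec <- simulate_session(generator_config(seed = 3), profile_ramp(60), 60)
  expect_s3_class(rec, "mf_recording")
  expect_equal(nrow(rec$data), 60 * 128)   # 7680 samples per channel
  expect_equal(ncol(rec$data), 17)
  expect_setequal(unique(rec$channels$modality),
                  c("ecg", "emg", "temperature", "eye", "eeg"))
  expect_setequal(rec$channels$name[rec$channels$modality == "eeg"],
                  c("AF3", "F3", "O1", "O2", "F4", "AF4"))
})

test_that("identical generator configuration reproduces bit-identical data", {
  cfg <- generator_config(seed = 42)
  r1 <- simulate_session(cfg, profile_step(30), 30)
  r2 <- simulate_session(cfg, profile_step(30), 30)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_session(generator_config(seed = 43), profile_step(30), 30)
  expect_false(identical(r1$data, r3$data))
})

test_that("generator rejects short sessions and malformed profiles", {
  cfg <- generator_config(seed = 1)
  expect_error(simulate_session(cfg, profile_ramp(5), 5), "too short")
  expect_error(fatigue_profile(c(0, 10), c(0, 1.5)), "invalid fatigue profile")
  expect_error(fatigue_profile(c(5, 10), c(0, 1)), "invalid fatigue profile")
  expect_error(fatigue_profile(c(0, 10, 10), c(0, 1, 1)),
               "invalid fatigue profile")
  # profile must span the session
  expect_error(simulate_session(cfg, profile_ramp(30), 60),
               "invalid fatigue profile")
})

test_that("band_power concentrates on the right band", {
  rate <- 128
  t <- (0:(8 * rate - 1)) / rate
  x <- sin(2 * pi * 10 * t)
  expect_gt(band_power(x, rate, c(8, 13)),
            10 * band_power(x, rate, c(13, 30)))
  expect_equal(band_power(numeric(8 * rate), rate, c(8, 13)), 0)
  expect_error(band_power(x, rate, c(13, 70)), "band out of range")
  expect_error(band_power(x[1:100], rate, c(8, 13)), "at least 2 s")
})

test_that("white-noise band power is proportional to bandwidth", {
  x <- mfsense:::with_seed(7, stats::rnorm(2^15))
  ratio <- band_power(x, 128, c(13, 30)) / band_power(x, 128, c(8, 13))
  expect_gt(ratio, (17 / 5) * 0.7)
  expect_lt(ratio, (17 / 5) * 1.3)
})

test_that("a doubled alpha endpoint raises alpha power in the fatigued half", {
  amps_lo <- c(delta = 20, theta = 10, alpha = 10, beta = 5)
  amps_hi <- c(delta = 20, theta = 10, alpha = 20, beta = 5)
  cfg <- generator_config(eeg_band_amplitudes_low = amps_lo,
                          eeg_band_amplitudes_high = amps_hi, seed = 5)
  rec <- simulate_session(cfg, profile_step(120), 120)
  eeg <- rec$channels$name[rec$channels$modality == "eeg"]
  half <- nrow(rec$data) / 2
  for (ch in eeg) {
    p1 <- band_power(rec$data[1:half, ch], 128, c(8, 13))
    p2 <- band_power(rec$data[(half + 1):nrow(rec$data), ch], 128, c(8, 13))
    expect_gt(p2, p1)
  }
})

test_that("zero effect size leaves head and tail band powers indistinguishable", {
  amps <- c(delta = 20, theta = 10, alpha = 10, beta = 5)
  for (seed in c(21, 22, 23)) {
    cfg <- generator_config(eeg_band_amplitudes_low = amps,
                            eeg_band_amplitudes_high = amps, seed = seed)
    rec <- simulate_session(cfg, profile_step(126), 126)
    # per-6s-window alpha power in the first vs last third, per channel
    segs <- segment(rec, window_spec(), case_config(3))
    bp <- segment_alpha_power(segs)
    n <- length(bp)
    third <- floor(n / 3)
    p <- stats::t.test(bp[1:third], bp[(n - third + 1):n])$p.value
    expect_gt(p, 0.01)
  }
})

test_that("alpha power is monotone over a staircase profile (seed majority)", {
  amps_lo <- c(delta = 20, theta = 10, alpha = 10, beta = 5)
  amps_hi <- c(delta = 20, theta = 10, alpha = 20, beta = 5)
  hits <- 0L
  for (seed in 1:20) {
    cfg <- generator_config(eeg_band_amplitudes_low = amps_lo,
                            eeg_band_amplitudes_high = amps_hi, seed = seed)
    prof <- fatigue_profile(c(0, 20, 20.01, 40, 40.01, 60),
                            c(0, 0, 0.5, 0.5, 1, 1))
    rec <- simulate_session(cfg, prof, 60)
    eeg <- rec$channels$name[rec$channels$modality == "eeg"]
    step_power <- vapply(1:3, function(s) {
      idx <- ((s - 1) * 20 * 128 + 1):(s * 20 * 128)
      mean(vapply(eeg, function(ch)
        band_power(rec$data[idx, ch], 128, c(8, 13)), 0))
    }, 0)
    if (!is.unsorted(step_power)) hits <- hits + 1L
  }
  expect_gt(hits, 10L)
})

test_that("recordings round-trip losslessly through the text dialect", {
  rec <- simulate_session(generator_config(seed = 9), profile_ramp(10), 10,
                          session_meta = list(subject_id = "S07",
                                              kss_pre = 3, kss_post = 6))
  path <- file.path(tempdir(), "rt.csv")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$data, rec$data)
  expect_equal(back$channels, rec$channels)
  expect_equal(back$rate, rec$rate)
  expect_equal(back$session_meta$kss_post, 6)
})

test_that("malformed recording files produce named errors", {
  path <- file.path(tempdir(), "bad.csv")
  on.exit(unlink(path), add = TRUE)
  writeLines(c("# mfsense-recording v1", "# rate: 128",
               "# channel: A ecg mV 128", "# channel: B emg mV 128",
               "A,B", "1,2", "3,"), path)
  expect_error(read_recording(path), "B")
  writeLines(character(0), path)
  expect_error(read_recording(path), "no channels found")
  writeLines(c("# mfsense-recording v1", "# rate: 128",
               "# channel: A sweat mV 128", "A", "1"), path)
  expect_error(read_recording(path), "unknown modality")
})

test_that("KSS scores outside 1..9 are rejected at construction", {
  data <- matrix(0, 128 * 6, 1, dimnames = list(NULL, "ECG"))
  ch <- data.frame(name = "ECG", modality = "ecg", units = "mV",
                   native_rate = 128)
  expect_error(mf_recording(data, ch, session_meta = list(kss_pre = 0)),
               "\\[1, 9\\]")
  expect_error(mf_recording(data, ch, session_meta = list(kss_post = 9.5)),
               "\\[1, 9\\]")
  expect_silent(mf_recording(data, ch, session_meta = list(kss_pre = 9)))
})
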