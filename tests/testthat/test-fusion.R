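# Resampling, sliding-window segmentation and normalization.

test_that("window_spec derives step and segment size", {
  w <- window_spec()
  expect_equal(w$step_s, 4)
  expect_equal(w$samples_per_segment, 768L)
  expect_error(window_spec(length_s = 6, overlap_s = 6), "overlap_s")
  expect_error(window_spec(length_s = 6, overlap_s = -1), "overlap_s")
})

test_that("resampling is an identity at the native rate and preserves constants", {
  rec <- make_flat_recording(10)
  expect_identical(resample(rec, 128), rec)
  const <- rec
  const$data[, 1] <- 3.7
  up <- resample(const, 200)
  expect_true(all(abs(up$data - 3.7) < 1e-12))
  expect_equal(nrow(up$data), 2000)
  expect_error(resample(rec, -1), "positive")
})

test_that("linear resampling tracks a below-Nyquist sinusoid", {
  t64 <- (0:(64 * 10 - 1)) / 64
  data <- matrix(sin(2 * pi * 4 * t64), ncol = 1,
                 dimnames = list(NULL, "ECG"))
  ch <- data.frame(name = "ECG", modality = "ecg", units = "mV",
                   native_rate = 64)
  rec <- mf_recording(data, ch, rate = 64)
  up <- resample(rec, 128)
  t128 <- (0:(nrow(up$data) - 1)) / 128
  expect_lt(max(abs(up$data[, 1] - sin(2 * pi * 4 * t128))), 0.05)
})

test_that("segment counts follow the floor rule", {
  # 22 s -> 5 segments at 0, 4, 8, 12, 16 s
  segs <- segment(make_flat_recording(22), window_spec(),
                  case_config(1))
  expect_equal(dim(segs$segments)[3], 5L)
  expect_equal(segs$start_times, c(0, 4, 8, 12, 16))
  # boundary: exactly one window
  expect_equal(dim(segment(make_flat_recording(6), window_spec(),
                           case_config(1))$segments)[3], 1L)
  expect_error(segment(make_flat_recording(5.9)), "too short")
  expect_error(segment(make_flat_recording(10),
                       window_spec(rate = 64)), "does not match")
})

test_that("a 60 s Case-3 session gives 14 segments of 6 x 768", {
  rec <- simulate_session(generator_config(seed = 2), profile_ramp(60), 60)
  segs <- segment(rec, window_spec(), case_config(3))
  expect_equal(dim(segs$segments), c(6L, 768L, 14L))
  expect_equal(segs$channel_order, c("AF3", "F3", "O1", "O2", "F4", "AF4"))
})

test_that("consecutive segments share exactly the 256 overlap columns", {
  rec <- simulate_session(generator_config(seed = 2), profile_ramp(30), 30)
  segs <- segment(rec, window_spec(), case_config(4))
  n <- dim(segs$segments)[3]
  for (k in seq_len(n - 1)) {
    expect_identical(segs$segments[, 513:768, k],
                     segs$segments[, 1:256, k + 1])
  }
  # and the overlap equals the source recording slice
  expect_equal(segs$segments[, 513:768, 1],
               t(rec$data[513:768, segs$channel_order]))
})

test_that("case channel subsets are 3 + 8 + 6 and Case 4 is their union", {
  rec <- simulate_session(generator_config(seed = 2), profile_ramp(10), 10)
  rows <- vapply(1:4, function(cid)
    dim(segment(rec, window_spec(), case_config(cid))$segments)[1], 0L)
  expect_equal(rows, c(3L, 8L, 6L, 17L))
  expect_equal(rows[4], sum(rows[1:3]))
  # segment count invariant to channel subset
  counts <- vapply(1:4, function(cid)
    dim(segment(rec, window_spec(), case_config(cid))$segments)[3], 0L)
  expect_equal(length(unique(counts)), 1L)
})

test_that("requesting channels missing from the recording names them", {
  rec <- make_flat_recording(10)   # ECG only
  expect_error(segment(rec, window_spec(), case_config(3)), "no channels")
})

test_that("normalizer zero-centres and unit-scales its own fit set", {
  rec <- simulate_session(generator_config(seed = 4), profile_ramp(30), 30)
  segs <- segment(rec, window_spec(), case_config(4))
  norm <- fit_normalizer(segs)
  nseg <- apply_normalizer(segs, norm)
  flat <- matrix(nseg$segments, nrow = dim(nseg$segments)[1])
  expect_true(all(abs(rowMeans(flat)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(flat^2)) - 1) < 1e-6))
})

test_that("constant channels normalize to zero via the sd floor", {
  segs <- make_dummy_segments(4)
  segs$segments[1, , ] <- 5
  norm <- fit_normalizer(segs)
  out <- apply_normalizer(segs, norm)
  expect_true(all(out$segments[1, , ] == 0))
})

test_that("normalization of shifted data is the expected affine map", {
  segs <- make_dummy_segments(6, seed = 8)
  norm <- fit_normalizer(segs)
  shifted <- segs
  shifted$segments <- segs$segments + 2.5
  a <- apply_normalizer(segs, norm)
  b <- apply_normalizer(shifted, norm)
  expect_equal(b$segments, a$segments + 2.5 / norm$sd, tolerance = 1e-12)
  empty <- mfsense:::subset_segments(segs, integer(0))
  expect_error(fit_normalizer(empty), "empty training set")
})

test_that("refitting the normalizer on rescaled data gives identical segments", {
  segs <- make_dummy_segments(5, seed = 3)
  scaled <- segs
  scaled$segments <- segs$segments * 7
  a <- apply_normalizer(segs, fit_normalizer(segs))
  b <- apply_normalizer(scaled, fit_normalizer(scaled))
  expect_equal(a$segments, b$segments, tolerance = 1e-9)
})
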