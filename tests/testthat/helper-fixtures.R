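# Shared fixtures: all data is generated in code at test time.

# brute-force triple-loop implementation of the valid temporal
# convolution summed over channel depth: the independent oracle for
# conv_forward
conv_oracle <- function(x, w, b = numeric(dim(w)[1])) {
  nf <- dim(w)[1]; nc <- dim(w)[2]; k <- dim(w)[3]
  lo <- ncol(x) - k + 1L
  out <- matrix(0, nf, lo)
  for (f in seq_len(nf))
    for (j in seq_len(lo)) {
      s <- b[f]
      for (cc in seq_len(nc))
        for (kk in seq_len(k))
          s <- s + w[f, cc, kk] * x[cc, j + kk - 1L]
      out[f, j] <- s
    }
  out
}

# an mf_cnn object with freshly initialized (untrained) weights, for
# tests that only need a deterministic forward pass
make_random_model <- function(spec, seed = 1, classes = c("low", "high")) {
  w <- mfsense:::with_seed(seed, mfsense:::init_weights(spec))
  structure(list(spec = spec, weights = w, classes = classes,
                 history = data.frame(), best_epoch = 0L,
                 best_val_acc = NA_real_, control = train_config(),
                 n_train = 0L),
            class = "mf_cnn")
}

# minimal fused_segments object with n random segments (for labeling and
# smoothing arithmetic that only depends on segment count/order)
make_dummy_segments <- function(n, n_ch = 2, spw = 16, seed = 1) {
  arr <- mfsense:::with_seed(seed,
    array(stats::rnorm(n_ch * spw * n), dim = c(n_ch, spw, n)))
  dimnames(arr) <- list(paste0("ch", seq_len(n_ch)), NULL, NULL)
  structure(list(segments = arr,
                 start_times = (seq_len(n) - 1) * 4,
                 channel_order = paste0("ch", seq_len(n_ch)),
                 window = window_spec(),
                 case_id = 4L, labels = NULL, scale = NULL),
            class = "fused_segments")
}

# single-channel recording of a given duration (cheap to build for
# segmentation arithmetic over many durations)
make_flat_recording <- function(duration, rate = 128, value = 0) {
  n <- round(duration * rate)
  data <- matrix(seq_len(n) + value, n, 1, dimnames = list(NULL, "ECG"))
  ch <- data.frame(name = "ECG", modality = "ecg", units = "mV",
                   native_rate = rate)
  mf_recording(data, ch, rate = rate)
}

# mean alpha-band power over the EEG channels of each segment
segment_alpha_power <- function(segs, rate = 128) {
  eeg <- intersect(segs$channel_order,
                   c("AF3", "F3", "O1", "O2", "F4", "AF4"))
  vapply(seq_len(dim(segs$segments)[3]), function(i)
    mean(vapply(eeg, function(ch)
      band_power(segs$segments[ch, , i], rate, c(8, 13)), 0)), 0)
}

# independent band-power threshold classifier: midpoint between the
# labeled class means of mean alpha power; returns its accuracy on the
# labeled segments
band_power_classifier_accuracy <- function(segs) {
  lab <- mfsense:::labeled_subset(segs)
  bp <- segment_alpha_power(lab)
  thr <- mean(c(mean(bp[lab$labels == "low"]),
                mean(bp[lab$labels == "high"])))
  mean((bp > thr) == (lab$labels == "high"))
}

# demo session pair + trained model, built once and reused across
# acceptance blocks (training is the expensive step)
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_session <- function(seed) {
  rec <- simulate_session(generator_config(seed = seed), profile_step(600),
                          600,
                          session_meta = list(subject_id = "S01",
                                              kss_pre = 2, kss_post = 4))
  segs <- segment(rec, window_spec(), case_config(3))
  assign_labels(segs, derive_scale(kss_report("S01", 2, 4)))
}

acceptance_fixture <- function() {
  if (!is.null(.acceptance_cache$fix)) return(.acceptance_cache$fix)
  rec <- simulate_session(generator_config(seed = 11), profile_step(600),
                          600,
                          session_meta = list(subject_id = "S01",
                                              kss_pre = 2, kss_post = 4))
  segs <- combine_segments(acceptance_session(11), acceptance_session(12))
  cv <- train_cv(segs, control = demo_train_config(folds = 5, seed = 1))
  .acceptance_cache$fix <- list(rec = rec, segs = segs, cv = cv)
  .acceptance_cache$fix
}
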