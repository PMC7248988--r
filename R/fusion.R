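# Raw-level fusion: common clock, channel selection (Cases 1-4), sliding
# window segmentation into the 2D CNN input, per-channel normalization.

#' Sliding-window specification
#'
#' Windows are half-open `[start, start + length_s)` on the common clock;
#' consecutive windows overlap by `overlap_s`, so the step is
#' `length_s - overlap_s`.
#'
#' @param length_s Window length in seconds (default 6).
#' @param overlap_s Overlap between consecutive windows, `0 <= overlap_s <
#'   length_s` (default 2).
#' @param rate Common sampling rate in Hz (default 128).
#' @return A `window_spec` with derived `step_s` and
#'   `samples_per_segment = length_s * rate` (768 at the defaults).
#' @export
window_spec <- function(length_s = 6, overlap_s = 2, rate = 128) {
  stopifnot(is_scalar_num(length_s), length_s > 0,
            is_scalar_num(overlap_s), is_scalar_num(rate), rate > 0)
  if (overlap_s < 0 || overlap_s >= length_s)
    stop("need 0 <= overlap_s < length_s", call. = FALSE)
  structure(list(
    length_s = length_s, overlap_s = overlap_s,
    step_s = length_s - overlap_s, rate = rate,
    samples_per_segment = as.integer(round(length_s * rate))
  ), class = "window_spec")
}

#' Sensor-configuration cases
#'
#' Case 1 = \{ECG, EMG, temperature\}; Case 2 = eye tracker (3-DOF
#' accelerometer, 3-DOF gyroscope, both pupil diameters); Case 3 = the six
#' EEG channels; Case 4 = all available sensors.
#'
#' @param case_id Integer 1-4.
#' @return A `case_config`.
#' @export
case_config <- function(case_id) {
  if (!is_count(case_id) || !(case_id %in% 1:4))
    stop("case_id must be 1, 2, 3 or 4", call. = FALSE)
  modalities <- switch(case_id,
                       c("ecg", "emg", "temperature"),
                       "eye",
                       "eeg",
                       MODALITIES)
  structure(list(case_id = as.integer(case_id), modalities = modalities),
            class = "case_config")
}

# channel names selected by a case, in the canonical fusion row order
# (ECG, EMG, temperature, eye block, EEG block; recording order within a
# block)
case_channel_names <- function(case, channels) {
  stopifnot(inherits(case, "case_config"))
  sel <- channels[channels$modality %in% case$modalities, , drop = FALSE]
  sel <- sel[order(match(sel$modality, MODALITY_ORDER)), , drop = FALSE]
  sel$name
}

#' Resample a recording to a target common rate
#'
#' Linear interpolation over the original sample timestamps; the duration
#' is preserved to within one sample period.  No anti-alias filter is
#' applied: intended for signals whose content is below the target Nyquist
#' frequency.
#'
#' @param recording An [mf_recording()].
#' @param target_rate Target rate in Hz.
#' @return An [mf_recording()] at `target_rate`.
#' @export
resample <- function(recording, target_rate) {
  stopifnot(inherits(recording, "mf_recording"))
  if (!is_scalar_num(target_rate) || target_rate <= 0)
    stop("target rate must be positive", call. = FALSE)
  n_old <- nrow(recording$data)
  if (n_old < 2) stop("every channel needs at least 2 samples", call. = FALSE)
  if (target_rate == recording$rate) return(recording)
  # pad one linearly-extrapolated sample so target grids that extend
  # past the last source timestamp keep the local slope rather than
  # flattening out
  t_old <- (seq_len(n_old + 1) - 1) / recording$rate
  n_new <- round(recording$duration * target_rate)
  t_new <- (seq_len(n_new) - 1) / target_rate
  data <- vapply(seq_len(ncol(recording$data)), function(j) {
    y <- recording$data[, j]
    y <- c(y, 2 * y[n_old] - y[n_old - 1])
    stats::approx(t_old, y, xout = t_new, rule = 2)$y
  }, numeric(n_new))
  colnames(data) <- colnames(recording$data)
  channels <- recording$channels
  mf_recording(data, channels, rate = target_rate,
               session_meta = recording$session_meta)
}

#' Cut a recording into fused 2D segments
#'
#' Applies the sliding window to the case-selected channels and stacks
#' them into channels-by-samples matrices (the CNN input).  Segments start
#' at `0, step_s, 2 step_s, ...`; the count is
#' `floor((duration - length_s) / step_s) + 1` and trailing partial
#' windows are dropped.
#'
#' @param recording An [mf_recording()].
#' @param window A [window_spec()]; its rate must match the recording.
#' @param case A [case_config()] selecting the channel subset.
#' @return A `fused_segments` object: a `channels x samples x n_segments`
#'   array plus start times, channel order and window/case metadata.
#' @export
segment <- function(recording, window = window_spec(rate = recording$rate),
                    case = case_config(4)) {
  stopifnot(inherits(recording, "mf_recording"),
            inherits(window, "window_spec"))
  if (abs(window$rate - recording$rate) > 1e-9)
    stop("window rate (", window$rate, ") does not match recording rate (",
         recording$rate, ")", call. = FALSE)
  if (recording$duration < window$length_s)
    stop("recording too short to segment (< ", window$length_s, " s)",
         call. = FALSE)
  sel <- case_channel_names(case, recording$channels)
  missing <- setdiff(sel, colnames(recording$data))
  if (length(missing))
    stop("missing requested channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!length(sel))
    stop("case ", case$case_id, " selects no channels in this recording",
         call. = FALSE)
  spw <- window$samples_per_segment
  step <- as.integer(round(window$step_s * window$rate))
  n <- nrow(recording$data)
  n_seg <- (n - spw) %/% step + 1L
  segs <- array(0, dim = c(length(sel), spw, n_seg),
                dimnames = list(sel, NULL, NULL))
  for (s in seq_len(n_seg)) {
    idx <- (s - 1L) * step + seq_len(spw)
    segs[, , s] <- t(recording$data[idx, sel, drop = FALSE])
  }
  structure(list(
    segments = segs,
    start_times = (seq_len(n_seg) - 1) * window$step_s,
    channel_order = sel,
    window = window,
    case_id = case$case_id,
    labels = NULL,
    scale = NULL
  ), class = "fused_segments")
}

#' @export
print.fused_segments <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf("<fused_segments> %d segments of %d channels x %d samples (case %d)\n",
              d[3], d[1], d[2], x$case_id))
  if (!is.null(x$labels))
    cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                   table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

n_segments <- function(x) dim(x$segments)[3]

# subset segments by index, preserving metadata
subset_segments <- function(x, idx) {
  out <- x
  out$segments <- x$segments[, , idx, drop = FALSE]
  out$start_times <- x$start_times[idx]
  if (!is.null(x$labels)) out$labels <- x$labels[idx]
  out
}

#' Pool fused segments from several sessions
#'
#' Concatenates segment sets with identical channel order, window and
#' case along the segment axis, offsetting start times so sessions
#' follow one another.  Labels are concatenated when every input is
#' labeled.  Used to pool labeled windows from a pair (or more) of
#' recorded sessions of one subject.
#'
#' @param ... Two or more `fused_segments` objects.
#' @return A single `fused_segments` object.
#' @export
combine_segments <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 2L,
            all(vapply(parts, inherits, TRUE, "fused_segments")))
  first <- parts[[1]]
  for (p in parts[-1]) {
    if (!identical(p$channel_order, first$channel_order) ||
        !identical(p$case_id, first$case_id) ||
        !identical(unclass(p$window), unclass(first$window)))
      stop("segment sets differ in channels, case or window",
           call. = FALSE)
  }
  n_each <- vapply(parts, n_segments, 0L)
  d <- dim(first$segments)
  out <- first
  out$segments <- array(unlist(lapply(parts, `[[`, "segments")),
                        dim = c(d[1], d[2], sum(n_each)),
                        dimnames = list(first$channel_order, NULL, NULL))
  offs <- cumsum(c(0, vapply(parts, function(p)
    max(p$start_times) + p$window$length_s, 0)))
  out$start_times <- unlist(lapply(seq_along(parts), function(i)
    parts[[i]]$start_times + offs[i]))
  labs <- lapply(parts, `[[`, "labels")
  out$labels <- if (all(!vapply(labs, is.null, TRUE))) {
    factor(unlist(lapply(labs, as.character)),
           levels = c("low", "unknown", "high"))
  }
  out
}

#' Fit a per-channel normalizer on training segments
#'
#' Computes each channel's mean and standard deviation pooled over all
#' training segments and time points.  Raw-level fusion stacks channels
#' with grossly different physical scales (uV next to degrees C), so
#' per-channel z-scoring is required before the matrices reach the
#' network.  Fit on training data only; apply everywhere.
#'
#' @param training_segments A `fused_segments` object (the training set).
#' @return A `segment_normalizer`: data.frame of channel, mean, sd (sd
#'   floored at 1e-8 so constant channels map to zero).
#' @export
fit_normalizer <- function(training_segments) {
  stopifnot(inherits(training_segments, "fused_segments"))
  segs <- training_segments$segments
  if (!length(segs) || dim(segs)[3] == 0L)
    stop("empty training set", call. = FALSE)
  d <- dim(segs)
  flat <- matrix(segs, nrow = d[1])   # channels x (samples * segments)
  m <- rowMeans(flat)
  s <- sqrt(rowMeans((flat - m)^2))
  s <- pmax(s, 1e-8)
  structure(data.frame(channel = training_segments$channel_order,
                       mean = m, sd = s),
            class = c("segment_normalizer", "data.frame"))
}

#' Apply a fitted normalizer to segments
#'
#' @param segments A `fused_segments` object.
#' @param normalizer A [fit_normalizer()] result with matching channels.
#' @return `segments` with each channel row centred and scaled by the
#'   training statistics.
#' @export
apply_normalizer <- function(segments, normalizer) {
  stopifnot(inherits(segments, "fused_segments"),
            inherits(normalizer, "segment_normalizer"))
  if (!identical(segments$channel_order, normalizer$channel))
    stop("normalizer channels do not match segment channel order",
         call. = FALSE)
  out <- segments
  out$segments <- (segments$segments - normalizer$mean) / normalizer$sd
  out
}
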