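# Streaming mental-fatigue assessment: every step (4 s at the default
# window), classify the latest fused 6 s segment and smooth the
# classification outputs over a trailing window of 5 steps, so
# intermediate (transition) MF levels emerge between the two trained
# boundary classes.

# trailing moving average over the last `k` values; during warm-up
# (fewer than k values so far) the mean runs over what is available
trailing_mean <- function(values, k) {
  vapply(seq_along(values), function(s)
    mean(values[max(1L, s - k + 1L):s]), 0)
}

#' Run the streaming MF assessment loop over a recording
#'
#' Replays the recording through the sliding window: at each step
#' `t = 6, 10, 14, ...` s the 6 s window ending at `t` is fused,
#' normalized and classified, and the MF level is the mean over the last
#' `min(window_steps, steps so far)` steps of either the high-class
#' indicator (`smooth = "class"`, the default: the argmax mapped to 0/1)
#' or the high-class softmax probability (`smooth = "probs"`).  The
#' resulting trace is bounded in `[0, 1]` by construction and, once
#' `window_steps` steps have elapsed with class smoothing, cannot jump by
#' more than `1/window_steps` per step.
#'
#' @param model A fitted [mf_cnn()] whose input shape matches the case
#'   channels.
#' @param recording An [mf_recording()] of at least one window length.
#' @param case A [case_config()].
#' @param normalizer The training-set [fit_normalizer()] statistics.
#' @param window A [window_spec()].
#' @param smooth `"class"` or `"probs"`.
#' @param window_steps Trailing smoothing window length in steps
#'   (default 5).
#' @return An `mf_trace`: step times (segment end, seconds), smoothed
#'   levels, raw per-step probabilities and classes.
#' @export
assess_stream <- function(model, recording, case, normalizer,
                          window = window_spec(rate = recording$rate),
                          smooth = c("class", "probs"),
                          window_steps = 5L) {
  smooth <- match.arg(smooth)
  stopifnot(inherits(model, "mf_cnn"), is_count(window_steps))
  segs <- segment(recording, window, case)   # errors if too short
  if (dim(segs$segments)[1] != model$spec$n_channels)
    stop("case selects ", dim(segs$segments)[1],
         " channels but the model expects ", model$spec$n_channels,
         call. = FALSE)
  segs <- apply_normalizer(segs, normalizer)
  probs <- predict(model, segs, type = "prob")
  hi_col <- ncol(probs)                      # classes ordered low..high
  raw_class <- max.col(probs, ties.method = "first") - 1L
  value <- if (smooth == "class") as.numeric(raw_class == hi_col - 1L)
           else probs[, hi_col]
  levels <- trailing_mean(value, window_steps)
  structure(list(
    times = segs$start_times + window$length_s,
    levels = levels,
    raw_probs = probs,
    raw_class = raw_class,
    window_steps = as.integer(window_steps),
    smooth = smooth,
    case_id = case$case_id
  ), class = "mf_trace")
}

#' @export
print.mf_trace <- function(x, ...) {
  cat(sprintf("<mf_trace> %d steps over %.0f s (case %d, smoothing %d steps, %s)\n",
              length(x$times), max(x$times), x$case_id, x$window_steps,
              x$smooth))
  cat(sprintf("  level range [%.2f, %.2f]\n", min(x$levels), max(x$levels)))
  invisible(x)
}

#' @export
as.data.frame.mf_trace <- function(x, ...) {
  data.frame(time = x$times, level = x$levels)
}

#' Plot an MF trace
#'
#' Time on the horizontal axis (seconds), smoothed MF level on the
#' vertical.  `train_marks = c(t_low_end, t_high_start)` draws the
#' conventional markers: a green dashed line at the end of the low-MF
#' training region and a red dashed line at the start of the high-MF
#' region.
#'
#' @param x An `mf_trace`.
#' @param train_marks Optional numeric length-2 vector of times in
#'   seconds.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mf_trace <- function(x, train_marks = NULL, ...) {
  graphics::plot(x$times, x$levels, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "time (s)", ylab = "MF level", ...)
  if (!is.null(train_marks)) {
    graphics::abline(v = train_marks[1], lty = 2, col = "darkgreen")
    graphics::abline(v = train_marks[2], lty = 2, col = "red")
  }
  invisible(x)
}
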