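# KSS-derived mental-fatigue scale and boundary labeling of a session's
# head and tail segments.

#' Pre/post-session KSS questionnaire report
#'
#' @param subject_id Subject identifier.
#' @param kss_pre,kss_post Karolinska Sleepiness Scale scores (integers
#'   1-9) reported before and after the session.
#' @return A `kss_report`.
#' @export
kss_report <- function(subject_id, kss_pre, kss_post) {
  for (v in list(kss_pre, kss_post))
    if (!is_scalar_num(v) || v != round(v) || v < 1 || v > 9)
      stop("KSS scores must be integers in [1, 9]", call. = FALSE)
  structure(list(subject_id = subject_id,
                 kss_pre = as.integer(kss_pre),
                 kss_post = as.integer(kss_post)),
            class = "kss_report")
}

#' Derive a per-participant mental-fatigue scale from KSS scores
#'
#' The participant's lowest reported KSS score defines the low-MF boundary
#' level and the highest the high-MF boundary; any KSS levels strictly
#' between become intermediate transition states.  The numeric map sends
#' the low boundary to 0, the high boundary to 1 and spaces transitions
#' evenly in between.
#'
#' @param report A [kss_report()] with distinct pre/post scores.
#' @return An `mf_scale` with `low_level`, `high_level`,
#'   `transition_levels` and `numeric_map` (named by KSS level).
#' @export
derive_scale <- function(report) {
  stopifnot(inherits(report, "kss_report"))
  if (report$kss_pre == report$kss_post)
    stop("degenerate scale: no MF progression reported", call. = FALSE)
  low <- min(report$kss_pre, report$kss_post)
  high <- max(report$kss_pre, report$kss_post)
  levels <- low:high
  numeric_map <- (levels - low) / (high - low)
  names(numeric_map) <- levels
  structure(list(
    subject_id = report$subject_id,
    low_level = low, high_level = high,
    transition_levels = if (high - low > 1) (low + 1):(high - 1) else integer(0),
    numeric_map = numeric_map
  ), class = "mf_scale")
}

#' @export
print.mf_scale <- function(x, ...) {
  cat(sprintf("<mf_scale> KSS %d (low MF = 0) .. KSS %d (high MF = 1), %d transition state(s)\n",
              x$low_level, x$high_level, length(x$transition_levels)))
  if (length(x$transition_levels))
    cat("  transitions:",
        paste(sprintf("KSS %d -> %.3g", x$transition_levels,
                      x$numeric_map[as.character(x$transition_levels)]),
              collapse = ", "), "\n")
  invisible(x)
}

#' Label the head and tail of a session for training
#'
#' The first `floor(head_frac * N)` segments of a time-ordered session are
#' labeled `low` (the state reported before the session) and the last
#' `floor(tail_frac * N)` are labeled `high`; everything between is
#' `unknown` and is excluded from training, serving only to probe
#' generalization across the transition.
#'
#' @param segments A time-ordered `fused_segments` object.
#' @param scale An [derive_scale()] result attached for provenance.
#' @param head_frac,tail_frac Fractions of the session labeled at each
#'   end (default 0.2 each); must sum to less than 1.
#' @return `segments` with a `labels` factor
#'   (`levels = c("low", "unknown", "high")`) and the scale attached.
#' @export
assign_labels <- function(segments, scale, head_frac = 0.2, tail_frac = 0.2) {
  stopifnot(inherits(segments, "fused_segments"),
            inherits(scale, "mf_scale"))
  if (head_frac + tail_frac >= 1)
    stop("head_frac + tail_frac must be < 1", call. = FALSE)
  if (head_frac < 0 || tail_frac < 0)
    stop("label fractions must be nonnegative", call. = FALSE)
  n <- n_segments(segments)
  if (n < 1) stop("no segments to label", call. = FALSE)
  n_low <- floor(head_frac * n)
  n_high <- floor(tail_frac * n)
  if (n_low < 1 || n_high < 1)
    stop("insufficient segments to label", call. = FALSE)
  lab <- rep("unknown", n)
  lab[seq_len(n_low)] <- "low"
  lab[(n - n_high + 1):n] <- "high"
  out <- segments
  out$labels <- factor(lab, levels = c("low", "unknown", "high"))
  out$scale <- scale
  out
}

# labeled subset (low/high only), with labels as a two-level factor
labeled_subset <- function(segments) {
  stopifnot(!is.null(segments$labels))
  idx <- which(segments$labels != "unknown")
  out <- subset_segments(segments, idx)
  out$labels <- factor(as.character(out$labels), levels = c("low", "high"))
  out
}
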