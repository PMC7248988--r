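# Domain types for multichannel physiological recordings and their
# plain-text serialization.

MODALITIES <- c("ecg", "emg", "temperature", "eeg", "eye")
EEG_CHANNEL_NAMES <- c("AF3", "F3", "O1", "O2", "F4", "AF4")

# canonical channel row order used when fusing: ECG, EMG, temperature,
# eye-tracker block, EEG block
MODALITY_ORDER <- c("ecg", "emg", "temperature", "eye", "eeg")

#' Describe one physiological channel
#'
#' @param name Short unique channel identifier (e.g. `"ECG"`, `"AF3"`).
#' @param modality One of `"ecg"`, `"emg"`, `"temperature"`, `"eeg"`, `"eye"`.
#' @param units Free-text unit label (`"uV"`, `"degC"`, `"mm"`, ...).
#' @param native_rate Native sampling rate of the sensor in Hz.
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(name, modality, units, native_rate = 128) {
  modality <- match.arg(modality, MODALITIES)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is_scalar_num(native_rate) || native_rate <= 0)
    stop("native_rate must be a positive number", call. = FALSE)
  if (modality == "eeg" && !(name %in% EEG_CHANNEL_NAMES))
    stop("EEG channel name must be one of: ",
         paste(EEG_CHANNEL_NAMES, collapse = ", "), call. = FALSE)
  structure(list(name = name, modality = modality, units = units,
                 native_rate = native_rate),
            class = "channel_spec")
}

#' The full 17-channel sensor suite
#'
#' One ECG trace (three-lead sensor), one EMG trace (three-lead sensor),
#' axillary temperature, the eye-tracker block (3-DOF accelerometer, 3-DOF
#' gyroscope, left/right pupil diameter) and six EEG channels
#' (AF3, F3, O1, O2, F4, AF4), in the canonical fusion row order.
#'
#' @param rate Common sampling rate recorded as each channel's native rate.
#' @return A data.frame with columns `name`, `modality`, `units`,
#'   `native_rate`.
#' @export
default_channel_suite <- function(rate = 128) {
  ch <- rbind(
    data.frame(name = "ECG",  modality = "ecg",         units = "mV"),
    data.frame(name = "EMG",  modality = "emg",         units = "mV"),
    data.frame(name = "TEMP", modality = "temperature", units = "degC"),
    data.frame(name = c("ACCX", "ACCY", "ACCZ"), modality = "eye",
               units = "m/s^2"),
    data.frame(name = c("GYRX", "GYRY", "GYRZ"), modality = "eye",
               units = "deg/s"),
    data.frame(name = c("PUPL", "PUPR"), modality = "eye", units = "mm"),
    data.frame(name = EEG_CHANNEL_NAMES, modality = "eeg", units = "uV")
  )
  ch$native_rate <- rate
  ch
}

#' Construct a multichannel recording on a common clock
#'
#' @param data Numeric matrix, samples in rows, one column per channel;
#'   column names must match `channels$name`.
#' @param channels data.frame of channel metadata (`name`, `modality`,
#'   `units`, `native_rate`), e.g. from [default_channel_suite()].
#' @param rate Common sampling rate in Hz (nominal 128).
#' @param session_meta List with optional `subject_id`, `kss_pre`,
#'   `kss_post`; KSS scores, when present, must be integers in 1..9.
#' @return An object of class `mf_recording`.
#' @export
mf_recording <- function(data, channels, rate = 128, session_meta = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric matrix (samples x channels)", call. = FALSE)
  if (!is_scalar_num(rate) || rate <= 0)
    stop("rate must be positive", call. = FALSE)
  channels <- as.data.frame(channels)
  needed <- c("name", "modality", "units", "native_rate")
  if (!all(needed %in% names(channels)))
    stop("channels must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(channels$name))
    stop("channel names must be unique", call. = FALSE)
  bad <- setdiff(channels$modality, MODALITIES)
  if (length(bad))
    stop("unknown modality tag: ", paste(bad, collapse = ", "), call. = FALSE)
  if (ncol(data) != nrow(channels))
    stop("data has ", ncol(data), " columns but ", nrow(channels),
         " channels are described", call. = FALSE)
  if (is.null(colnames(data))) colnames(data) <- channels$name
  if (!identical(colnames(data), channels$name))
    stop("data column names must match channel names in order", call. = FALSE)
  bad_eeg <- channels$name[channels$modality == "eeg" &
                             !(channels$name %in% EEG_CHANNEL_NAMES)]
  if (length(bad_eeg))
    stop("invalid EEG channel name(s): ", paste(bad_eeg, collapse = ", "),
         call. = FALSE)
  for (k in c("kss_pre", "kss_post")) {
    v <- session_meta[[k]]
    if (!is.null(v) && !is.na(v)) {
      if (!is_scalar_num(v) || v != round(v) || v < 1 || v > 9)
        stop(k, " must be an integer in [1, 9]", call. = FALSE)
    }
  }
  structure(list(
    data = data,
    channels = channels,
    rate = rate,
    duration = nrow(data) / rate,
    session_meta = session_meta
  ), class = "mf_recording")
}

#' @export
print.mf_recording <- function(x, ...) {
  cat(sprintf("<mf_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              ncol(x$data), nrow(x$data), x$duration, x$rate))
  tab <- table(x$channels$modality)
  cat("  modalities:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  sm <- x$session_meta
  if (length(sm))
    cat(sprintf("  subject: %s  KSS pre/post: %s/%s\n",
                sm$subject_id %||% "?", sm$kss_pre %||% "?",
                sm$kss_post %||% "?"))
  invisible(x)
}

#' Write a recording to a column-oriented text table
#'
#' The recording is written as a CSV with `#`-prefixed header lines carrying
#' the common rate and per-channel metadata, one column per channel on the
#' common clock.  Session metadata (subject id, KSS scores) goes to a JSON
#' sidecar at `<path>.json`.  Values are written with 17 significant digits
#' so the round trip through [read_recording()] is bit-exact.
#'
#' @param recording An [mf_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "mf_recording"))
  ch <- recording$channels
  hdr <- c(
    "# mfsense-recording v1",
    sprintf("# rate: %.17g", recording$rate),
    sprintf("# channel: %s %s %s %.17g",
            ch$name, ch$modality, ch$units, ch$native_rate)
  )
  writeLines(hdr, path)
  txt <- as.data.frame(
    lapply(seq_len(ncol(recording$data)), function(j)
      formatC(recording$data[, j], digits = 17, format = "g")),
    col.names = ch$name, check.names = FALSE)
  data.table::fwrite(txt, path, append = TRUE, col.names = TRUE,
                     quote = FALSE)
  meta <- recording$session_meta
  jsonlite::write_json(if (length(meta)) meta else structure(list(), names = character()),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV path; the `<path>.json` sidecar is read when present.
#' @return An [mf_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 200L)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(lines) || !length(hdr))
    stop("no channels found", call. = FALSE)
  rate_line <- grep("^# rate:", hdr, value = TRUE)
  if (!length(rate_line)) stop("no channels found", call. = FALSE)
  rate <- as.numeric(sub("^# rate:\\s*", "", rate_line[1]))
  ch_lines <- grep("^# channel:", hdr, value = TRUE)
  if (!length(ch_lines)) stop("no channels found", call. = FALSE)
  parts <- strsplit(sub("^# channel:\\s*", "", ch_lines), "\\s+")
  channels <- data.frame(
    name = vapply(parts, `[`, "", 1L),
    modality = vapply(parts, `[`, "", 2L),
    units = vapply(parts, `[`, "", 3L),
    native_rate = as.numeric(vapply(parts, `[`, "", 4L))
  )
  bad <- setdiff(channels$modality, MODALITIES)
  if (length(bad))
    stop("unknown modality tag: ", paste(bad, collapse = ", "), call. = FALSE)
  dt <- data.table::fread(path, skip = length(hdr), header = TRUE,
                          colClasses = "numeric", data.table = FALSE)
  if (!nrow(dt) || !ncol(dt)) stop("no channels found", call. = FALSE)
  short <- names(dt)[vapply(dt, anyNA, TRUE)]
  if (length(short))
    stop("channel(s) shorter than others: ", paste(short, collapse = ", "),
         call. = FALSE)
  data <- as.matrix(dt)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    as.list(jsonlite::read_json(meta_path, simplifyVector = TRUE))
  } else list()
  mf_recording(data, channels, rate = rate, session_meta = meta)
}
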