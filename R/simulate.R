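# Synthetic session generator: a latent fatigue trajectory drives
# class-dependent structure in every modality so the downstream fusion,
# training and assessment stages are testable without human recordings.

#' Canonical EEG frequency bands (Hz)
#'
#' Delta 0.3-4, theta 4-8, alpha 8-13, beta 13-30 Hz.
#' @export
EEG_BANDS <- list(delta = c(0.3, 4), theta = c(4, 8),
                  alpha = c(8, 13), beta = c(13, 30))

#' Piecewise-linear latent fatigue trajectory
#'
#' The latent level `lambda(t)` in `[0, 1]` drives every modality's
#' class-dependent parameters during simulation; 0 is the fully rested
#' state, 1 the fully fatigued state.
#'
#' @param times Strictly increasing breakpoint times in seconds; the first
#'   must be 0 and the last must equal the simulated session duration.
#' @param levels Latent levels in `[0, 1]`, one per breakpoint.
#' @return A `fatigue_profile` object.
#' @export
fatigue_profile <- function(times, levels) {
  ok <- is.numeric(times) && is.numeric(levels) &&
    length(times) == length(levels) && length(times) >= 2L &&
    all(is.finite(times)) && all(is.finite(levels)) &&
    all(diff(times) > 0) && times[1] == 0 &&
    all(levels >= 0) && all(levels <= 1)
  if (!ok) stop("invalid fatigue profile", call. = FALSE)
  structure(list(times = as.numeric(times), levels = as.numeric(levels)),
            class = "fatigue_profile")
}

#' Step fatigue profile: low until `t_change`, then high
#' @param duration Session length in seconds.
#' @param t_change Time of the step, seconds.
#' @param low,high Latent levels before/after the step.
#' @return A [fatigue_profile()].
#' @export
profile_step <- function(duration, t_change = duration / 2, low = 0, high = 1) {
  eps <- min(1e-6, t_change / 2)
  fatigue_profile(c(0, t_change - eps, t_change, duration),
                  c(low, low, high, high))
}

#' Linear ramp fatigue profile from `low` at t = 0 to `high` at the end
#' @inheritParams profile_step
#' @return A [fatigue_profile()].
#' @export
profile_ramp <- function(duration, low = 0, high = 1) {
  fatigue_profile(c(0, duration), c(low, high))
}

# lambda(t) by linear interpolation
profile_at <- function(profile, t) {
  stats::approx(profile$times, profile$levels, xout = t, rule = 2)$y
}

#' Generator configuration for synthetic sessions
#'
#' Every modality has a rested ("low") and a fatigued ("high") parameter
#' endpoint; at latent level `lambda` the effective parameter is the convex
#' combination `(1 - lambda) * low + lambda * high`.  Defaults encode the
#' physiological signatures the generator emulates: alpha and theta EEG
#' amplitude rise with fatigue, heart rate drops, EMG contraction amplitude
#' declines, body temperature drifts slowly, pupil diameter is neutral by
#' default (no established direction).
#'
#' @param eeg_band_amplitudes_low,eeg_band_amplitudes_high Named numeric
#'   vectors with entries `delta`, `theta`, `alpha`, `beta`: per-band RMS
#'   oscillation amplitude in uV at lambda = 0 and lambda = 1.
#' @param heart_rate_low,heart_rate_high Heart rate endpoints, beats/min.
#' @param emg_amplitude_low,emg_amplitude_high EMG envelope amplitude
#'   endpoints, arbitrary units.
#' @param temp_start Axillary temperature at t = 0, degrees C.
#' @param temp_drift Temperature drift, degrees C per hour.
#' @param pupil_mean Baseline pupil diameter, mm.
#' @param pupil_fatigue_delta Added to pupil diameter at lambda = 1, mm.
#' @param eeg_phase_diffusion Brownian phase-diffusion rate of the EEG
#'   band components in rad^2/s (default 0.2, i.e. a coherence time of
#'   about 10 s, typical of cortical rhythms); 0 gives perfectly coherent
#'   sinusoids.
#' @param noise_sd Named per-modality Gaussian noise standard deviations
#'   (`ecg`, `emg`, `temperature`, `eeg`, `eye`).
#' @param seed Integer seed; identical configurations (including seed)
#'   reproduce bit-identical recordings.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    eeg_band_amplitudes_low  = c(delta = 20, theta = 10, alpha = 10, beta = 5),
    eeg_band_amplitudes_high = c(delta = 20, theta = 20, alpha = 20, beta = 5),
    heart_rate_low = 70, heart_rate_high = 60,
    emg_amplitude_low = 1.0, emg_amplitude_high = 0.5,
    temp_start = 36.8, temp_drift = -0.2,
    pupil_mean = 3.5, pupil_fatigue_delta = 0,
    eeg_phase_diffusion = 0.2,
    noise_sd = c(ecg = 0.05, emg = 0.1, temperature = 0.02,
                 eeg = 5, eye = 0.05),
    seed = 1L) {
  band_keys <- names(EEG_BANDS)
  for (v in list(eeg_band_amplitudes_low, eeg_band_amplitudes_high)) {
    if (!setequal(names(v), band_keys))
      stop("EEG band amplitudes must be named exactly: ",
           paste(band_keys, collapse = ", "), call. = FALSE)
    if (any(v < 0)) stop("band amplitudes must be nonnegative", call. = FALSE)
  }
  if (!setequal(names(noise_sd), MODALITIES))
    stop("noise_sd must be named exactly: ",
         paste(MODALITIES, collapse = ", "), call. = FALSE)
  if (any(noise_sd < 0)) stop("noise sds must be nonnegative", call. = FALSE)
  stopifnot(heart_rate_low >= 0, heart_rate_high >= 0,
            emg_amplitude_low >= 0, emg_amplitude_high >= 0,
            pupil_mean >= 0)
  structure(list(
    eeg_band_amplitudes_low = eeg_band_amplitudes_low[band_keys],
    eeg_band_amplitudes_high = eeg_band_amplitudes_high[band_keys],
    heart_rate_low = heart_rate_low, heart_rate_high = heart_rate_high,
    emg_amplitude_low = emg_amplitude_low,
    emg_amplitude_high = emg_amplitude_high,
    temp_start = temp_start, temp_drift = temp_drift,
    pupil_mean = pupil_mean, pupil_fatigue_delta = pupil_fatigue_delta,
    eeg_phase_diffusion = eeg_phase_diffusion,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "generator_config")
}

# one EEG channel: per band, a mixture of `n_comp` random-phase sinusoids
# whose joint RMS amplitude tracks the time-varying band amplitude A(t);
# each component gets amplitude A(t)/sqrt(n_comp) so total band power is
# A(t)^2 / 2, the power of a single sinusoid of amplitude A(t).  Each
# component's phase diffuses as a Brownian walk (variance `phase_diffusion`
# rad^2 per second), giving the oscillation the finite coherence time
# (~ 2 / phase_diffusion seconds) of real cortical rhythms: windows far
# apart in time are independent oscillation draws rather than
# time-shifted copies of one deterministic waveform, while the spectral
# broadening (~0.03 Hz) is negligible against the band widths.
simulate_eeg_channel <- function(t, amp_low, amp_high, lambda, noise,
                                 n_comp = 8L, phase_diffusion = 0.2,
                                 rate = 128) {
  x <- numeric(length(t))
  step_sd <- sqrt(phase_diffusion / rate)
  for (b in names(EEG_BANDS)) {
    edges <- EEG_BANDS[[b]]
    amp_t <- (1 - lambda) * amp_low[[b]] + lambda * amp_high[[b]]
    freqs <- stats::runif(n_comp, edges[1], edges[2])
    phases <- stats::runif(n_comp, 0, 2 * pi)
    for (i in seq_len(n_comp)) {
      drift <- if (phase_diffusion > 0)
        cumsum(stats::rnorm(length(t), 0, step_sd)) else 0
      x <- x + (amp_t / sqrt(n_comp)) *
        sin(2 * pi * freqs[i] * t + phases[i] + drift)
    }
  }
  x + stats::rnorm(length(t), 0, noise)
}

# Gaussian pulse train at the instantaneous heart rate: one narrow bump per
# cardiac cycle (morphological realism is out of scope).
simulate_ecg <- function(t, rate, hr_t, noise, width = 0.04) {
  beat_phase <- cumsum(hr_t / 60) / rate     # cycles elapsed
  frac <- beat_phase - floor(beat_phase)
  pulse <- exp(-(frac - 0.5)^2 / (2 * width^2))
  pulse + stats::rnorm(length(t), 0, noise)
}

#' Simulate a full multichannel session
#'
#' Generates the 17-channel sensor suite on a common clock.  At latent
#' level `lambda(t)` each modality's parameters are the convex combination
#' of the configuration's low/high endpoints: EEG channels are sums of
#' band-limited random-phase sinusoid mixtures plus Gaussian noise, ECG is
#' a periodic pulse train at the interpolated heart rate, EMG is
#' amplitude-modulated broadband noise, temperature is a slow drift, pupil
#' diameter is the baseline plus the lambda-scaled fatigue delta, and the
#' accelerometer/gyroscope channels are neutral noise.
#'
#' @param config A [generator_config()].
#' @param profile A [fatigue_profile()] whose last breakpoint is at
#'   `duration`.
#' @param duration Session length in seconds (at least 6, the fusion
#'   window length).
#' @param rate Common sampling rate in Hz; must exceed twice the highest
#'   EEG band edge (default 128).
#' @param session_meta Optional list (`subject_id`, `kss_pre`, `kss_post`).
#' @return An [mf_recording()], reproducible bit-for-bit from
#'   `config$seed`.
#' @export
simulate_session <- function(config, profile, duration, rate = 128,
                             session_meta = list()) {
  stopifnot(inherits(config, "generator_config"))
  if (!inherits(profile, "fatigue_profile"))
    stop("invalid fatigue profile", call. = FALSE)
  if (!is_scalar_num(duration) || duration < 6)
    stop("session too short to segment (need >= 6 s)", call. = FALSE)
  if (!is_scalar_num(rate) || rate <= 2 * max(unlist(EEG_BANDS)))
    stop("rate must exceed twice the highest band edge (60 Hz)",
         call. = FALSE)
  if (abs(profile$times[length(profile$times)] - duration) > 1e-9)
    stop("invalid fatigue profile: last breakpoint must be at `duration`",
         call. = FALSE)

  channels <- default_channel_suite(rate)
  n <- round(rate * duration)
  t <- (seq_len(n) - 1) / rate
  lambda <- profile_at(profile, t)
  ns <- config$noise_sd

  with_seed(config$seed, {
    data <- matrix(0, n, nrow(channels),
                   dimnames = list(NULL, channels$name))
    hr_t <- (1 - lambda) * config$heart_rate_low +
      lambda * config$heart_rate_high
    data[, "ECG"] <- simulate_ecg(t, rate, hr_t, ns[["ecg"]])
    emg_amp <- (1 - lambda) * config$emg_amplitude_low +
      lambda * config$emg_amplitude_high
    data[, "EMG"] <- emg_amp * stats::rnorm(n) +
      stats::rnorm(n, 0, ns[["emg"]])
    data[, "TEMP"] <- config$temp_start + config$temp_drift * (t / 3600) +
      stats::rnorm(n, 0, ns[["temperature"]])
    for (nm in c("ACCX", "ACCY")) data[, nm] <- stats::rnorm(n, 0, ns[["eye"]])
    data[, "ACCZ"] <- 9.81 + stats::rnorm(n, 0, ns[["eye"]])
    for (nm in c("GYRX", "GYRY", "GYRZ"))
      data[, nm] <- stats::rnorm(n, 0, ns[["eye"]])
    pupil <- config$pupil_mean + lambda * config$pupil_fatigue_delta
    data[, "PUPL"] <- pupil + stats::rnorm(n, 0, ns[["eye"]])
    data[, "PUPR"] <- pupil + stats::rnorm(n, 0, ns[["eye"]])
    for (nm in EEG_CHANNEL_NAMES)
      data[, nm] <- simulate_eeg_channel(
        t, config$eeg_band_amplitudes_low, config$eeg_band_amplitudes_high,
        lambda, ns[["eeg"]],
        phase_diffusion = config$eeg_phase_diffusion %||% 0.2, rate = rate)
    mf_recording(data, channels, rate = rate, session_meta = session_meta)
  })
}

#' Band power of a signal
#'
#' Integrates the periodogram power spectral density estimate over a
#' frequency band.
#'
#' @param samples Numeric vector, at least 2 s of signal at `rate`.
#' @param rate Sampling rate in Hz.
#' @param band Length-2 numeric `(low, high)` in Hz, inside `(0, rate/2)`.
#' @param detrend Remove a linear trend before estimating the spectrum.
#' @return Nonnegative scalar band power.
#' @export
band_power <- function(samples, rate, band, detrend = TRUE) {
  stopifnot(is.numeric(samples), is_scalar_num(rate), rate > 0,
            is.numeric(band), length(band) == 2L)
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= rate / 2)
    stop("band out of range", call. = FALSE)
  if (length(samples) < 2 * rate)
    stop("need at least 2 s of signal to estimate band power",
         call. = FALSE)
  if (stats::sd(samples) == 0) return(0)
  sp <- stats::spec.pgram(stats::ts(samples, frequency = rate),
                          taper = 0, detrend = detrend, fast = TRUE,
                          plot = FALSE)
  sel <- sp$freq >= band[1] & sp$freq < band[2]
  df <- sp$freq[2] - sp$freq[1]
  sum(sp$spec[sel]) * df
}
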