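#' Stimulation-artifact specification
#'
#' Describes the stereotyped artifact a biphasic stimulation pulse
#' leaves on nearby recording electrodes: a sharp ~10 ms biphasic
#' deflection repeating at the pulse rate for the duration of the
#' train, with amplitude decaying exponentially with distance from the
#' stimulation-pair midpoint.  The default peak amplitude is 20x the
#' eyes-closed alpha amplitude: the raw artifact dwarfs the biological
#' signal, as in recordings near stimulating electrodes, and the true
#' ratio is not known, so it is exposed here.
#'
#' @param pulse_rate pulses per second.
#' @param train_duration stimulation-train length in seconds.
#' @param waveform_duration single-deflection length in ms.
#' @param peak_amplitude absolute peak of the deflection on the closest
#'   channel (same arbitrary units as the signal).
#' @param channel_gain_decay_length spatial decay length in mm of the
#'   per-channel gain `exp(-distance / decay_length)`.
#' @return object of class `artifact_spec`.
#' @export
artifact_spec <- function(pulse_rate = 10, train_duration = 5,
                          waveform_duration = 10, peak_amplitude = 200,
                          channel_gain_decay_length = 10) {
  stopifnot(pulse_rate > 0, train_duration > 0,
            waveform_duration / 1000 < 1 / pulse_rate,
            peak_amplitude >= 0, channel_gain_decay_length > 0)
  structure(list(pulse_rate = pulse_rate, train_duration = train_duration,
                 waveform_duration = waveform_duration,
                 peak_amplitude = peak_amplitude,
                 channel_gain_decay_length = channel_gain_decay_length),
            class = "artifact_spec")
}

#' Synthetic-trial configuration
#'
#' Parameters of the synthetic ECoG generator.  Each 15 s trial is
#' structured as 5 s pre-stimulation, 5 s stimulation, 5 s
#' post-stimulation at 800 Hz, and each channel carries (1) a
#' state-scaled alpha sinusoid with small per-channel phase jitter,
#' (2) independent 1/f background noise, and (3) a common 60 Hz line
#' component.  Two fields emulate stimulation effects on the underlying
#' signal itself: `alpha_boost_during` multiplies the alpha amplitude
#' inside the stimulation epoch (for planted modulation-index ground
#' truth), and `entrain_amp_by_state` adds a sinusoid at the stimulation
#' frequency during that epoch, strongest in the task-engaged state
#' where entrainment is expected and absent with eyes closed.
#'
#' @param sample_rate Hz.
#' @param trial_duration seconds (pre/stim/post epochs of equal length,
#'   stimulation onset at one third of the trial).
#' @param alpha_freq endogenous oscillation frequency in Hz.
#' @param alpha_amplitude_by_state named vector (eyes_closed >=
#'   eyes_open >= task, all nonnegative), arbitrary units.
#' @param one_over_f_exponent spectral exponent of the background noise.
#' @param noise_scale standard deviation of the background noise.
#' @param line_noise_amp amplitude of the 60 Hz line component.
#' @param phase_jitter_sd per-channel oscillation phase jitter, radians.
#' @param amp_topography_range per-channel multiplicative amplitude
#'   range (uniform) for the oscillatory components, emulating the
#'   spatial topography oscillations show across a grid; without it a
#'   perfectly coherent rhythm would be annihilated by common average
#'   referencing.
#' @param alpha_boost_during multiplicative alpha-amplitude factor in
#'   the stimulation epoch.
#' @param entrain_amp_by_state named vector, amplitude of the added
#'   stimulation-frequency component during the stimulation epoch.
#' @param stim_freq stimulation frequency in Hz.
#' @param artifact an [artifact_spec()].
#' @param seed integer seed; the generator is bit-reproducible.
#' @return object of class `synthetic_trial_config`.
#' @export
synthetic_trial_config <- function(sample_rate = 800, trial_duration = 15,
                                   alpha_freq = 7.1,
                                   alpha_amplitude_by_state =
                                     c(eyes_closed = 10, eyes_open = 4,
                                       task = 1),
                                   one_over_f_exponent = 1,
                                   noise_scale = 2, line_noise_amp = 1,
                                   phase_jitter_sd = 0.1,
                                   amp_topography_range = c(0.5, 1.5),
                                   alpha_boost_during = 1,
                                   entrain_amp_by_state =
                                     c(eyes_closed = 0, eyes_open = 0.5,
                                       task = 1.5),
                                   stim_freq = 10,
                                   artifact = artifact_spec(),
                                   seed = 1L) {
  a <- alpha_amplitude_by_state
  stopifnot(all(c("eyes_closed", "eyes_open", "task") %in% names(a)),
            all(a >= 0),
            a["eyes_closed"] >= a["eyes_open"], a["eyes_open"] >= a["task"],
            alpha_freq > 0, alpha_freq < sample_rate / 2,
            trial_duration > 0, noise_scale >= 0, line_noise_amp >= 0,
            alpha_boost_during >= 0)
  structure(list(sample_rate = sample_rate, trial_duration = trial_duration,
                 alpha_freq = alpha_freq, alpha_amplitude_by_state = a,
                 one_over_f_exponent = one_over_f_exponent,
                 noise_scale = noise_scale, line_noise_amp = line_noise_amp,
                 phase_jitter_sd = phase_jitter_sd,
                 amp_topography_range = amp_topography_range,
                 alpha_boost_during = alpha_boost_during,
                 entrain_amp_by_state = entrain_amp_by_state,
                 stim_freq = stim_freq, artifact = artifact,
                 seed = as.integer(seed)),
            class = "synthetic_trial_config")
}

#' Stereotyped biphasic artifact waveform
#'
#' One cycle of a raised-cosine-windowed sine: sharp, biphasic,
#' exactly zero-mean, scaled to the requested peak amplitude.
#' Deterministic given the spec.
#'
#' @param spec an [artifact_spec()].
#' @param sample_rate Hz at which to render the waveform.
#' @return numeric vector of length
#'   `round(waveform_duration / 1000 * sample_rate)`.
#' @export
artifact_waveform <- function(spec, sample_rate) {
  stopifnot(inherits(spec, "artifact_spec"))
  n <- round(spec$waveform_duration / 1000 * sample_rate)
  if (n < 4) stop("waveform shorter than 4 samples at this rate")
  th <- 2 * pi * (seq_len(n) - 1) / n
  w <- sin(th) * (0.5 - 0.5 * cos(th))
  w / max(abs(w)) * spec$peak_amplitude
}

# 1/f^exponent Gaussian background noise via FFT spectral shaping,
# rescaled to the requested standard deviation (0 Hz component removed).
one_over_f_noise <- function(n, sample_rate, exponent, sd_target) {
  if (sd_target == 0) return(numeric(n))
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * sample_rate / n
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(X * shape, inverse = TRUE) / n)
  x / stats::sd(x) * sd_target
}

#' Inject stimulation artifacts into a clean recording
#'
#' Places the stereotyped artifact waveform at `pulse_rate` intervals
#' starting at the recording's stimulation-onset annotation, scaling it
#' per channel by `exp(-distance / decay_length)` from the
#' stimulation-pair midpoint.  Returns the paired ground truth used to
#' test artifact removal.
#'
#' @param clean a [raw_recording()] with at least one trial onset.
#' @param layout an [make_layout()] object with a stimulation pair.
#' @param spec an [artifact_spec()].
#' @return object of class `synthetic_trial`: `clean`, `contaminated`,
#'   `artifact_only` (all [raw_recording()]s, with `contaminated =
#'   clean + artifact_only` sample-exact), `true_artifact_times`
#'   (onset sample indices at the recording rate), and `spec`.
#' @export
inject_artifacts <- function(clean, layout, spec) {
  stopifnot(inherits(clean, "raw_recording"), inherits(spec, "artifact_spec"))
  if (!length(clean$trial_onsets)) stop("recording has no stimulation onset")
  fs <- clean$sample_rate
  onset <- clean$trial_onsets[1]
  n_events <- floor(spec$train_duration * spec$pulse_rate)
  times <- onset + round((seq_len(n_events) - 1) * fs / spec$pulse_rate)
  wf <- artifact_waveform(spec, fs)
  if (max(times) + length(wf) - 1 > ncol(clean$data))
    stop("stimulation train extends past the end of the recording")
  gains <- exp(-stim_distances(layout) / spec$channel_gain_decay_length)
  art <- matrix(0, nrow(clean$data), ncol(clean$data))
  for (t0 in times) {
    idx <- t0:(t0 + length(wf) - 1L)
    art[, idx] <- art[, idx] + outer(gains, wf)
  }
  contaminated <- clean
  contaminated$data <- clean$data + art
  artifact_only <- clean
  artifact_only$data <- art
  structure(list(clean = clean, contaminated = contaminated,
                 artifact_only = artifact_only,
                 true_artifact_times = times, spec = spec),
            class = "synthetic_trial")
}

#' Generate one synthetic ECoG trial
#'
#' Builds the clean multichannel signal for the requested behavioral
#' state, annotates the stimulation onset at one third of the trial,
#' and injects stimulation artifacts (skipped, with a zero
#' `artifact_only` track, when the artifact peak amplitude is 0).
#' Bit-reproducible for a given config seed.
#'
#' @param config a [synthetic_trial_config()].
#' @param layout an [make_layout()] object.
#' @param state one of `"eyes_closed"`, `"eyes_open"`, `"task"`.
#' @return a `synthetic_trial` (see [inject_artifacts()]); each
#'   recording's `layout` field is populated.
#' @export
generate_trial <- function(config, layout, state) {
  stopifnot(inherits(config, "synthetic_trial_config"),
            inherits(layout, "electrode_layout"))
  states <- c("eyes_closed", "eyes_open", "task")
  if (!state %in% states) stop("unknown state: ", state)
  set.seed(config$seed)
  fs <- config$sample_rate
  n <- round(config$trial_duration * fs)
  n_ch <- nrow(layout$positions)
  t_s <- (seq_len(n) - 1) / fs
  epoch_len <- config$trial_duration / 3
  onset <- round(epoch_len * fs) + 1L
  stim_win <- t_s >= epoch_len & t_s < 2 * epoch_len

  amp <- unname(config$alpha_amplitude_by_state[state])
  amp_t <- rep(amp, n)
  amp_t[stim_win] <- amp * config$alpha_boost_during
  entrain <- unname(config$entrain_amp_by_state[state])
  line <- config$line_noise_amp * sin(2 * pi * 60 * t_s)

  data <- matrix(0, n_ch, n)
  # per-channel phase jitter for both oscillatory components; a
  # perfectly common-mode rhythm would vanish under common average
  # referencing, unlike real spatially varying oscillations
  phases <- stats::rnorm(n_ch, 0, config$phase_jitter_sd)
  phases_e <- stats::rnorm(n_ch, 0, config$phase_jitter_sd)
  tr_ <- config$amp_topography_range
  gains_a <- stats::runif(n_ch, tr_[1], tr_[2])
  gains_e <- stats::runif(n_ch, tr_[1], tr_[2])
  for (ch in seq_len(n_ch)) {
    alpha <- gains_a[ch] * amp_t *
      sin(2 * pi * config$alpha_freq * t_s + phases[ch])
    entr <- numeric(n)
    entr[stim_win] <- gains_e[ch] * entrain *
      sin(2 * pi * config$stim_freq * t_s[stim_win] + phases_e[ch])
    noise <- one_over_f_noise(n, fs, config$one_over_f_exponent,
                              config$noise_scale)
    data[ch, ] <- alpha + noise + line + entr
  }
  clean <- raw_recording(data, fs, layout$labels, layout,
                         trial_onsets = onset)
  spec <- config$artifact
  if (spec$peak_amplitude == 0) {
    zero <- clean
    zero$data <- matrix(0, n_ch, n)
    trial <- structure(list(clean = clean, contaminated = clean,
                            artifact_only = zero,
                            true_artifact_times = integer(), spec = spec),
                       class = "synthetic_trial")
  } else {
    trial <- inject_artifacts(clean, layout, spec)
  }
  trial$config <- config
  trial$state <- state
  trial
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "<synthetic_trial> state=%s, %d channels, %d artifact events\n",
    if (is.null(x$state)) "?" else x$state,
    nrow(x$clean$data), length(x$true_artifact_times)))
  invisible(x)
}
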