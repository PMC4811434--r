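#' Select the reference channel for artifact detection
#'
#' Stimulation artifacts are ~10 ms deflections whose energy sits near
#' 100 Hz.  The channel with the highest power in `band_center +/- 10
#' Hz` during the stimulation window (train onset to onset + 5 s, or
#' the recording end) carries the largest artifacts and is used for
#' detection; its event times apply to all channels, since pulses hit
#' every electrode simultaneously.
#'
#' @param rec a [raw_recording()] with a stimulation onset.
#' @param band_center Hz, default 100.
#' @param window_s stimulation-window length in seconds.
#' @return 1-based channel index (ties broken toward the lowest index).
#' @export
select_artifact_channel <- function(rec, band_center = 100, window_s = 5) {
  stopifnot(inherits(rec, "raw_recording"),
            band_center + 10 < rec$sample_rate / 2)
  if (!length(rec$trial_onsets)) stop("recording has no stimulation window")
  i0 <- rec$trial_onsets[1]
  i1 <- min(ncol(rec$data), i0 + round(window_s * rec$sample_rate) - 1L)
  bp <- apply(rec$data[, i0:i1, drop = FALSE], 1, function(x) {
    sp <- periodogram_power(x, rec$sample_rate)
    band_power(sp$freq, sp$power, band_center, 20)
  })
  which.max(bp)  # first max = lowest index on ties
}

#' Remove slow trends with piecewise cubic fits
#'
#' High-pass filtering by cubic polynomial fitting: the signal is tiled
#' into windows, a cubic is least-squares fitted in each, and the fit
#' is subtracted.  Slow biological rhythms are removed while sharp
#' transients (artifacts) survive nearly intact, which is what the
#' threshold detector needs.
#'
#' @param x numeric signal.
#' @param window window length in samples (>= 8).
#' @return detrended signal, same length.
#' @export
poly_detrend <- function(x, window) {
  if (window < 8) stop("window must be >= 8 samples")
  n <- length(x)
  if (window > n) stop("window longer than signal")
  out <- numeric(n)
  starts <- seq(1L, n, by = window)
  for (s in starts) {
    e <- min(n, s + window - 1L)
    seg <- x[s:e]
    tt <- seq_along(seg)
    fit <- stats::lm.fit(cbind(1, tt, tt^2, tt^3), seg)
    out[s:e] <- fit$residuals
  }
  out
}

#' Detect artifact times by robust threshold crossing
#'
#' Flags excursions of the detrended signal beyond `threshold_k` MADs
#' (median absolute deviation, consistency-scaled) and returns the
#' peak-aligned sample index of each excursion, enforcing a refractory
#' `min_separation` between events.  MAD thresholding makes detection
#' invariant to overall amplitude scaling.
#'
#' @param x detrended signal at the working (upsampled) rate.
#' @param threshold_k threshold in MAD multiples, default 6.
#' @param min_separation refractory period in samples.
#' @param align_signal signal used for peak alignment, defaulting to
#'   `x`.  Passing the raw (un-detrended) trace avoids peak jitter
#'   caused by tile-dependent distortion of the detrending fit.
#' @return object of class `artifact_events`: `times` (strictly
#'   increasing sample indices), `threshold` used, plus bookkeeping
#'   fields filled by the caller.
#' @export
detect_artifact_times <- function(x, threshold_k = 6, min_separation,
                                  align_signal = x) {
  stopifnot(threshold_k > 0, min_separation >= 1,
            length(align_signal) == length(x))
  thr <- threshold_k * stats::mad(x)
  above <- which(abs(x) > thr)
  times <- integer()
  if (length(above)) {
    # A biphasic artifact has two near-equal lobes; aligning on |x|
    # would flip lobes between events.  Fix the polarity from the
    # single strongest excursion and align every event on that lobe.
    pol <- sign(align_signal[which.max(abs(align_signal))])
    gaps <- which(diff(above) > 1)
    run_start <- above[c(1L, gaps + 1L)]
    run_end <- above[c(gaps, length(above))]
    # search beyond the (possibly narrow or lobe-split) threshold run
    # so the aligned peak is the waveform's, not the run's, maximum
    pad <- max(4L, min_separation %/% 4L)
    peaks <- mapply(function(s, e) {
      idx <- max(1L, s - pad):min(length(align_signal), e + pad)
      idx[which.max(pol * align_signal[idx])]
    }, run_start, run_end)
    # refractory: keep a peak only if far enough from the last kept one
    for (p in peaks) {
      if (!length(times) || p - times[length(times)] >= min_separation)
        times <- c(times, p)
    }
  }
  structure(list(times = as.integer(times), threshold = thr,
                 reference_channel = NA_integer_,
                 segment_half_width = NA_integer_),
            class = "artifact_events")
}

# Zero-phase 4th-order Butterworth low-pass (applied forward-backward).
lowpass_zp <- function(x, cutoff, fs) {
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  signal::filtfilt(bf, x)
}

#' Resample by an integer factor
#'
#' Upsampling uses band-limited (FFT zero-padding) interpolation,
#' which is exact for signals already band-limited below Nyquist --
#' linear interpolation would impose a sinc-squared droop of about 1%
#' at 40 Hz, visible in round-trip comparisons.  Downsampling applies
#' a zero-phase anti-alias low-pass at 0.45x the target rate and
#' decimates.  Both directions are zero-phase, so event times stay
#' aligned.
#'
#' @param x numeric signal.
#' @param factor integer resampling factor.
#' @param fs input sampling rate in Hz.
#' @param direction `"up"` or `"down"`.
#' @return resampled signal (length `factor * length(x)` going up).
#' @export
resample_by <- function(x, factor, fs, direction = c("up", "down")) {
  direction <- match.arg(direction)
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(x)
  if (direction == "up") {
    n <- length(x)
    N <- n * factor
    X <- stats::fft(x)
    half <- n %/% 2
    Xup <- complex(N)
    if (n %% 2 == 0) {
      Xup[1:half] <- X[1:half]
      Xup[half + 1] <- X[half + 1] / 2          # Nyquist bin, split
      Xup[N - half + 1] <- X[half + 1] / 2
      if (half >= 2) Xup[(N - half + 2):N] <- X[(half + 2):n]
    } else {
      Xup[1:(half + 1)] <- X[1:(half + 1)]
      Xup[(N - half + 1):N] <- X[(half + 2):n]
    }
    Re(stats::fft(Xup, inverse = TRUE)) / n
  } else {
    y <- lowpass_zp(x, 0.45 * fs / factor, fs)
    y[seq(1, length(y), by = factor)]
  }
}

#' Template-matching stimulation-artifact removal
#'
#' Channel-wise pipeline: (1) upsample to the working rate (default
#' 3200 Hz, 4x the clinical 800 Hz); (2) around each detected event,
#' extract a peak-aligned segment of `+/- segment_ms`; (3) build that
#' event's template as the moving average of five artifact segments
#' (the event itself, two before, two after; fewer at the sequence
#' ends); (4) scale the template by its least-squares projection onto
#' the segment and subtract; (5) remove the residual step at the
#' segment edges by subtracting the line between the edge offsets;
#' (6) anti-alias filter and downsample back to the original rate.
#' Samples outside every segment are returned bit-identical.
#'
#' @param rec a [raw_recording()] at the original rate.
#' @param events an `artifact_events` object with times at the working
#'   rate (from [detect_artifact_times()] on the upsampled reference
#'   channel), or `NULL` to run detection internally.
#' @param upsample_factor integer, default 4 (800 -> 3200 Hz).
#' @param segment_ms segment half-width in ms, default 18 (covers the
#'   ~10 ms deflection plus its anti-alias ringing and settling).
#' @param threshold_k,min_separation_ms detection parameters used when
#'   `events` is `NULL`.
#' @param detrend_window_ms cubic-detrend window for detection, ms.
#' @param line_freq mains frequency in Hz regressed out of artifact
#'   templates (the 60 Hz line is phase-locked to a 10 Hz pulse train
#'   and would otherwise contaminate them); `NULL` disables.
#' @return list: `cleaned` (a [raw_recording()]), `events`, and
#'   `reference_channel`.
#' @export
remove_artifacts <- function(rec, events = NULL, upsample_factor = 4,
                             segment_ms = 18, threshold_k = 6,
                             min_separation_ms = 50,
                             detrend_window_ms = 100, line_freq = 60) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sample_rate
  fs_up <- fs * upsample_factor
  if (is.null(events)) {
    ref <- select_artifact_channel(rec)
    up_ref <- resample_by(rec$data[ref, ], upsample_factor, fs, "up")
    det <- poly_detrend(up_ref, round(detrend_window_ms / 1000 * fs_up))
    events <- detect_artifact_times(det, threshold_k,
                                    round(min_separation_ms / 1000 * fs_up),
                                    align_signal = up_ref)
    events$reference_channel <- ref
  }
  half <- round(segment_ms / 1000 * fs_up)
  events$segment_half_width <- half
  if (length(events$times) < 1) {
    warning("no artifact events: returning the recording unchanged")
    return(list(cleaned = rec, events = events,
                reference_channel = events$reference_channel))
  }
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    up <- resample_by(rec$data[ch, ], upsample_factor, fs, "up")
    up <- subtract_templates(up, events$times, half,
                             fs = fs_up, line_freq = line_freq)
    down <- resample_by(up, upsample_factor, fs_up, "down")
    out$data[ch, ] <- down[seq_len(ncol(rec$data))]
  }
  list(cleaned = out, events = events,
       reference_channel = events$reference_channel)
}

# Detrend of one short segment: absorbs the smooth neural signal while
# the sharp artifact deflection survives.  The basis is a line plus,
# when `line_freq` and `fs` are given, a sine/cosine pair at the line
# frequency: the 60 Hz mains component is phase-locked to the 10 Hz
# pulse grid (exactly six cycles per pulse), so without these
# regressors it enters the template coherently and its gated
# subtraction creates sidebands at pulse-rate harmonics.  Fitting is
# restricted to samples outside `exclude` (the artifact support) so
# the fit cannot absorb the artifact shape itself.
seg_detrend <- function(s, exclude = NULL, degree = 1L, fs = NULL,
                        line_freq = NULL) {
  tt <- seq_along(s) / length(s)
  X <- cbind(1, stats::poly(tt, degree = degree, raw = TRUE))
  if (!is.null(line_freq) && !is.null(fs)) {
    ts <- seq_along(s) / fs
    X <- cbind(X, sin(2 * pi * line_freq * ts), cos(2 * pi * line_freq * ts))
  }
  fit_idx <- setdiff(seq_along(s), exclude)
  if (length(fit_idx) < 4 * ncol(X)) {        # exclusion too aggressive
    fit_idx <- seq_along(s)
    X <- cbind(1, tt)
  }
  beta <- stats::lm.fit(X[fit_idx, , drop = FALSE], s[fit_idx])$coefficients
  beta[is.na(beta)] <- 0
  s - drop(X %*% beta)
}

# Peak alignment by cross-correlation with the grand mean segment.
# Single-event peak picking is noise-driven when the artifact's two
# lobes have near-equal amplitude, so each event is instead shifted
# (within +/- align_search samples) to maximize its inner product with
# the mean of all line-detrended segments; a biphasic template makes
# that optimum sharp and consistent across events.
align_to_mean_segment <- function(x, times, half, align_search) {
  n <- length(x)
  pad <- half + align_search
  ok <- times - pad >= 1L & times + pad <= n
  grab <- function(c0, h) x[(c0 - h):(c0 + h)]
  detr <- seg_detrend
  if (sum(ok) < 2) return(times)
  gm <- Reduce(`+`, lapply(times[ok], grab, h = half)) / sum(ok)
  gm <- detr(gm)
  vapply(times, function(t0) {
    if (t0 - pad < 1L || t0 + pad > n) return(t0)
    wide <- detr(grab(t0, pad))
    shifts <- -align_search:align_search
    score <- vapply(shifts, function(s) {
      seg <- wide[(align_search + s + 1):(align_search + s + 2 * half + 1)]
      sum(seg * gm)
    }, numeric(1))
    t0 + shifts[which.max(score)]
  }, integer(1))
}

# Core template subtraction on one upsampled channel.
subtract_templates <- function(x, times, half, align_search = 12L,
                               fs = NULL, line_freq = NULL) {
  n <- length(x)
  centers <- align_to_mean_segment(x, as.integer(times), half, align_search)
  # Recenter on the artifact's energy centroid: peak alignment lands on
  # the leading lobe, but the deflection plus its anti-alias ringing is
  # asymmetric around it, and the detrend basis below must only ever be
  # fitted on artifact-free segment edges.
  ok <- centers - half >= 1L & centers + half <= n
  if (sum(ok) >= 2) {
    gm0 <- Reduce(`+`, lapply(centers[ok],
                              function(c0) x[(c0 - half):(c0 + half)])) /
      sum(ok)
    w <- seg_detrend(gm0)^2
    c_off <- as.integer(round(sum(seq_along(w) * w) / sum(w))) - (half + 1L)
    centers <- centers + c_off
  }
  segs <- lapply(centers, function(c0) {
    lo <- c0 - half
    hi <- c0 + half
    if (lo < 1 || hi > n) {
      warning("artifact segment truncated at recording boundary")
      NULL
    } else x[lo:hi]
  })
  keep <- !vapply(segs, is.null, logical(1))
  centers <- centers[keep]
  segs <- segs[keep]
  m <- length(segs)
  if (!m) return(x)
  # Each segment is the sharp artifact riding on slow neural signal
  # plus the mains component; a line plus a sine/cosine pair at the
  # line frequency, fitted on the outer 20% of the segment at each
  # end, absorbs those, so templates are averaged from detrended
  # segments and only the stereotyped artifact shape is subtracted,
  # not neighboring neural or line activity.
  len <- 2L * half + 1L
  pad <- max(4L, round(0.2 * len))
  excl <- (pad + 1L):(len - pad)
  segs_d <- lapply(segs, seg_detrend, exclude = excl, degree = 1L,
                   fs = fs, line_freq = line_freq)
  for (k in seq_len(m)) {
    nb <- max(1L, k - 2L):min(m, k + 2L)      # available neighbors only
    template <- Reduce(`+`, segs_d[nb]) / length(nb)
    # stereotypy guard: only a shape reproduced across the averaged
    # segments is an artifact.  Compare the template's energy against
    # the between-segment residual scatter; pure noise gives a ratio
    # near m/(m-1), a real artifact orders of magnitude more.  Without
    # this, re-running removal (or cleaning an artifact-free channel)
    # would project out genuine signal along a noise template.
    within <- mean(vapply(nb, function(j)
      mean((segs_d[[j]] - template)^2), numeric(1)))
    f_ratio <- mean(template^2) / (within / length(nb) + 1e-300)
    if (length(nb) >= 2 && f_ratio < 4) next
    seg <- segs[[k]]
    scale <- sum(seg * template) / sum(template * template)
    cleaned <- seg - scale * template
    # edge-offset correction: force continuity with the samples just
    # outside the segment by removing the line between edge offsets
    lo <- centers[k] - half
    hi <- centers[k] + half
    left_ref <- if (lo > 1) x[lo - 1L] else cleaned[1]
    right_ref <- if (hi < n) x[hi + 1L] else cleaned[length(cleaned)]
    o1 <- cleaned[1] - left_ref
    o2 <- cleaned[length(cleaned)] - right_ref
    ramp <- seq(o1, o2, length.out = length(cleaned))
    x[lo:hi] <- cleaned - ramp
  }
  x
}
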