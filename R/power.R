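#' Periodogram power spectrum
#'
#' Computes a one-sided periodogram of a real signal with a rectangular
#' window: `P(f) = |X(f)|^2 / n^2`, i.e. the squared amplitude of each
#' Fourier component (a unit-amplitude sinusoid on an exact bin carries
#' power 0.25 split over the positive-frequency bin).  Deterministic and
#' leakage-prone by design; adequate for the pure-tone forward models it
#' is used with.
#'
#' @param x numeric vector, the signal.
#' @param sample_rate sampling rate in Hz.
#' @return list with `freq` (Hz, from 0 to Nyquist) and `power`.
#' @export
periodogram_power <- function(x, sample_rate) {
  stopifnot(is.numeric(x), length(x) >= 2, sample_rate > 0)
  n <- length(x)
  X <- stats::fft(x)
  n_keep <- floor(n / 2) + 1L
  p <- (Mod(X[seq_len(n_keep)]) / n)^2
  # fold negative-frequency power into the one-sided spectrum
  if (n_keep > 2L) {
    last <- if (n %% 2 == 0) n_keep - 1L else n_keep
    p[2:last] <- 2 * p[2:last]
  }
  list(freq = (seq_len(n_keep) - 1L) * sample_rate / n, power = p)
}

#' Integrated power in a frequency band
#'
#' Sums periodogram (or any spectrum) power over `[center - width/2,
#' center + width/2]`, inclusive of grid points falling on either edge.
#'
#' @param freq frequency grid in Hz.
#' @param power nonnegative power values on `freq`.
#' @param center band center in Hz.
#' @param width full band width in Hz.
#' @return scalar band power.
#' @export
band_power <- function(freq, power, center, width) {
  stopifnot(length(freq) == length(power), width >= 0)
  sel <- freq >= center - width / 2 & freq <= center + width / 2
  sum(power[sel])
}

#' Welch-averaged power spectrum
#'
#' Averages modified periodograms of Hann-windowed, 50%-overlapping
#' segments.  Averaging tames the chi-squared variance of single
#' periodogram bins, so narrow spectral lines can be judged against the
#' local floor on a dB scale.
#'
#' @param x numeric signal.
#' @param sample_rate Hz.
#' @param seg_seconds segment length in seconds (default 2, giving a
#'   0.5 Hz grid on which 10 Hz harmonics fall exactly).
#' @return list with `freq` and `power`.
#' @export
welch_power <- function(x, sample_rate, seg_seconds = 2) {
  nseg <- round(seg_seconds * sample_rate)
  stopifnot(nseg >= 8, length(x) >= nseg)
  hop <- nseg %/% 2
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  acc <- NULL
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * win
    sp <- periodogram_power(seg, sample_rate)
    acc <- if (is.null(acc)) sp$power else acc + sp$power
  }
  list(freq = sp$freq, power = acc / length(starts))
}

#' Residual artifact-harmonic excess
#'
#' QC metric for artifact removal: for each harmonic of the stimulation
#' rate inside `range`, compares Welch-spectrum power at the harmonic
#' (1 s segments put every 10 Hz harmonic exactly on the 1 Hz grid)
#' against the local spectral floor (median power within +/- 5 Hz,
#' excluding the harmonic bin) and reports the excess in dB.  Welch
#' averaging (~29 segments on a 15 s trial) keeps the chance
#' fluctuation of a single bin near 1 dB, so residual lines a few dB
#' above the floor are genuinely detectable.  The 60 Hz line frequency
#' is excluded by default since line noise is present in the
#' underlying signal, not an artifact residual.
#'
#' @param x cleaned single-channel signal.
#' @param sample_rate Hz.
#' @param base_freq stimulation rate in Hz, default 10.
#' @param range harmonics considered, default 20-100 Hz.
#' @param exclude harmonic frequencies to skip, default 60.
#' @return named numeric vector of dB excesses, one per harmonic.
#' @export
harmonic_excess_db <- function(x, sample_rate, base_freq = 10,
                               range = c(20, 100), exclude = 60) {
  sp <- welch_power(x, sample_rate, seg_seconds = 1)
  harms <- seq(base_freq * ceiling(range[1] / base_freq),
               min(range[2], sample_rate / 2 - 5), by = base_freq)
  harms <- setdiff(harms, exclude)
  out <- vapply(harms, function(h) {
    core <- abs(sp$freq - h) < 1e-9
    local <- sp$freq >= h - 5 & sp$freq <= h + 5 & !core
    10 * log10(sp$power[core] / stats::median(sp$power[local]))
  }, numeric(1))
  names(out) <- harms
  out
}

#' Frequency of the spectral maximum within a range
#'
#' @param freq frequency grid in Hz.
#' @param power power values on `freq`.
#' @param range length-2 numeric, inclusive search range in Hz.
#' @return frequency (Hz) of the global maximum inside `range`; ties are
#'   broken toward the lower frequency.
#' @export
spectral_peak_freq <- function(freq, power, range = c(1, 40)) {
  sel <- which(freq >= range[1] & freq <= range[2])
  if (!length(sel)) stop("no frequencies inside the search range")
  f <- freq[sel]
  p <- power[sel]
  f[which.max(p)]  # which.max returns the first (lowest-frequency) maximum
}
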