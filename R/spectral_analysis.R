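#' Notch-filter and re-reference a recording
#'
#' Preprocessing applied after artifact removal: a second-order IIR
#' notch at the line frequency per channel, then common average
#' referencing (the instantaneous mean across channels is subtracted
#' from every channel).  With a single channel the referencing step is
#' skipped with a warning.
#'
#' @param rec a [raw_recording()].
#' @param line_freq notch center in Hz, default 60.
#' @param notch_q quality factor (center / bandwidth), default 30.
#' @return a [raw_recording()] with filtered, referenced data.
#' @export
preprocess <- function(rec, line_freq = 60, notch_q = 30) {
  stopifnot(inherits(rec, "raw_recording"))
  out <- rec
  for (ch in seq_len(nrow(out$data)))
    out$data[ch, ] <- notch_filter(out$data[ch, ], rec$sample_rate,
                                   line_freq, notch_q)
  if (nrow(out$data) >= 2) {
    out$data <- sweep(out$data, 2, colMeans(out$data))
  } else {
    warning("single channel: skipping common average reference")
  }
  out
}

#' Second-order IIR notch filter
#'
#' Standard biquad notch (constrained pole-zero placement): zeros on
#' the unit circle at the notch frequency, poles at radius set by the
#' quality factor.  Applied forward-backward for zero phase.
#'
#' @param x signal.
#' @param sample_rate Hz.
#' @param freq notch center, Hz.
#' @param q quality factor.
#' @return filtered signal.
#' @export
notch_filter <- function(x, sample_rate, freq, q = 30) {
  stopifnot(freq > 0, freq < sample_rate / 2)
  w0 <- 2 * pi * freq / sample_rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::filtfilt(signal::Arma(b = b, a = a), x)
}

#' The dual-resolution analysis frequency grid
#'
#' 0.5-20 Hz in 0.1 Hz steps (196 frequencies) plus 21-80 Hz in 1 Hz
#' steps (60 frequencies): fine resolution where alpha-band structure
#' lives, coarse above.
#'
#' @return numeric vector of 256 frequencies in Hz.
#' @export
analysis_freq_grid <- function() {
  c(seq(0.5, 20, by = 0.1), seq(21, 80, by = 1))
}

#' Morlet wavelet time-frequency power
#'
#' Convolves the signal with complex Morlet wavelets (Gaussian-windowed
#' complex exponentials, `cycles` cycles FWHM-equivalent: the Gaussian
#' envelope has sd `cycles / (2 pi f)` in time).  Envelopes are
#' normalized to unit gain at the wavelet's center frequency, so a
#' unit-amplitude sinusoid at an on-grid frequency yields time-mean
#' power 0.25 there.  Samples within the wavelet's half support of the
#' signal edges are flagged (returned in the `edge` attribute) and
#' should be excluded from epoch averages.
#'
#' @param x single-channel signal.
#' @param sample_rate Hz.
#' @param freqs frequency grid, Hz (default [analysis_freq_grid()]).
#' @param cycles wavelet width in cycles, default 7.
#' @param edge_cap_s upper bound, in seconds, on the per-frequency edge
#'   exclusion half-width (low frequencies otherwise exclude entire
#'   5 s epochs).
#' @return `length(freqs) x length(x)` power matrix; attribute
#'   `edge_half_width` gives the per-frequency exclusion half-width in
#'   samples.
#' @export
morlet_power <- function(x, sample_rate, freqs = analysis_freq_grid(),
                         cycles = 7, edge_cap_s = 1.5) {
  stopifnot(is.numeric(x), length(x) >= 8)
  if (any(freqs >= sample_rate / 2)) stop("frequency above Nyquist")
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  fft_freqs <- (seq_len(nfft) - 1) / nfft * sample_rate
  # two-sided frequency axis for the wavelet's Gaussian transfer
  fft_freqs[fft_freqs > sample_rate / 2] <-
    fft_freqs[fft_freqs > sample_rate / 2] - sample_rate
  pow <- matrix(NA_real_, length(freqs), n)
  edge <- integer(length(freqs))
  for (k in seq_along(freqs)) {
    f0 <- freqs[k]
    sd_t <- cycles / (2 * pi * f0)                 # seconds
    sd_f <- 1 / (2 * pi * sd_t)
    # analytic wavelet: Gaussian around +f0, unit peak gain; factor 2
    # recovers the analytic-signal amplitude of a real input
    H <- 2 * exp(-(fft_freqs - f0)^2 / (2 * sd_f^2)) *
      (fft_freqs > 0)
    w <- stats::fft(X * H, inverse = TRUE)[seq_len(n)] / nfft
    pow[k, ] <- Mod(w)^2 / 4   # |A e^{i phi}|^2 / 4 = A^2/4 for a tone
    edge[k] <- min(round(2 * sd_t * sample_rate),
                   round(edge_cap_s * sample_rate))
  }
  attr(pow, "edge_half_width") <- edge
  attr(pow, "freqs") <- freqs
  attr(pow, "sample_rate") <- sample_rate
  pow
}

#' Epoch-averaged wavelet spectra
#'
#' Time-averages a [morlet_power()] matrix within the pre/during/post
#' epochs of a stimulation trial, excluding samples within each
#' wavelet's edge half-width of the trial edges and of the epoch
#' boundaries (so stimulation-epoch power cannot bleed into the
#' flanking epochs).
#'
#' @param tf a [morlet_power()] matrix with its attributes.
#' @param onset stimulation onset sample (1-based).
#' @param epoch_s epoch duration in seconds, default 5 (pre epoch is
#'   the `epoch_s` before `onset`, then during, then post).
#' @return object of class `epoch_spectra`: `freqs`, `pre`, `during`,
#'   `post` (mean power per frequency).
#' @export
epoch_spectra <- function(tf, onset, epoch_s = 5) {
  freqs <- attr(tf, "freqs")
  fs <- attr(tf, "sample_rate")
  edge <- attr(tf, "edge_half_width")
  n <- ncol(tf)
  len <- round(epoch_s * fs)
  bounds <- list(pre = c(onset - len, onset - 1),
                 during = c(onset, onset + len - 1),
                 post = c(onset + len, onset + 2 * len - 1))
  if (bounds$pre[1] < 1 || bounds$post[2] > n)
    stop("trial epochs do not fit within the recording")
  out <- list(freqs = freqs)
  for (ep in names(bounds)) {
    b <- bounds[[ep]]
    out[[ep]] <- vapply(seq_along(freqs), function(k) {
      lo <- b[1] + edge[k]
      hi <- b[2] - edge[k]
      if (lo > hi) return(NA_real_)
      mean(tf[k, lo:hi])
    }, numeric(1))
  }
  structure(out, class = "epoch_spectra")
}

#' Locate the endogenous spectral peak
#'
#' Finds the maximum of the pre-stimulation spectrum within the search
#' range.  A peak qualifies only if it exceeds `prominence` times the
#' median power over the range; otherwise the trial carries no
#' detectable endogenous rhythm and an error of class
#' `oscistim_no_peak` is thrown (callers exclude and log such trials).
#' Ties resolve to the lower frequency.
#'
#' @param spec an [epoch_spectra()] object.
#' @param search_range Hz, default 3-15.
#' @param prominence multiple of the range median, default 1.2.
#' @return peak frequency in Hz.
#' @export
find_endogenous_peak <- function(spec, search_range = c(3, 15),
                                 prominence = 1.2) {
  stopifnot(inherits(spec, "epoch_spectra"))
  sel <- which(spec$freqs >= search_range[1] &
               spec$freqs <= search_range[2] & !is.na(spec$pre))
  if (!length(sel)) stop("no valid frequencies in the search range")
  p <- spec$pre[sel]
  best <- which.max(p)
  if (p[best] < prominence * stats::median(p))
    stop(structure(class = c("oscistim_no_peak", "error", "condition"),
                   list(message = "no qualifying endogenous peak",
                        call = sys.call(-1))))
  spec$freqs[sel][best]
}

#' Modulation index
#'
#' Normalized band-power change between two epochs:
#' `(S_b2 - S_b1) / (S_b2 + S_b1)`, bounded in `[-1, 1]`.  Epoch 1 is
#' conventionally the pre-stimulation epoch.
#'
#' @param s_b1 mean band power in epoch 1 (>= 0).
#' @param s_b2 mean band power in epoch 2 (>= 0).
#' @return scalar in `[-1, 1]`.
#' @export
modulation_index <- function(s_b1, s_b2) {
  stopifnot(s_b1 >= 0, s_b2 >= 0)
  if (s_b1 + s_b2 == 0) stop("modulation index undefined: both powers zero")
  (s_b2 - s_b1) / (s_b2 + s_b1)
}

#' Band-average power from an epoch spectrum
#'
#' Mean power over `[center - width/2, center + width/2]`, inclusive
#' of grid points on both edges; NA frequencies (fully edge-excluded)
#' are dropped.
#'
#' @param spec an [epoch_spectra()] object.
#' @param epoch `"pre"`, `"during"`, or `"post"`.
#' @param center band center, Hz.
#' @param width full band width, Hz (3 for the endogenous band, 2 for
#'   the stimulation band).
#' @return mean band power.
#' @export
epoch_band_power <- function(spec, epoch, center, width) {
  stopifnot(inherits(spec, "epoch_spectra"),
            epoch %in% c("pre", "during", "post"))
  sel <- spec$freqs >= center - width / 2 & spec$freqs <= center + width / 2
  mean(spec[[epoch]][sel], na.rm = TRUE)
}

#' Per-state modulation-index statistics
#'
#' For each state: mean, SEM, and a one-sample t test of the MIs
#' against zero; for each state pair: a two-sample (pooled-variance) t
#' test of the difference.  Mirrors the combination of one-sample and
#' two-sample t tests used for stimulation-modulation ECoG analyses.
#'
#' @param mis_by_state named list of numeric MI vectors (>= 2 values
#'   each).
#' @param alpha significance level for the convenience flags.
#' @return list with data frames `per_state` (state, n, mean, sem, t,
#'   p, significant) and `pairs` (state1, state2, t, p, significant).
#' @export
compare_states <- function(mis_by_state, alpha = 0.05) {
  stopifnot(is.list(mis_by_state), length(mis_by_state) >= 1)
  for (v in mis_by_state) {
    if (length(v) < 2) stop("need >= 2 observations per state")
    if (stats::sd(v) == 0) stop("zero-variance group: t statistics degenerate")
  }
  per_state <- do.call(rbind, lapply(names(mis_by_state), function(st) {
    v <- mis_by_state[[st]]
    tt <- stats::t.test(v, mu = 0)
    data.frame(state = st, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)),
               t = unname(tt$statistic), p = tt$p.value,
               significant = tt$p.value < alpha)
  }))
  pairs <- NULL
  sts <- names(mis_by_state)
  if (length(sts) >= 2) {
    cmb <- utils::combn(sts, 2)
    pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      tt <- stats::t.test(mis_by_state[[cmb[1, j]]],
                          mis_by_state[[cmb[2, j]]], var.equal = TRUE)
      data.frame(state1 = cmb[1, j], state2 = cmb[2, j],
                 t = unname(tt$statistic), p = tt$p.value,
                 significant = tt$p.value < alpha)
    }))
  }
  list(per_state = per_state, pairs = pairs)
}

#' Peak-frequency shift test
#'
#' Compares per-trial spectral peak frequencies between two epochs
#' (e.g., pre-stimulation vs during-stimulation) with a two-sided
#' Wilcoxon rank-sum test and reports both medians.
#'
#' @param pre_peaks,post_peaks numeric vectors of per-trial peak
#'   frequencies (>= 3 each).
#' @return list: `median_pre`, `median_post`, `shift` (difference of
#'   medians), `p` (rank-sum).
#' @export
peak_shift_test <- function(pre_peaks, post_peaks) {
  if (length(pre_peaks) < 3 || length(post_peaks) < 3)
    stop("need >= 3 peak estimates per group")
  w <- stats::wilcox.test(pre_peaks, post_peaks, exact = FALSE)
  list(median_pre = stats::median(pre_peaks),
       median_post = stats::median(post_peaks),
       shift = stats::median(post_peaks) - stats::median(pre_peaks),
       p = w$p.value)
}

#' Modulation index versus distance from the stimulation site
#'
#' Splits electrodes into near (`distance < cutoff`) and far
#' (`distance >= cutoff`) groups by Euclidean distance from the
#' stimulation-pair midpoint and compares group MIs with a two-sample
#' t test.  Stimulation effects are expected to be confined to the
#' near group.
#'
#' @param mi numeric vector of modulation indices, one per entry.
#' @param electrode integer vector of electrode indices (parallel to
#'   `mi`).
#' @param layout an [make_layout()] object with a stimulation pair.
#' @param cutoff distance cutoff in mm, default 20 (strict `<` for
#'   near).
#' @return list with `near` and `far` summaries (n, mean, sem), the
#'   per-electrode `distance` vector, and `p` (two-sample t, `NA` with
#'   a warning when either group is empty).
#' @export
mi_vs_distance <- function(mi, electrode, layout, cutoff = 20) {
  stopifnot(length(mi) == length(electrode))
  d_all <- stim_distances(layout)
  d <- d_all[electrode]
  near <- mi[d < cutoff]
  far <- mi[d >= cutoff]
  summ <- function(v) list(n = length(v), mean = mean(v),
                           sem = stats::sd(v) / sqrt(length(v)))
  p <- NA_real_
  if (!length(near) || !length(far)) {
    warning("empty distance group: comparison skipped")
  } else if (length(near) >= 2 && length(far) >= 2) {
    p <- stats::t.test(near, far, var.equal = TRUE)$p.value
  }
  list(near = summ(near), far = summ(far), distance = d, p = p)
}
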