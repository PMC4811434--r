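#' Multichannel recording container
#'
#' Minimal container for (real or synthetic) multichannel
#' electrophysiology: a channels x samples matrix plus sampling rate,
#' channel labels, optional electrode layout, and stimulation-train
#' onset sample indices.
#'
#' @param data numeric matrix, channels x samples.
#' @param sample_rate sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @param layout an [make_layout()] object, or `NULL`.
#' @param trial_onsets integer sample indices (1-based) of
#'   stimulation-train starts.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(data, sample_rate, channel_labels = NULL,
                          layout = NULL, trial_onsets = integer()) {
  stopifnot(is.matrix(data), is.numeric(data), all(is.finite(data)),
            sample_rate > 0)
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  stopifnot(length(channel_labels) == nrow(data))
  trial_onsets <- as.integer(trial_onsets)
  if (length(trial_onsets) &&
      (any(trial_onsets < 1) || any(trial_onsets > ncol(data))))
    stop("trial_onsets outside the recording")
  structure(list(data = data, sample_rate = sample_rate,
                 channel_labels = channel_labels, layout = layout,
                 trial_onsets = trial_onsets),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate))
  if (length(x$trial_onsets))
    cat("  stimulation onsets at sample(s):",
        paste(x$trial_onsets, collapse = ", "), "\n")
  invisible(x)
}

#' Rectangular electrode grid layout
#'
#' Positions `n_rows * n_cols` electrodes on a rectangular lattice with
#' the given inter-electrode spacing (clinical ECoG grids use 10 mm).
#' Electrodes are ordered row-major, so the first two electrodes of any
#' multi-electrode layout are adjacent; these form the default
#' stimulation pair.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param spacing inter-electrode distance in mm.
#' @return object of class `electrode_layout`: `positions` (n x 2 matrix
#'   of x, y in mm), `labels`, and `stim_pair` (indices of the two
#'   stimulated electrodes, `NULL` with a warning for a single-electrode
#'   layout).
#' @export
make_layout <- function(n_rows, n_cols, spacing = 10) {
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be >= 1")
  if (spacing <= 0) stop("spacing must be positive")
  pos <- cbind(x = rep((seq_len(n_cols) - 1) * spacing, times = n_rows),
               y = rep((seq_len(n_rows) - 1) * spacing, each = n_cols))
  n <- nrow(pos)
  stim_pair <- if (n >= 2) c(1L, 2L) else NULL
  if (is.null(stim_pair))
    warning("single-electrode layout: no stimulation pair defined")
  structure(list(positions = pos,
                 labels = sprintf("E%02d", seq_len(n)),
                 spacing = spacing, n_rows = n_rows, n_cols = n_cols,
                 stim_pair = stim_pair),
            class = "electrode_layout")
}

#' Electrode distances from the stimulation-pair midpoint
#'
#' @param layout an [make_layout()] object with a stimulation pair.
#' @return numeric vector of Euclidean distances in mm.
#' @export
stim_distances <- function(layout) {
  stopifnot(inherits(layout, "electrode_layout"))
  if (is.null(layout$stim_pair)) stop("layout has no stimulation pair")
  mid <- colMeans(layout$positions[layout$stim_pair, , drop = FALSE])
  sqrt(colSums((t(layout$positions) - mid)^2))
}
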