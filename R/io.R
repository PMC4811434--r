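#' Write a recording to a trial directory
#'
#' Internal exchange format: one whitespace-delimited text file with
#' the channels x samples matrix (one row per channel) plus a JSON
#' sidecar holding the sampling rate, channel labels, electrode layout,
#' and stimulation onsets.
#'
#' @param rec a [raw_recording()].
#' @param dir output directory (created if needed).
#' @param name file stem, default "trial".
#' @return `dir`, invisibly.
#' @export
write_trial <- function(rec, dir, name = "trial") {
  stopifnot(inherits(rec, "raw_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(rec$data, file.path(dir, paste0(name, "_data.txt")),
                     row.names = FALSE, col.names = FALSE)
  meta <- list(sample_rate = rec$sample_rate,
               channel_labels = rec$channel_labels,
               trial_onsets = rec$trial_onsets)
  if (!is.null(rec$layout))
    meta$layout <- list(n_rows = rec$layout$n_rows,
                        n_cols = rec$layout$n_cols,
                        spacing = rec$layout$spacing,
                        stim_pair = rec$layout$stim_pair)
  jsonlite::write_json(meta, file.path(dir, paste0(name, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a recording from a trial directory
#'
#' @param dir directory written by [write_trial()].
#' @param name file stem, default "trial".
#' @return a [raw_recording()].
#' @export
read_trial <- function(dir, name = "trial") {
  data <- as.matrix(utils::read.table(
    file.path(dir, paste0(name, "_data.txt"))))
  dimnames(data) <- NULL
  meta <- jsonlite::read_json(file.path(dir, paste0(name, "_meta.json")),
                              simplifyVector = TRUE)
  layout <- NULL
  if (!is.null(meta$layout)) {
    layout <- make_layout(meta$layout$n_rows, meta$layout$n_cols,
                          meta$layout$spacing)
    layout$stim_pair <- as.integer(meta$layout$stim_pair)
  }
  raw_recording(data, meta$sample_rate, meta$channel_labels, layout,
                trial_onsets = meta$trial_onsets %||% integer())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
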