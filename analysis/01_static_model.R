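#!/usr/bin/env Rscript
# Static threshold-summation model: how behavioral state (oscillation
# strength) gates the response to 10 Hz pulse stimulation.
#
# Writes results/static/: the per-state spectral peaks and the
# two-parameter strength sweep matrices.

library(oscistim)

out_dir <- "results/static"
res <- run_model_study("static", out_dir = out_dir)

peaks <- vapply(res$regimes, `[[`, numeric(1), "peak")
cat("Dominant output peak by state (7 Hz endogenous, 10 Hz pulses):\n")
print(peaks)
cat("\nWith a strong oscillation the output stays at the endogenous",
    "frequency;\nwith the oscillation suppressed the pulse train",
    "entrains the output at 10 Hz.\n\n")

sw <- res$sweep
ps <- sw$power_stim[which.min(abs(sw$osc_grid - 1.5)), ]
cat("Stimulation-frequency power along the stimulation-strength axis",
    "(oscillation strength 1.5):\n")
print(signif(ps, 3))
cat("monotone nondecreasing:", all(diff(ps) >= 0), "\n\n")

d <- sw$delta_power_osc[, which.min(abs(sw$stim_grid - 1))]
cat("Endogenous-band power change along the oscillation-strength axis",
    "(stimulation strength ~1):\n")
print(signif(d, 3))
cat("interior maximum at oscillation strength",
    sw$osc_grid[which.max(d)], "\n")
cat("\nTables written to", out_dir, "\n")
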