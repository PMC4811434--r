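# Shared fixtures: a small clinical-style grid and a fast trial config.

test_layout <- function() make_layout(2, 4, 10)

test_config <- function(seed = 1L, ...) {
  synthetic_trial_config(seed = seed, ...)
}

# 0.5-40 Hz zero-phase band-pass, used to compare cleaned vs true
# signals on the band the analysis actually uses.
bandpass_05_40 <- function(x, fs) {
  bf <- signal::butter(4, c(0.5, 40) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}
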