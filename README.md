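# oscistim

Forward models and analysis tools for studying how 10 Hz periodic
direct cortical stimulation interacts with endogenous alpha
oscillations as a function of behavioral state (eyes closed, eyes
open, task engaged). Intended for computational neuroscientists and
electrophysiologists who need a tested, fully synthetic-data-driven
reimplementation of this modeling-and-analysis chain.

The package implements:

* **A static threshold-summation model.** An endogenous sine of
  amplitude *A* (behavioral state) plus the convolution of a 10 Hz
  pulse train with the response kernel *f(t) = t·e^(−0.01t)* (unit
  peak, scaled by stimulation strength *S*), gated by a threshold:
  output = sine + response where the sum exceeds 0, else the bare
  sine. Strong oscillations confine the response to a narrow phase
  band; suppressed oscillations (A below the train's ~0.13·S Fourier
  amplitude at 10 Hz) let the output entrain at the stimulation
  frequency.
* **A delayed-feedback oscillator network.** N excitatory/inhibitory
  units with sparse 1/(ρN) connectivity, a logistic rate function
  (slope 35), a 65 ms thalamo-cortical loop that generates the alpha
  rhythm and a 290 ms cortico-cortical loop, integrated with an
  Euler–Maruyama scheme (Rcpp); the synthetic ECoG is the population
  average of V_e + V_i.
* **Template-matching stimulation-artifact removal.** Upsample to
  3200 Hz, detect pulse times on the highest-artifact channel (6 MAD
  threshold), subtract a five-event moving-average template per
  channel with least-squares scaling and edge-offset correction,
  downsample.
* **Spectral analysis and statistics.** 60 Hz notch, common average
  reference, Morlet-wavelet power on a dual-resolution grid (0.5–20 Hz
  by 0.1, 21–80 Hz by 1), pre/during/post epoch spectra, the
  modulation index MI = (S_b2 − S_b1)/(S_b2 + S_b1) on the endogenous
  (peak ± 1.5 Hz) and stimulation (9–11 Hz) bands, one- and two-sample
  t tests, a rank-sum peak-shift test, and distance-resolved
  modulation around the stimulation pair.
* **A seeded synthetic-ECoG generator** producing clean /
  contaminated / artifact-only ground-truth triples with
  state-dependent alpha, 1/f background, line noise, and stereotyped
  10 ms biphasic artifacts decaying with distance.

## Worked example

The numbered drivers under `analysis/` run the studies end to end and
write their tables under `results/`. The core of the static study:

```r
library(oscistim)

for (state in names(static_state_amplitudes())) {
  p <- static_model_params(osc_amplitude = static_state_amplitudes()[[state]])
  sp <- periodogram_power(simulate_static(p)$output, p$sample_rate)
  cat(state, spectral_peak_freq(sp$freq, sp$power, c(1, 40)), "Hz\n")
}
```

```
eyes_closed 7 Hz
eyes_open 7 Hz
task 10 Hz
```

With the 7 Hz oscillation strong (eyes closed) the output spectrum
stays at the endogenous frequency; with the oscillation suppressed
(task engaged) the 10 Hz pulse train dominates — entrainment. The
end-to-end synthetic analysis (`analysis/04_state_modulation.R`)
recovers the same state dependence from generated ECoG after artifact
removal and preprocessing:

```
One-sample t tests of the stimulation-band MIs against zero:
        state  n   mean    sem    t        p significant
1 eyes_closed 24 0.0278 0.0232 1.20 0.242040       FALSE
2   eyes_open 24 0.0449 0.0282 1.59 0.124929       FALSE
3        task 16 0.2912 0.0632 4.61 0.000343        TRUE
```

Only the task-engaged state shows a significant stimulation-band
power increase (MI ≈ 0.29): the planted entrainment effect, recovered
through the full cleaning-and-analysis chain.

The artifact-removal QC (`analysis/03_artifact_removal.R`) reports,
per trial, all 50 pulses detected, cleaned-vs-truth correlations
≥ 0.99 in 0.5–40 Hz, and residual pulse harmonics reduced from ~25 dB
to ~2 dB above the local spectral floor.

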