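---
title: "Models and methods: state-dependent modulation of cortical alpha oscillations by periodic stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscistim)
```

# The scientific problem

Cortical alpha oscillations (~7-13 Hz) wax and wane with behavioral
state: strongest with eyes closed, weaker with eyes open, suppressed
during task engagement. When the cortex is stimulated with a 10 Hz
pulse train, the response depends on that state: a robust endogenous
rhythm is barely perturbed, an intermediate rhythm can be enhanced at
its own frequency, and a suppressed rhythm lets the network follow the
stimulation frequency (entrainment). This package implements two
forward models of this state dependence, the ECoG preprocessing needed
to observe it around large stimulation artifacts, and the
modulation-index statistics used to quantify it, together with a
synthetic-ECoG generator so the whole chain is testable without
patient recordings.

# The static threshold-summation model

The endogenous oscillation is a pure sine of amplitude $A$ (the
"oscillation strength", encoding behavioral state) and frequency 7 Hz.
The cortical response to a pulse train at 10 Hz is the linear
convolution of unit impulses with the response kernel

$$f(t) = t\,e^{-0.01 t}, \quad t \text{ in ms},$$

normalized to unit peak and scaled by the stimulation strength $S$.
The output applies a single nonlinearity: at samples where
$\text{sine} + \text{response}$ fails to exceed the threshold (default
0), the output reverts to the bare sine. Phase-dependent gating of the
stimulation response, and hence all the state dependence, follows from
this rule.

## Regime geometry and the state amplitudes

The kernel is smooth on the 100 ms pulse period, so the steady-state
response to the train is mostly a DC pedestal with a ripple at the
pulse rate. The ripple's 10 Hz Fourier amplitude, per unit stimulation
strength, is

$$\frac{2\,|K(10\,\mathrm{Hz})|}{T \cdot k_{peak}} \approx 0.13,
\qquad K(\omega) = \frac{1}{(0.01 + i\omega)^2},$$

with $T = 100$ ms. The output spectrum is therefore dominated by the
stimulation frequency only when the oscillation amplitude lies below
roughly $0.13\,S$: that threshold *is* the boundary of the entrainment
regime. The package's illustrative state amplitudes are 5 (eyes
closed), 1.5 (eyes open), and 0.1 (task engaged), in units of the
kernel peak: the first far above the boundary, the last safely inside
the entrainment region. These are model constants chosen to place each
state in its qualitative regime; they are not measured quantities.

```{r static, eval = FALSE}
p <- static_model_params(osc_amplitude = static_state_amplitudes()[["task"]])
sim <- simulate_static(p)
sp <- periodogram_power(sim$output, p$sample_rate)
spectral_peak_freq(sp$freq, sp$power, c(1, 40))  # 10
```

Other numerical choices: 1 kHz sampling over 5 s (resolving both tones
exactly on the 0.2 Hz periodogram grid), kernel support truncated at
1000 ms (below 0.005% of peak), rectangular-window periodogram
(deterministic and adequate for pure tones), and band power in a
±0.5 Hz band normalized by the total 0.5-40 Hz power of the matched
no-stimulation run. The "(0, 0)" sweep cell, whose reference run
carries no power, reports 0 when the band power is itself 0.

# The delayed-feedback oscillator network

`simulate_network()` integrates $N = 100$ excitatory/inhibitory unit
pairs (the population size is not part of the published parameter
table; 100 is large enough for the $1/(\rho N)$ synaptic scaling to
self-average) with sparse Bernoulli connectivity ($\rho = 0.8$,
nonzero weights $1/(\rho N)$, i.i.d. entries so self-connections are
permitted), a logistic rate function of slope 35, a thalamo-cortical
feedback loop of delay 65 ms (gain $-0.5$) through which the alpha
rhythm emerges, and a cortico-cortical loop of delay 290 ms (gain
$0.85$). Integration is Euler-Maruyama with noise increment
$\sqrt{2 D \, dt}\,\eta / \tau$, zero-initialized history, and a
discarded 2 s burn-in; the synthetic ECoG is the population average of
$V_e + V_i$ at every step, later block-averaged to 1 kHz for spectral
analysis with the same machinery applied to data.

## Choices where the published description is not self-consistent

Three aspects of the published parameter table cannot be integrated
literally and reproduce the described dynamics; each was resolved by
fixed-point analysis and simulation, and each resolution is exposed as
an explicit parameter rather than hidden.

**State input.** With the baseline input $-0.23$ *added* to the state
inputs (0 / 0.27 / 0.50), the resting state lands at total input
$-0.23$, which places the network in a quiet low-potential attractor:
no alpha rhythm exists there (the oscillatory window in total input is
roughly $[-0.15, +0.05]$), and the eyes-open state would carry the
*strongest* rhythm — inverting the described state ordering. Reading
the state input as the *total* excitatory input (equivalently,
`I_bias = 0`, the default of `network_study_config()`) puts the
resting state inside the oscillatory window (self-sustained ~7 Hz
rhythm), the eyes-open state just past its edge (damped resonance),
and the task state deep in the damped region — exactly the described
phenomenology.

**Stimulation drive.** The published biphasic pulse (+S for 200 µs,
then −S for 200 µs, S = 0.2) is charge balanced; resolved exactly at
$dt = 0.1$ ms it produces no measurable response in any state. A 1 ms
integration step cannot represent the reversal phase at all — the
drive such a step actually delivers is +S for the single onset step.
`stimulus_protocol(phase_width = 1000, biphasic = FALSE)` reproduces
that effective drive at any step size and is what the network studies
use; the printed waveform remains available and tested.

**Outlasting effects.** The cortico-cortical loop can only sustain
activity if membrane potentials reach its threshold $h_2 = 0.15$.
Under the conventions above, every state's operating point lies in
$[-0.63, -0.15]$, stimulation-driven excursions are ~0.02, and the
resting-state limit cycle tops out near $-0.1$ — the loop never
activates, and post-stimulation power returns to baseline regardless
of the cortico-cortical gain. A tenfold larger noise convention
($\sqrt{2 D\, dt}\,\eta$ without the $1/\tau$ factor, a defensible
reading of the published noise term) does produce outlasting
enhancement at intermediate input, but it buries the task-state 10 Hz
entrainment in noise and drags the resting-state peak below 7 Hz. No
single convention yields all of the published signatures; the package
keeps the standard Euler-Maruyama convention, and the outlasting
contrast is reported as not reproduced. Relatedly, the eyes-open and
task states differ only in the damping of an almost-silent resonance,
so the eyes-open ≥ task alpha-power ordering is not resolvable at
desk-scale run lengths; the decisive, tested ordering is the resting
state's dominance over both.

# Stimulation-artifact removal

The template-matching chain: upsample each channel 4x (800 to 3200
samples/s), detect artifact times on the single reference channel with
the most ~100 Hz power (threshold 6 MADs on a tile-wise
cubic-detrended trace, 50 ms refractory), then per channel extract
peak-aligned segments around each event, build the event's template as
the moving average of five detrended segments (the event itself, two
before, two after; fewer at the ends), scale it by least-squares
projection onto the segment, subtract, remove the residual edge step
by subtracting the line between edge offsets, and downsample back.

Four refinements proved necessary for clean subtraction and are worth
recording:

* **Alignment.** A biphasic deflection has two near-equal lobes, so
  single-event peak picking flips lobes event to event and smears the
  template. Events are aligned by cross-correlation against the grand
  mean segment, then recentered on the artifact's energy centroid so
  the asymmetric deflection-plus-ringing sits symmetrically inside the
  segment.
* **Detrend basis.** Each segment's smooth background is fitted only
  on the outer 20% of the segment at each end (a fit through the
  middle would absorb the S-shaped artifact itself) with a line plus a
  sine/cosine pair at the mains frequency: 60 Hz is exactly
  phase-locked to a 10 Hz pulse grid (six cycles per pulse), so
  without those regressors the line component enters the template
  coherently and its gated subtraction manufactures sidebands at
  pulse-rate harmonics.
* **Stereotypy guard.** Subtraction is skipped when the template's
  energy is not clearly above the between-segment scatter (ratio below
  4; pure noise gives ~$m/(m-1)$). Without this, re-running removal or
  cleaning an artifact-free channel would project genuine signal onto
  a noise template.
* **Band-limited resampling.** Upsampling uses FFT zero-padding
  rather than linear interpolation, whose sinc² droop (~1% at 40 Hz)
  would dominate round-trip error budgets.

On synthetic ground truth (artifact peak 20x the resting alpha
amplitude — the true ratio is unpublished, so it is a config
parameter), cleaned channels correlate ≥ 0.99 with the clean truth in
0.5-40 Hz and residual pulse harmonics sit within ~2 dB of the local
spectral floor, down from ~25 dB. The residual-harmonic QC
(`harmonic_excess_db()`) uses a Welch spectrum with 1 s segments: the
chance fluctuation of a single raw periodogram bin is several dB, so
only an averaged estimate makes a small dB bound meaningful.

# Spectral analysis and statistics

After cleaning: a second-order IIR biquad notch at 60 Hz (Q = 30,
zero-phase), then common average referencing. Power spectra come from
complex Morlet wavelets (7 cycles — conventional, and the subsequent
band averaging makes results insensitive to it) on the dual-resolution
grid 0.5-20 Hz by 0.1 plus 21-80 Hz by 1 (256 frequencies). Wavelet
envelopes are normalized to unit gain at their center frequency, so a
unit tone yields time-mean power 0.25 at its own frequency and the
peak is unbiased on the grid. Samples within two envelope standard
deviations of trial edges and epoch boundaries are excluded from epoch
means (capped at 1.5 s: at 0.5 Hz the full exclusion would swallow an
entire 5 s epoch), preventing stimulation-epoch power from bleeding
into the flanking epochs.

The endogenous band is the pre-stimulation spectral peak (searched in
3-15 Hz, required to exceed 1.2x the range median — an uninformative
spectrum excludes the trial) ± 1.5 Hz; the stimulation band is
9-11 Hz; both inclusive of edge grid points. The modulation index is
$(S_{b2} - S_{b1}) / (S_{b2} + S_{b1})$, epoch 1 being pre-stimulation.
Statistics are one-sample t tests of MIs against zero, pooled-variance
two-sample t tests between states, a two-sided Wilcoxon rank-sum test
for peak-frequency shifts, and a near/far split at 20 mm (strict `<`
for near) from the stimulation-pair midpoint for distance-resolved
modulation. MIs are tabulated per state x trial x electrode x band x
epoch pair, so any aggregation convention can be applied downstream.

# The synthetic-ECoG generator

Each 15 s, 800 Hz trial (5 s pre / 5 s stimulation / 5 s post) carries
a state-scaled alpha sinusoid at 7.1 Hz (amplitudes 10 / 4 / 1 for
eyes closed / eyes open / task), pink ($1/f$) background noise of SD
2, and a common 60 Hz line component of amplitude 1 — values chosen
once as a realistic field-potential mixture with a clearly visible
state ladder. Oscillatory components get per-channel phase jitter
(SD 0.1 rad) and per-channel amplitude gains drawn from U(0.5, 1.5):
without that spatial topography a perfectly coherent rhythm would be
annihilated by common average referencing, which real rhythms are not.
Two fields plant ground-truth stimulation effects: a during-epoch
alpha amplitude factor (for modulation-index recovery tests, where a
factor $k$ must return $\mathrm{MI} = (k^2-1)/(k^2+1)$) and a
during-epoch 10 Hz component (amplitudes 0 / 0.5 / 1.5 by state,
emulating state-dependent entrainment). Artifacts are one cycle of a
raised-cosine-windowed sine (~10 ms, biphasic, exactly zero-mean),
repeating at 10 Hz for 5 s, scaled per channel by
$\exp(-d/10\,\mathrm{mm})$ from the stimulation-pair midpoint.

What the generator does *not* emulate — and hence what passing tests
do not establish about recordings: volume conduction and realistic
spatial correlation of the background, non-sinusoidal or drifting
alpha waveforms, amplifier saturation near the stimulating electrodes,
epileptiform transients, distance dependence of the planted
entrainment effect, and artifact shape variation across pulses (the
injected artifact is perfectly stereotyped, which is the regime the
template method assumes).

# Problem sizes

The bundled studies and tests use desk-scale sizes chosen to keep the
full suite comfortably reproducible: 8-electrode grids, 3 trials per
state in the end-to-end analysis, 10 seeds for the network-state
criteria at $dt = 0.1$ ms, coarser $dt = 0.5$ ms (delays remain exact
multiples) for unit-level network properties, and 20 trials for the
artifact-removal fidelity sweep.
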