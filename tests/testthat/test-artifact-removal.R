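test_that("the reference channel is the one with the largest injected artifact", {
  lay <- test_layout()
  tr <- generate_trial(test_config(seed = 4), lay, "eyes_closed")
  ref <- select_artifact_channel(tr$contaminated)
  gains <- exp(-stim_distances(lay) / 10)
  # the stim-pair channels share the maximal gain; either is correct
  expect_true(ref %in% which(gains == max(gains)))

  # all-identical channels resolve to the first (tie rule)
  same <- tr$contaminated
  for (ch in 2:nrow(same$data)) same$data[ch, ] <- same$data[1, ]
  expect_equal(select_artifact_channel(same), 1L)

  single <- raw_recording(tr$contaminated$data[1, , drop = FALSE], 800,
                          trial_onsets = tr$contaminated$trial_onsets)
  expect_equal(select_artifact_channel(single), 1L)

  no_stim <- raw_recording(tr$contaminated$data, 800)
  expect_error(select_artifact_channel(no_stim), "stimulation window")
})

test_that("piecewise cubic detrending kills smooth trends and keeps transients", {
  n <- 3200
  tt <- seq_len(n)
  cubic <- 2 + 0.01 * tt - 3e-6 * tt^2 + 5e-10 * tt^3
  out <- poly_detrend(cubic, 320)
  expect_lt(max(abs(out)), 1e-6 * max(abs(cubic)))

  spike <- numeric(n)
  spike[1600:1603] <- 40
  out <- poly_detrend(cubic + spike, 320)
  expect_lt(abs(max(out) - 40) / 40, 0.05)

  tone <- sin(2 * pi * 100 * (tt - 1) / 3200)
  out <- poly_detrend(tone, 320)                # 100 ms windows
  expect_gt(max(abs(out)), 0.9)

  expect_error(poly_detrend(1:10, 4), ">= 8")
  expect_error(poly_detrend(1:10, 100), "longer than signal")
})

test_that("threshold detection finds every pulse within one upsampled sample", {
  lay <- test_layout()
  tr <- generate_trial(test_config(seed = 6), lay, "eyes_closed")
  res <- remove_artifacts(tr$contaminated)
  expect_length(res$events$times, 50)
  # offsets from the injected onsets: one consistent lobe-alignment
  # constant (the waveform's two lobes are equal, so which lobe anchors
  # the peak is a convention), with at most +/- 1 sample jitter
  onsets_up <- (tr$true_artifact_times - 1L) * 4L + 1L
  offs <- res$events$times - onsets_up
  expect_true(all(abs(offs - stats::median(offs)) <= 1))
  wf_len_up <- length(artifact_waveform(tr$spec, 3200))
  expect_true(stats::median(offs) >= 0 &&
              stats::median(offs) <= wf_len_up)

  # amplitude rescaling leaves detected times unchanged (MAD scaling)
  scaled <- tr$contaminated
  scaled$data <- scaled$data * 2
  res2 <- remove_artifacts(scaled)
  expect_identical(res2$events$times, res$events$times)

  # flat noise below threshold yields no events
  set.seed(1)
  ev <- detect_artifact_times(rnorm(5000), threshold_k = 6,
                              min_separation = 100)
  expect_length(ev$times, 0)
})

test_that("template subtraction nearly eliminates a pure artifact train", {
  lay <- test_layout()
  tr <- generate_trial(test_config(seed = 8), lay, "eyes_closed")
  art <- tr$artifact_only
  # detection needs background noise for its MAD floor; take times
  # from the contaminated pipeline and clean the artifact-only track
  det <- remove_artifacts(tr$contaminated)
  res <- remove_artifacts(art, events = det$events)
  for (ch in c(1, 4, 8)) {
    expect_lt(stats::sd(res$cleaned$data[ch, ]),
              0.05 * stats::sd(art$data[ch, ]))
  }
})

test_that("cleaning recovers the underlying signal on every channel", {
  lay <- test_layout()
  for (s in c(21, 22)) {
    tr <- generate_trial(test_config(seed = s), lay, "eyes_closed")
    res <- remove_artifacts(tr$contaminated)
    for (ch in seq_len(nrow(lay$positions))) {
      r <- cor(bandpass_05_40(res$cleaned$data[ch, ], 800),
               bandpass_05_40(tr$clean$data[ch, ], 800))
      expect_gt(r, 0.95)
    }
    hx <- vapply(seq_len(nrow(lay$positions)), function(ch)
      max(harmonic_excess_db(res$cleaned$data[ch, ], 800)), numeric(1))
    expect_lt(max(hx), 3)
  }
})

test_that("subtraction is local: samples away from every event are untouched", {
  lay <- test_layout()
  tr <- generate_trial(test_config(seed = 9), lay, "eyes_closed")
  up <- resample_by(tr$contaminated$data[3, ], 4, 800, "up")
  det <- remove_artifacts(tr$contaminated)
  half <- det$events$segment_half_width
  out <- oscistim:::subtract_templates(up, det$events$times, half,
                                       fs = 3200, line_freq = 60)
  # conservative margin: half-width plus the alignment search radius
  margin <- half + 16L
  touched <- rep(FALSE, length(up))
  for (t0 in det$events$times) {
    lo <- max(1L, t0 - margin)
    hi <- min(length(up), t0 + margin)
    touched[lo:hi] <- TRUE
  }
  expect_identical(out[!touched], up[!touched])
})

test_that("resampling round-trips low-frequency content below 0.1% RMS", {
  set.seed(3)
  fs <- 800
  t <- (0:7999) / fs
  x <- sin(2 * pi * 9 * t) + 0.5 * sin(2 * pi * 43 * t) +
    0.2 * sin(2 * pi * 87 * t)
  up <- resample_by(x, 4, fs, "up")
  back <- resample_by(up, 4, fs * 4, "down")[seq_along(x)]
  core <- 400:7600                             # away from filter edges
  expect_lt(sqrt(mean((back[core] - x[core])^2)) / sqrt(mean(x[core]^2)),
            0.001)
})

test_that("edge events and re-runs behave gracefully", {
  lay <- test_layout()
  tr <- generate_trial(test_config(seed = 10), lay, "eyes_closed")

  # no events: pass-through with a warning
  ev0 <- structure(list(times = integer(), threshold = 1,
                        reference_channel = 1L,
                        segment_half_width = NA_integer_),
                   class = "artifact_events")
  expect_warning(res0 <- remove_artifacts(tr$contaminated, events = ev0),
                 "unchanged")
  expect_identical(res0$cleaned$data, tr$contaminated$data)

  # events hugging the recording boundary are truncated (once per
  # channel), not fatal
  evb <- remove_artifacts(tr$contaminated)$events
  evb$times <- c(5L, evb$times)
  w <- capture_warnings(remove_artifacts(tr$contaminated, events = evb))
  expect_true(all(grepl("truncated", w)))
  expect_length(w, nrow(tr$contaminated$data))

  # second pass changes almost nothing relative to the first pass
  res1 <- remove_artifacts(tr$contaminated)
  first_delta <- sqrt(mean((res1$cleaned$data - tr$contaminated$data)^2))
  res2 <- remove_artifacts(res1$cleaned, events = res1$events)
  second_delta <- sqrt(mean((res2$cleaned$data - res1$cleaned$data)^2))
  expect_lt(second_delta, 0.01 * first_delta)
})
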