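make_rec <- function(data, fs = 800) raw_recording(data, fs)

test_that("preprocessing notches the line and removes the common mode", {
  fs <- 800
  t <- (0:3999) / fs
  base <- rbind(sin(2 * pi * 7 * t), cos(2 * pi * 7 * t),
                0.5 * sin(2 * pi * 13 * t))
  common <- 2 * sin(2 * pi * 10 * t)
  line <- sin(2 * pi * 60 * t)
  rec <- make_rec(base + rep(1, 3) %o% (common + line))
  out <- preprocess(rec)

  # common average reference: zero mean across channels at every sample
  expect_lt(max(abs(colMeans(out$data))), 1e-10)

  # a common-mode component identical on all channels vanishes
  rec2 <- make_rec(base)
  out2 <- preprocess(rec2)
  expect_equal(out$data, out2$data, tolerance = 1e-6)

  # pure 60 Hz attenuated by >= 20 dB
  z <- sin(2 * pi * 60 * t)
  zn <- notch_filter(z, fs, 60)
  expect_lt(20 * log10(stats::sd(zn) / stats::sd(z)), -20)

  expect_warning(preprocess(make_rec(base[1, , drop = FALSE])),
                 "single channel")
})

test_that("Morlet power peaks at the tone frequency and scales quadratically", {
  fs <- 800
  t <- (0:7999) / fs
  x <- sin(2 * pi * 10 * t)
  tf <- morlet_power(x, fs)
  fg <- attr(tf, "freqs")
  expect_length(fg, 256)                       # 196 fine + 60 coarse
  mp <- rowMeans(tf)
  expect_equal(fg[which.max(mp)], 10)

  tf2 <- morlet_power(2 * x, fs)
  mid <- 2000:6000                             # away from edges
  expect_equal(rowMeans(tf2[, mid]) / rowMeans(tf[, mid]),
               rep(4, 256), tolerance = 1e-6)

  expect_error(morlet_power(x, fs, freqs = c(10, 500)), "Nyquist")
})

test_that("epoch averaging respects boundaries and edge exclusion", {
  fs <- 800
  n <- 15 * fs
  t <- (seq_len(n) - 1) / fs
  onset <- 5 * fs + 1

  # stationary signal: the three epoch spectra agree closely
  set.seed(2)
  x <- sin(2 * pi * 9 * t) + rnorm(n, 0, 0.1)
  es <- epoch_spectra(morlet_power(x, fs), onset)
  sel <- which(es$freqs >= 8 & es$freqs <= 10)
  gap <- max(abs(es$during[sel] - es$pre[sel]) / es$pre[sel])
  expect_lt(gap, 0.10)

  # a tone confined to the middle epoch stays out of the flanks
  y <- numeric(n)
  mid <- t >= 5 & t < 10
  y[mid] <- sin(2 * pi * 10 * t[mid])
  es2 <- epoch_spectra(morlet_power(y + rnorm(n, 0, 0.02), fs), onset)
  i10 <- which.min(abs(es2$freqs - 10))
  expect_gt(es2$during[i10], 5 * es2$pre[i10])

  expect_error(epoch_spectra(morlet_power(x[1:6000], fs), onset),
               "do not fit")
})

test_that("endogenous peak detection reports, rejects, and tie-breaks", {
  fs <- 800
  n <- 15 * fs
  t <- (seq_len(n) - 1) / fs
  x <- 2 * sin(2 * pi * 7.1 * t) + rnorm(n, 0, 0.3)
  es <- epoch_spectra(morlet_power(x, fs), 5 * fs + 1)
  expect_equal(find_endogenous_peak(es), 7.1)

  # flat spectrum: no qualifying peak
  flat <- es
  flat$pre <- rep(1, length(flat$freqs))
  expect_error(find_endogenous_peak(flat), class = "oscistim_no_peak")

  # exact tie resolves to the lower frequency
  two <- flat
  two$pre[two$freqs %in% c(7, 9)] <- 5
  expect_equal(find_endogenous_peak(two), 7)
})

test_that("the modulation index obeys its arithmetic and bounds", {
  expect_equal(modulation_index(3, 3), 0)
  expect_equal(modulation_index(0, 2), 1)
  expect_equal(modulation_index(3, 1), -0.5)
  expect_error(modulation_index(0, 0), "undefined")

  grid <- seq(0, 5, by = 0.25)
  for (a in grid) for (b in grid) {
    if (a + b == 0) next
    mi <- modulation_index(a, b)
    expect_lte(abs(mi), 1)
    expect_equal(mi, -modulation_index(b, a))
  }
})

test_that("state comparisons reproduce closed-form t statistics", {
  cs <- compare_states(list(g = c(1, 2, 3)))
  expect_equal(cs$per_state$t, 3.464, tolerance = 1e-3)
  expect_equal(cs$per_state$p, 0.0742, tolerance = 1e-3)

  # equal-mean groups give a zero two-sample statistic
  cs2 <- compare_states(list(a = c(1, 2, 3), b = c(0.5, 2, 3.5)))
  expect_equal(cs2$pairs$t, 0, tolerance = 1e-12)

  expect_error(compare_states(list(a = c(1, 1, 1))), "zero-variance")
  expect_error(compare_states(list(a = 1)), ">= 2")

  # power: n = 50 MIs ~ N(0.05, 0.02) detected in >= 99% of replicates
  set.seed(42)
  hits <- mean(vapply(1:200, function(i) {
    v <- rnorm(50, 0.05, 0.02)
    compare_states(list(x = v))$per_state$significant
  }, logical(1)))
  expect_gte(hits, 0.99)
})

test_that("the peak-shift test sees a pure shift and not identity", {
  expect_equal(peak_shift_test(c(8.9, 9, 9.1), c(8.9, 9, 9.1))$shift, 0)
  expect_equal(stats::median(c(8.9, 9.0, 9.1)), 9.0)

  set.seed(7)
  pre <- rnorm(20, 7.1, 0.3)
  post <- pre + 2
  res <- peak_shift_test(pre, post)
  expect_equal(res$shift, 2, tolerance = 1e-9)
  expect_lt(res$p, 0.01)

  expect_error(peak_shift_test(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("distance grouping splits at the cutoff and resolves a decay", {
  lay <- test_layout()
  d <- stim_distances(lay)
  expect_equal(d[1], 5)                        # stim pair midpoint (5, 0)

  # an electrode exactly at the cutoff belongs to the far group
  mi <- rep(0.1, length(d))
  res <- mi_vs_distance(mi, seq_along(d), lay, cutoff = max(d))
  expect_equal(res$far$n, sum(d >= max(d)))

  # exponentially decaying effects concentrate in the near group
  set.seed(1)
  mi <- 0.3 * exp(-d / 10) + rnorm(length(d), 0, 0.01)
  res <- mi_vs_distance(mi, seq_along(d), lay, cutoff = 20)
  expect_gt(res$near$mean, res$far$mean)

  expect_warning(mi_vs_distance(mi, seq_along(d), lay, cutoff = 1000),
                 "empty")
})
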