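# Fast parameterizations: coarser dt (delays stay divisible) and small
# N where population size is irrelevant.

test_that("connectivity draws have the prescribed weights and density", {
  # dense limit: every entry 1/N
  cs <- build_connectivity(10, 1, seed = 1)
  expect_true(all(cs$W_ee == 1 / 10))

  # nonzero entries all equal 1/(rho N)
  cs <- build_connectivity(50, 0.8, seed = 2)
  vals <- unique(as.vector(cs$W_ie))
  expect_setequal(round(vals, 12), round(c(0, 1 / (0.8 * 50)), 12))

  # binomial concentration of the density over 20 seeds
  dens <- vapply(1:20, function(s) {
    mean(build_connectivity(200, 0.8, seed = s)$W_ee > 0)
  }, numeric(1))
  expect_true(all(abs(dens - 0.8) < 0.03))

  expect_error(build_connectivity(10, 0, seed = 1), "rho")
  expect_error(build_connectivity(10, 1.2, seed = 1), "rho")
})

test_that("the logistic response has the printed midpoint, slope, and symmetry", {
  h <- -0.3
  expect_equal(sigmoid_rate(h, h), 0.5)
  expect_equal(sigmoid_rate(h + 0.1, h), 1 / (1 + exp(-3.5)),
               tolerance = 1e-12)
  v <- seq(-2, 2, by = 0.37)
  expect_equal(sigmoid_rate(v, h) + sigmoid_rate(2 * h - v, h),
               rep(1, length(v)), tolerance = 1e-12)
})

test_that("the biphasic drive follows the cycle structure", {
  prot <- stimulus_protocol(amplitude = 0.2)  # stim epoch 5-10 s
  cyc <- 5000                                  # a cycle start, in ms
  expect_equal(stimulation_drive(cyc + 0.1, prot), 0.2)
  expect_equal(stimulation_drive(cyc + 0.3, prot), -0.2)
  expect_equal(stimulation_drive(cyc + 50, prot), 0)
  expect_equal(stimulation_drive(cyc - 1, prot), 0)      # before epoch
  expect_equal(stimulation_drive(10500, prot), 0)        # after epoch

  # monophasic mode applies only the leading phase
  protm <- stimulus_protocol(amplitude = 0.2, biphasic = FALSE)
  expect_equal(stimulation_drive(cyc + 0.3, protm), 0)
  expect_equal(stimulation_drive(cyc + 0.1, protm), 0.2)
})

test_that("the linear leak relaxes to its closed-form fixed point", {
  p <- network_params(N = 4, g_ee = 0, g_ei = 0, g_ie = 0, g_ii = 0,
                      g1 = 0, g2 = 0, noise_D = 0, I_bias = -0.23,
                      I_state = c(eyes_closed = 0.1), dt = 0.5, seed = 1)
  prot <- stimulus_protocol(pre_duration = 1, stim_duration = 0.5,
                            post_duration = 0.5, amplitude = 0)
  sim <- simulate_network(p, prot, "eyes_closed", burn_in = 1,
                          keep_potentials = TRUE)
  expect_equal(tail(sim$ecog, 1), -(-0.23 + 0.1) / -1.5 + 0 / -1.5,
               tolerance = 1e-6)
  # V_i has no input, so its fixed point is 0
  expect_equal(max(abs(sim$V_i[, ncol(sim$V_i)])), 0, tolerance = 1e-9)
})

test_that("the synthetic ECoG equals the population average exactly", {
  p <- network_params(N = 20, dt = 0.5, seed = 3)
  prot <- stimulus_protocol(pre_duration = 0.5, stim_duration = 0.5,
                            post_duration = 0.5)
  sim <- simulate_network(p, prot, "eyes_open", burn_in = 0.2,
                          keep_potentials = TRUE)
  expect_equal(sim$ecog, colMeans(sim$V_e + sim$V_i), tolerance = 1e-12)
  expect_equal(length(sim$epochs$pre) + length(sim$epochs$during) +
               length(sim$epochs$post), length(sim$ecog))

  # identical params + seed give identical trajectories
  sim2 <- simulate_network(p, prot, "eyes_open", burn_in = 0.2)
  expect_identical(sim$ecog, sim2$ecog)
})

test_that("stationary noise variance matches the Ornstein-Uhlenbeck closed form", {
  # all couplings and inputs off: tau dV = a V dt + sqrt(2 D) dW, so
  # var(V_e) = D / (tau_e |a|)
  p <- network_params(N = 2, g_ee = 0, g_ei = 0, g_ie = 0, g_ii = 0,
                      g1 = 0, g2 = 0, I_bias = 0,
                      I_state = c(eyes_closed = 0), noise_D = 0.01,
                      dt = 0.5, seed = 7)
  prot <- stimulus_protocol(pre_duration = 40, stim_duration = 30,
                            post_duration = 30, amplitude = 0)
  sim <- simulate_network(p, prot, "eyes_closed", burn_in = 2,
                          keep_potentials = TRUE)
  v_theory <- 0.01 / (10 * 1.5)
  v_emp <- mean(apply(sim$V_e, 1, stats::var))
  expect_lt(abs(v_emp - v_theory) / v_theory, 0.10)
})

test_that("delayed feedback acts exactly one delay after the perturbation", {
  mkp <- function(g1 = 0, g2 = 0)
    network_params(N = 4, g_ee = 0, g_ei = 0, g_ie = 0, g_ii = 0,
                   g1 = g1, g2 = g2, I_bias = 0,
                   I_state = c(eyes_closed = 0), noise_D = 0, dt = 0.5,
                   seed = 1)
  prot <- function(A)
    stimulus_protocol(pre_duration = 0.5, stim_duration = 0.2,
                      post_duration = 1.3, phase_width = 1000,
                      amplitude = A, biphasic = FALSE)
  run <- function(g1, g2, A)
    simulate_network(mkp(g1, g2), prot(A), "eyes_closed",
                     burn_in = 0.5)$ecog
  d_on <- run(0, 0, 0.1) - run(0, 0, 0)
  d_g1 <- (run(0.3, 0, 0.1) - run(0.3, 0, 0)) - d_on
  d_g2 <- (run(0, 0.3, 0.1) - run(0, 0.3, 0)) - d_on
  first <- function(x) which(abs(x) > 1e-12)[1]
  # the loop input changes exactly D/dt steps after the perturbation;
  # the first-order integrator expresses it in V one step later
  expect_equal(first(d_g1) - first(d_on), 65 / 0.5 + 1)
  expect_equal(first(d_g2) - first(d_on), 290 / 0.5 + 1)
  expect_equal(first(d_g2) - first(d_g1), (290 - 65) / 0.5)
})

test_that("a diverging integration names the failing step", {
  p <- network_params(N = 4, a = +5, noise_D = 0, dt = 0.5, seed = 1)
  prot <- stimulus_protocol(pre_duration = 2, stim_duration = 0.5,
                            post_duration = 0.5, amplitude = 0)
  expect_error(simulate_network(p, prot, "eyes_closed", burn_in = 0),
               "diverged at step")
})

test_that("pre-stimulation alpha power is strongest with eyes closed across seeds", {
  # Sign test over 10 seeds at a coarse-but-valid step.  The resting
  # state carries a self-sustained alpha rhythm; the two driven states
  # are both heavily damped, so the decisive, testable ordering is the
  # resting state's dominance over each of them (the eyes-open vs task
  # difference is a tiny damping difference of an almost-silent
  # resonance and is not resolvable at this problem size).
  wins_co <- wins_ct <- 0L
  prot <- stimulus_protocol(pre_duration = 4, stim_duration = 0.5,
                            post_duration = 0.5, amplitude = 0)
  for (s in 1:10) {
    cfg <- network_study_config(seed = s, dt = 0.5)
    al <- vapply(c("eyes_closed", "eyes_open", "task"), function(st) {
      sim <- simulate_network(cfg$params, prot, st, burn_in = 2)
      x <- sim$ecog[sim$epochs$pre]
      sp <- periodogram_power(x - mean(x), sim$sample_rate)
      band_power(sp$freq, sp$power, 10, 6)
    }, numeric(1))
    wins_co <- wins_co + (al[1] >= al[2])
    wins_ct <- wins_ct + (al[1] >= al[3])
  }
  # one-sided sign test at alpha = 0.05: >= 9 of 10
  expect_gte(wins_co, 9)
  expect_gte(wins_ct, 9)
})

test_that("the condition suite returns aligned epoch spectra per state", {
  cfg <- network_study_config(seed = 4, dt = 0.5)
  suite <- run_condition_suite(cfg$params, cfg$protocol)
  expect_named(suite, c("eyes_closed", "eyes_open", "task"))
  for (st in names(suite)) {
    expect_named(suite[[st]], c("freq", "pre", "during", "post"))
    expect_length(suite[[st]]$pre, length(suite[[st]]$freq))
  }
  # task engages with the stimulation frequency during the train
  spt <- suite$task
  expect_equal(spectral_peak_freq(spt$freq, spt$during, c(1, 40)), 10)
  # eyes closed holds its endogenous rhythm
  spc <- suite$eyes_closed
  pk <- spectral_peak_freq(spc$freq, spc$during, c(2, 40))
  expect_true(pk >= 6 && pk <= 13)
})
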