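#' End-to-end analysis of (synthetic) stimulation ECoG
#'
#' Composes the full processing chain in its canonical order --
#' artifact removal, notch filter, common average reference, wavelet
#' spectra, modulation indices, statistics -- over a set of generated
#' trials, and returns the tidy modulation-index table plus the
#' statistical summaries.  Trials whose pre-stimulation spectrum has
#' no qualifying endogenous peak are excluded and logged, not fatal.
#'
#' @param layout an [make_layout()] object.
#' @param base_config a [synthetic_trial_config()]; per-trial seeds are
#'   derived as `base_config$seed + trial index`.
#' @param states character vector of behavioral states to run.
#' @param n_trials trials per state.
#' @param stim_band_width full width of the stimulation band, Hz.
#' @param endo_band_width full width of the endogenous band, Hz.
#' @param out_dir if non-`NULL`, writes `modulation_indices.csv`,
#'   `statistics.json`, and `manifest.json` there.
#' @return list: `mi_table` (data frame: state, trial, electrode,
#'   distance_mm, band, epoch_pair, mi), `stats` (per band and epoch
#'   pair, [compare_states()] output), `distance` ([mi_vs_distance()]
#'   for the stimulation band, pre->during), `excluded` (character log
#'   of skipped trials), `peaks` (per-trial endogenous peaks), and
#'   `manifest`.
#' @export
run_ecog_analysis <- function(layout, base_config = synthetic_trial_config(),
                              states = c("eyes_closed", "eyes_open", "task"),
                              n_trials = 3, stim_band_width = 2,
                              endo_band_width = 3, out_dir = NULL) {
  rows <- list()
  excluded <- character()
  peaks <- list()
  trial_counter <- 0L
  for (st in states) {
    for (tr in seq_len(n_trials)) {
      trial_counter <- trial_counter + 1L
      cfg <- base_config
      cfg$seed <- base_config$seed + trial_counter
      trial <- generate_trial(cfg, layout, st)
      cleaned <- if (length(trial$true_artifact_times)) {
        remove_artifacts(trial$contaminated)$cleaned
      } else {
        trial$contaminated
      }
      prep <- preprocess(cleaned)
      onset <- prep$trial_onsets[1]
      specs <- lapply(seq_len(nrow(prep$data)), function(ch) {
        tf <- morlet_power(prep$data[ch, ], prep$sample_rate)
        epoch_spectra(tf, onset)
      })
      # endogenous peak from the channel-average pre spectrum
      avg <- specs[[1]]
      for (f in c("pre", "during", "post"))
        avg[[f]] <- rowMeans(vapply(specs, `[[`, numeric(length(avg$freqs)), f))
      peak <- tryCatch(find_endogenous_peak(avg), oscistim_no_peak = function(e) NA)
      if (is.na(peak)) {
        excluded <- c(excluded,
                      sprintf("state=%s trial=%d: no endogenous peak", st, tr))
        next
      }
      peaks[[sprintf("%s_%d", st, tr)]] <- peak
      bands <- list(endogenous = c(peak, endo_band_width),
                    stimulation = c(base_config$stim_freq, stim_band_width))
      for (ch in seq_along(specs)) {
        for (bn in names(bands)) {
          b <- bands[[bn]]
          s_pre <- epoch_band_power(specs[[ch]], "pre", b[1], b[2])
          for (ep in c("during", "post")) {
            s_ep <- epoch_band_power(specs[[ch]], ep, b[1], b[2])
            rows[[length(rows) + 1L]] <- data.frame(
              state = st, trial = tr, electrode = ch,
              distance_mm = stim_distances(layout)[ch], band = bn,
              epoch_pair = paste0("pre_", ep),
              mi = modulation_index(s_pre, s_ep))
          }
        }
      }
    }
  }
  mi_table <- do.call(rbind, rows)
  stats_out <- list()
  if (!is.null(mi_table)) {
    for (bn in unique(mi_table$band)) {
      for (ep in unique(mi_table$epoch_pair)) {
        sub <- mi_table[mi_table$band == bn & mi_table$epoch_pair == ep, ]
        grp <- split(sub$mi, sub$state)
        grp <- grp[vapply(grp, length, 1L) >= 2]
        if (length(grp))
          stats_out[[paste(bn, ep, sep = ".")]] <- compare_states(grp)
      }
    }
  }
  dist_out <- NULL
  if (!is.null(mi_table)) {
    sub <- mi_table[mi_table$band == "stimulation" &
                    mi_table$epoch_pair == "pre_during", ]
    if (nrow(sub))
      dist_out <- suppressWarnings(
        mi_vs_distance(sub$mi, sub$electrode, layout))
  }
  manifest <- list(
    stage_order = c("clean", "notch", "reference", "spectra", "mi", "stats"),
    states = states, n_trials = n_trials, base_seed = base_config$seed,
    stim_band_width = stim_band_width, endo_band_width = endo_band_width,
    package_version = as.character(utils::packageVersion("oscistim")))
  out <- list(mi_table = mi_table, stats = stats_out, distance = dist_out,
              excluded = excluded, peaks = unlist(peaks),
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(mi_table,
                     file.path(out_dir, "modulation_indices.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(stats = stats_out, distance = dist_out, peaks = out$peaks,
           excluded = excluded),
      file.path(out_dir, "statistics.json"), auto_unbox = TRUE,
      digits = NA, force = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run a forward-model study
#'
#' Executes either the static-model study (the two regime simulations
#' plus the two-parameter strength sweep) or the network study (the
#' three behavioral states plus the two feedback-loop ablations) and
#' optionally writes figure-ready delimited tables and a JSON
#' manifest.
#'
#' @param mode `"static"` or `"network"`.
#' @param seed integer seed (network mode).
#' @param out_dir if non-`NULL`, tables are written there.
#' @param dt network integration step, ms.
#' @return mode-dependent list of results (see the analysis scripts
#'   for worked usage).
#' @export
run_model_study <- function(mode = c("static", "network"), seed = 1L,
                            out_dir = NULL, dt = 0.1) {
  mode <- match.arg(mode)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (mode == "static") {
    base <- static_model_params()
    amps <- static_state_amplitudes()
    regimes <- lapply(amps, function(a) {
      p <- base
      p$osc_amplitude <- a
      sim <- simulate_static(p)
      sp <- periodogram_power(sim$output, p$sample_rate)
      list(peak = spectral_peak_freq(sp$freq, sp$power, c(1, 40)),
           spectrum = sp, trace = sim)
    })
    sweep <- sweep_strengths(seq(0.2, 5, length.out = 10),
                             seq(0.2, 2, length.out = 10), base)
    out <- list(regimes = regimes, sweep = sweep)
    if (!is.null(out_dir)) {
      utils::write.table(
        data.frame(state = names(amps), amplitude = unname(amps),
                   peak_hz = vapply(regimes, `[[`, numeric(1), "peak")),
        file.path(out_dir, "static_regimes.tsv"),
        sep = "\t", row.names = FALSE)
      utils::write.table(sweep$power_stim,
                         file.path(out_dir, "sweep_power_stim.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      utils::write.table(sweep$delta_power_osc,
                         file.path(out_dir, "sweep_delta_power_osc.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    }
  } else {
    cfg <- network_study_config(seed = seed, dt = dt)
    suite <- run_condition_suite(cfg$params, cfg$protocol)
    ablations <- list()
    for (ab in c("g1", "g2")) {
      p <- cfg$params
      p[[ab]] <- 0
      ablations[[ab]] <- run_condition_suite(p, cfg$protocol)
    }
    out <- list(suite = suite, ablations = ablations, config = cfg)
    if (!is.null(out_dir)) {
      for (st in names(suite)) {
        sp <- suite[[st]]
        utils::write.table(
          data.frame(freq = sp$freq, pre = sp$pre, during = sp$during,
                     post = sp$post),
          file.path(out_dir, sprintf("network_spectra_%s.tsv", st)),
          sep = "\t", row.names = FALSE)
      }
    }
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(mode = mode, seed = seed, dt = dt,
           package_version = as.character(utils::packageVersion("oscistim"))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
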