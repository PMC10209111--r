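derive_seed <- function(seed, stage, k = 0L) {
  ((as.numeric(seed) %% 1e6) * 20011 + stage * 104729 + k * 7919) %%
    2147483629
}

fnv1a <- function(text) {
  bytes <- as.integer(charToRaw(text))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the electrophysiology analysis pipeline end to end
#'
#' Simulate-or-load, then QC -> classification -> per-unit x condition
#' metrics -> modulation calls -> per-layer proportion tables with
#' chi-square + Marascuillo annotations -> population ISI curves.
#' Deterministic given `config$seed` (a single seed fans out to per-stage
#' generators). Every stage logs its row counts; input units are conserved
#' as analyzed + excluded-with-reason.
#'
#' @param config A [default_config()]-style configuration.
#' @param out_dir Optional directory; when given, all tables are written
#'   as TSV plus a YAML run manifest (config hash, seed, package version).
#' @param session Optional precomputed `list(train, events)` (e.g. loaded
#'   with [read_sorted_spikes()]); simulated from `config$simulate`
#'   otherwise.
#' @return list: `metrics`, `calls`, `proportions`, `pairwise`
#'   (Marascuillo rows), `isi_curve`, `classification`, `counts`,
#'   `manifest`.
#' @export
run_ephys_pipeline <- function(config = default_config(), out_dir = NULL,
                               session = NULL) {
  validate_config(config)
  sim_cfg <- config$simulate
  if (is.null(session)) {
    specs <- sample_unit_specs(sim_cfg$n_units,
                               derive_seed(config$seed, 1), sim_cfg)
    protocol <- default_protocol(sim_cfg$n_trials, sim_cfg$n_pulses,
                                 sim_cfg$stim_s, sim_cfg$gap_m_ml_s,
                                 sim_cfg$gap_other_s)
    session <- simulate_session(specs, protocol,
                                seed = derive_seed(config$seed, 2))
  }
  train <- session$train
  events <- session$events
  message("units in: ", nrow(train$units))

  cls <- classify_units(train, events, config = config)
  keep <- cls$unit_id[cls$qc_pass]
  message("QC pass: ", length(keep), " / excluded: ",
          nrow(cls) - length(keep))

  win <- do.call(window_spec, config$window)
  conditions <- intersect(c("L", "M", "ML"), unique(events$condition))
  metrics <- list(); calls <- list(); cdfs <- list()
  i <- 0L
  for (uid in keep) {
    for (cond in conditions) {
      i <- i + 1L
      al <- align_spikes(train, events, uid, cond, win)
      m <- unit_condition_metrics(al, config$burst$isi_cutoff_ms)
      base_counts <- vapply(trial_window_spikes(al, "baseline"), length,
                            numeric(1))
      resp_counts <- vapply(trial_window_spikes(al, "response"), length,
                            numeric(1))
      ct <- paired_count_test(base_counts, resp_counts)
      tt <- timing_deviation_test(al,
        n_resamples = config$timing_test$n_resamples,
        seed = derive_seed(config$seed, 3, i),
        method = config$timing_test$method)
      cm <- classify_modulation(
        p_count = if (ct$all_zero && ct$n == 0) NA_real_ else ct$p,
        p_timing = if (tt$testable) tt$p else NA_real_,
        delta_count = ct$delta_count, alpha = config$alpha)
      layer <- cls$layer[cls$unit_id == uid]
      metrics[[i]] <- cbind(m, layer = layer)
      calls[[i]] <- data.frame(unit_id = uid, condition = cond,
                               group = layer, p_count = cm$p_count,
                               p_timing = cm$p_timing,
                               delta_count = cm$delta_count,
                               significant = cm$significant,
                               direction = cm$direction)
      if (cond == "ML") {
        cdfs[[uid]] <- suppressWarnings(isi_cdf(al))
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  calls <- do.call(rbind, calls)
  message("metrics rows: ", nrow(metrics), "; calls rows: ", nrow(calls))

  props <- condition_proportions(calls)
  pairwise <- list()
  for (g in unique(props$group)) {
    sub <- props[props$group == g, ]
    succ <- sub$n_enhanced + sub$n_suppressed + sub$n_timing_only
    # chi-square needs >= 3 conditions and a non-degenerate pooled rate
    if (nrow(sub) >= 3 && sum(succ) > 0 && sum(succ) < sum(sub$n)) {
      chs <- chisq_homogeneity(succ, sub$n)
      mar <- marascuillo(succ, sub$n, labels = as.character(sub$condition),
                         alpha = config$alpha)
      mar$group <- g
      mar$chisq_p <- chs$p
      pairwise[[g]] <- mar
    }
  }
  pairwise <- if (length(pairwise)) do.call(rbind, pairwise) else NULL
  isi_curve <- if (length(Filter(Negate(is.null), cdfs)))
    population_median_cdf(cdfs) else NULL

  manifest <- list(seed = config$seed,
                   config_hash = fnv1a(yaml::as.yaml(
                     lapply(unclass(config), function(x)
                       if (is.data.frame(x)) as.list(x) else x))),
                   package_version =
                     as.character(utils::packageVersion("optoephys")),
                   n_units_in = nrow(train$units),
                   n_units_analyzed = length(keep),
                   n_units_excluded = nrow(cls) - length(keep))
  counts <- data.frame(stage = c("input", "qc_pass", "excluded",
                                 "metrics_rows", "calls_rows"),
                       n = c(nrow(train$units), length(keep),
                             nrow(cls) - length(keep), nrow(metrics),
                             nrow(calls)))
  res <- list(metrics = metrics, calls = calls, proportions = props,
              pairwise = pairwise, isi_curve = isi_curve,
              classification = cls, counts = counts, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_table(metrics, file.path(out_dir, "unit_metrics.tsv"))
    write_results_table(calls, file.path(out_dir, "modulation_calls.tsv"))
    write_results_table(props, file.path(out_dir, "proportions.tsv"))
    write_results_table(cls, file.path(out_dir, "classification.tsv"))
    if (!is.null(pairwise)) {
      write_results_table(pairwise, file.path(out_dir, "marascuillo.tsv"))
    }
    if (!is.null(isi_curve)) {
      write_results_table(isi_curve, file.path(out_dir, "isi_curve.tsv"))
    }
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  }
  res
}

#' Run the behavior analysis pipeline end to end
#'
#' Per animal: simulate (or load) a von Frey session with and without
#' laser, compute the psychometric curve, 60% withdrawal threshold and
#' sensitization AUC; simulate a baseline and a conditioning place session
#' and compute preference indices. Returns per-animal rows plus group
#' summaries (mean +/- SEM). Deterministic given `config$seed`.
#'
#' @param config A [default_config()]-style configuration.
#' @param out_dir Optional output directory for TSVs and the run manifest.
#' @return list: `vonfrey` (per animal x laser), `place` (per animal x
#'   session), `summary` (group means +/- SEM), `manifest`.
#' @export
run_behavior_pipeline <- function(config = default_config(),
                                  out_dir = NULL) {
  validate_config(config)
  b <- config$behavior
  vf_rows <- list(); pl_rows <- list()
  for (a in seq_len(b$n_animals)) {
    thr_a <- with_seed(derive_seed(config$seed, 10, a),
                       b$threshold_g * stats::rlnorm(1, 0, 0.15))
    sess <- simulate_vonfrey(
      list(threshold_g = thr_a, slope = b$slope, laser_shift = b$laser_shift),
      filaments = b$filaments_g, n_per_filament = b$n_per_filament,
      seed = derive_seed(config$seed, 11, a))
    for (on in c(FALSE, TRUE)) {
      curve <- withdrawal_curve(sess[sess$laser == on, ])
      vf_rows[[length(vf_rows) + 1L]] <- data.frame(
        animal = a, laser = on,
        threshold_60_g = as.numeric(threshold_at(curve, 0.6)),
        auc = sensitivity_auc(curve),
        auc_normalized = sensitivity_auc(curve, normalize = TRUE))
    }
    pp <- b$place
    base <- simulate_place_session(
      p_stay_paired = (pp$p_stay_paired + pp$p_stay_unpaired) / 2,
      p_stay_unpaired = (pp$p_stay_paired + pp$p_stay_unpaired) / 2,
      duration_s = pp$duration_s, dt_s = pp$dt_s,
      seed = derive_seed(config$seed, 12, a))
    cond <- simulate_place_session(
      p_stay_paired = pp$p_stay_paired,
      p_stay_unpaired = pp$p_stay_unpaired,
      duration_s = pp$duration_s, dt_s = pp$dt_s,
      seed = derive_seed(config$seed, 13, a))
    for (s in list(list(lab = "baseline", tr = base),
                   list(lab = "conditioning", tr = cond))) {
      occ <- occupancy_times(s$tr, dt_s = pp$dt_s)
      pl_rows[[length(pl_rows) + 1L]] <- data.frame(
        animal = a, session = s$lab, paired_s = occ$paired_s,
        unpaired_s = occ$unpaired_s, neutral_s = occ$neutral_s,
        pi = preference_index(occ$paired_s, occ$unpaired_s))
    }
  }
  vonfrey <- do.call(rbind, vf_rows)
  place <- do.call(rbind, pl_rows)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summ <- rbind(
    do.call(rbind, lapply(c(FALSE, TRUE), function(on) {
      sub <- vonfrey[vonfrey$laser == on, ]
      data.frame(measure = paste0("auc_laser_", ifelse(on, "on", "off")),
                 mean = mean(sub$auc), sem = sem(sub$auc), n = nrow(sub))
    })),
    do.call(rbind, lapply(unique(place$session), function(sl) {
      sub <- place[place$session == sl, ]
      data.frame(measure = paste0("pi_", sl), mean = mean(sub$pi),
                 sem = sem(sub$pi), n = nrow(sub))
    })))
  manifest <- list(seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("optoephys")),
                   n_animals = b$n_animals)
  res <- list(vonfrey = vonfrey, place = place, summary = summ,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_table(vonfrey, file.path(out_dir, "vonfrey.tsv"))
    write_results_table(place, file.path(out_dir, "place.tsv"))
    write_results_table(summ, file.path(out_dir, "behavior_summary.tsv"))
    yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  }
  res
}
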