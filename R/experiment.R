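# End-to-end orchestration: configuration, the full simulated experiment,
# and TSV/JSON serialization of its outputs.

#' Full experiment configuration
#'
#' Collects every knob of the simulated experiment. Defaults reproduce the
#' study conditions: a 20-participant real-time cohort with balanced 10/10
#' double-blind group assignment, 4 runs of 7 stations, decoders trained on
#' a separate explicitly-instructed cohort, pilot normalization from a
#' separate free-interpretation cohort, and a $20 bonus cap. Real-time
#' agents are heterogeneous: per-participant decodability (`snr`) and
#' learning rate are drawn uniformly from the given ranges, emulating the
#' wide variation in decoding accuracy observed across participants.
#'
#' @param n_participants Real-time cohort size (even).
#' @param n_runs Runs per participant.
#' @param n_features Feature-space dimension.
#' @param separation Template separation.
#' @param n_train Training-cohort size.
#' @param n_pilot Pilot-cohort size.
#' @param regularization_c Decoder inverse regularization.
#' @param snr_range Range of per-participant signal scaling.
#' @param learning_rate_range Range of per-participant learning rates.
#' @param probe_temperature Probe policy softness.
#' @param payout_cap Bonus cap in dollars.
#' @param mode `"live"` or `"yoked"` feedback.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_participants = 20, n_runs = 4,
                              n_features = 100, separation = 2,
                              n_train = 20, n_pilot = 10,
                              regularization_c = 1,
                              snr_range = c(0.2, 1.5),
                              learning_rate_range = c(0.05, 0.4),
                              probe_temperature = 0.5,
                              payout_cap = 20,
                              mode = c("live", "yoked"),
                              seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_participants %% 2 == 0, n_train %% 2 == 0, n_pilot >= 2)
  structure(
    list(n_participants = as.integer(n_participants),
         n_runs = as.integer(n_runs),
         n_features = as.integer(n_features), separation = separation,
         n_train = as.integer(n_train), n_pilot = as.integer(n_pilot),
         regularization_c = regularization_c, snr_range = snr_range,
         learning_rate_range = learning_rate_range,
         probe_temperature = probe_temperature, payout_cap = payout_cap,
         mode = mode, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# Short provenance digest of a config (stable across sessions).
config_digest <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

# Deterministic stage seeds derived from the master seed, kept < 2^31.
stage_seed <- function(seed, stage) {
  offs <- c(templates = 11L, training = 23L, pilot = 37L, agents = 53L,
            sessions = 101L, questionnaire = 211L)
  (as.integer(seed) * 7919L + offs[[stage]]) %% 2000000000L
}

#' Run the full simulated experiment
#'
#' Orchestrates every stage: template construction, training-cohort
#' generation and decoder fitting, pilot cohort and normalization, the
#' closed-loop (or yoked) real-time sessions, post-scan questionnaires and
#' behavioral scoring, and the group analyses (decoding accuracy, median
#' split, group t tests, the decoding-accuracy vs. correct-interpretation
#' correlation, and run-wise aggregates). Fully deterministic given
#' `config$seed`. In yoked mode a live donor cohort is simulated first and
#' each participant receives a same-group donor's feedback.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, all tables are written as
#'   TSV with a JSON sidecar carrying the config, seed and config digest.
#' @return A list with `templates`, `stations`, `models`, `norms`, `logs`,
#'   `behavior` (per-participant scores + payout), `summaries` (with median
#'   split), `analyses` (t tests and correlations) and `aggregates`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  templates <- make_templates(config$n_features, config$separation,
                              seed = stage_seed(config$seed, "templates"))
  stations <- default_stations()
  timing <- timing_config()

  train_cfg <- cohort_config(config$n_train, config$n_runs,
                             config$n_features, snr = 1,
                             seed = stage_seed(config$seed, "training"))
  training <- generate_training_cohort(train_cfg, templates, stations)
  models <- train_station_models(training, config$regularization_c)

  pilot_cfg <- cohort_config(max(2L, config$n_pilot), config$n_runs,
                             config$n_features, snr = 1,
                             seed = stage_seed(config$seed, "pilot"))
  pilot <- generate_pilot_cohort(pilot_cfg, templates, models, stations)
  norms <- estimate_pilot_norms(pilot)

  set.seed(stage_seed(config$seed, "agents"))
  groups <- sample(rep(c("cheating", "paranoid"),
                       each = config$n_participants / 2))
  snrs <- stats::runif(config$n_participants, config$snr_range[1],
                       config$snr_range[2])
  lrs <- stats::runif(config$n_participants,
                      config$learning_rate_range[1],
                      config$learning_rate_range[2])
  seeds <- (stage_seed(config$seed, "sessions") +
              17L * seq_len(config$n_participants)) %% 2000000000L

  make_agent <- function(i) {
    agent_state(theta = 0, learning_rate = lrs[i],
                probe_temperature = config$probe_temperature, snr = snrs[i])
  }
  live <- lapply(seq_len(config$n_participants), function(i) {
    run_session(i, groups[i], make_agent(i), models, norms, templates,
                stations, timing, config$n_runs, seed = seeds[i])
  })
  logs <- if (config$mode == "live") {
    live
  } else {
    # donor: the next same-group participant, cyclically
    lapply(seq_len(config$n_participants), function(i) {
      mates <- setdiff(which(groups == groups[i]), i)
      donor <- mates[which(mates > i)[1]]
      if (is.na(donor)) donor <- mates[1]
      run_yoked_session(i, groups[i], make_agent(i), models, norms,
                        templates, live[[donor]], stations, timing,
                        config$n_runs, seed = seeds[i])
    })
  }

  set.seed(stage_seed(config$seed, "questionnaire"))
  behavior <- do.call(rbind, lapply(seq_along(logs), function(i) {
    q <- generate_questionnaire(logs[[i]]$final_state$theta)
    b <- score_behavior(q, logs[[i]]$group)
    cbind(data.frame(participant_id = i, group = logs[[i]]$group), b,
          payout = round(compute_payout(logs[[i]]$events,
                                        config$payout_cap), 2))
  }))

  summaries <- summarize_participants(logs)
  # an agent that never declared one lens has undefined decoding accuracy;
  # keep it flagged (NA) and skip the split rather than abort the cohort
  summaries <- tryCatch(median_split(summaries), error = function(e) {
    warning("median split unavailable: ", conditionMessage(e),
            call. = FALSE)
    summaries$split <- NA_character_
    summaries
  })
  summaries <- merge(summaries,
                     behavior[, c("participant_id", "comprehension",
                                  "correct_interpretation",
                                  "correct_empathy")],
                     by = "participant_id")

  ok <- !is.na(summaries$decoding_accuracy)
  analyses <- list(
    comprehension_by_group = group_ttest(summaries$comprehension,
                                         summaries$group),
    interpretation_by_group = group_ttest(summaries$correct_interpretation,
                                          summaries$group),
    decoding_vs_correct_interpretation = pearson_r(
      summaries$decoding_accuracy[ok],
      summaries$correct_interpretation[ok]),
    empathy_vs_interpretation = pearson_r(summaries$correct_empathy,
                                          summaries$correct_interpretation),
    interpretation_by_split = if (!anyNA(summaries$split)) group_ttest(
      summaries$correct_interpretation,
      factor(summaries$split, levels = c("best", "worst")),
      tails = "one", direction = "greater")
  )
  split_map <- stats::setNames(summaries$split,
                               as.character(summaries$participant_id))
  aggregates <- list(
    by_run_group = aggregate_sessions(logs, by = c("run", "group")),
    by_station_split = if (!anyNA(split_map))
      aggregate_sessions(logs, by = c("run", "station", "split"),
                         split = split_map)
  )

  res <- list(config = config, templates = templates, stations = stations,
              models = models, norms = norms, pilot = pilot, logs = logs,
              behavior = behavior, summaries = summaries,
              analyses = analyses, aggregates = aggregates)
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

#' Write experiment outputs as TSV + JSON
#'
#' BIDS-inspired layout: one events TSV and JSON sidecar per participant
#' under `sub-XX/`, plus cohort-level tables (`norms.tsv`, `behavior.tsv`,
#' `summaries.tsv`, aggregate tables) and `models.json`. Every sidecar
#' carries the master seed and a digest of the configuration.
#'
#' @param result The list returned by [run_experiment()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  digest <- config_digest(result$config)
  wtsv <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (lg in result$logs) {
    sub <- file.path(out_dir, sprintf("sub-%02d", lg$participant_id))
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    ev <- lg$events
    ev$onset <- ev$onset_tr * 1.5
    ev$duration <- ev$duration_trs * 1.5
    utils::write.table(ev, file.path(sub, "events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(participant = lg$participant_id, group = lg$group,
           mode = lg$mode, seed = lg$seed, config_digest = digest),
      file.path(sub, "events.json"), auto_unbox = TRUE)
  }
  wtsv(result$norms, "norms.tsv")
  wtsv(result$behavior, "behavior.tsv")
  wtsv(result$summaries, "summaries.tsv")
  wtsv(result$aggregates$by_run_group, "aggregate_run_group.tsv")
  if (!is.null(result$aggregates$by_station_split)) {
    wtsv(result$aggregates$by_station_split, "aggregate_station_split.tsv")
  }
  jsonlite::write_json(
    list(config = unclass(result$config), config_digest = digest,
         models = lapply(result$models, unclass),
         analyses = result$analyses),
    file.path(out_dir, "models.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
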