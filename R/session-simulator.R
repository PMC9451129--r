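# Closed-loop session simulation: probe -> pattern -> decode -> normalize ->
# reward -> agent update, over runs x stations, plus a yoked-control mode.

#' Simulated participant state
#'
#' The agent holds a latent interpretation `theta` in \[-1, 1\] (+1 fully
#' cheating, -1 fully paranoid), which drives both its station activity
#' patterns and its probe responses, and is nudged by rewarded feedback.
#'
#' @param theta Initial latent interpretation.
#' @param learning_rate Nonnegative step size of the reward update.
#' @param probe_temperature Positive softness of the probe policy; as it
#'   approaches 0 the probe deterministically reports `sign(theta)`.
#' @param snr Pattern signal scaling for this participant (individual
#'   decodability).
#' @param lens_commitment How strongly adopting a lens at a probe shifts the
#'   momentary interpretation during the following station (0 = the declared
#'   lens leaves no neural trace; participants are instructed to adopt their
#'   declared lens, so the default is a substantial 0.5). During a station
#'   the momentary interpretation is
#'   `clamp(theta + lens_commitment * sign(choice))`.
#' @return A list of class `agent_state`.
#' @export
agent_state <- function(theta = 0, learning_rate = 0.3,
                        probe_temperature = 0.5, snr = 1,
                        lens_commitment = 0.5) {
  stopifnot(theta >= -1, theta <= 1, learning_rate >= 0,
            probe_temperature > 0, snr >= 0, lens_commitment >= 0)
  structure(
    list(theta = theta, learning_rate = learning_rate,
         probe_temperature = probe_temperature, snr = snr,
         lens_commitment = lens_commitment),
    class = "agent_state"
  )
}

#' Probe policy: which lens will the agent adopt?
#'
#' P(cheating) = logistic(theta / temperature). The returned choice is what
#' the participant declares at the pre-station probe; it need not match the
#' assigned group.
#'
#' @param state An `agent_state`.
#' @param u Optional uniform draw in \[0, 1\] (supplied by the session's
#'   probe substream); defaults to a fresh draw.
#' @return `"cheating"` or `"paranoid"`.
#' @export
agent_probe_policy <- function(state, u = stats::runif(1)) {
  p_cheat <- stats::plogis(state$theta / state$probe_temperature)
  if (u < p_cheat) "cheating" else "paranoid"
}

#' Reinforcement update of the agent after feedback
#'
#' The lens declared at the probe is reinforced in proportion to the
#' delivered reward: `theta <- clamp(theta + lr * reward * sign(choice))`
#' with sign +1 for cheating and -1 for paranoid. A zero reward leaves the
#' state unchanged.
#'
#' @param state An `agent_state`.
#' @param probe_choice `"cheating"` or `"paranoid"`.
#' @param score_reward Delivered reward in \[0, 1\].
#' @return The updated `agent_state` with `theta` clamped to \[-1, 1\].
#' @export
agent_update <- function(state, probe_choice, score_reward) {
  stopifnot(probe_choice %in% c("cheating", "paranoid"),
            score_reward >= 0, score_reward <= 1)
  sgn <- if (probe_choice == "cheating") 1 else -1
  state$theta <- min(1, max(-1, state$theta +
                              state$learning_rate * score_reward * sgn))
  state
}

# Derive the named RNG substreams from a participant seed (kept < 2^31).
session_substreams <- function(seed) {
  base <- as.integer(seed) %% 715827882L  # 3 * base + 2 stays below 2^31
  list(patterns = 3L * base, probes = 3L * base + 1L,
       questionnaire = 3L * base + 2L)
}

#' Run one closed-loop neurofeedback session
#'
#' Executes the full per-station loop for `n_runs` runs of 7 stations each:
#' the agent declares a lens at the probe, its activity pattern is sampled at
#' the hemodynamically shifted window, the station decoder produces p(c),
#' the score is pilot-normalized, aligned with the (double-blind) assigned
#' group and thresholded, and the delivered reward updates the agent at
#' feedback onset. The assigned group is fixed across all runs. All
#' randomness flows from `seed` through named pattern/probe substreams, so a
#' session is reproducible bit-for-bit.
#'
#' @param participant_id Identifier stored in the log.
#' @param group Assigned group, `"cheating"` or `"paranoid"`.
#' @param state Initial [agent_state()].
#' @param models Station models from [train_station_models()].
#' @param norms Pilot norms from [estimate_pilot_norms()].
#' @param templates The [make_templates()] pair the cohort was built from.
#' @param stations Station data.frame.
#' @param timing A [timing_config()].
#' @param n_runs Number of runs (<= 4; truncated sessions are supported).
#' @param seed Per-participant seed.
#' @return A `session_log`: list with `participant_id`, `group`, `events`
#'   (one row per station x run: onsets, `p_c`, `score_c`, `score_final`,
#'   `score_reward`, `probe_choice`), `final_state` and `seed`.
#' @export
run_session <- function(participant_id, group, state, models, norms,
                        templates, stations = default_stations(),
                        timing = timing_config(), n_runs = 4, seed = 1) {
  stopifnot(group %in% c("cheating", "paranoid"), n_runs >= 1)
  run_session_impl(participant_id, group, state, models, norms, templates,
                   stations, timing, n_runs, seed, donor_events = NULL)
}

run_session_impl <- function(participant_id, group, state, models, norms,
                             templates, stations, timing, n_runs, seed,
                             donor_events) {
  validate_stations(stations)
  stopifnot(inherits(templates, "template_pair"))
  ss <- session_substreams(seed)
  n_st <- nrow(stations)
  # Pre-seeded draw blocks realize the named substreams.
  set.seed(ss$probes)
  probe_u <- matrix(stats::runif(n_runs * n_st), nrow = n_runs)
  set.seed(ss$patterns)
  noise <- array(stats::rnorm(n_runs * n_st * length(templates$direction)),
                 dim = c(n_runs, n_st, length(templates$direction)))
  events <- vector("list", n_runs * n_st)
  k <- 1L
  for (r in seq_len(n_runs)) {
    for (s in seq_len(n_st)) {
      tl <- station_timeline(stations[s, ], timing)
      choice <- agent_probe_policy(state, probe_u[r, s])
      # the agent adopts the declared lens for the station, so the momentary
      # interpretation combines the latent state with the probed choice
      eff_theta <- min(1, max(-1, state$theta + state$lens_commitment *
                                (if (choice == "cheating") 1 else -1)))
      mid <- (templates$template_cheating + templates$template_paranoid) / 2
      shift <- (stations$bias[s] + state$snr * eff_theta) *
        (templates$separation / 2)
      pattern <- mid + shift * templates$direction + noise[r, s, ]
      p_c <- predict_cheating_probability(models[[s]], pattern)
      score_c <- normalize_score(p_c, norms, stations$station_index[s])
      score_final <- apply_group(score_c, group)
      own_reward <- threshold_reward(score_final)
      yoked_fallback <- FALSE
      if (is.null(donor_events)) {
        delivered <- own_reward
      } else {
        d <- donor_events[donor_events$run == r &
                            donor_events$station_index ==
                              stations$station_index[s], ]
        yoked_fallback <- d$probe_choice[1] != choice
        delivered <- d$score_reward[1]
      }
      # reward reaches the agent at feedback onset, after the 4-TR delay
      state <- agent_update(state, choice, delivered)
      events[[k]] <- data.frame(
        run = r, station_index = stations$station_index[s],
        onset_tr = tl$station_window[1], duration_trs = stations$n_trs[s],
        feedback_onset_tr = tl$feedback_onset_tr,
        probe_choice = choice, p_c = p_c, score_c = score_c,
        score_final = score_final, score_reward = delivered,
        own_score_reward = own_reward, yoked_fallback = yoked_fallback
      )
      k <- k + 1L
    }
  }
  structure(
    list(participant_id = participant_id, group = group,
         events = do.call(rbind, events), final_state = state, seed = seed,
         mode = if (is.null(donor_events)) "live" else "yoked"),
    class = "session_log"
  )
}

#' Run a yoked-control session
#'
#' Identical to [run_session()] except that the feedback delivered (and used
#' for the agent update) at each station is the *donor's* reward for that
#' station, provided the donor behaviorally chose the same lens at that
#' station's probe; when the donor's probe choice differs, the donor's
#' reward for that station is delivered anyway and the event is flagged
#' `yoked_fallback`. The participant's own decoded p(c) and would-be reward
#' (`own_score_reward`) are still logged for analysis. The donor must come
#' from the same assigned group.
#'
#' @inheritParams run_session
#' @param donor_log A completed `session_log` from the same assigned group.
#' @return A `session_log` with delivered rewards taken from the donor.
#' @export
run_yoked_session <- function(participant_id, group, state, models, norms,
                              templates, donor_log,
                              stations = default_stations(),
                              timing = timing_config(), n_runs = 4,
                              seed = 1) {
  stopifnot(inherits(donor_log, "session_log"))
  if (donor_log$group != group) {
    stop("donor must share the participant's assigned group", call. = FALSE)
  }
  if (max(donor_log$events$run) < n_runs) {
    stop("donor session has fewer runs than requested", call. = FALSE)
  }
  run_session_impl(participant_id, group, state, models, norms, templates,
                   stations, timing, n_runs, seed,
                   donor_events = donor_log$events)
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> participant %s (%s group, %s mode)\n",
              x$participant_id, x$group, x$mode))
  cat(sprintf("  %d events over %d run(s); total reward %.3f; final theta %.3f\n",
              nrow(x$events), max(x$events$run), sum(x$events$score_reward),
              x$final_state$theta))
  invisible(x)
}
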