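# The transformation from decoded probability to displayed/rewarded score,
# pilot normalization, and the session timing arithmetic.

#' Estimate per-station pilot normalization parameters
#'
#' Computes, for each station, the mean and SD of the decoded cheating
#' probability over all pilot participants and runs. These define the
#' "average neural interpretation trajectory": feedback later rewards
#' deviation from this per-station average, not the absolute decoded state,
#' which controls for stations where the narrative itself leans strongly
#' toward one interpretation. The SD uses the population convention by
#' default (the pilot is treated as a fixed reference distribution).
#'
#' @param pilot_pc Data.frame from [generate_pilot_cohort()] with columns
#'   `station_index` and `p_c`.
#' @param sd_mode `"population"` (divide by N, default) or `"sample"`.
#' @return A data.frame of class `pilot_norms` with columns `station_index`,
#'   `mu`, `sigma`.
#' @export
estimate_pilot_norms <- function(pilot_pc,
                                 sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(is.data.frame(pilot_pc),
            all(c("station_index", "p_c") %in% names(pilot_pc)))
  sp <- split(pilot_pc$p_c, pilot_pc$station_index)
  if (any(vapply(sp, length, 1L) < 2)) {
    stop("need at least 2 pilot p(c) samples per station", call. = FALSE)
  }
  mu <- vapply(sp, mean, numeric(1))
  sigma <- vapply(sp, function(v) {
    s2 <- stats::var(v)
    if (sd_mode == "population") s2 <- s2 * (length(v) - 1) / length(v)
    sqrt(s2)
  }, numeric(1))
  if (any(sigma <= 0)) {
    stop(sprintf("degenerate pilot norms: sigma = 0 at station(s) %s",
                 paste(names(sp)[sigma <= 0], collapse = ", ")),
         call. = FALSE)
  }
  structure(
    data.frame(station_index = as.integer(names(sp)), mu = unname(mu),
               sigma = unname(sigma)),
    class = c("pilot_norms", "data.frame")
  )
}

#' Normalize a decoded probability to a neurofeedback score
#'
#' The score transformation:
#' `score_c = (p_c - mu_st) / (3 * sigma_st) + 0.5`, clipped to \[0, 1\].
#' The 3-sigma scaling maps typical z-scored deviations roughly onto
#' \[-0.5, 0.5\], so adding 0.5 centers the display range on 0.5: a
#' participant whose p(c) equals the pilot station mean scores exactly 0.5.
#'
#' @param p_c Decoded cheating probability (vectorized).
#' @param norms A `pilot_norms` data.frame.
#' @param station_index Station identifier(s) matching `norms`.
#' @return `score_c` in \[0, 1\], strictly increasing in `p_c` between the
#'   clip bounds.
#' @export
normalize_score <- function(p_c, norms, station_index) {
  i <- match(station_index, norms$station_index)
  if (anyNA(i)) stop("unknown station_index", call. = FALSE)
  sigma <- norms$sigma[i]
  if (any(sigma <= 0)) {
    stop("degenerate pilot norms: sigma must be > 0", call. = FALSE)
  }
  raw <- (p_c - norms$mu[i]) / (3 * sigma) + 0.5
  pmin(1, pmax(0, raw))
}

#' Align the score with the assigned group
#'
#' Members of the cheating group see `score_c` itself; members of the
#' paranoid group see its complement `1 - score_c`, so for both groups a
#' higher displayed score means decoded activity further toward the
#' *assigned* interpretation.
#'
#' @param score_c Normalized score(s) in \[0, 1\].
#' @param group `"cheating"` or `"paranoid"` (scalar or vectorized).
#' @return `score_final` in \[0, 1\].
#' @export
apply_group <- function(score_c, group) {
  if (!all(group %in% c("cheating", "paranoid"))) {
    stop("group must be \"cheating\" or \"paranoid\"", call. = FALSE)
  }
  stopifnot(all(score_c >= 0 & score_c <= 1))
  n <- max(length(score_c), length(group))
  ifelse(rep_len(group, n) == "cheating", rep_len(score_c, n),
         1 - rep_len(score_c, n))
}

#' Threshold the score for reward delivery
#'
#' Participants earn money only by scoring strictly above the station mean
#' in the assigned direction: scores at or below 0.5 deliver 0.
#'
#' @param score_final Group-aligned score(s) in \[0, 1\].
#' @return `score_reward`: `score_final` where `> 0.5`, else 0.
#' @export
threshold_reward <- function(score_final) {
  stopifnot(all(score_final >= 0 & score_final <= 1))
  ifelse(score_final > 0.5, score_final, 0)
}

#' Total monetary payout for a session
#'
#' Each station is worth an equal share of the bonus cap, scaled by its
#' thresholded reward score, so a perfect session saturates the cap.
#'
#' @param events Data.frame of feedback events with a `score_reward` column.
#' @param cap Maximum bonus in dollars (default 20).
#' @return Total payout in dollars, in \[0, cap\].
#' @export
compute_payout <- function(events, cap = 20) {
  stopifnot(is.data.frame(events), "score_reward" %in% names(events))
  sum(events$score_reward) * cap / nrow(events)
}

#' Session timing configuration
#'
#' Timeline constants in TR (1.5 s) units: the analyzed BOLD window is
#' shifted 3 TRs (4.5 s) after the on-screen station to account for
#' hemodynamic lag, plus 1 TR of analysis time before feedback appears
#' (4 TRs, 6 s, after station end). Both probe lead times reported for the
#' display sequence (probe 4 s before the station window, station starting
#' 2 s after the probe response) are exposed as configuration.
#'
#' @param tr_seconds Repetition time in seconds.
#' @param hemodynamic_shift_trs Hemodynamic shift in TRs.
#' @param analysis_delay_trs Analysis time in TRs.
#' @param probe_lead_seconds Probe onset lead before the station, seconds.
#' @param probe_to_station_seconds Gap from probe response to station start.
#' @param run_trs Run length in TRs (about 12 minutes at defaults).
#' @return A list of class `timing_config`.
#' @export
timing_config <- function(tr_seconds = 1.5, hemodynamic_shift_trs = 3,
                          analysis_delay_trs = 1, probe_lead_seconds = 4,
                          probe_to_station_seconds = 2, run_trs = 480) {
  stopifnot(tr_seconds > 0, hemodynamic_shift_trs >= 0,
            analysis_delay_trs >= 0, run_trs > 0)
  structure(
    list(tr_seconds = tr_seconds,
         hemodynamic_shift_trs = as.integer(hemodynamic_shift_trs),
         analysis_delay_trs = as.integer(analysis_delay_trs),
         probe_lead_seconds = probe_lead_seconds,
         probe_to_station_seconds = probe_to_station_seconds,
         run_trs = as.integer(run_trs)),
    class = "timing_config"
  )
}

#' Number of TRs spanned by a hemodynamic lag
#'
#' @param lag_seconds Hemodynamic lag in seconds.
#' @param tr_seconds Repetition time in seconds.
#' @return Integer number of TRs (`lag_seconds / tr_seconds`).
#' @export
lag_in_trs <- function(lag_seconds, tr_seconds = 1.5) {
  shift <- lag_seconds / tr_seconds
  if (abs(shift - round(shift)) > 1e-9) {
    stop("lag is not a whole number of TRs", call. = FALSE)
  }
  as.integer(round(shift))
}

#' Timeline of one station
#'
#' Computes, in TR units, the probe onset, the on-screen station window, the
#' hemodynamically shifted window actually analyzed, and the feedback onset
#' (station end + shift + analysis delay).
#'
#' @param station One row of a station data.frame (`start_tr`, `n_trs`).
#' @param timing A [timing_config()].
#' @return List with `probe_onset_tr` (fractional TRs), `station_window`
#'   (first/last TR), `analyzed_window`, `feedback_onset_tr`.
#' @export
station_timeline <- function(station, timing = timing_config()) {
  stopifnot(inherits(timing, "timing_config"))
  start <- station$start_tr
  end <- station$start_tr + station$n_trs - 1L
  shift <- timing$hemodynamic_shift_trs
  analyzed <- c(start + shift, end + shift)
  if (analyzed[2] > timing$run_trs) {
    stop("analyzed window extends past the end of the run", call. = FALSE)
  }
  list(
    probe_onset_tr = start - timing$probe_lead_seconds / timing$tr_seconds,
    station_window = c(start, end),
    analyzed_window = analyzed,
    feedback_onset_tr = end + shift + timing$analysis_delay_trs
  )
}
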