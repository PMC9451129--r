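# Synthetic cohort generation: interpretation templates, training and pilot
# cohorts, and station-level activity patterns for closed-loop agents.

#' Build a pair of interpretation templates
#'
#' Constructs two activity templates in an abstract feature space, one for
#' each story interpretation ("cheating" and "paranoid"). The templates share
#' a random base pattern and differ only along a random unit direction, so
#' their Euclidean distance equals `separation` exactly. All downstream
#' decodability is controlled by this separation relative to the unit-SD
#' pattern noise.
#'
#' @param n_features Number of features (>= 2). Stands in for voxels of a
#'   theory-of-mind/default-mode ROI; default 100.
#' @param separation Nonnegative Euclidean distance between the two templates.
#' @param seed Integer seed; the construction is deterministic given the seed.
#' @return An object of class `template_pair`: a list with
#'   `template_cheating`, `template_paranoid` (numeric vectors of length
#'   `n_features`), `direction` (unit vector from paranoid to cheating) and
#'   `separation`.
#' @examples
#' tp <- make_templates(n_features = 10, separation = 2, seed = 1)
#' sqrt(sum((tp$template_cheating - tp$template_paranoid)^2))
#' @export
make_templates <- function(n_features = 100, separation = 2, seed = 1) {
  if (!is.numeric(n_features) || length(n_features) != 1 || n_features < 2) {
    stop("`n_features` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(separation) || length(separation) != 1 || separation < 0) {
    stop("`separation` must be a single nonnegative number", call. = FALSE)
  }
  n_features <- as.integer(n_features)
  set.seed(as.integer(seed))
  base <- stats::rnorm(n_features)
  dir <- stats::rnorm(n_features)
  dir <- dir / sqrt(sum(dir^2))
  structure(
    list(
      template_cheating = base + (separation / 2) * dir,
      template_paranoid = base - (separation / 2) * dir,
      direction = dir,
      separation = separation
    ),
    class = "template_pair"
  )
}

#' Default station layout for one run
#'
#' Seven analysis windows ("stations") per run, with durations between 3 and
#' 16.5 s at a 1.5 s TR, disjoint and ordered within a roughly 12-minute run.
#' Each station carries a stimulus-driven `bias` in \[-1, 1\]: the narrative
#' leans toward the cheating (+) or paranoid (-) interpretation at that point
#' of the story regardless of the listener. Defaults span \[-0.6, 0.6\],
#' emulating pilot observations of strongly biased stations and exercising
#' the pilot normalization.
#'
#' @param biases Numeric length-7 vector of station biases in \[-1, 1\].
#' @return A data.frame with columns `station_index` (0..6), `start_tr`,
#'   `n_trs` and `bias`.
#' @export
default_stations <- function(biases = seq(-0.6, 0.6, length.out = 7)) {
  stopifnot(length(biases) == 7, all(abs(biases) <= 1))
  st <- data.frame(
    station_index = 0:6,
    start_tr = c(40L, 100L, 160L, 230L, 300L, 370L, 440L),
    n_trs = c(2L, 4L, 6L, 8L, 10L, 11L, 5L),
    bias = as.numeric(biases)
  )
  validate_stations(st)
  st
}

validate_stations <- function(stations) {
  stopifnot(is.data.frame(stations),
            all(c("station_index", "start_tr", "n_trs", "bias") %in%
                  names(stations)))
  dur <- stations$n_trs * 1.5
  if (any(dur < 3 | dur > 16.5)) {
    stop("station durations must lie in [3, 16.5] seconds", call. = FALSE)
  }
  ends <- stations$start_tr + stations$n_trs
  if (is.unsorted(stations$start_tr, strictly = TRUE) ||
      any(utils::head(ends, -1) > utils::tail(stations$start_tr, -1))) {
    stop("station windows must be disjoint and ordered", call. = FALSE)
  }
  invisible(stations)
}

#' Cohort configuration
#'
#' Bundles the sizes and noise parameters of a simulated cohort. Defaults
#' match the study design: 20 participants, balanced 10/10 assignment to the
#' cheating and paranoid groups, 4 runs of 7 stations.
#'
#' @param n_participants Cohort size (even, split equally between groups).
#' @param n_runs Runs per participant.
#' @param n_features Feature-space dimension.
#' @param snr Scaling of the latent interpretation signal relative to the
#'   unit-SD pattern noise.
#' @param seed Master seed for the cohort.
#' @return A list of class `cohort_config` including a balanced
#'   `group_assignment` factor.
#' @export
cohort_config <- function(n_participants = 20, n_runs = 4, n_features = 100,
                          snr = 1, seed = 1) {
  stopifnot(n_participants >= 2, n_participants %% 2 == 0,
            n_runs >= 1, n_features >= 2, snr > 0)
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_runs = as.integer(n_runs),
      n_features = as.integer(n_features),
      snr = snr,
      seed = as.integer(seed),
      group_assignment = rep(c("cheating", "paranoid"),
                             each = n_participants / 2)
    ),
    class = "cohort_config"
  )
}

#' Sample one station's activity pattern
#'
#' The pattern model: midpoint of the two templates, shifted along the
#' discriminant direction by the station's stimulus bias plus the agent's
#' latent interpretation (`snr * theta`), plus isotropic unit-SD Gaussian
#' noise. The expected projection onto the discriminant direction is strictly
#' increasing in `theta` with slope `snr * separation / 2`.
#'
#' @param theta Latent interpretation in \[-1, 1\] (+1 cheating, -1 paranoid).
#' @param bias Station stimulus bias in \[-1, 1\].
#' @param templates A `template_pair`.
#' @param snr Signal scaling (see [cohort_config()]).
#' @param noise_sd Noise SD (default 1; 0 gives the noiseless expectation).
#' @return Numeric feature vector of length `n_features`.
#' @export
sample_station_pattern <- function(theta, bias, templates, snr = 1,
                                   noise_sd = 1) {
  stopifnot(inherits(templates, "template_pair"))
  mid <- (templates$template_cheating + templates$template_paranoid) / 2
  shift <- (bias + snr * theta) * (templates$separation / 2)
  mid + shift * templates$direction +
    stats::rnorm(length(mid), sd = noise_sd)
}

#' Generate a labeled training cohort
#'
#' Emulates the prior-study data the station decoders are trained on:
#' participants explicitly instructed to hold one interpretation, so the
#' latent state is pinned at +1 (cheating) or -1 (paranoid) according to the
#' assigned label. One pattern per participant x run x station.
#'
#' @param config A [cohort_config()].
#' @param templates A [make_templates()] pair.
#' @param stations A station data.frame, see [default_stations()].
#' @return A data.frame with identifier columns `participant`, `group`,
#'   `run`, `station_index` and feature columns `f1..fN`.
#' @export
generate_training_cohort <- function(config, templates,
                                     stations = default_stations()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_stations(stations)
  set.seed(config$seed)
  rows <- list()
  k <- 1L
  for (p in seq_len(config$n_participants)) {
    grp <- config$group_assignment[p]
    theta <- if (grp == "cheating") 1 else -1
    for (r in seq_len(config$n_runs)) {
      for (s in seq_len(nrow(stations))) {
        pat <- sample_station_pattern(theta, stations$bias[s], templates,
                                      snr = config$snr)
        rows[[k]] <- c(p, r, stations$station_index[s], pat)
        k <- k + 1L
      }
    }
  }
  m <- do.call(rbind, rows)
  out <- data.frame(
    participant = as.integer(m[, 1]),
    group = config$group_assignment[m[, 1]],
    run = as.integer(m[, 2]),
    station_index = as.integer(m[, 3])
  )
  feats <- m[, -(1:3), drop = FALSE]
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  cbind(out, as.data.frame(feats))
}

#' Generate a pilot cohort of decoded probabilities
#'
#' Simulates a free-interpretation pilot: each pilot participant's latent
#' interpretation `theta` is drawn uniformly from \[-1, 1\] and held for the
#' session, patterns are sampled at every run x station, and the trained
#' station decoders score them. The resulting per-station p(c) samples,
#' pooled over participants and runs from both conditions, are the reference
#' distribution for the feedback normalization.
#'
#' @param config A [cohort_config()] (its `n_participants` is the pilot size).
#' @param templates A `template_pair`.
#' @param models A list of 7 station models from [train_station_models()].
#' @param stations Station data.frame.
#' @return A data.frame with columns `participant`, `run`, `station_index`,
#'   `p_c`.
#' @export
generate_pilot_cohort <- function(config, templates, models,
                                  stations = default_stations()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_stations(stations)
  set.seed(config$seed)
  thetas <- stats::runif(config$n_participants, -1, 1)
  out <- expand.grid(
    station_index = stations$station_index,
    run = seq_len(config$n_runs),
    participant = seq_len(config$n_participants)
  )[, 3:1]
  pc <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    s <- match(out$station_index[i], stations$station_index)
    pat <- sample_station_pattern(thetas[out$participant[i]],
                                  stations$bias[s], templates,
                                  snr = config$snr)
    pc[i] <- predict_cheating_probability(models[[s]], pat)
  }
  out$p_c <- pc
  rownames(out) <- NULL
  out
}

#' Generate a post-scan questionnaire from an agent's final state
#'
#' Produces the 27 comprehension answers, 12 interpretation answers and four
#' empathy ratings from the agent's latent interpretation `theta`.
#' Interpretation items are Bernoulli with P(cheating-consistent) =
#' (1 + theta) / 2, coded +1/-1; one item (the excluded one, mirroring the
#' question all participants answered from prior knowledge) is flagged
#' non-scored. Comprehension answers are correct with a fixed high
#' probability independent of `theta`. Empathy ratings for Arthur increase
#' and for Lee decrease with `theta` (Joanie tracks Lee; "the girl" is
#' neutral), discretized to the 1-5 scale.
#'
#' @param theta Final latent interpretation in \[-1, 1\].
#' @param p_comprehension Per-item probability of a correct comprehension
#'   answer (default 0.9).
#' @param key Comprehension answer key, see [comprehension_key()].
#' @return An object of class `questionnaire_response`: list with
#'   `comprehension_answers` (length 27), `interpretation_answers`
#'   (length 12, values +1/-1), `excluded_item` (index of the non-scored
#'   interpretation item), `empathy` (named integer vector for Arthur, Lee,
#'   Joanie, girl).
#' @export
generate_questionnaire <- function(theta, p_comprehension = 0.9,
                                   key = comprehension_key()) {
  stopifnot(length(theta) == 1, theta >= -1, theta <= 1)
  options <- c("a", "b", "c", "d")
  comp <- vapply(seq_along(key), function(i) {
    if (stats::runif(1) < p_comprehension) key[i]
    else sample(setdiff(options, key[i]), 1)
  }, character(1))
  interp <- ifelse(stats::runif(12) < (1 + theta) / 2, 1L, -1L)
  clamp5 <- function(x) as.integer(pmin(5, pmax(1, round(x))))
  empathy <- c(
    Arthur = clamp5(3 + 1.5 * theta + stats::rnorm(1, sd = 0.5)),
    Lee    = clamp5(3 - 1.5 * theta + stats::rnorm(1, sd = 0.5)),
    Joanie = clamp5(3 - 1.0 * theta + stats::rnorm(1, sd = 0.5)),
    girl   = clamp5(3 + stats::rnorm(1, sd = 0.5))
  )
  structure(
    list(
      comprehension_answers = comp,
      interpretation_answers = interp,
      excluded_item = 12L,
      empathy = empathy
    ),
    class = "questionnaire_response"
  )
}

#' Fixed comprehension answer key
#'
#' A deterministic 27-item single-choice key used by the synthetic
#' questionnaire generator and the comprehension scorer.
#'
#' @return Character vector of length 27 with values in a-d.
#' @export
comprehension_key <- function() {
  rep(c("a", "b", "c", "d"), length.out = 27)
}
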