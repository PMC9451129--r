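# Participant- and group-level statistics: decoding accuracy, median split,
# t tests, correlations, Bonferroni correction, and run/station aggregates.

#' Per-participant decoding accuracy
#'
#' The station-to-station correspondence between behavioral probe responses
#' and classifier evidence: the mean p(c) over stations where the
#' participant declared the cheating lens minus the mean p(c) over stations
#' where they declared the paranoid lens, pooled over all runs. Positive
#' values mean the decoder tracks the interpretation the participant *says*
#' they are adopting, regardless of assigned group.
#'
#' @param log A `session_log`.
#' @return Scalar in \[-1, 1\], or `NA` (with a warning) when one probe
#'   label was never chosen, in which case the measure is undefined.
#' @export
decoding_accuracy <- function(log) {
  stopifnot(inherits(log, "session_log"))
  ev <- log$events
  cheat <- ev$p_c[ev$probe_choice == "cheating"]
  paran <- ev$p_c[ev$probe_choice == "paranoid"]
  if (length(cheat) == 0 || length(paran) == 0) {
    warning(sprintf(
      "participant %s never chose the %s lens; decoding accuracy undefined",
      log$participant_id,
      if (length(cheat) == 0) "cheating" else "paranoid"), call. = FALSE)
    return(NA_real_)
  }
  mean(cheat) - mean(paran)
}

#' Summarize a cohort of session logs
#'
#' @param logs List of `session_log` objects.
#' @return Data.frame with one row per participant: `participant_id`,
#'   `group`, `decoding_accuracy`, mean delivered reward and mean p(c).
#' @export
summarize_participants <- function(logs) {
  do.call(rbind, lapply(logs, function(lg) {
    data.frame(
      participant_id = lg$participant_id,
      group = lg$group,
      decoding_accuracy = suppressWarnings(decoding_accuracy(lg)),
      mean_p_c = mean(lg$events$p_c),
      mean_score_reward = mean(lg$events$score_reward),
      final_theta = lg$final_state$theta
    )
  }))
}

#' Median split by decoding accuracy, within assigned group
#'
#' Splits each assigned interpretation group at its median decoding
#' accuracy: the top half goes to the "best"-decoding group, the bottom half
#' to "worst". With the standard 10/10 cohort this yields 5 best and 5 worst
#' from each group. Ties and the split point are resolved deterministically
#' by ranking on (decoding accuracy, participant id).
#'
#' @param summaries Data.frame with `participant_id`, `group`,
#'   `decoding_accuracy` (no `NA`s).
#' @return The input with an added `split` column (`"best"`/`"worst"`).
#' @export
median_split <- function(summaries) {
  stopifnot(all(c("participant_id", "group", "decoding_accuracy") %in%
                  names(summaries)))
  if (anyNA(summaries$decoding_accuracy)) {
    stop("decoding accuracy must be defined for all participants",
         call. = FALSE)
  }
  summaries$split <- NA_character_
  for (g in unique(summaries$group)) {
    idx <- which(summaries$group == g)
    if (length(idx) %% 2 != 0) {
      stop(sprintf("group %s has odd size; median split is ambiguous", g),
           call. = FALSE)
    }
    ord <- idx[order(-summaries$decoding_accuracy[idx],
                     summaries$participant_id[idx])]
    summaries$split[ord[seq_len(length(idx) / 2)]] <- "best"
    summaries$split[ord[-seq_len(length(idx) / 2)]] <- "worst"
  }
  summaries
}

#' Pooled-variance two-sample t test
#'
#' Student's independent-samples t test with pooled variance
#' (df = n1 + n2 - 2; 18 for the standard 10 vs 10 comparison). One-tailed
#' tests honor the stated direction: `direction = "greater"` tests whether
#' the first group's mean exceeds the second's.
#'
#' @param values Numeric vector of observations.
#' @param group_labels Two-level grouping aligned with `values`; the first
#'   level (factor order, or first occurrence) is the "first" group.
#' @param tails `"two"` or `"one"`.
#' @param direction For one-tailed tests, `"greater"` or `"less"`.
#' @return List with `t`, `df`, `p`.
#' @export
group_ttest <- function(values, group_labels, tails = c("two", "one"),
                        direction = c("greater", "less")) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  f <- if (is.factor(group_labels)) droplevels(group_labels)
       else factor(group_labels, levels = unique(group_labels))
  if (nlevels(f) != 2 || any(table(f) < 2)) {
    stop("need exactly two groups with n >= 2 each", call. = FALSE)
  }
  alt <- if (tails == "two") "two.sided" else direction
  ht <- stats::t.test(values[f == levels(f)[1]], values[f == levels(f)[2]],
                      var.equal = TRUE, alternative = alt)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson correlation with two-tailed p value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r` and two-tailed `p` (t transform on n - 2 df).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = unname(ht$p.value))
}

#' Bonferroni correction
#'
#' Adjusts p values for a family of tests: `min(1, p * family_size)`.
#'
#' @param p_values Numeric p values in \[0, 1\].
#' @param family_size Number of tests in the family (default
#'   `length(p_values)`).
#' @return Adjusted p values.
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1),
            family_size >= length(p_values))
  stats::p.adjust(p_values, method = "bonferroni", n = family_size)
}

#' Aggregate session logs into mean +/- sem tables
#'
#' Long-format group summaries of the decoded probability, the delivered
#' reward and the probe-correct fraction (probe choice matching the assigned
#' group), grouped by any combination of `run`, `station`, `group` and
#' `split`. The standard error uses the per-cell participant n; cells with a
#' single participant get `NA` sem.
#'
#' @param logs List of `session_log` objects.
#' @param by Character subset of `c("run", "station", "group", "split")`.
#' @param split Optional named split assignment (`participant_id` ->
#'   `"best"`/`"worst"`), required when `"split"` is in `by`.
#' @return Data.frame with the grouping columns plus `measure`, `mean`,
#'   `sem`, `n`.
#' @export
aggregate_sessions <- function(logs, by = c("run", "group"), split = NULL) {
  stopifnot(length(logs) >= 1,
            all(by %in% c("run", "station", "group", "split")))
  per <- do.call(rbind, lapply(logs, function(lg) {
    ev <- lg$events
    ev$participant_id <- lg$participant_id
    ev$group <- lg$group
    ev$probe_correct <- as.numeric(ev$probe_choice == lg$group)
    ev
  }))
  if ("split" %in% by) {
    stopifnot(!is.null(split))
    per$split <- unname(split[as.character(per$participant_id)])
  }
  keymap <- c(run = "run", station = "station_index", group = "group",
              split = "split")
  keys <- unname(keymap[by])
  measures <- c(p_c = "p_c", score_reward = "score_reward",
                probe_correct_fraction = "probe_correct")
  out <- list()
  for (m in names(measures)) {
    # participant-level means first, then group mean +/- sem across them
    pl <- stats::aggregate(
      per[[measures[m]]],
      by = c(per[c(keys, "participant_id")]),
      FUN = mean
    )
    gl <- do.call(rbind, lapply(
      split(pl, pl[keys], drop = TRUE),
      function(d) {
        cell <- d[1, keys, drop = FALSE]
        cell$measure <- m
        cell$mean <- mean(d$x)
        cell$sem <- if (nrow(d) > 1) stats::sd(d$x) / sqrt(nrow(d))
                    else NA_real_
        cell$n <- nrow(d)
        cell
      }))
    out[[m]] <- gl
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
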