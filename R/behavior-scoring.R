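# Post-scan questionnaire scoring: comprehension, interpretation bias,
# empathy differences, and the "correct" (group-aligned) transforms.

#' Interpretation score from the questionnaire
#'
#' Each scored interpretation item is coded +1 (cheating-consistent) or -1
#' (paranoid-consistent); the score is the mean code over the 11 scored
#' items (one of the 12 items is excluded from scoring). +1 means every
#' answer was consistent with the cheating interpretation, -1 with the
#' paranoid interpretation.
#'
#' @param response A `questionnaire_response`.
#' @return Scalar in \[-1, 1\].
#' @export
score_interpretation <- function(response) {
  stopifnot(inherits(response, "questionnaire_response"))
  ans <- response$interpretation_answers
  if (length(ans) != 12) {
    stop("expected 12 interpretation items", call. = FALSE)
  }
  scored <- ans[-response$excluded_item]
  if (length(scored) != 11 || !all(scored %in% c(-1, 1))) {
    stop("expected 11 scored items coded +1/-1", call. = FALSE)
  }
  mean(scored)
}

#' Align a bias score with the assigned group
#'
#' Multiplies scores of paranoid-group participants by -1, so that for every
#' participant a positive value means "consistent with the assigned
#' interpretation". Applies identically to interpretation scores and to
#' empathy differences. The transform is its own inverse.
#'
#' @param score Numeric score(s).
#' @param group `"cheating"` or `"paranoid"` (vectorized).
#' @return The group-aligned ("correct") score.
#' @export
correct_transform <- function(score, group) {
  if (!all(group %in% c("cheating", "paranoid"))) {
    stop("group must be \"cheating\" or \"paranoid\"", call. = FALSE)
  }
  n <- max(length(score), length(group))
  out <- ifelse(rep_len(group, n) == "paranoid", -rep_len(score, n),
                rep_len(score, n))
  if (is.integer(score)) out <- as.integer(out)
  out
}

#' Empathy difference between Arthur and Lee
#'
#' A single score of empathic bias: the 1-5 empathy rating for Arthur minus
#' the rating for Lee. Positive values are expected under the cheating
#' interpretation (sympathy with the possibly-betrayed Arthur), negative
#' under the paranoid one.
#'
#' @param empathy Named numeric vector with at least `Arthur` and `Lee`.
#' @return Integer in \[-4, 4\].
#' @export
empathy_difference <- function(empathy) {
  if (!all(c("Arthur", "Lee") %in% names(empathy)) ||
      anyNA(empathy[c("Arthur", "Lee")])) {
    stop("empathy ratings for Arthur and Lee are required", call. = FALSE)
  }
  as.integer(empathy[["Arthur"]] - empathy[["Lee"]])
}

#' Comprehension score
#'
#' Fraction of the 27 comprehension items answered exactly as in the key.
#'
#' @param response A `questionnaire_response`.
#' @param key Character vector of length 27, see [comprehension_key()].
#' @return Fraction in \[0, 1\].
#' @export
score_comprehension <- function(response, key = comprehension_key()) {
  stopifnot(inherits(response, "questionnaire_response"))
  ans <- response$comprehension_answers
  if (length(ans) != length(key)) {
    stop("answer/key length mismatch", call. = FALSE)
  }
  mean(ans == key)
}

#' All behavioral scores for one participant
#'
#' Convenience wrapper returning comprehension, interpretation, empathy
#' difference and their group-aligned ("correct") versions as one row.
#'
#' @param response A `questionnaire_response`.
#' @param group Assigned group.
#' @param key Comprehension key.
#' @return One-row data.frame with `comprehension`, `interpretation`,
#'   `correct_interpretation`, `empathy_diff`, `correct_empathy`.
#' @export
score_behavior <- function(response, group, key = comprehension_key()) {
  interp <- score_interpretation(response)
  ed <- empathy_difference(response$empathy)
  data.frame(
    comprehension = score_comprehension(response, key),
    interpretation = interp,
    correct_interpretation = correct_transform(interp, group),
    empathy_diff = ed,
    correct_empathy = correct_transform(ed, group)
  )
}
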