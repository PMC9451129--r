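# Per-station probabilistic decoders of the listener's interpretation.

#' Train the per-station logistic decoders
#'
#' Fits one L2-regularized logistic regression per station on the labeled
#' training cohort, predicting the cheating interpretation from the station's
#' activity pattern. The penalty strength follows the sklearn-style inverse
#' regularization `C` (default 1): the ridge penalty is `1 / (C * n)` on
#' glmnet's scale, so the two parameterizations optimize the same convex
#' objective. Features are not standardized (the pattern space is already
#' homoscedastic by construction).
#'
#' @param training_set A data.frame from [generate_training_cohort()]:
#'   `station_index`, `group` and feature columns `f*`.
#' @param regularization_c Positive inverse regularization strength.
#' @return A list of `station_model` objects (one per station, in
#'   `station_index` order), each with `station_index`, `weights`,
#'   `intercept` and `regularization_c`.
#' @export
train_station_models <- function(training_set, regularization_c = 1) {
  stopifnot(is.data.frame(training_set), regularization_c > 0)
  feat_cols <- grep("^f[0-9]+$", names(training_set), value = TRUE)
  stopifnot(length(feat_cols) >= 2)
  stations <- sort(unique(training_set$station_index))
  lapply(stations, function(s) {
    sub <- training_set[training_set$station_index == s, , drop = FALSE]
    y <- factor(sub$group, levels = c("paranoid", "cheating"))
    if (nlevels(droplevels(y)) < 2) {
      stop(sprintf("station %d training data contain a single class", s),
           call. = FALSE)
    }
    x <- as.matrix(sub[, feat_cols, drop = FALSE])
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = 1 / (regularization_c * nrow(x)),
                          standardize = FALSE, thresh = 1e-12)
    structure(
      list(
        station_index = as.integer(s),
        weights = as.numeric(fit$beta[, 1]),
        intercept = as.numeric(fit$a0),
        regularization_c = regularization_c
      ),
      class = "station_model"
    )
  })
}

#' Decoded probability of the cheating interpretation
#'
#' Applies a station model to an activity pattern and returns
#' p(c) = logistic(weights . pattern + intercept), the probability that the
#' listener currently holds the cheating interpretation; the paranoid
#' probability is exactly `1 - p(c)`.
#'
#' @param model A `station_model`.
#' @param pattern Numeric feature vector matching the training dimension.
#' @return Scalar in (0, 1).
#' @export
predict_cheating_probability <- function(model, pattern) {
  stopifnot(inherits(model, "station_model"))
  if (length(pattern) != length(model$weights)) {
    stop(sprintf("pattern length %d does not match model dimension %d",
                 length(pattern), length(model$weights)), call. = FALSE)
  }
  stats::plogis(sum(model$weights * pattern) + model$intercept)
}
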