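test_that("templates are built at the requested separation", {
  # zero separation collapses the pair
  tp0 <- make_templates(10, separation = 0, seed = 1)
  expect_identical(tp0$template_cheating, tp0$template_paranoid)

  # distance equals separation, recomputed with an independent norm routine
  for (sep in c(0.5, 1, 2)) {
    tp <- make_templates(10, separation = sep, seed = 1)
    d <- norm(matrix(tp$template_cheating - tp$template_paranoid), "F")
    expect_equal(d, sep, tolerance = 1e-12)
  }

  # different seeds give different bases but the same pairwise distance
  a <- make_templates(50, 1, seed = 1)
  b <- make_templates(50, 1, seed = 2)
  expect_false(isTRUE(all.equal(a$template_cheating, b$template_cheating)))
  expect_equal(sqrt(sum((b$template_cheating - b$template_paranoid)^2)), 1)

  expect_error(make_templates(1, 1, 1), "n_features")
  expect_error(make_templates(10, -1, 1), "separation")
})

test_that("station patterns have the defined expectation and theta slope", {
  tp <- make_templates(20, separation = 2, seed = 4)
  mid <- (tp$template_cheating + tp$template_paranoid) / 2

  # noiseless symmetry: theta = 0, bias = 0 sits at the midpoint
  expect_equal(sample_station_pattern(0, 0, tp, snr = 1, noise_sd = 0), mid)

  # theta = +1 lands on the cheating side of the midpoint
  p1 <- sample_station_pattern(1, 0, tp, snr = 1, noise_sd = 0)
  expect_gt(sum((p1 - mid) * tp$direction), 0)
  expect_equal(p1, tp$template_cheating)

  # Monte-Carlo oracle: sample mean within 3 SE of the defined expectation
  set.seed(42)
  theta <- 0.3; bias <- -0.2; snr <- 1.5
  draws <- replicate(10000,
                     sum(sample_station_pattern(theta, bias, tp, snr) *
                           tp$direction))
  expected_proj <- sum(mid * tp$direction) +
    (bias + snr * theta) * tp$separation / 2
  expect_lt(abs(mean(draws) - expected_proj), 3 / sqrt(10000))

  # slope of the expected projection in theta is snr * separation / 2
  e1 <- sum(sample_station_pattern(0.9, 0, tp, snr, noise_sd = 0) *
              tp$direction)
  e0 <- sum(sample_station_pattern(0.1, 0, tp, snr, noise_sd = 0) *
              tp$direction)
  expect_equal((e1 - e0) / 0.8, snr * tp$separation / 2, tolerance = 1e-10)
})

test_that("training cohorts have exact counts, determinism and separability", {
  tp <- make_templates(20, separation = 4, seed = 7)
  cfg <- cohort_config(20, 1, 20, seed = 8)
  tc <- generate_training_cohort(cfg, tp)
  expect_equal(nrow(tc), 20 * 1 * 7)
  expect_equal(as.vector(table(tc$group)), c(70, 70))

  # byte-identical regeneration under the same seed
  expect_identical(tc, generate_training_cohort(cfg, tp))

  # large separation, small effective noise: classes linearly separable per
  # station along the template direction (independent separator oracle)
  tp_big <- make_templates(20, separation = 10, seed = 7)
  tc_big <- generate_training_cohort(cohort_config(20, 1, 20, seed = 8),
                                     tp_big)
  feats <- as.matrix(tc_big[, grep("^f", names(tc_big))])
  proj <- feats %*% tp_big$direction
  for (s in 0:6) {
    i <- tc_big$station_index == s
    expect_gt(min(proj[i & tc_big$group == "cheating"]),
              max(proj[i & tc_big$group == "paranoid"]))
  }
})

test_that("pilot cohorts have exact counts and reflect station bias", {
  cfg <- cohort_config(10, 4, 30, seed = 21)
  pil <- generate_pilot_cohort(cfg, fix_templates, fix_models, fix_stations)
  expect_equal(nrow(pil), 10 * 4 * 7)
  expect_equal(unname(table(pil$station_index)), rep(40L, 7),
               ignore_attr = TRUE)
  expect_true(all(pil$p_c > 0 & pil$p_c < 1))

  # positive-bias stations decode higher p(c) than negative-bias ones.
  # Decoders trained on biased stations absorb the bias into their
  # intercepts, so the stimulus-driven effect is isolated with decoders
  # trained on a bias-free stimulus.
  flat <- default_stations(biases = rep(0, 7))
  m0 <- train_station_models(generate_training_cohort(
    cohort_config(12, 2, 30, seed = 22), fix_templates, flat))
  pil2 <- generate_pilot_cohort(cohort_config(40, 4, 30, seed = 23),
                                fix_templates, m0, fix_stations)
  mu <- tapply(pil2$p_c, pil2$station_index, mean)
  bias <- fix_stations$bias[match(as.integer(names(mu)),
                                  fix_stations$station_index)]
  expect_gt(mean(mu[bias > 0]), mean(mu[bias < 0]))
  expect_gt(stats::cor(as.numeric(mu), bias), 0.8)
})

test_that("questionnaires track the latent interpretation", {
  # theta = +1: interpretation items are cheating-consistent with prob 1
  set.seed(1)
  q <- generate_questionnaire(1)
  expect_length(q$comprehension_answers, 27)
  expect_length(q$interpretation_answers, 12)
  expect_true(all(q$interpretation_answers == 1L))
  expect_true(all(q$empathy >= 1 & q$empathy <= 5))

  set.seed(2)
  expect_true(all(generate_questionnaire(-1)$interpretation_answers == -1L))

  # binomial oracle: item mean near 2 * P(+1) - 1 at theta = 0.5
  set.seed(3)
  draws <- replicate(2000, mean(generate_questionnaire(0.5,
    p_comprehension = 1)$interpretation_answers))
  p <- (1 + 0.5) / 2
  se <- sqrt(p * (1 - p) / 12) * 2 / sqrt(2000)
  expect_lt(abs(mean(draws) - (2 * p - 1)), 3 * se)

  # theta = 0 symmetry over many draws
  set.seed(4)
  m0 <- mean(replicate(2000,
                       mean(generate_questionnaire(0)$interpretation_answers)))
  expect_lt(abs(m0), 3 * sqrt(0.25 / 12) * 2 / sqrt(2000))
})

test_that("degenerate zero-separation cohorts decode at chance", {
  tp <- make_templates(20, separation = 0, seed = 31)
  tc <- generate_training_cohort(cohort_config(20, 2, 20, seed = 32), tp)
  m <- train_station_models(tc)
  # held-out patterns from the same null model
  set.seed(33)
  acc <- mean(vapply(1:200, function(i) {
    g <- sample(c("cheating", "paranoid"), 1)
    pat <- sample_station_pattern(ifelse(g == "cheating", 1, -1), 0, tp)
    pc <- predict_cheating_probability(m[[sample(7, 1)]], pat)
    (pc > 0.5) == (g == "cheating")
  }, logical(1)))
  expect_lt(abs(acc - 0.5), 0.12)  # binomial 3 SE at n = 200 is ~0.106
})
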