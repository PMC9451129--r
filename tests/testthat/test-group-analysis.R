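fake_log <- function(id, group, p_c, choice) {
  structure(
    list(participant_id = id, group = group,
         events = data.frame(run = rep(1L, length(p_c)),
                             station_index = seq_along(p_c) - 1L,
                             p_c = p_c, score_reward = 0,
                             probe_choice = choice),
         final_state = agent_state(), seed = 1L, mode = "live"),
    class = "session_log")
}

test_that("decoding accuracy contrasts p(c) by declared lens", {
  lg <- fake_log(1, "cheating", c(0.7, 0.7, 0.4, 0.4),
                 c("cheating", "cheating", "paranoid", "paranoid"))
  expect_equal(decoding_accuracy(lg), 0.3)
  # identical p(c) for both lenses
  lg0 <- fake_log(1, "cheating", rep(0.6, 4),
                  c("cheating", "paranoid", "cheating", "paranoid"))
  expect_equal(decoding_accuracy(lg0), 0)
  # brute-force oracle on a random log
  set.seed(151)
  pc <- runif(28); ch <- sample(c("cheating", "paranoid"), 28, TRUE)
  lgr <- fake_log(2, "paranoid", pc, ch)
  sc <- sp <- 0; nc <- np <- 0
  for (i in 1:28) {
    if (ch[i] == "cheating") { sc <- sc + pc[i]; nc <- nc + 1 }
    else { sp <- sp + pc[i]; np <- np + 1 }
  }
  expect_equal(decoding_accuracy(lgr), sc / nc - sp / np,
               tolerance = 1e-12)
  # a never-chosen lens leaves the measure undefined, flagged not dropped
  one <- fake_log(3, "cheating", c(0.5, 0.6), c("cheating", "cheating"))
  expect_warning(res <- decoding_accuracy(one), "never chose")
  expect_true(is.na(res))
})

test_that("the median split yields equal best/worst halves per group", {
  smry <- data.frame(
    participant_id = 1:20,
    group = rep(c("cheating", "paranoid"), each = 10),
    decoding_accuracy = c(seq(-0.2, 0.25, length.out = 10),
                          seq(0.3, -0.15, length.out = 10)))
  sp <- median_split(smry)
  tab <- table(sp$group, sp$split)
  expect_true(all(tab == 5))
  # membership equals an independent sort-based oracle
  for (g in c("cheating", "paranoid")) {
    d <- smry[smry$group == g, ]
    best_ids <- d$participant_id[order(-d$decoding_accuracy,
                                       d$participant_id)][1:5]
    expect_setequal(sp$participant_id[sp$group == g & sp$split == "best"],
                    best_ids)
  }
  # all-equal accuracies resolve deterministically, sizes still 5 + 5
  smry$decoding_accuracy <- 0.1
  sp2 <- median_split(smry)
  expect_true(all(table(sp2$group, sp2$split) == 5))
  expect_setequal(
    sp2$participant_id[sp2$group == "cheating" & sp2$split == "best"], 1:5)

  odd <- smry[1:19, ]
  expect_error(median_split(odd), "odd size")
  smry$decoding_accuracy[1] <- NA
  expect_error(median_split(smry), "defined")
})

test_that("group t tests match the pooled-variance closed form", {
  # closed-form oracle on fixed small vectors
  x <- c(2.1, 3.4, 1.9, 2.8, 3.0)
  y <- c(1.2, 2.2, 1.8, 1.5, 2.0, 1.1)
  vals <- c(x, y)
  lab <- rep(c("a", "b"), c(5, 6))
  res <- group_ttest(vals, lab)
  sp2 <- ((5 - 1) * var(x) + (6 - 1) * var(y)) / (5 + 6 - 2)
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 6))
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$df, 9)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 9), tolerance = 1e-10)

  # one-tailed p honors the direction
  g <- group_ttest(vals, lab, tails = "one", direction = "greater")
  expect_equal(g$p, pt(t_oracle, 9, lower.tail = FALSE), tolerance = 1e-10)
  l <- group_ttest(vals, lab, tails = "one", direction = "less")
  expect_equal(l$p, pt(t_oracle, 9), tolerance = 1e-10)

  # 10 vs 10 gives df = 18; identical means give t = 0, p = 1
  same <- rep(c(1, 2, 3, 4, 5), 4)
  res18 <- group_ttest(same, rep(c("a", "b"), each = 10))
  expect_equal(res18$df, 18)
  expect_equal(res18$t, 0)
  expect_equal(res18$p, 1)
  expect_error(group_ttest(x, rep("a", 5)), "two groups")
})

test_that("Pearson correlations match the t-transform closed form", {
  x <- c(1, 2, 4, 5, 7, 8, 10)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(161)
  y <- rnorm(7)
  res <- pearson_r(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_oracle <- r_oracle * sqrt(5 / (1 - r_oracle^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 5), tolerance = 1e-10)
  expect_error(pearson_r(x, rep(1, 7)), "variance")
  expect_error(pearson_r(1:2, 1:2), "length")

  # permutation oracle: p is uniform under independence
  set.seed(162)
  ps <- replicate(2000, pearson_r(rnorm(10), rnorm(10))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("Bonferroni correction multiplies and caps p values", {
  expect_equal(bonferroni(0.0016, 7), 0.0112)
  expect_lt(bonferroni(0.0016, 7), 0.05)
  expect_equal(bonferroni(0.015, 4), 0.06)
  expect_gt(bonferroni(0.015, 4), 0.05)
  expect_equal(bonferroni(1, 3), 1)
  expect_equal(bonferroni(c(0.01, 0.4), 4), c(0.04, 1))
})

test_that("aggregates match a naive nested-loop computation", {
  ag <- agent_state(0, 0.2, snr = 1)
  logs <- lapply(1:4, function(i)
    run_session(i, if (i %% 2) "cheating" else "paranoid", ag, fix_models,
                fix_norms, fix_templates, fix_stations, n_runs = 2,
                seed = 170 + i))
  tab <- aggregate_sessions(logs, by = c("run", "group"))

  for (r in 1:2) for (g in c("cheating", "paranoid")) {
    # oracle: participant means first, then mean/sem across participants
    pm <- vapply(logs[vapply(logs, `[[`, "", "group") == g],
                 function(lg) mean(lg$events$p_c[lg$events$run == r]),
                 numeric(1))
    row <- tab[tab$run == r & tab$group == g & tab$measure == "p_c", ]
    expect_equal(row$mean, mean(pm), tolerance = 1e-12)
    expect_equal(row$sem, sd(pm) / sqrt(length(pm)), tolerance = 1e-12)
    expect_equal(row$n, length(pm))
  }

  # probe-correct fraction measure agrees with direct counting
  row <- tab[tab$run == 1 & tab$group == "cheating" &
               tab$measure == "probe_correct_fraction", ]
  pm <- vapply(logs[c(1, 3)], function(lg)
    mean(lg$events$probe_choice[lg$events$run == 1] == "cheating"),
    numeric(1))
  expect_equal(row$mean, mean(pm), tolerance = 1e-12)

  # single participant per cell: sem flagged NA
  solo <- aggregate_sessions(logs[1], by = "group")
  expect_true(all(is.na(solo$sem)))
  # two identical participants: sem exactly 0
  clone <- logs[[1]]
  clone$participant_id <- 99
  twin <- aggregate_sessions(list(logs[[1]], clone), by = "group")
  expect_true(all(twin$sem == 0))
})
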