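test_that("contingency building counts valid answered prediction trials only", {
  tr <- make_trials(actual = c("hit", "hit", "miss", "miss"),
                    verbalized = c("hit", "miss", "hit", "miss"))
  cnt <- build_contingency(tr)
  expect_equal(c(cnt$n_hit_verb_hit, cnt$n_hit_verb_miss,
                 cnt$n_miss_verb_hit, cnt$n_miss_verb_miss), rep(1, 4))

  tr2 <- make_trials(actual = rep("hit", 5),
                     verbalized = c("hit", "hit", "changed", "miss", "hit"))
  cnt2 <- build_contingency(tr2)
  expect_equal(cnt2$n, 4)
  expect_equal(unname(cnt2$excluded["changed_answer"]), 1)

  tr3 <- make_trials(actual = c("hit", "miss"), verbalized = c("none", "none"))
  expect_error(build_contingency(tr3), "zero valid")
  expect_error(build_contingency(tr3[0, ]), "prediction")
})

test_that("generator ledger counts equal built counts", {
  coh <- simulate_cohort(cohort_config(n_participants = 1,
                                       n_trials_per_participant = 500,
                                       seed = 12))
  tr <- coh$trials
  cnt <- build_contingency(tr)
  keep <- tr$condition == "prediction" & tr$valid &
    tr$verbalized %in% c("hit", "miss")
  expect_equal(cnt$n_hit_verb_hit,
               sum(tr$actual[keep] == "hit" & tr$verbalized[keep] == "hit"))
  expect_equal(cnt$n, sum(keep))
})

test_that("d' and c follow the z-transform definitions", {
  # HR = FA = 0.5: no sensitivity, no bias
  s0 <- sdt_metrics(contingency_counts(50, 50, 50, 50), correction = "none")
  expect_equal(s0$d_prime, 0)
  expect_equal(s0$c, 0)

  # normal-quantile oracle: z(0.6915) = 0.5, z(0.3085) = -0.5
  s1 <- sdt_metrics(contingency_counts(6915, 3085, 3085, 6915),
                    correction = "none")
  expect_lt(abs(s1$d_prime - 1), 1e-3)
  expect_lt(abs(s1$c - 0), 1e-3)

  # z(0.9332) = 1.5, z(0.3085) = -0.5
  s2 <- sdt_metrics(contingency_counts(9332, 668, 3085, 6915),
                    correction = "none")
  expect_lt(abs(s2$d_prime - 2), 1e-3)
  expect_lt(abs(s2$c - (-0.5)), 1e-3)

  # log-linear correction keeps extreme rates inside (0, 1)
  s3 <- sdt_metrics(contingency_counts(10, 0, 0, 10))
  expect_true(s3$hit_rate < 1 && s3$false_alarm_rate > 0)
  expect_true(is.finite(s3$d_prime))
  expect_error(sdt_metrics(contingency_counts(10, 0, 0, 10),
                           correction = "none"), "extreme")
  expect_error(sdt_metrics(contingency_counts(3, 4, 0, 0)), "row")
})

test_that("chance rate follows the unconditional-probability formula", {
  expect_equal(chance_rate(contingency_counts(25, 25, 25, 25)), 50)
  # margins 0.6 / 0.7: 0.42 + 0.12 -> 54
  expect_equal(chance_rate(contingency_counts(42, 18, 28, 12)), 54)
  # degenerate margins: chance 100, accuracy undefined
  cnt <- contingency_counts(10, 0, 0, 0)
  expect_equal(chance_rate(cnt), 100)
  pa <- prediction_accuracy(cnt)
  expect_false(pa$defined)
  expect_true(is.na(pa$acc_pred))
})

test_that("chance-corrected accuracy matches the worked examples", {
  expect_equal(acc_pred(80, 75), 20)
  expect_equal(acc_pred(55, 50), 10)
  expect_equal(acc_pred(60, 60), 0)
  expect_warning(expect_true(is.na(acc_pred(100, 100))), "undefined")
})

test_that("accuracy equals the brute-force formula on all small tables", {
  for (i in 1:200) {
    set.seed(i)
    cells <- as.vector(stats::rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    cnt <- contingency_counts(cells[1], cells[2], cells[3], cells[4])
    orc <- oracle_acc(cells[1], cells[2], cells[3], cells[4])
    pa <- prediction_accuracy(cnt)
    if (!pa$defined) next
    expect_equal(pa$acc_pred, orc$acc, tolerance = 1e-12)
    expect_equal(pa$pc_chance, orc$pc_chance, tolerance = 1e-12)
  }
})

test_that("with margins fixed, more agreement never lowers the accuracy", {
  for (rep in 1:50) {
    set.seed(rep)
    n <- sample(8:60, 1)
    r1 <- sample(1:(n - 1), 1)          # actual hits
    c1 <- sample(1:(n - 1), 1)          # verbalized hits
    lo <- max(0, r1 + c1 - n)
    hi <- min(r1, c1)
    if (hi <= lo) next
    accs <- sapply(lo:hi, function(n11) {
      pa <- prediction_accuracy(contingency_counts(
        n11, r1 - n11, c1 - n11, n - r1 - c1 + n11))
      pa$acc_pred
    })
    expect_true(all(diff(accs) >= -1e-12))
  }
})

test_that("blocks split valid prediction trials with the remainder at the end", {
  coh <- simulate_cohort(cohort_config(n_participants = 1,
                                       n_trials_per_participant = 500,
                                       invalid_trial_rate = 0,
                                       no_answer_rate = 0,
                                       changed_answer_rate = 0, seed = 5))
  bl <- blockwise_accuracy(coh$trials)
  expect_equal(bl$n, rep(50, 5))

  # 249 valid prediction trials -> 50, 50, 50, 50, 49
  tr <- make_trials(actual = sample(c("hit", "miss"), 249, TRUE),
                    verbalized = sample(c("hit", "miss"), 249, TRUE))
  expect_equal(blockwise_accuracy(tr)$n, c(50, 50, 50, 50, 49))

  # blocks with an empty actual-outcome row are flagged, not errors
  tr2 <- make_trials(actual = c(rep("hit", 5), rep(c("hit", "miss"), 10)),
                     verbalized = rep(c("hit", "miss"), length.out = 25))
  bl2 <- blockwise_accuracy(tr2, n_blocks = 5)
  expect_true(is.data.frame(bl2) && nrow(bl2) == 5)
})

test_that("stationary cohorts show no first-to-last block trend on average", {
  diffs <- replicate(30, {
    coh <- simulate_cohort(cohort_config(
      n_participants = 1, n_trials_per_participant = 500,
      invalid_trial_rate = 0, no_answer_rate = 0, changed_answer_rate = 0,
      seed = sample.int(1e6, 1)))
    bl <- blockwise_accuracy(coh$trials)
    bl$acc_pred[1] - bl$acc_pred[5]
  })
  expect_lt(abs(mean(diffs, na.rm = TRUE)),
            3 * sd(diffs, na.rm = TRUE) / sqrt(sum(!is.na(diffs))) + 1e-9)
})

test_that("the prediction fit exposes coherent cohort-level results", {
  coh <- simulate_cohort(cohort_config(n_participants = 6,
                                       n_trials_per_participant = 300,
                                       seed = 8))
  fit <- fit_prediction(coh)
  expect_s3_class(fit, "prediction_fit")
  expect_equal(nrow(fit$participants), 6)
  expect_named(coef(fit), c("hit_rate", "d_prime", "c", "acc_pred"))
  sm <- summary(fit)
  expect_true(all(c("test", "statistic", "p", "bf10") %in% names(sm$tests)))
  expect_true(all(sm$tests$p >= 0 & sm$tests$p <= 1))
  # simulate() regenerates cohorts with the fitted parameter set
  sim <- simulate(fit, nsim = 1, seed = 4, n_trials = 100)
  expect_s3_class(sim[[1]], "throw_cohort")
  expect_equal(nrow(sim[[1]]$ledger$participants), 6)
  f <- tempfile(fileext = ".csv")
  write_metrics_csv(fit, f)
  expect_true(all(c("participant_id", "d_prime", "acc_pred") %in%
                    names(read.csv(f))))
  unlink(f)
})

test_that("accuracy and sensitivity are tightly coupled across a diverse cohort", {
  coh <- simulate_cohort(cohort_config(
    n_participants = 100, n_trials_per_participant = 500,
    hit_rate = 0.634, d_prime = function(n) runif(n, 0, 1.5),
    criterion_c = function(n) runif(n, -0.8, 0.2),
    bias_performance_coupling = 0, invalid_trial_rate = 0,
    no_answer_rate = 0, changed_answer_rate = 0, seed = 14))
  fit <- fit_prediction(coh)
  expect_gt(cor(fit$participants$acc_pred, fit$participants$d_prime), 0.9)
})
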