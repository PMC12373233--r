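test_that("one-sample t matches hand computation and handles edge cases", {
  r <- one_sample_t(c(1, 2, 3, 4, 5), 0)
  expect_equal(r$statistic, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$effect_size, r$statistic^2 / (r$statistic^2 + 4),
               tolerance = 1e-12)

  sym <- one_sample_t(c(-2, -1, 0, 1, 2), 0)
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  expect_equal(sym$effect_size, 0)

  expect_error(one_sample_t(rep(1, 5), 0), "zero variance")
  expect_error(one_sample_t(3, 0), ">= 2")

  # one-tailed p halves the two-tailed p on the tested side
  x <- c(0.5, 1.2, 0.8, 1.5, 0.9)
  expect_equal(one_sample_t(x, 0, tail = "greater")$p_value,
               one_sample_t(x, 0)$p_value / 2, tolerance = 1e-12)
})

test_that("paired t reduces to a one-sample test on differences", {
  set.seed(3)
  x <- rnorm(10)
  y <- rnorm(10)
  expect_equal(paired_t(x, y)$statistic, one_sample_t(x - y, 0)$statistic)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(x, y[1:5]), "equal length")
  big <- paired_t(x + 5, x + rnorm(10, 0, 0.1), tail = "greater")
  expect_lt(big$p_value, 1e-6)
})

test_that("pearson correlation statistics follow the exact formulas", {
  x <- c(1, 2, 3, 4, 6)
  r1 <- pearson_r(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  r2 <- pearson_r(x, -x)
  expect_equal(r2$r, -1)
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  r3 <- pearson_r(a, b)
  rr <- cor(a, b)
  expect_equal(r3$statistic, rr * sqrt(18 / (1 - rr^2)), tolerance = 1e-12)
  expect_equal(r3$effect_size, rr^2, tolerance = 1e-12)
  expect_error(pearson_r(a, rep(1, 20)), "degenerate")
  # null correlations centre on zero
  set.seed(5)
  rs <- replicate(400, cor(rnorm(20), rnorm(20)))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(400))
})

test_that("frequentist statistics match brute-force oracles to 1e-10", {
  set.seed(11)
  v <- rnorm(19, 0.3)
  r <- one_sample_t(v, 0)
  t_direct <- (mean(v) - 0) / (sd(v) / sqrt(19))
  expect_equal(r$statistic, t_direct, tolerance = 1e-10)
  expect_equal(r$p_value, 2 * pt(-abs(t_direct), 18), tolerance = 1e-10)

  x <- rnorm(19); y <- rnorm(19)
  rc <- pearson_r(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rc$r, r_direct, tolerance = 1e-10)

  cells <- expand.grid(participant_id = sprintf("S%02d", 1:12),
                       verbalized = c("hit", "miss"),
                       actual = c("hit", "miss"), stringsAsFactors = FALSE)
  cells$value <- rnorm(nrow(cells)) + 0.5 * (cells$verbalized == "miss") +
    0.2 * (cells$actual == "hit") * (cells$verbalized == "hit")
  res <- rm_anova_2x2(cells)
  orc <- oracle_rm_anova(cells)
  expect_equal(res$verbalized$statistic, orc$F_a, tolerance = 1e-10)
  expect_equal(res$actual$statistic, orc$F_b, tolerance = 1e-10)
  expect_equal(res$interaction$statistic, orc$F_ab, tolerance = 1e-10)
  expect_equal(res$verbalized$effect_size, orc$eta2p_a, tolerance = 1e-10)
  expect_equal(res$actual$effect_size, orc$eta2p_b, tolerance = 1e-10)
  expect_equal(res$interaction$effect_size, orc$eta2p_ab, tolerance = 1e-10)
  expect_equal(res$verbalized$df[2], orc$df2)
})

test_that("each 2x2 within-subject F equals the squared paired t on its contrast", {
  set.seed(21)
  cells <- expand.grid(participant_id = sprintf("S%02d", 1:10),
                       verbalized = c("hit", "miss"),
                       actual = c("hit", "miss"), stringsAsFactors = FALSE)
  cells$value <- rnorm(nrow(cells)) - 0.4 * (cells$verbalized == "hit")
  res <- rm_anova_2x2(cells)
  cm <- tapply(cells$value, list(cells$participant_id, cells$verbalized,
                                 cells$actual), mean)
  contr_a <- (cm[, "hit", "hit"] + cm[, "hit", "miss"]) / 2 -
    (cm[, "miss", "hit"] + cm[, "miss", "miss"]) / 2
  t_a <- unname(t.test(contr_a)$statistic)
  expect_equal(res$verbalized$statistic, t_a^2, tolerance = 1e-10)

  # listwise deletion: a participant missing one cell is dropped
  cells2 <- cells[-1, ]
  res2 <- rm_anova_2x2(cells2)
  expect_equal(res2$verbalized$df[2], 8)
  expect_error(rm_anova_2x2(cells[cells$participant_id == "S01", ]), ">= 2")
})

test_that("type-I error is calibrated at the nominal level", {
  set.seed(31)
  rej <- mean(replicate(400, one_sample_t(rnorm(19), 0)$p_value < 0.05))
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(rej - 0.05), 3 * se)
})

test_that("JZS t Bayes factors behave as Bayes factors must", {
  # t = 0: the null is favoured
  expect_lt(bayes_factor_t(0, 20), 1)
  # reciprocity via stat_result
  r <- one_sample_t(c(1, 2, 3, 4, 5), 0)
  expect_equal(r$bf10 * r$bf01, 1, tolerance = 1e-12)
  # strictly increasing in |t| for fixed n
  for (n in c(10, 19, 50)) {
    bfs <- sapply(seq(0, 6, by = 0.5), function(t) bayes_factor_t(t, n))
    expect_true(all(diff(bfs) > 0))
  }
  # one-sided factors double up on the matching side at t = 0
  expect_equal(bayes_factor_t(0, 15, tail = "greater") +
                 bayes_factor_t(0, 15, tail = "less"),
               2 * bayes_factor_t(0, 15), tolerance = 1e-6)
  expect_error(bayes_factor_t(Inf, 10), "finite")
})

test_that("Bayes factors reproduce independently computed reference values", {
  # frozen values from an independent JZS implementation (numerical
  # integration of the Cauchy-prior marginal likelihood)
  expect_equal(bayes_factor_t(4.242640687, 5), 5.756672619, tolerance = 1e-4)
  expect_equal(bayes_factor_t(2.5, 20), 2.702287857, tolerance = 1e-4)
  expect_equal(bayes_factor_t(0, 20), 0.232356481, tolerance = 1e-4)
  expect_equal(bayes_factor_r(0.5, 20), 2.915944801, tolerance = 1e-4)
  expect_equal(bayes_factor_r(-0.64, 19), 16.23332246, tolerance = 1e-4)
})

test_that("correlation Bayes factor uses a proper sampling density", {
  # the exact density of r must integrate to 1 for fixed rho and n
  for (rho in c(0, 0.5, -0.7)) {
    tot <- integrate(function(r)
      vapply(r, function(ri)
        throwpredict:::pearson_r_density(ri, rho, 15), numeric(1)),
      -1, 1, rel.tol = 1e-9)$value
    expect_equal(tot, 1, tolerance = 1e-6)
  }
  expect_gt(bayes_factor_r(0.8, 20, tail = "greater"),
            bayes_factor_r(0.8, 20))
  r <- pearson_r(c(1, 3, 2, 5, 4, 6), c(2, 4, 3, 7, 6, 9))
  expect_equal(r$bf10 * r$bf01, 1, tolerance = 1e-12)
})

test_that("Bayes factor categories follow the conventional boundaries", {
  out <- bf_category(c(1, 2.99, 3, 9.99, 10, 29.99, 30, 99.99, 100, 1000))
  expect_equal(out$category,
               c("anecdotal", "anecdotal", "sufficient", "sufficient",
                 "strong", "strong", "very strong", "very strong",
                 "extreme", "extreme"))
  inv <- bf_category(c(0.5, 1 / 20))
  expect_equal(inv$favours, c("H0", "H0"))
  expect_equal(inv$category, c("anecdotal", "strong"))
})
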