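#' Fit the outcome-prediction model to a trial table
#'
#' The central estimator of the package: for every participant it builds the
#' actual-by-verbalized contingency table over valid prediction trials and
#' estimates the equal-variance signal-detection parameters (sensitivity `d'`,
#' criterion `c`), the raw percent correct, the individual chance rate, the
#' chance-corrected prediction accuracy `%Acc_Pred`, and the blockwise
#' accuracy across the session. The overall throwing hit rate (proportion of
#' actual hits over all valid trials, both conditions) is reported alongside.
#'
#' @param data trial data frame with columns `participant_id`, `trial_index`,
#'   `condition`, `actual`, `verbalized`, `valid` (a `throw_cohort` is also
#'   accepted).
#' @param correction extreme-rate correction for the SDT measures
#'   (`"loglinear"`, the default, or `"none"`); the accuracy measures always
#'   use raw proportions.
#' @param n_blocks number of session blocks for the time course (default 5).
#' @return An object of class `prediction_fit` with components
#'   `participants` (one row per participant: `hit_rate_overall`, `HR`, `FA`,
#'   `d_prime`, `c`, `pc_chance`, `pc_pred`, `acc_pred`, `n_valid`,
#'   `n_excluded`), `blocks` (per participant x block), `hit_rate_by_condition`
#'   (per participant hit rate in prediction vs feedback trials), and `call`.
#' @seealso [summary.prediction_fit()] for the inference battery,
#'   [simulate.prediction_fit()] for parametric-bootstrap cohorts.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 3,
#'                                      n_trials_per_participant = 100))
#' fit <- fit_prediction(coh)
#' coef(fit)
#' @export
fit_prediction <- function(data, correction = c("loglinear", "none"),
                           n_blocks = 5) {
  if (inherits(data, "throw_cohort")) data <- data$trials
  correction <- match.arg(correction)
  ids <- unique(data$participant_id)
  rows <- vector("list", length(ids))
  blocks <- vector("list", length(ids))
  hrc <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sub <- data[data$participant_id == ids[k], , drop = FALSE]
    cnt <- build_contingency(sub)
    sdt <- sdt_metrics(cnt, correction = correction)
    pa <- prediction_accuracy(cnt)
    vsub <- sub[sub$valid, , drop = FALSE]
    rows[[k]] <- data.frame(
      participant_id = ids[k],
      hit_rate_overall = mean(vsub$actual == "hit"),
      HR = sdt$hit_rate, FA = sdt$false_alarm_rate,
      d_prime = sdt$d_prime, c = sdt$c,
      pc_chance = pa$pc_chance, pc_pred = pa$pc_pred, acc_pred = pa$acc_pred,
      n_valid = cnt$n, n_excluded = sum(cnt$excluded),
      stringsAsFactors = FALSE
    )
    bl <- blockwise_accuracy(sub, n_blocks = n_blocks)
    bl <- cbind(participant_id = ids[k], bl, stringsAsFactors = FALSE)
    blocks[[k]] <- bl
    hrc[[k]] <- data.frame(
      participant_id = ids[k],
      hit_rate_prediction = mean(vsub$actual[vsub$condition == "prediction"] == "hit"),
      hit_rate_feedback = mean(vsub$actual[vsub$condition == "feedback"] == "hit"),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    participants = do.call(rbind, rows),
    blocks = do.call(rbind, blocks),
    hit_rate_by_condition = do.call(rbind, hrc),
    correction = correction, n_blocks = n_blocks,
    call = match.call()
  ), class = "prediction_fit")
}

#' @export
print.prediction_fit <- function(x, ...) {
  p <- x$participants
  cat(sprintf("Outcome-prediction fit: %d participants\n", nrow(p)))
  cat(sprintf("  mean hit rate %.2f%%, d' = %.3f, c = %.3f, %%Acc_Pred = %.2f\n",
              100 * mean(p$hit_rate_overall), mean(p$d_prime), mean(p$c),
              mean(p$acc_pred, na.rm = TRUE)))
  invisible(x)
}

#' Cohort-level coefficients of a prediction fit
#'
#' @param object a `prediction_fit`.
#' @param ... unused.
#' @return named vector of cohort means: `hit_rate` (percent), `d_prime`,
#'   `c`, `acc_pred` (percent).
#' @export
coef.prediction_fit <- function(object, ...) {
  p <- object$participants
  c(hit_rate = 100 * mean(p$hit_rate_overall),
    d_prime = mean(p$d_prime),
    c = mean(p$c),
    acc_pred = mean(p$acc_pred, na.rm = TRUE))
}

#' Inference battery for a prediction fit
#'
#' Runs the cohort-level tests on the fitted per-participant measures:
#' one-tailed one-sample t-tests on `d'` (> 0), `c` (< 0) and `%Acc_Pred`
#' (> 0); a two-tailed paired test of the first versus last session block; a
#' paired test of the hit rate with versus without prediction; and Pearson
#' correlations of the hit rate with `c`, `%Acc_Pred` and `d'`, and of
#' `%Acc_Pred` with `d'`. Each result carries its effect size and a
#' default-prior Bayes factor.
#'
#' @param object a `prediction_fit`.
#' @param cauchy_scale Cauchy prior scale for the t-test Bayes factors.
#' @param ... unused.
#' @return An object of class `summary.prediction_fit` containing the fit and
#'   a `tests` data frame (`test`, `statistic`, `df`, `p`, `tail`,
#'   `effect_size`, `effect_kind`, `bf10`).
#' @export
summary.prediction_fit <- function(object, cauchy_scale = 0.707, ...) {
  p <- object$participants
  # tests that are not estimable on a given cohort (too few participants,
  # degenerate variance) are skipped rather than aborting the summary
  try_stat <- function(expr) tryCatch(expr, error = function(e) NULL)
  res <- list(
    d_prime_vs_0 = try_stat(one_sample_t(p$d_prime, 0, tail = "greater",
                                         cauchy_scale = cauchy_scale)),
    c_vs_0 = try_stat(one_sample_t(p$c, 0, tail = "less",
                                   cauchy_scale = cauchy_scale)),
    acc_pred_vs_0 = try_stat(one_sample_t(p$acc_pred[!is.na(p$acc_pred)], 0,
                                          tail = "greater",
                                          cauchy_scale = cauchy_scale))
  )
  bl <- object$blocks
  first <- bl$acc_pred[bl$block == 1]
  last <- bl$acc_pred[bl$block == object$n_blocks]
  ok <- !is.na(first) & !is.na(last)
  if (sum(ok) >= 2) {
    res$acc_pred_first_vs_last <- try_stat(
      paired_t(first[ok], last[ok], tail = "two",
               cauchy_scale = cauchy_scale))
  }
  hrc <- object$hit_rate_by_condition
  res$hit_rate_pred_vs_feedback <- try_stat(
    paired_t(hrc$hit_rate_prediction, hrc$hit_rate_feedback, tail = "two",
             cauchy_scale = cauchy_scale))
  res$cor_hit_rate_c <- try_stat(pearson_r(p$hit_rate_overall, p$c))
  res$cor_hit_rate_acc_pred <- try_stat(pearson_r(p$hit_rate_overall, p$acc_pred))
  res$cor_hit_rate_d_prime <- try_stat(pearson_r(p$hit_rate_overall, p$d_prime))
  res$cor_acc_pred_d_prime <- try_stat(pearson_r(p$acc_pred, p$d_prime))
  res <- Filter(Negate(is.null), res)

  structure(list(fit = object, tests = stat_results_table(res)),
            class = "summary.prediction_fit")
}

#' @export
print.summary.prediction_fit <- function(x, ...) {
  print(x$fit)
  cat("\nStatistical tests:\n")
  tab <- x$tests
  tab$statistic <- round(tab$statistic, 3)
  tab$p <- signif(tab$p, 3)
  tab$effect_size <- round(tab$effect_size, 3)
  tab$bf10 <- signif(tab$bf10, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot a prediction fit
#'
#' Left panel: per-participant chance-corrected accuracy against sensitivity
#' `d'` (the two measures track each other closely). Right panel: accuracy by
#' session block (cohort mean +/- SE).
#'
#' @param x a `prediction_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.prediction_fit <- function(x, ...) {
  p <- x$participants
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(p$d_prime, p$acc_pred, xlab = "d'", ylab = "%Acc_Pred",
                 main = "Accuracy vs sensitivity", pch = 19, ...)
  bl <- x$blocks
  mns <- tapply(bl$acc_pred, bl$block, mean, na.rm = TRUE)
  ses <- tapply(bl$acc_pred, bl$block, function(v)
    stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  bx <- as.numeric(names(mns))
  graphics::plot(bx, mns, type = "b", pch = 19, xlab = "session block",
                 ylab = "%Acc_Pred", main = "Accuracy over blocks",
                 ylim = range(c(mns - ses, mns + ses), na.rm = TRUE))
  graphics::arrows(bx, mns - ses, bx, mns + ses, angle = 90, code = 3,
                   length = 0.04)
  invisible(x)
}

#' Parametric-bootstrap cohorts from a prediction fit
#'
#' Simulates new trial tables from the fitted per-participant parameters
#' (overall hit rate, `d'`, `c`), preserving each participant's number of
#' trials. Useful for assessing the sampling variability of the cohort-level
#' measures.
#'
#' @param object a `prediction_fit`.
#' @param nsim number of simulated cohorts.
#' @param seed integer seed.
#' @param n_trials trials per participant in each simulated cohort (default
#'   500).
#' @param ... unused.
#' @return list of `nsim` `throw_cohort` objects.
#' @export
simulate.prediction_fit <- function(object, nsim = 1, seed = 1L,
                                    n_trials = 500, ...) {
  p <- object$participants
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    cfg <- cohort_config(
      n_participants = nrow(p), n_trials_per_participant = n_trials,
      hit_rate = pmin(pmax(p$hit_rate_overall, 1e-3), 1 - 1e-3),
      d_prime = pmax(p$d_prime, 0), criterion_c = p$c,
      bias_performance_coupling = 0,
      invalid_trial_rate = 0, no_answer_rate = 0, changed_answer_rate = 0,
      speech_fail_rate = 0, seed = sub_seed(seed, s)
    )
    out[[s]] <- simulate_cohort(cfg)
  }
  out
}
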