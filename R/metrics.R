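#' Build the 2x2 actual-by-verbalized contingency table
#'
#' Counts valid prediction trials cross-classified by the actual outcome and
#' the verbalized prediction. Trials are omitted when the participant gave no
#' answer or changed the answer (`verbalized` of `"none"` or `"changed"`), or
#' when the trial was flagged invalid; the omitted counts are reported.
#'
#' @param trials data frame with columns `condition`, `actual`, `verbalized`,
#'   `valid` (a `throw_cohort` is also accepted).
#' @return An object of class `contingency_counts`: counts `n_hit_verb_hit`,
#'   `n_hit_verb_miss`, `n_miss_verb_hit`, `n_miss_verb_miss`, total `n`,
#'   margin proportions `act_hit`, `act_miss`, `verb_hit`, `verb_miss`, and
#'   an `excluded` breakdown.
#' @export
build_contingency <- function(trials) {
  if (inherits(trials, "throw_cohort")) trials <- trials$trials
  need <- c("condition", "actual", "verbalized", "valid")
  if (!all(need %in% names(trials))) {
    stop("trials must contain: ", paste(need, collapse = ", "), call. = FALSE)
  }
  pred <- trials[trials$condition == "prediction", , drop = FALSE]
  if (nrow(pred) == 0) stop("no prediction-condition trials", call. = FALSE)

  excluded <- c(
    invalid_flag = sum(!pred$valid),
    no_answer = sum(pred$valid & pred$verbalized %in% "none"),
    changed_answer = sum(pred$valid & pred$verbalized %in% "changed")
  )
  keep <- pred$valid & pred$verbalized %in% c("hit", "miss")
  use <- pred[keep, , drop = FALSE]
  if (nrow(use) == 0) stop("zero valid prediction trials", call. = FALSE)

  n11 <- sum(use$actual == "hit" & use$verbalized == "hit")
  n10 <- sum(use$actual == "hit" & use$verbalized == "miss")
  n01 <- sum(use$actual == "miss" & use$verbalized == "hit")
  n00 <- sum(use$actual == "miss" & use$verbalized == "miss")
  contingency_counts(n11, n10, n01, n00, excluded = excluded)
}

#' Construct contingency counts directly
#'
#' @param n_hit_verb_hit,n_hit_verb_miss,n_miss_verb_hit,n_miss_verb_miss
#'   non-negative cell counts (actual x verbalized).
#' @param excluded optional named vector of excluded-trial counts.
#' @return A `contingency_counts` object.
#' @export
contingency_counts <- function(n_hit_verb_hit, n_hit_verb_miss,
                               n_miss_verb_hit, n_miss_verb_miss,
                               excluded = c(invalid_flag = 0L, no_answer = 0L,
                                            changed_answer = 0L)) {
  cells <- c(n_hit_verb_hit, n_hit_verb_miss, n_miss_verb_hit, n_miss_verb_miss)
  if (any(cells < 0) || anyNA(cells)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  n <- sum(cells)
  if (n < 1) stop("total count must be >= 1", call. = FALSE)
  structure(list(
    n_hit_verb_hit = n_hit_verb_hit, n_hit_verb_miss = n_hit_verb_miss,
    n_miss_verb_hit = n_miss_verb_hit, n_miss_verb_miss = n_miss_verb_miss,
    n = n,
    act_hit = (n_hit_verb_hit + n_hit_verb_miss) / n,
    act_miss = (n_miss_verb_hit + n_miss_verb_miss) / n,
    verb_hit = (n_hit_verb_hit + n_miss_verb_hit) / n,
    verb_miss = (n_hit_verb_miss + n_miss_verb_miss) / n,
    excluded = excluded
  ), class = "contingency_counts")
}

#' @export
print.contingency_counts <- function(x, ...) {
  m <- matrix(c(x$n_hit_verb_hit, x$n_hit_verb_miss,
                x$n_miss_verb_hit, x$n_miss_verb_miss), 2, 2, byrow = TRUE,
              dimnames = list(actual = c("hit", "miss"),
                              verbalized = c("hit", "miss")))
  print(m)
  cat(sprintf("n = %d valid prediction trials; excluded: %s\n", x$n,
              paste(names(x$excluded), x$excluded, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Signal-detection measures from a contingency table
#'
#' Hit rate HR = P(verbalized hit | actual hit) and false-alarm rate
#' FA = P(verbalized hit | actual miss); sensitivity `d' = z(HR) - z(FA)` and
#' criterion `c = -(z(HR) + z(FA)) / 2` with `z` the standard-normal quantile.
#' With the log-linear correction (default), 0.5 is added to each cell and 1
#' to each row total before the rates are formed, which keeps both rates
#' strictly inside (0, 1); with `correction = "none"`, extreme rates make the
#' quantile transform undefined and raise an error.
#'
#' @param counts a `contingency_counts`.
#' @param correction `"loglinear"` or `"none"`.
#' @return An object of class `sdt_metrics`: `hit_rate`, `false_alarm_rate`,
#'   `d_prime`, `c`, `correction_applied`.
#' @examples
#' sdt_metrics(contingency_counts(45, 20, 25, 35))
#' @export
sdt_metrics <- function(counts, correction = c("loglinear", "none")) {
  stopifnot(inherits(counts, "contingency_counts"))
  correction <- match.arg(correction)
  n_hit <- counts$n_hit_verb_hit + counts$n_hit_verb_miss
  n_miss <- counts$n_miss_verb_hit + counts$n_miss_verb_miss
  if (n_hit < 1 || n_miss < 1) {
    stop("both actual-hit and actual-miss rows need at least one trial",
         call. = FALSE)
  }
  if (correction == "loglinear") {
    hr <- (counts$n_hit_verb_hit + 0.5) / (n_hit + 1)
    fa <- (counts$n_miss_verb_hit + 0.5) / (n_miss + 1)
  } else {
    hr <- counts$n_hit_verb_hit / n_hit
    fa <- counts$n_miss_verb_hit / n_miss
    if (hr %in% c(0, 1) || fa %in% c(0, 1)) {
      stop("extreme rates (0 or 1): d' and c undefined without correction",
           call. = FALSE)
    }
  }
  structure(list(
    hit_rate = hr, false_alarm_rate = fa,
    d_prime = stats::qnorm(hr) - stats::qnorm(fa),
    c = -(stats::qnorm(hr) + stats::qnorm(fa)) / 2,
    correction_applied = correction == "loglinear"
  ), class = "sdt_metrics")
}

#' @export
print.sdt_metrics <- function(x, ...) {
  cat(sprintf("SDT: HR = %.4f, FA = %.4f, d' = %.4f, c = %.4f%s\n",
              x$hit_rate, x$false_alarm_rate, x$d_prime, x$c,
              if (x$correction_applied) " (log-linear correction)" else ""))
  invisible(x)
}

#' Individual chance rate of correct answers (percent)
#'
#' Expected percentage of correct predictions if the verbal answers were
#' statistically independent of the outcomes, given both margins:
#' `(act_hit * verb_hit + act_miss * verb_miss) * 100`. Raw (uncorrected)
#' proportions are used.
#'
#' @param counts a `contingency_counts`.
#' @return chance rate on the percent scale.
#' @examples
#' chance_rate(contingency_counts(42, 18, 28, 12))  # 0.6/0.7 margins -> 54
#' @export
chance_rate <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  (counts$act_hit * counts$verb_hit + counts$act_miss * counts$verb_miss) * 100
}

#' Chance-corrected prediction accuracy (percent scale)
#'
#' The proportion of the exploitable range above the individual chance level
#' actually achieved:
#' \deqn{%Acc_{Pred} = 100 (%C_{Pred} - %C_{Chance}) / (100 - %C_{Chance})}
#' A participant 5 percentage points above a 75% chance level scores 20;
#' 5 points above a 50% chance level scores 10.
#'
#' @param pc_pred percentage of correct predictions, in `[0, 100]`.
#' @param pc_chance individual chance rate, in `[0, 100)`.
#' @return accuracy on the percent scale; `NA` (with a warning) when
#'   `pc_chance` is 100, where the measure is undefined.
#' @examples
#' acc_pred(80, 75)  # 20
#' acc_pred(55, 50)  # 10
#' @export
acc_pred <- function(pc_pred, pc_chance) {
  if (any(pc_chance >= 100)) {
    warning("chance level of 100%: prediction accuracy undefined")
    return(ifelse(pc_chance >= 100, NA_real_,
                  100 * (pc_pred - pc_chance) / (100 - pc_chance)))
  }
  100 * (pc_pred - pc_chance) / (100 - pc_chance)
}

#' Prediction accuracy of a contingency table
#'
#' Computes the raw percent correct, the individual chance rate, and the
#' chance-corrected accuracy [acc_pred()].
#'
#' @param counts a `contingency_counts`.
#' @return An object of class `prediction_accuracy`: `pc_chance`, `pc_pred`,
#'   `acc_pred` (all percent), and `defined` (`FALSE` when the chance level
#'   is 100).
#' @export
prediction_accuracy <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  pc_chance <- chance_rate(counts)
  pc_pred <- 100 * (counts$n_hit_verb_hit + counts$n_miss_verb_miss) / counts$n
  defined <- pc_chance < 100
  structure(list(
    pc_chance = pc_chance, pc_pred = pc_pred,
    acc_pred = if (defined) 100 * (pc_pred - pc_chance) / (100 - pc_chance)
               else NA_real_,
    defined = defined
  ), class = "prediction_accuracy")
}

#' @export
print.prediction_accuracy <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("%%C_Pred = %.2f, %%C_Chance = %.2f, %%Acc_Pred = %.2f\n",
                x$pc_pred, x$pc_chance, x$acc_pred))
  } else {
    cat("chance level 100%: prediction accuracy undefined\n")
  }
  invisible(x)
}

#' Blockwise prediction accuracy across the session
#'
#' Splits a participant's valid prediction trials, in temporal order, into
#' `n_blocks` contiguous blocks and computes the accuracy measures per block.
#' Block sizes are `round(n / n_blocks)` with the remainder absorbed by the
#' last block (249 valid trials over 5 blocks gives 50, 50, 50, 50, 49). With
#' 500 alternating trials and no exclusions each block holds 50 prediction
#' trials. Blocks whose contingency table has an empty actual-outcome row are
#' flagged undefined rather than raising an error.
#'
#' @param trials trial data frame (one participant) or `throw_cohort` subset.
#' @param n_blocks number of blocks (default 5, i.e. blocks of 20%).
#' @return data frame with one row per block: `block`, `n`, `pc_chance`,
#'   `pc_pred`, `acc_pred`, `defined`.
#' @export
blockwise_accuracy <- function(trials, n_blocks = 5) {
  if (inherits(trials, "throw_cohort")) trials <- trials$trials
  pred <- trials[trials$condition == "prediction" & trials$valid &
                   trials$verbalized %in% c("hit", "miss"), , drop = FALSE]
  pred <- pred[order(pred$trial_index), , drop = FALSE]
  n <- nrow(pred)
  if (n < n_blocks) stop("fewer valid prediction trials than blocks", call. = FALSE)
  base <- round(n / n_blocks)
  sizes <- c(rep(base, n_blocks - 1), n - base * (n_blocks - 1))
  if (any(sizes < 1)) stop("block sizes degenerate", call. = FALSE)
  block <- rep(seq_len(n_blocks), times = sizes)

  out <- data.frame(block = seq_len(n_blocks), n = sizes,
                    pc_chance = NA_real_, pc_pred = NA_real_,
                    acc_pred = NA_real_, defined = FALSE)
  for (b in seq_len(n_blocks)) {
    sub <- pred[block == b, , drop = FALSE]
    n11 <- sum(sub$actual == "hit" & sub$verbalized == "hit")
    n10 <- sum(sub$actual == "hit" & sub$verbalized == "miss")
    n01 <- sum(sub$actual == "miss" & sub$verbalized == "hit")
    n00 <- sum(sub$actual == "miss" & sub$verbalized == "miss")
    if ((n11 + n10) < 1 || (n01 + n00) < 1) next  # empty row: undefined block
    pa <- prediction_accuracy(contingency_counts(n11, n10, n01, n00))
    out$pc_chance[b] <- pa$pc_chance
    out$pc_pred[b] <- pa$pc_pred
    out$acc_pred[b] <- pa$acc_pred
    out$defined[b] <- pa$defined
  }
  out
}
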