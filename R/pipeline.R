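#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]. In `"simulate"` mode a
#' [cohort_config()] drives the synthetic-data generator; in `"provided"` mode
#' all three input paths (trial CSV, audio directory with a sidecar index,
#' kinematics directory) are required.
#'
#' @param mode `"simulate"` or `"provided"`.
#' @param cohort a [cohort_config()] (simulate mode).
#' @param trials_csv path to the trial table (provided mode).
#' @param audio_dir directory of mono WAV clips plus `audio_index.csv`
#'   (`participant_id,trial_index,audio_ref,t0_rel_release_s`).
#' @param kinematics_dir directory of per-trial long-format kinematics CSVs
#'   named `<participant_id>_t<trial_index>.csv`.
#' @param min_dist_m calibrated fingertip-ball distance for release detection
#'   (provided mode).
#' @param correction SDT extreme-rate correction (`"loglinear"` or `"none"`).
#' @param n_blocks session blocks for the accuracy time course.
#' @param alpha significance level reported alongside the tests.
#' @param cauchy_scale Cauchy prior scale for the Bayes factors.
#' @param synthesize_audio in simulate mode, synthesise WAV-grade clips for
#'   answered trials and run the full envelope/extraction chain instead of
#'   using ledger speech values (slow; intended for small cohorts).
#' @param seed integer seed (simulate mode; defaults to the cohort seed).
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "provided"),
                       cohort = cohort_config(),
                       trials_csv = NULL, audio_dir = NULL,
                       kinematics_dir = NULL, min_dist_m = 0.12,
                       correction = "loglinear", n_blocks = 5,
                       alpha = 0.05, cauchy_scale = 0.707,
                       synthesize_audio = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (!inherits(cohort, "cohort_config")) {
      stop("configuration error: simulate mode requires a cohort_config",
           call. = FALSE)
    }
  } else {
    paths <- c(trials_csv = trials_csv, audio_dir = audio_dir,
               kinematics_dir = kinematics_dir)
    if (length(paths) < 3 || any(!nzchar(paths))) {
      stop("configuration error: provided mode requires trials_csv, audio_dir and kinematics_dir",
           call. = FALSE)
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("configuration error: input path(s) not found: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(mode = mode, cohort = cohort, trials_csv = trials_csv,
                 audio_dir = audio_dir, kinematics_dir = kinematics_dir,
                 min_dist_m = min_dist_m, correction = correction,
                 n_blocks = n_blocks, alpha = alpha,
                 cauchy_scale = cauchy_scale,
                 synthesize_audio = synthesize_audio,
                 seed = seed %||% if (mode == "simulate") cohort$seed else 1L),
            class = "run_config")
}

#' Apply the trial-exclusion rules
#'
#' Builds the nested analysis sets and the machine-readable exclusion audit:
#' trials flagged invalid at acquisition are removed from all analyses;
#' prediction trials without a usable answer (`"none"` or `"changed"`) are
#' removed from the prediction analyses; answered trials whose speech features
#' could not be extracted are removed from the speech analyses only.
#' Participants without any extractable speech remain in the behavioural set
#' but are dropped from speech analyses.
#'
#' @param trials trial data frame.
#' @param speech_features data frame with `participant_id`, `trial_index`,
#'   `onset_latency_s`, `max_amplitude`, `valid` (or `NULL`).
#' @return list with `behavioral` (trial rows for behavioural analyses),
#'   `speech` (features joined with outcome labels, speech-valid only),
#'   `audit` (one row per excluded trial: `participant_id`, `trial_index`,
#'   `stage`, `reason`), and `fractions` (excluded fraction per stage).
#' @export
apply_exclusions <- function(trials, speech_features = NULL) {
  pred <- trials$condition == "prediction"
  reason <- rep(NA_character_, nrow(trials))
  reason[!trials$valid] <- "invalid_flag"
  reason[trials$valid & pred & trials$verbalized %in% "none"] <- "no_answer"
  reason[trials$valid & pred & trials$verbalized %in% "changed"] <- "changed_answer"
  keep <- is.na(reason)
  audit <- data.frame(
    participant_id = trials$participant_id[!keep],
    trial_index = trials$trial_index[!keep],
    stage = rep("behavioral", sum(!keep)), reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  behavioral <- trials[keep, , drop = FALSE]

  speech <- NULL
  if (!is.null(speech_features) && nrow(speech_features) > 0) {
    key <- function(d) paste(d$participant_id, d$trial_index)
    sf <- speech_features
    if (any(!key(sf) %in% key(trials))) {
      stop("speech features reference unknown participant/trial keys",
           call. = FALSE)
    }
    bkey <- key(behavioral[behavioral$condition == "prediction", , drop = FALSE])
    in_behav <- key(sf) %in% bkey
    fail <- in_behav & !(sf$valid %in% TRUE)
    if (any(fail)) {
      audit <- rbind(audit, data.frame(
        participant_id = sf$participant_id[fail],
        trial_index = sf$trial_index[fail],
        stage = rep("speech", sum(fail)),
        reason = rep("speech_extraction_failed", sum(fail)),
        stringsAsFactors = FALSE
      ))
    }
    sf <- sf[in_behav & sf$valid %in% TRUE, , drop = FALSE]
    lab <- behavioral[, c("participant_id", "trial_index", "actual", "verbalized")]
    speech <- merge(sf, lab, by = c("participant_id", "trial_index"),
                    sort = FALSE)
  }
  n_pred <- sum(pred)
  pred_key <- paste(trials$participant_id[pred], trials$trial_index[pred])
  audit_pred <- paste(audit$participant_id, audit$trial_index) %in% pred_key
  fractions <- c(
    behavioral_pct = 100 * sum(audit$stage == "behavioral") / nrow(trials),
    speech_pct = if (n_pred > 0) 100 * sum(audit_pred) / n_pred else NA_real_
  )
  list(behavioral = behavioral, speech = speech, audit = audit,
       fractions = fractions)
}

# Synthesise audio for answered trials and run the full extraction chain.
synthesize_and_extract <- function(cohort) {
  truth <- cohort$ledger$trials
  answered <- which(!is.na(truth$latency_s))
  fs <- cohort$config$audio_fs_hz
  out <- truth[answered, c("participant_id", "trial_index"), drop = FALSE]
  out$onset_latency_s <- NA_real_
  out$max_amplitude <- NA_real_
  out$valid <- FALSE
  for (j in seq_along(answered)) {
    i <- answered[j]
    if (!truth$speech_valid[i]) next     # injected technical failure
    dur <- truth$latency_s[i] + 0.6
    clip <- simulate_speech_clip(
      latency_s = truth$latency_s[i], amplitude = truth$amplitude[i],
      fs_hz = fs, duration_s = dur,
      noise_sd = 0.005 * max(truth$amplitude[i], 0.1),
      seed = sub_seed(cohort$config$seed, 7919 + i)
    )
    ft <- speech_features(clip)
    out$onset_latency_s[j] <- ft$onset_latency_s
    out$max_amplitude[j] <- ft$max_amplitude
    out$valid[j] <- isTRUE(ft$valid)
  }
  out
}

# Per-participant mean rel_latency / rel_amplitude in the four outcome cells.
speech_cell_means <- function(speech_norm) {
  ok <- speech_norm$participant_speech_ok & !is.na(speech_norm$rel_latency)
  s <- speech_norm[ok, , drop = FALSE]
  agg <- stats::aggregate(
    cbind(rel_latency, rel_amplitude) ~ participant_id + verbalized + actual,
    data = s, FUN = mean)
  agg[order(agg$participant_id, agg$verbalized, agg$actual), ]
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, exclusion accounting, the prediction-metrics
#' fit, speech normalization, and the statistical battery, and returns a
#' reproducible report. Identical configuration and seed give identical
#' reports.
#'
#' @param config a [run_config()].
#' @return object of class `throw_report`: list with `participants`, `blocks`,
#'   `tests` (cohort inference table), `speech_cells` (per-participant cell
#'   means of relative latency/amplitude), `speech_anova` (two 2x2
#'   repeated-measures ANOVAs), `speech_bias_cor` (latency and amplitude
#'   hit-miss differences correlated with the criterion), `exclusions`
#'   (audit + fractions), `alpha`, and `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$cohort)
    trials <- cohort$trials
    speech <- if (config$synthesize_audio) synthesize_and_extract(cohort)
              else cohort_speech_features(cohort)
  } else {
    trials <- read_trials_csv(config$trials_csv)
    speech <- extract_provided_speech(config)
    trials <- update_release_times(trials, config)
  }

  exc <- apply_exclusions(trials, speech)
  fit <- fit_prediction(exc$behavioral, correction = config$correction,
                        n_blocks = config$n_blocks)
  sm <- summary(fit, cauchy_scale = config$cauchy_scale)

  speech_anova <- NULL
  speech_cells <- NULL
  speech_bias_cor <- NULL
  if (!is.null(exc$speech) && nrow(exc$speech) > 0) {
    norm <- normalize_by_participant(exc$speech)
    cells <- speech_cell_means(norm)
    speech_cells <- cells
    lat <- data.frame(participant_id = cells$participant_id,
                      verbalized = cells$verbalized, actual = cells$actual,
                      value = cells$rel_latency)
    amp <- data.frame(participant_id = cells$participant_id,
                      verbalized = cells$verbalized, actual = cells$actual,
                      value = cells$rel_amplitude)
    speech_anova <- tryCatch(list(
      rel_latency = rm_anova_2x2(lat, cauchy_scale = config$cauchy_scale),
      rel_amplitude = rm_anova_2x2(amp, cauchy_scale = config$cauchy_scale)
    ), error = function(e) NULL)
    speech_bias_cor <- tryCatch(
      speech_bias_correlations(cells, fit$participants),
      error = function(e) NULL)
  }

  structure(list(
    participants = fit$participants,
    blocks = fit$blocks,
    tests = sm$tests,
    speech_cells = speech_cells,
    speech_anova = speech_anova,
    speech_bias_cor = speech_bias_cor,
    exclusions = exc[c("audit", "fractions")],
    alpha = config$alpha,
    seed = config$seed,
    mode = config$mode
  ), class = "throw_report")
}

# Correlate per-participant verbalized hit-minus-miss differences in relative
# latency / amplitude with the criterion c.
speech_bias_correlations <- function(cells, participants) {
  diff_of <- function(v) {
    byp <- split(cells, cells$participant_id)
    vapply(byp, function(s) {
      h <- mean(s[[v]][s$verbalized == "hit"])
      m <- mean(s[[v]][s$verbalized == "miss"])
      h - m
    }, numeric(1))
  }
  dl <- diff_of("rel_latency")
  da <- diff_of("rel_amplitude")
  cvals <- participants$c[match(names(dl), participants$participant_id)]
  list(latency_diff_vs_c = pearson_r(dl, cvals),
       amplitude_diff_vs_c = pearson_r(da, cvals))
}

extract_provided_speech <- function(config) {
  idx_path <- file.path(config$audio_dir, "audio_index.csv")
  if (!file.exists(idx_path)) {
    stop("configuration error: audio_index.csv not found in audio_dir",
         call. = FALSE)
  }
  idx <- utils::read.csv(idx_path, stringsAsFactors = FALSE)
  out <- idx[, c("participant_id", "trial_index")]
  out$onset_latency_s <- NA_real_
  out$max_amplitude <- NA_real_
  out$valid <- FALSE
  for (i in seq_len(nrow(idx))) {
    f <- file.path(config$audio_dir, idx$audio_ref[i])
    if (!file.exists(f)) next
    w <- read_wav(f)
    ft <- speech_features(w$samples, fs_hz = w$fs_hz,
                          t0_rel_release_s = idx$t0_rel_release_s[i])
    out$onset_latency_s[i] <- ft$onset_latency_s
    out$max_amplitude[i] <- ft$max_amplitude
    out$valid[i] <- isTRUE(ft$valid)
  }
  out
}

update_release_times <- function(trials, config) {
  for (i in which(trials$condition == "prediction")) {
    f <- file.path(config$kinematics_dir,
                   sprintf("%s_t%03d.csv", trials$participant_id[i],
                           trials$trial_index[i]))
    if (!file.exists(f)) next
    st <- read_kinematics_csv(f, fs_hz = config$cohort$mocap_fs_hz %||% 240)
    ev <- tryCatch(detect_release_distance(st, config$min_dist_m),
                   error = function(e) NULL)
    if (is.null(ev)) {
      trials$valid[i] <- FALSE
    } else {
      trials$release_time_s[i] <- ev$time_s
    }
  }
  trials
}

#' @export
print.throw_report <- function(x, ...) {
  cat(sprintf("throw_report (%s mode, seed %d): %d participants\n",
              x$mode, x$seed, nrow(x$participants)))
  cat(sprintf("  excluded from behavioural analyses: %.2f%% of trials\n",
              x$exclusions$fractions[["behavioral_pct"]]))
  cat("\nCohort measures:\n")
  p <- x$participants
  cat(sprintf("  hit rate %.2f%% | d' %.3f | c %.3f | %%Acc_Pred %.2f\n",
              100 * mean(p$hit_rate_overall), mean(p$d_prime), mean(p$c),
              mean(p$acc_pred, na.rm = TRUE)))
  cat("\nTests:\n")
  tab <- x$tests
  tab$statistic <- round(tab$statistic, 3)
  tab$p <- signif(tab$p, 3)
  tab$effect_size <- round(tab$effect_size, 3)
  tab$bf10 <- signif(tab$bf10, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' JSON report plus CSVs of the per-participant metrics, block accuracies,
#' test table and exclusion audit. Output is deterministic for a given
#' configuration and seed.
#'
#' @param report a `throw_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "throw_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$participants,
                   file.path(dir, "participant_metrics.csv"), row.names = FALSE)
  utils::write.csv(report$blocks, file.path(dir, "block_accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(report$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  utils::write.csv(report$exclusions$audit, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  json <- report
  json$speech_anova <- lapply(json$speech_anova, function(block)
    lapply(block, unclass))
  json$speech_bias_cor <- lapply(json$speech_bias_cor, unclass)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       dataframe = "columns", digits = NA, na = "null",
                       auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}
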