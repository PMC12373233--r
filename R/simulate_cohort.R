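#' Configuration for a synthetic prediction cohort
#'
#' Bundles every parameter of the behavioural generative model. Defaults
#' emulate the study conditions the pipeline was designed for: 19 experienced
#' throwers completing 500 free throws each, with visual/auditory occlusion and
#' a verbal hit/miss prediction on every second trial, an equal-variance
#' signal-detection decision process with sensitivity `d_prime` and criterion
#' `criterion_c`, and verbal responses whose onset latency and loudness shift
#' with the verbalized outcome.
#'
#' The decision model places the internal evidence for an actual hit at
#' \eqn{+d'/2} and for an actual miss at \eqn{-d'/2} (unit variance) and
#' responds "hit" iff the evidence exceeds the criterion \eqn{c}, so that
#' \eqn{HR = \Phi(d'/2 - c)} and \eqn{FA = \Phi(-d'/2 - c)}.
#'
#' `hit_rate`, `d_prime` and `criterion_c` may each be a scalar, a vector of
#' length `n_participants`, or a sampler `function(n)` drawing per-participant
#' values. When hit rates vary, the realised criterion is coupled to
#' performance as \eqn{c_i = c_0 - slope (hr_i - \overline{hr})}, so a positive
#' `bias_performance_coupling` yields the negative criterion-performance
#' correlation seen in throwers (better shooters answer "hit" more liberally)
#' while keeping `criterion_c` the cohort-mean criterion.
#'
#' @param n_participants number of simulated participants.
#' @param n_trials_per_participant throws per participant; conditions alternate
#'   with trial 1 a feedback trial, so half the trials are prediction trials.
#' @param hit_rate probability of an actual hit; scalar, vector, or sampler.
#' @param d_prime sensitivity of the verbal prediction (>= 0).
#' @param criterion_c response criterion; negative values bias toward "hit".
#' @param bias_performance_coupling slope linking per-participant hit rate to
#'   the criterion (see Details).
#' @param latency_base_s mean verbal onset latency after ball release, seconds.
#' @param latency_hit_shift_s additive latency shift for verbalized hits
#'   (negative = faster "hit" answers).
#' @param latency_noise_sd_s trial-level latency noise SD, seconds.
#' @param amplitude_base baseline peak speech-envelope amplitude (arbitrary
#'   units).
#' @param amplitude_hit_gain multiplicative amplitude gain for verbalized hits.
#' @param amplitude_noise_sdlog trial-level log-normal amplitude noise SD.
#' @param latency_participant_sd_s between-participant latency offset SD.
#' @param amplitude_participant_sdlog between-participant log-amplitude SD.
#' @param invalid_trial_rate probability a trial is flagged invalid at
#'   acquisition (detached markers, tracking loss).
#' @param no_answer_rate probability a prediction trial receives no verbal
#'   answer.
#' @param changed_answer_rate probability the participant changes the answer
#'   within a trial (excluded like no-answer trials).
#' @param speech_fail_rate probability speech features of an otherwise valid
#'   answer cannot be extracted (technical failure).
#' @param audio_fs_hz audio sampling rate used when clips are synthesised.
#' @param mocap_fs_hz motion-capture sampling rate, frames per second.
#' @param seed integer seed; identical seed + config gives identical output.
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_participants = 19,
                          n_trials_per_participant = 500,
                          hit_rate = 0.634,
                          d_prime = 0.36,
                          criterion_c = -0.32,
                          bias_performance_coupling = 1.2,
                          latency_base_s = 0.8,
                          latency_hit_shift_s = -0.1,
                          latency_noise_sd_s = 0.15,
                          amplitude_base = 1.0,
                          amplitude_hit_gain = 1.25,
                          amplitude_noise_sdlog = 0.25,
                          latency_participant_sd_s = 0.08,
                          amplitude_participant_sdlog = 0.2,
                          invalid_trial_rate = 0.0082,
                          no_answer_rate = 0.004,
                          changed_answer_rate = 0.002,
                          speech_fail_rate = 0.0262,
                          audio_fs_hz = 16000,
                          mocap_fs_hz = 240,
                          seed = 1L) {
  check_positive(n_participants, "n_participants")
  check_positive(n_trials_per_participant, "n_trials_per_participant")
  if (!is.function(hit_rate)) check_prob(hit_rate, "hit_rate", open = TRUE)
  if (!is.function(d_prime)) {
    if (!is.numeric(d_prime) || anyNA(d_prime) || any(d_prime < 0)) {
      stop("configuration error: 'd_prime' must be >= 0", call. = FALSE)
    }
  }
  if (!is.function(criterion_c) &&
      (!is.numeric(criterion_c) || anyNA(criterion_c))) {
    stop("configuration error: 'criterion_c' must be numeric", call. = FALSE)
  }
  check_prob(invalid_trial_rate, "invalid_trial_rate")
  check_prob(no_answer_rate, "no_answer_rate")
  check_prob(changed_answer_rate, "changed_answer_rate")
  check_prob(speech_fail_rate, "speech_fail_rate")
  check_positive(latency_base_s, "latency_base_s")
  check_positive(amplitude_base, "amplitude_base")
  check_positive(amplitude_hit_gain, "amplitude_hit_gain")
  check_positive(latency_noise_sd_s, "latency_noise_sd_s", strict = FALSE)
  check_positive(amplitude_noise_sdlog, "amplitude_noise_sdlog", strict = FALSE)
  if (audio_fs_hz < 8000) {
    stop("configuration error: 'audio_fs_hz' must be >= 8000 (500-4000 Hz band)",
         call. = FALSE)
  }
  check_positive(mocap_fs_hz, "mocap_fs_hz")
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_trials_per_participant = as.integer(n_trials_per_participant),
    hit_rate = hit_rate, d_prime = d_prime, criterion_c = criterion_c,
    bias_performance_coupling = bias_performance_coupling,
    latency_base_s = latency_base_s, latency_hit_shift_s = latency_hit_shift_s,
    latency_noise_sd_s = latency_noise_sd_s,
    amplitude_base = amplitude_base, amplitude_hit_gain = amplitude_hit_gain,
    amplitude_noise_sdlog = amplitude_noise_sdlog,
    latency_participant_sd_s = latency_participant_sd_s,
    amplitude_participant_sdlog = amplitude_participant_sdlog,
    invalid_trial_rate = invalid_trial_rate,
    no_answer_rate = no_answer_rate,
    changed_answer_rate = changed_answer_rate,
    speech_fail_rate = speech_fail_rate,
    audio_fs_hz = audio_fs_hz, mocap_fs_hz = mocap_fs_hz,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate a cohort of throwers with verbal outcome predictions
#'
#' Generates trial-level behavioural data with the statistical structure the
#' analysis pipeline assumes, together with a ground-truth ledger recording
#' every latent draw (evidence values, true speech latencies/amplitudes,
#' injected exclusions), so each downstream stage can be verified against
#' known truth.
#'
#' Actual outcomes are Bernoulli at the participant's hit rate on every trial.
#' On prediction trials (even trial indices; trial 1 is a feedback trial) an
#' evidence value is drawn from \eqn{N(\pm d'/2, 1)} and "hit" is verbalized
#' iff it exceeds the participant's criterion. A small fraction of prediction
#' trials receive no answer or a changed answer, and a small fraction of all
#' trials are flagged invalid, mirroring acquisition losses.
#'
#' @param config a [cohort_config()].
#' @return An object of class `throw_cohort`: a list with
#'   \describe{
#'     \item{trials}{data frame with columns `participant_id`, `trial_index`,
#'       `condition`, `actual`, `verbalized`, `valid`, `release_time_s`,
#'       `audio_ref`.}
#'     \item{ledger}{ground truth: per-participant parameters and per-trial
#'       latent evidence, speech latency/amplitude and speech validity.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 2,
#'                                      n_trials_per_participant = 20))
#' head(coh$trials)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("configuration error: 'config' must be a cohort_config", call. = FALSE)
  }
  np <- config$n_participants
  nt <- config$n_trials_per_participant

  set.seed(config$seed)
  hr <- resolve_param(config$hit_rate, np, "hit_rate")
  check_prob(hr, "hit_rate", open = TRUE)
  dp <- resolve_param(config$d_prime, np, "d_prime")
  if (any(dp < 0)) stop("configuration error: 'd_prime' must be >= 0", call. = FALSE)
  c0 <- resolve_param(config$criterion_c, np, "criterion_c")
  cc <- c0 - config$bias_performance_coupling * (hr - mean(hr))
  lat_off <- stats::rnorm(np, 0, config$latency_participant_sd_s)
  amp_mult <- exp(stats::rnorm(np, 0, config$amplitude_participant_sdlog))

  per_part <- vector("list", np)
  for (i in seq_len(np)) {
    set.seed(sub_seed(config$seed, i))
    trial <- seq_len(nt)
    condition <- ifelse(trial %% 2L == 0L, "prediction", "feedback")
    actual <- ifelse(stats::runif(nt) < hr[i], "hit", "miss")
    release_time_s <- stats::runif(nt, 1.8, 3.2)
    pred <- condition == "prediction"

    evidence <- rep(NA_real_, nt)
    evidence[pred] <- ifelse(actual[pred] == "hit", dp[i] / 2, -dp[i] / 2) +
      stats::rnorm(sum(pred))
    verbalized <- rep(NA_character_, nt)
    verbalized[pred] <- ifelse(evidence[pred] > cc[i], "hit", "miss")

    u <- stats::runif(nt)
    no_ans <- pred & u < config$no_answer_rate
    changed <- pred & !no_ans &
      u < config$no_answer_rate + config$changed_answer_rate
    verbalized[no_ans] <- "none"
    verbalized[changed] <- "changed"

    valid <- stats::runif(nt) >= config$invalid_trial_rate

    answered <- pred & verbalized %in% c("hit", "miss")
    latency <- rep(NA_real_, nt)
    amplitude <- rep(NA_real_, nt)
    n_ans <- sum(answered)
    if (n_ans > 0) {
      is_hit_ans <- verbalized[answered] == "hit"
      latency[answered] <- pmax(
        0.15,
        config$latency_base_s + lat_off[i] +
          ifelse(is_hit_ans, config$latency_hit_shift_s, 0) +
          stats::rnorm(n_ans, 0, config$latency_noise_sd_s)
      )
      amplitude[answered] <- config$amplitude_base * amp_mult[i] *
        ifelse(is_hit_ans, config$amplitude_hit_gain, 1) *
        exp(stats::rnorm(n_ans, 0, config$amplitude_noise_sdlog))
    }
    speech_valid <- answered & valid &
      stats::runif(nt) >= config$speech_fail_rate

    pid <- sprintf("P%02d", i)
    audio_ref <- ifelse(answered, sprintf("%s_t%03d.wav", pid, trial),
                        NA_character_)
    per_part[[i]] <- list(
      trials = data.frame(
        participant_id = pid, trial_index = trial, condition = condition,
        actual = actual, verbalized = verbalized, valid = valid,
        release_time_s = release_time_s, audio_ref = audio_ref,
        stringsAsFactors = FALSE
      ),
      truth = data.frame(
        participant_id = pid, trial_index = trial, evidence = evidence,
        latency_s = latency, amplitude = amplitude,
        speech_valid = speech_valid, stringsAsFactors = FALSE
      )
    )
  }

  trials <- do.call(rbind, lapply(per_part, `[[`, "trials"))
  truth <- do.call(rbind, lapply(per_part, `[[`, "truth"))
  rownames(trials) <- rownames(truth) <- NULL
  ledger <- list(
    participants = data.frame(
      participant_id = sprintf("P%02d", seq_len(np)),
      hit_rate = hr, d_prime = dp, criterion_c = cc,
      latency_offset_s = lat_off, amplitude_mult = amp_mult,
      stringsAsFactors = FALSE
    ),
    trials = truth
  )
  structure(list(trials = trials, ledger = ledger, config = config),
            class = "throw_cohort")
}

#' @export
print.throw_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic throw cohort: %d participants x %d trials (%d prediction trials each)\n",
    x$config$n_participants, x$config$n_trials_per_participant,
    sum(x$trials$condition == "prediction") / x$config$n_participants
  ))
  cat(sprintf("  mean true d' = %.3f, mean true c = %.3f, mean hit rate = %.3f\n",
              mean(x$ledger$participants$d_prime),
              mean(x$ledger$participants$criterion_c),
              mean(x$ledger$participants$hit_rate)))
  invisible(x)
}

#' Measured speech features implied by a cohort's ground truth
#'
#' Returns the per-trial speech features a perfect extractor would measure on
#' the cohort's audio: the ledger latency/amplitude for trials whose speech
#' was captured, with extraction failures marked invalid. Used by the pipeline
#' when full audio synthesis is not requested.
#'
#' @param cohort a `throw_cohort`.
#' @return data frame `participant_id, trial_index, onset_latency_s,
#'   max_amplitude, valid`.
#' @export
cohort_speech_features <- function(cohort) {
  stopifnot(inherits(cohort, "throw_cohort"))
  tr <- cohort$ledger$trials
  answered <- !is.na(tr$latency_s)
  data.frame(
    participant_id = tr$participant_id[answered],
    trial_index = tr$trial_index[answered],
    onset_latency_s = tr$latency_s[answered],
    max_amplitude = tr$amplitude[answered],
    valid = tr$speech_valid[answered],
    stringsAsFactors = FALSE
  )
}
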