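# Shared fixtures and independent oracles for the test suite.

# Minimal trial table builder.
make_trials <- function(actual, verbalized, condition = "prediction",
                        valid = TRUE, participant_id = "P01") {
  n <- length(actual)
  data.frame(
    participant_id = participant_id, trial_index = seq_len(n),
    condition = rep(condition, length.out = n), actual = actual,
    verbalized = verbalized, valid = rep(valid, length.out = n),
    release_time_s = 2, audio_ref = NA_character_,
    stringsAsFactors = FALSE
  )
}

# Brute-force chance rate / accuracy from the printed formulas, written
# independently of the package internals.
oracle_acc <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  act_hit <- (n11 + n10) / n
  verb_hit <- (n11 + n01) / n
  pc_chance <- (act_hit * verb_hit + (1 - act_hit) * (1 - verb_hit)) * 100
  pc_pred <- 100 * (n11 + n00) / n
  list(pc_chance = pc_chance, pc_pred = pc_pred,
       acc = 100 * (pc_pred - pc_chance) / (100 - pc_chance))
}

# Exhaustive frame scan for the distance-criterion release: first frame whose
# distance increment exceeds the threshold and that passes speed/contact
# confirmation, evaluated directly from the marker arrays.
oracle_release_scan <- function(stream, min_dist_m, threshold_m = 0.003) {
  ctr <- (stream$markers$pole_left + stream$markers$pole_right) / 2
  d <- sqrt(rowSums((stream$markers$fingertip - ctr)^2))
  n <- length(d)
  fs <- stream$fs_hz
  v <- matrix(NA_real_, n, 3)
  v[2:(n - 1), ] <- (ctr[3:n, ] - ctr[1:(n - 2), ]) * fs / 2
  v[1, ] <- (ctr[2, ] - ctr[1, ]) * fs
  v[n, ] <- (ctr[n, ] - ctr[n - 1, ]) * fs
  spd <- sqrt(rowSums(v^2))
  contact <- d <= min_dist_m + 0.005
  for (i in 2:n) {
    if (!(d[i] - d[i - 1] > threshold_m)) next
    pre <- which(contact[seq_len(i - 1)])
    if (length(pre) == 0) next
    r <- rle(contact[seq_len(i - 1)])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    tr <- which(r$values)
    len <- r$lengths[tr]
    onset <- starts[tr][max(which(len == max(len)))]
    if (spd[i] > 5 && (i - onset) / fs > 0.5) return(i - 1L)  # 0-based
  }
  NA_integer_
}

# Full sums-of-squares decomposition for a 2x2 within-subject design,
# computed from first principles.
oracle_rm_anova <- function(cells) {
  cm <- tapply(cells$value, list(cells$participant_id, cells$verbalized,
                                 cells$actual), mean)
  n <- dim(cm)[1]
  grand <- mean(cm)
  m_s <- apply(cm, 1, mean)
  m_a <- apply(cm, 2, mean)
  m_b <- apply(cm, 3, mean)
  m_sa <- apply(cm, c(1, 2), mean)
  m_sb <- apply(cm, c(1, 3), mean)
  m_ab <- apply(cm, c(2, 3), mean)
  ss_a <- n * 2 * sum((m_a - grand)^2)
  ss_b <- n * 2 * sum((m_b - grand)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + grand)^2)
  ss_sa <- 2 * sum((sweep(sweep(m_sa, 1, m_s), 2, m_a) + grand)^2)
  ss_sb <- 2 * sum((sweep(sweep(m_sb, 1, m_s), 2, m_b) + grand)^2)
  resid <- cm
  for (i in seq_len(n)) for (j in 1:2) for (k in 1:2) {
    resid[i, j, k] <- cm[i, j, k] - m_sa[i, j] - m_sb[i, k] - m_ab[j, k] +
      m_s[i] + m_a[j] + m_b[k] - grand
  }
  ss_sab <- sum(resid^2)
  list(
    F_a = (ss_a / 1) / (ss_sa / (n - 1)),
    F_b = (ss_b / 1) / (ss_sb / (n - 1)),
    F_ab = (ss_ab / 1) / (ss_sab / (n - 1)),
    eta2p_a = ss_a / (ss_a + ss_sa),
    eta2p_b = ss_b / (ss_b + ss_sb),
    eta2p_ab = ss_ab / (ss_ab + ss_sab),
    df2 = n - 1
  )
}
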