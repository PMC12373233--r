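#' Construct a statistical result record
#'
#' Uniform container for the inference suite: statistic, degrees of freedom,
#' p value, tail, effect size (eta squared or partial eta squared), and the
#' Bayes factor pair (`bf01 = 1 / bf10`).
#'
#' @param test_name label.
#' @param statistic test statistic.
#' @param df degrees of freedom (scalar or length-2 for F tests).
#' @param p_value p value.
#' @param tail `"one"` or `"two"`.
#' @param effect_size effect-size value.
#' @param effect_kind `"eta2"` or `"eta2_part"`.
#' @param bf10 Bayes factor for the alternative over the null.
#' @return object of class `stat_result`.
#' @export
stat_result <- function(test_name, statistic, df, p_value, tail,
                        effect_size, effect_kind = c("eta2", "eta2_part"),
                        bf10 = NA_real_) {
  effect_kind <- match.arg(effect_kind)
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value outside [0, 1]", call. = FALSE)
  }
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, tail = tail, effect_size = effect_size,
                 effect_kind = effect_kind, bf10 = bf10,
                 bf01 = 1 / bf10),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g (%s-tailed), %s = %.4f, BF10 = %.4g\n",
              x$test_name, x$statistic, paste(round(x$df, 2), collapse = ", "),
              x$p_value, x$tail, x$effect_kind, x$effect_size, x$bf10))
  invisible(x)
}

# Collapse a named list of stat_result objects into a data frame.
stat_results_table <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(test = nm, statistic = r$statistic,
               df = paste(round(r$df, 2), collapse = ","),
               p = r$p_value, tail = r$tail,
               effect_size = r$effect_size, effect_kind = r$effect_kind,
               bf10 = r$bf10, stringsAsFactors = FALSE)
  }))
}

#' One-sample Student t-test with effect size and Bayes factor
#'
#' t = (mean - mu0) / (sd / sqrt(n)), df = n - 1; the effect size is
#' eta squared = t^2 / (t^2 + df). The Bayes factor uses the JZS Cauchy prior
#' ([bayes_factor_t()]), truncated to the tested direction for one-tailed
#' tests.
#'
#' @param values numeric vector (n >= 2, nonzero variance).
#' @param mu0 null value.
#' @param tail `"two"`, `"greater"`, or `"less"`.
#' @param cauchy_scale prior scale for the Bayes factor.
#' @return A [stat_result()].
#' @examples
#' one_sample_t(c(1, 2, 3, 4, 5), 0)  # t = 4.2426, df = 4
#' @export
one_sample_t <- function(values, mu0 = 0, tail = c("two", "greater", "less"),
                         cauchy_scale = 0.707) {
  tail <- match.arg(tail)
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values) || !all(is.finite(values))) {
    stop("need >= 2 finite values", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("zero variance: t statistic undefined", call. = FALSE)
  }
  alt <- switch(tail, two = "two.sided", greater = "greater", less = "less")
  tt <- stats::t.test(values, mu = mu0, alternative = alt)
  tval <- unname(tt$statistic)
  df <- unname(tt$parameter)
  bf <- bayes_factor_t(tval, n = length(values), cauchy_scale = cauchy_scale,
                       tail = tail)
  stat_result("one_sample_t", tval, df, unname(tt$p.value),
              if (tail == "two") "two" else "one",
              effect_size = tval^2 / (tval^2 + df), effect_kind = "eta2",
              bf10 = bf)
}

#' Paired (dependent-samples) t-test
#'
#' A one-sample test on the pairwise differences `x - y` against zero.
#'
#' @param x,y paired numeric vectors of equal length.
#' @inheritParams one_sample_t
#' @return A [stat_result()].
#' @export
paired_t <- function(x, y, tail = c("two", "greater", "less"),
                     cauchy_scale = 0.707) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  r <- one_sample_t(x - y, 0, tail = tail, cauchy_scale = cauchy_scale)
  r$test_name <- "paired_t"
  r
}

#' Pearson correlation with effect size and Bayes factor
#'
#' Sample correlation with `t = r sqrt(df / (1 - r^2))`, `df = n - 2`; the
#' effect size is `eta2 = r^2`. The Bayes factor uses a stretched-beta prior
#' on the population correlation ([bayes_factor_r()]). Incomplete pairs are
#' dropped.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @param tail `"two"`, `"greater"`, or `"less"`.
#' @param kappa stretched-beta prior width for the Bayes factor.
#' @return A [stat_result()].
#' @export
pearson_r <- function(x, y, tail = c("two", "greater", "less"), kappa = 1) {
  tail <- match.arg(tail)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate variance: correlation undefined", call. = FALSE)
  }
  alt <- switch(tail, two = "two.sided", greater = "greater", less = "less")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = alt)
  r <- unname(ct$estimate)
  # a perfect correlation is the BF10 -> Inf limit of the sampling model
  bf <- if (abs(r) >= 1 - 1e-12) Inf
        else bayes_factor_r(r, n, kappa = kappa, tail = tail)
  out <- stat_result("pearson_r", unname(ct$statistic), unname(ct$parameter),
                     unname(ct$p.value),
                     if (tail == "two") "two" else "one",
                     effect_size = r^2, effect_kind = "eta2", bf10 = bf)
  out$r <- r
  out
}

#' 2x2 repeated-measures analysis of variance
#'
#' Within-subject ANOVA for two crossed two-level factors measured on every
#' participant (here: verbalized result x actual result, with the cell value
#' a participant's mean relative latency or amplitude). Each effect is tested
#' against its own participant-by-effect interaction with df (1, n - 1);
#' partial eta squared is `SS_effect / (SS_effect + SS_error)`. Participants
#' missing any cell are dropped listwise. Each effect's Bayes factor is
#' computed from the equivalent paired t statistic on the per-participant
#' contrast scores (`t^2 = F` for df1 = 1).
#'
#' @param cells data frame with columns `participant_id`, `verbalized`
#'   (two levels), `actual` (two levels), and `value` (the cell mean).
#' @param cauchy_scale prior scale for the Bayes factors.
#' @return named list of three [stat_result()]s: `verbalized`, `actual`,
#'   `interaction`.
#' @export
rm_anova_2x2 <- function(cells, cauchy_scale = 0.707) {
  need <- c("participant_id", "verbalized", "actual", "value")
  if (!all(need %in% names(cells))) {
    stop("cells must contain: ", paste(need, collapse = ", "), call. = FALSE)
  }
  cells <- cells[is.finite(cells$value), , drop = FALSE]
  counts <- table(cells$participant_id)
  complete <- names(counts)[counts == 4]
  cells <- cells[cells$participant_id %in% complete, , drop = FALSE]
  n <- length(complete)
  if (n < 2) stop("need >= 2 participants with all four cells", call. = FALSE)

  d <- data.frame(
    id = factor(cells$participant_id),
    A = factor(cells$verbalized), B = factor(cells$actual),
    y = cells$value
  )
  if (nlevels(d$A) != 2 || nlevels(d$B) != 2) {
    stop("both factors must have exactly two levels", call. = FALSE)
  }
  fit <- stats::aov(y ~ A * B + Error(id / (A * B)), data = d)
  sm <- summary(fit)

  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    list(F = tab[i, "F value"], df1 = tab[i, "Df"],
         p = tab[i, "Pr(>F)"],
         ss = tab[i, "Sum Sq"],
         ss_err = tab[trimws(rownames(tab)) == "Residuals", "Sum Sq"],
         df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"])
  }
  # per-participant cell means for the signed contrast t / Bayes factor
  cm <- tapply(d$y, list(d$id, d$A, d$B), mean)
  a <- dimnames(cm)[[2]]; b <- dimnames(cm)[[3]]
  contrA <- (cm[, a[1], b[1]] + cm[, a[1], b[2]] -
             cm[, a[2], b[1]] - cm[, a[2], b[2]]) / 2
  contrB <- (cm[, a[1], b[1]] + cm[, a[2], b[1]] -
             cm[, a[1], b[2]] - cm[, a[2], b[2]]) / 2
  contrAB <- (cm[, a[1], b[1]] - cm[, a[1], b[2]] -
              cm[, a[2], b[1]] + cm[, a[2], b[2]]) / 2

  mk <- function(term, stratum, contrast) {
    e <- pull(stratum, term)
    tval <- sign(mean(contrast)) * sqrt(e$F)
    bf <- if (stats::sd(contrast) > 0)
      bayes_factor_t(tval, n = n, cauchy_scale = cauchy_scale, tail = "two")
    else NA_real_
    stat_result(paste0("rm_anova_", term), e$F, c(e$df1, e$df2), e$p, "two",
                effect_size = e$ss / (e$ss + e$ss_err),
                effect_kind = "eta2_part", bf10 = bf)
  }
  list(
    verbalized = mk("A", "Error: id:A", contrA),
    actual = mk("B", "Error: id:B", contrB),
    interaction = mk("A:B", "Error: id:A:B", contrAB)
  )
}

#' Categorize a Bayes factor
#'
#' Evidence categories at the conventional boundaries 3, 10, 30 and 100:
#' anecdotal (1-3), sufficient (3-10), strong (10-30), very strong (30-100),
#' extreme (> 100). Bayes factors below 1 are categorized by the same
#' boundaries on `1 / bf10`, with the supported hypothesis reported as `"H0"`.
#'
#' @param bf10 Bayes factor(s) for the alternative over the null.
#' @return data frame with columns `bf10`, `favours` (`"H1"`, `"H0"`, or
#'   `"none"` at exactly 1) and `category`.
#' @export
bf_category <- function(bf10) {
  stopifnot(all(bf10 > 0))
  mag <- pmax(bf10, 1 / bf10)
  cat_lbl <- cut(mag, breaks = c(1, 3, 10, 30, 100, Inf),
                 labels = c("anecdotal", "sufficient", "strong",
                            "very strong", "extreme"),
                 right = FALSE, include.lowest = TRUE)
  data.frame(
    bf10 = bf10,
    favours = ifelse(bf10 > 1, "H1", ifelse(bf10 < 1, "H0", "none")),
    category = as.character(cat_lbl),
    stringsAsFactors = FALSE
  )
}
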