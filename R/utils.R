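# Internal helpers shared across modules.

# Deterministic per-participant sub-seed below 2^31 so adding participants to a
# cohort never perturbs the streams of existing ones.
sub_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(i) * 1000003
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_prob <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("configuration error: '%s' must be numeric and non-missing", name),
         call. = FALSE)
  }
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (bad) {
    stop(sprintf("configuration error: '%s' must lie in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x) || any(if (strict) x <= 0 else x < 0)) {
    stop(sprintf("configuration error: '%s' must be %s", name,
                 if (strict) "strictly positive" else "non-negative"),
         call. = FALSE)
  }
  invisible(x)
}

# Resolve a scalar / per-participant vector / sampler function into a vector of
# length n. Samplers draw from the current RNG stream.
resolve_param <- function(x, n, name) {
  v <- if (is.function(x)) x(n) else if (length(x) == 1L) rep(x, n) else x
  if (length(v) != n || !is.numeric(v) || anyNA(v)) {
    stop(sprintf("configuration error: '%s' must resolve to %d finite values",
                 name, n), call. = FALSE)
  }
  as.numeric(v)
}
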