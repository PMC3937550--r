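# Internal input validation helpers. All user-facing domain errors are
# signalled without a call to keep messages readable from the CLI.

stop_domain <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain("`%s` must be a single finite number", name)
  }
  if (strict_lower && x <= lower) {
    stop_domain("`%s` must be > %g (got %g)", name, lower, x)
  }
  if (!strict_lower && x < lower) {
    stop_domain("`%s` must be >= %g (got %g)", name, lower, x)
  }
  if (x > upper) {
    stop_domain("`%s` must be <= %g (got %g)", name, upper, x)
  }
  invisible(x)
}

check_vector <- function(x, name, lower = -Inf, strict_lower = FALSE,
                         min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len || !all(is.finite(x))) {
    stop_domain("`%s` must be a finite numeric vector of length >= %d",
                name, min_len)
  }
  if (strict_lower && any(x <= lower)) {
    stop_domain("all elements of `%s` must be > %g", name, lower)
  }
  if (!strict_lower && any(x < lower)) {
    stop_domain("all elements of `%s` must be >= %g", name, lower)
  }
  invisible(x)
}

# Columns every trial table must carry for model fitting.
trial_fit_columns <- c("s_sec", "w_sec", "r_sec")

check_trials <- function(trials, name = "trials",
                         cols = trial_fit_columns, min_rows = 1L) {
  if (!is.data.frame(trials)) {
    stop_domain("`%s` must be a data.frame of trials", name)
  }
  missing <- setdiff(cols, names(trials))
  if (length(missing) > 0L) {
    stop_domain("`%s` is missing required column(s): %s",
                name, paste(missing, collapse = ", "))
  }
  if (nrow(trials) < min_rows) {
    stop_domain("`%s` must contain at least %d trial(s)", name, min_rows)
  }
  invisible(trials)
}
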