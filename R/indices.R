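# Model-free data reduction: per-cell arithmetic means and aggregate ratio
# indices of the emotional-valence effect.

#' Per-cell mean reproduced durations for one subject
#'
#' Reduces a subject's trials to the arithmetic mean response per design cell
#' (valence x encoded duration). In the reference design each of the 9 cells
#' holds 5 trials; cells with fewer trials are averaged over what is present
#' with a warning, and empty cells are reported as `NA` (downstream use of an
#' empty cell is an error).
#'
#' @param trials Data frame with columns `valence`, `s_sec`, `r_sec`; the
#'   trials of one subject.
#' @param durations Encoded durations defining the columns, seconds
#'   (default `c(2, 4, 6)`, indexed i = 1, 2, 3).
#' @param valences Valence codes defining the rows (default `c("P","N","E")`).
#' @param trials_per_cell Expected trials per cell (default 5); fewer
#'   triggers a warning.
#' @return Object of class `cell_means`: list with `r_bar` (valence x
#'   duration matrix of mean responses, seconds) and `n` (trial counts).
#' @examples
#' tr <- data.frame(valence = rep(c("P", "N", "E"), each = 3),
#'                  s_sec = rep(c(2, 4, 6), 3), r_sec = rep(c(2, 4, 6), 3))
#' cell_means(tr, trials_per_cell = 1)$r_bar
#' @export
cell_means <- function(trials, durations = c(2, 4, 6),
                       valences = c("P", "N", "E"), trials_per_cell = 5) {
  check_trials(trials, cols = c("valence", "s_sec", "r_sec"))
  check_vector(durations, "durations", lower = 0, strict_lower = TRUE)
  if (!all(trials$valence %in% valences)) {
    stop_domain("unknown valence code(s): %s",
                paste(setdiff(unique(trials$valence), valences),
                      collapse = ", "))
  }
  di <- match(trials$s_sec, durations)
  if (anyNA(di)) {
    stop_domain("encoded duration(s) outside the design: %s",
                paste(unique(trials$s_sec[is.na(di)]), collapse = ", "))
  }
  vi <- match(trials$valence, valences)
  r_bar <- matrix(NA_real_, length(valences), length(durations),
                  dimnames = list(valences, paste0("s", durations)))
  n <- matrix(0L, length(valences), length(durations),
              dimnames = dimnames(r_bar))
  for (k in seq_len(nrow(trials))) {
    n[vi[k], di[k]] <- n[vi[k], di[k]] + 1L
  }
  sums <- matrix(0, length(valences), length(durations))
  for (k in seq_len(nrow(trials))) {
    sums[vi[k], di[k]] <- sums[vi[k], di[k]] + trials$r_sec[k]
  }
  filled <- n > 0L
  r_bar[filled] <- sums[filled] / n[filled]
  if (any(filled & n < trials_per_cell)) {
    warning(sprintf("%d cell(s) hold fewer than %d trials; means taken over what is present",
                    sum(filled & n < trials_per_cell), trials_per_cell),
            call. = FALSE)
  }
  structure(list(r_bar = r_bar, n = n, durations = durations),
            class = "cell_means")
}

#' Aggregate ratio index of a valence effect
#'
#' Model-free effect measure for valence `v` relative to the neutral
#' condition: the mean over the three encoded durations of the ratio of cell
#' means, \deqn{a_v = \frac{1}{3} \sum_i \bar r_{v,i} / \bar r_{E,i}.}
#' Units cancel, so the index is invariant under a common rescaling of all
#' responses, and its expected value is 1 when the valence has no effect.
#'
#' @param cm A [cell_means()] object.
#' @param v Valence to compare against neutral, `"P"` or `"N"`.
#' @return The aggregate ratio index \eqn{a_v} (dimensionless scalar).
#' @export
aggregate_ratio <- function(cm, v = c("P", "N")) {
  if (!inherits(cm, "cell_means")) {
    stop_domain("`cm` must be a cell_means object")
  }
  v <- match.arg(v)
  num <- cm$r_bar[v, ]
  den <- cm$r_bar["E", ]
  if (anyNA(num) || anyNA(den)) {
    stop_domain("aggregate_ratio('%s') needs all durations for '%s' and 'E'",
                v, v)
  }
  mean(num / den)
}
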