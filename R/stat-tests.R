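# Statistical battery: t-tests, within-subject ANOVA with Greenhouse-Geisser
# correction, Pearson correlation, fixed-bandwidth Gaussian KDE.

new_test_result <- function(statistic, df, p_value, method, estimate = NULL) {
  structure(
    list(statistic = statistic, df = df, p_value = p_value,
         method = method, estimate = estimate),
    class = "dkm_test"
  )
}

#' @export
print.dkm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' One-sample t-test
#'
#' Two-sided Student t-test of the mean of `values` against `mu0`:
#' \eqn{t = (\bar x - \mu_0)/(s/\sqrt n)} with \eqn{n - 1} degrees of
#' freedom. Used to test ratio indices and inflow ratios against their null
#' expectation of 1.
#'
#' @param values Numeric vector, length >= 2, with nonzero variance.
#' @param mu0 Null mean (default 1, the no-effect expectation for ratios).
#' @return Object of class `dkm_test` with `statistic`, `df`, `p_value`,
#'   `estimate` (the sample mean).
#' @examples
#' one_sample_t(c(1.1, 1.0, 1.05, 0.95, 1.2), mu0 = 1)
#' @export
one_sample_t <- function(values, mu0 = 1) {
  check_vector(values, "values", min_len = 2L)
  check_scalar(mu0, "mu0")
  s <- stats::sd(values)
  if (s == 0) {
    stop_domain("degenerate input: `values` has zero variance")
  }
  n <- length(values)
  t <- (mean(values) - mu0) / (s / sqrt(n))
  new_test_result(t, n - 1, 2 * stats::pt(-abs(t), n - 1),
                  "one-sample t-test", estimate = mean(values))
}

#' Paired t-test
#'
#' One-sample t-test of the pairwise differences `x - y` against zero; the
#' post-hoc test used between valence conditions within each duration.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Object of class `dkm_test`; `estimate` is the mean difference.
#' @export
paired_t <- function(x, y) {
  check_vector(x, "x", min_len = 2L)
  check_vector(y, "y", min_len = 2L)
  if (length(x) != length(y)) {
    stop_domain("`x` and `y` must have equal length")
  }
  res <- one_sample_t(x - y, mu0 = 0)
  res$method <- "paired t-test"
  res
}

#' Pearson correlation with t-based test
#'
#' Sample product-moment correlation with the usual two-sided test,
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n - 2} degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Object of class `dkm_test`; `statistic` and `estimate` are the
#'   correlation coefficient r.
#' @examples
#' pearson_r(c(1, 2, 3), c(2, 4, 7))
#' @export
pearson_r <- function(x, y) {
  check_vector(x, "x", min_len = 3L)
  check_vector(y, "y", min_len = 3L)
  if (length(x) != length(y)) {
    stop_domain("`x` and `y` must have equal length")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_domain("degenerate input: zero variance")
  }
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  new_test_result(r, df, p, "Pearson correlation", estimate = r)
}

# (k-1) x k matrix of orthonormal contrasts, rows orthogonal to the constant.
orthonormal_contrasts <- function(k) {
  cm <- stats::contr.helmert(k)
  t(cm) / sqrt(colSums(cm^2))
}

# Greenhouse-Geisser epsilon for the effect spanned by the orthonormal
# contrast rows C, from the covariance S of the subject-by-cell scores:
# eps = tr(CSC')^2 / (d * tr((CSC')^2)).
gg_epsilon <- function(S, C) {
  M <- C %*% S %*% t(C)
  d <- nrow(C)
  if (d == 1L) {
    return(1)
  }
  sum(diag(M))^2 / (d * sum(M * M))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject analysis of variance for one within factor (`y` a subjects
#' x levels matrix) or two fully crossed within factors (`y` a subjects x
#' levels-A x levels-B array, e.g. cell means indexed by valence and
#' duration). Each effect is tested against its effect-by-subject interaction;
#' the Greenhouse--Geisser sphericity correction
#' \eqn{\epsilon = \mathrm{tr}(M)^2 / \{d\,\mathrm{tr}(M^2)\}} (with
#' \eqn{M = C S C'} for orthonormal effect contrasts C and the covariance S
#' of the subject-by-cell scores, d the effect df) is applied
#' unconditionally, scaling both degrees of freedom. For a 2-level factor
#' \eqn{\epsilon = 1} exactly.
#'
#' @param y Numeric matrix (subjects x levels) or 3-d array (subjects x
#'   A-levels x B-levels), complete and balanced, >= 3 subjects.
#' @param factor_names Character names for the within factor(s); defaults to
#'   `"A"`/`"B"` or the dimnames of `y`.
#' @return Data frame with one row per effect: `effect`, `F`, `df1`, `df2`
#'   (uncorrected), `epsilon`, `df1_gg`, `df2_gg`, `p_gg`, `p_uncorrected`.
#' @examples
#' y <- rbind(c(1, 2, 3), c(2, 3, 4), c(3, 5, 4))
#' rm_anova_gg(y) # F = 7 on (2, 4) df before correction
#' @export
rm_anova_gg <- function(y, factor_names = NULL) {
  if (is.matrix(y)) {
    y <- array(y, dim = c(nrow(y), ncol(y), 1L))
    if (is.null(factor_names)) factor_names <- "A"
    one_way <- TRUE
  } else {
    one_way <- FALSE
  }
  if (!is.array(y) || length(dim(y)) != 3L || !is.numeric(y)) {
    stop_domain("`y` must be a subjects x levels matrix or a 3-d array")
  }
  if (anyNA(y)) {
    stop_domain("`y` has missing cells; the design must be complete")
  }
  n <- dim(y)[1]
  a <- dim(y)[2]
  b <- dim(y)[3]
  if (n < 3L) {
    stop_domain("at least 3 subjects are required")
  }
  if (is.null(factor_names)) {
    factor_names <- c("A", "B")
  }
  grand <- mean(y)
  m_i <- apply(y, 1, mean)    # subject means
  m_a <- apply(y, 2, mean)    # factor-A level means
  m_b <- apply(y, 3, mean)
  m_ia <- apply(y, c(1, 2), mean)
  m_ib <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)

  # Cell scores flattened subjects x (a*b), A-index varying fastest.
  X <- matrix(y, n, a * b)
  S <- stats::cov(X)
  Qa <- orthonormal_contrasts(a)
  effects <- list()

  add_effect <- function(name, ss_eff, df1, ss_err, df2, C) {
    F <- (ss_eff / df1) / (ss_err / df2)
    eps <- gg_epsilon(S, C)
    effects[[length(effects) + 1L]] <<- data.frame(
      effect = name, F = F, df1 = df1, df2 = df2, epsilon = eps,
      df1_gg = eps * df1, df2_gg = eps * df2,
      p_gg = stats::pf(F, eps * df1, eps * df2, lower.tail = FALSE),
      p_uncorrected = stats::pf(F, df1, df2, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  }

  ss_a <- n * b * sum((m_a - grand)^2)
  ss_as <- b * sum((m_ia - outer(m_i, rep(1, a)) -
                      outer(rep(1, n), m_a) + grand)^2)
  C_a <- kronecker(matrix(rep(1, b) / sqrt(b), nrow = 1), Qa)
  add_effect(factor_names[1], ss_a, a - 1, ss_as, (a - 1) * (n - 1), C_a)

  if (!one_way) {
    Qb <- orthonormal_contrasts(b)
    ss_b <- n * a * sum((m_b - grand)^2)
    ss_bs <- a * sum((m_ib - outer(m_i, rep(1, b)) -
                        outer(rep(1, n), m_b) + grand)^2)
    C_b <- kronecker(Qb, matrix(rep(1, a) / sqrt(a), nrow = 1))
    add_effect(factor_names[2], ss_b, b - 1, ss_bs, (b - 1) * (n - 1), C_b)

    resid_ab <- m_ab - outer(m_a, rep(1, b)) - outer(rep(1, a), m_b) + grand
    ss_ab <- n * sum(resid_ab^2)
    resid_abs <- y
    for (i in seq_len(n)) {
      resid_abs[i, , ] <- y[i, , ] - m_ia[i, ][row(m_ab)] -
        m_ib[i, ][col(m_ab)] - m_ab + m_i[i] +
        outer(m_a, rep(1, b)) + outer(rep(1, a), m_b) - grand
    }
    ss_abs <- sum(resid_abs^2)
    C_ab <- kronecker(Qb, Qa)
    add_effect(paste(factor_names, collapse = ":"), ss_ab,
               (a - 1) * (b - 1), ss_abs, (a - 1) * (b - 1) * (n - 1), C_ab)
  }
  do.call(rbind, effects)
}

#' Fixed-bandwidth Gaussian kernel density estimate
#'
#' Plain Gaussian-kernel density estimate with a user-fixed bandwidth
#' \eqn{\sigma}: \eqn{\hat f(g) = n^{-1} \sum_j \phi\{(g - x_j)/\sigma\} /
#' \sigma}. The reference display of the ratio-index distributions uses
#' \eqn{\sigma = 0.04} on the dimensionless index scale. The default grid
#' extends 8 bandwidths beyond the data range so that the trapezoidal
#' integral of the density is 1 to within 1e-3.
#'
#' @param values Numeric vector, length >= 1.
#' @param bandwidth Kernel standard deviation, same units as `values`, > 0.
#' @param grid Evaluation points; default `n_grid` equally spaced points
#'   spanning the data +/- 8 bandwidths.
#' @param n_grid Size of the default grid (default 512).
#' @return Object of class `kde_fixed`: list with `grid`, `density`,
#'   `bandwidth`.
#' @examples
#' k <- gaussian_kde(c(1.0, 1.1), bandwidth = 0.04)
#' @export
gaussian_kde <- function(values, bandwidth = 0.04, grid = NULL,
                         n_grid = 512) {
  check_vector(values, "values", min_len = 1L)
  check_scalar(bandwidth, "bandwidth", lower = 0, strict_lower = TRUE)
  if (is.null(grid)) {
    grid <- seq(min(values) - 8 * bandwidth, max(values) + 8 * bandwidth,
                length.out = n_grid)
  } else {
    check_vector(grid, "grid", min_len = 2L)
  }
  dens <- rowMeans(stats::dnorm(outer(grid, values, "-") / bandwidth)) /
    bandwidth
  structure(list(grid = grid, density = dens, bandwidth = bandwidth),
            class = "kde_fixed")
}
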