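# Independent oracles and small fixtures used across the suite.

# Brute-force two-way within-subject ANOVA by explicit loops over deviations;
# deliberately independent of rm_anova_gg's matrix algebra.
bf_rm_anova <- function(y) {
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  grand <- mean(y)
  m_i <- sapply(1:n, function(i) mean(y[i, , ]))
  m_a <- sapply(1:a, function(j) mean(y[, j, ]))
  m_b <- sapply(1:b, function(k) mean(y[, , k]))
  ss_a <- 0; ss_as <- 0; ss_b <- 0; ss_bs <- 0; ss_ab <- 0; ss_abs <- 0
  for (j in 1:a) ss_a <- ss_a + n * b * (m_a[j] - grand)^2
  for (k in 1:b) ss_b <- ss_b + n * a * (m_b[k] - grand)^2
  for (i in 1:n) for (j in 1:a) {
    ss_as <- ss_as + b * (mean(y[i, j, ]) - m_i[i] - m_a[j] + grand)^2
  }
  for (i in 1:n) for (k in 1:b) {
    ss_bs <- ss_bs + a * (mean(y[i, , k]) - m_i[i] - m_b[k] + grand)^2
  }
  for (j in 1:a) for (k in 1:b) {
    ss_ab <- ss_ab + n * (mean(y[, j, k]) - m_a[j] - m_b[k] + grand)^2
  }
  for (i in 1:n) for (j in 1:a) for (k in 1:b) {
    ss_abs <- ss_abs +
      (y[i, j, k] - mean(y[i, j, ]) - mean(y[i, , k]) - mean(y[, j, k]) +
         m_i[i] + m_a[j] + m_b[k] - grand)^2
  }
  c(A = (ss_a / (a - 1)) / (ss_as / ((a - 1) * (n - 1))),
    B = (ss_b / (b - 1)) / (ss_bs / ((b - 1) * (n - 1))),
    AB = (ss_ab / ((a - 1) * (b - 1))) /
      (ss_abs / ((a - 1) * (b - 1) * (n - 1))))
}

# Greenhouse-Geisser epsilon for a one-way layout via the eigenvalues of the
# double-centered covariance (an independent construction from the contrast
# route used in the package).
eps_eigen_oneway <- function(x) {
  k <- ncol(x)
  S <- cov(x)
  D <- diag(k) - 1 / k
  lam <- eigen(D %*% S %*% D, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-12]
  sum(lam)^2 / ((k - 1) * sum(lam^2))
}

# Fit every subject of a trial table, returning per-subject measures.
fit_cohort <- function(trials, ...) {
  ids <- unique(trials$subject_id)
  do.call(rbind, lapply(ids, function(id) {
    f <- fit_subject(trials[trials$subject_id == id, , drop = FALSE], ...)
    data.frame(subject_id = id, kappa_hat = f$kappa$kappa_hat,
               at_lower_bound = f$kappa$at_lower_bound,
               eta_P = f$eta$P$eta_hat, eta_N = f$eta$N$eta_hat,
               eta_E = f$eta$E$eta_hat,
               eta_pe = f$eta_pe, eta_ne = f$eta_ne,
               stringsAsFactors = FALSE)
  }))
}

# Aggregate ratio index per subject without any model fitting.
index_cohort <- function(trials, v = "P") {
  ids <- unique(trials$subject_id)
  vapply(ids, function(id) {
    aggregate_ratio(cell_means(trials[trials$subject_id == id, ,
                                      drop = FALSE]), v)
  }, numeric(1))
}

# Noiseless single-subject trial table on a fixed factorial design.
noiseless_trials <- function(kappa, eta = c(P = 1, N = 1, E = 1),
                             w = 2, reps = 5) {
  design <- expand.grid(valence = c("P", "N", "E"), s_sec = c(2, 4, 6),
                        rep = seq_len(reps), stringsAsFactors = FALSE)
  design$w_sec <- w
  design$r_sec <- vapply(seq_len(nrow(design)), function(i) {
    krf(design$s_sec[i], design$w_sec[i], kappa, eta[[design$valence[i]]])
  }, numeric(1))
  design$subject_id <- "S1"
  design
}
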