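# Per-subject parameter estimation: a three-step procedure.
#   1. kappa from all trials of a subject, formally assuming eta = 1;
#   2. eta per stimulus condition, holding kappa fixed;
#   3. net inflow ratios eta_PE = eta_P/eta_E, eta_NE = eta_N/eta_E.
# All fits are unweighted least squares on raw responses r; the objectives are
# smooth 1-D functions, minimised by a coarse grid scan followed by local
# refinement, so there is no local-minimum or starting-value risk.

# Minimise f over [lower, upper]: 200-point grid, then golden-section /
# parabolic refinement inside the bracketing grid interval.
minimise_1d <- function(f, lower, upper, n_grid = 200, tol = 1e-7) {
  grid <- seq(lower, upper, length.out = n_grid)
  vals <- vapply(grid, f, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, n_grid)]
  opt <- stats::optimize(f, c(lo, hi), tol = tol)
  if (opt$objective <= vals[i]) {
    list(minimum = opt$minimum, objective = opt$objective)
  } else {
    list(minimum = grid[i], objective = vals[i])
  }
}

#' Estimate the outflow rate kappa for one subject
#'
#' Step 1 of the DKM estimation: fit \eqn{\kappa} by unweighted least squares
#' of the observed responses on the klepsydraic reproduction function over the
#' subject's merged trial set, formally assuming an inflow ratio
#' \eqn{\eta = 1}. Since the model with \eqn{\eta = 1} predicts \eqn{r \le s},
#' subjects who systematically over-reproduce drive the minimiser to the
#' boundary \eqn{\kappa = 0} (a negative \eqn{\kappa} would be needed, which
#' is biophysically meaningless); the fit is then flagged via
#' `at_lower_bound`.
#'
#' @param trials Data frame with columns `s_sec`, `w_sec`, `r_sec` (one row
#'   per trial); at least 3 trials spanning at least 2 distinct durations.
#' @param kappa_max Upper search bound for kappa, 1/s (default 0.5).
#' @param n_grid Number of coarse grid points (default 200).
#' @return Object of class `kappa_fit`: list with `kappa_hat`, `sse`,
#'   `n_trials`, `at_lower_bound`.
#' @examples
#' tr <- data.frame(s_sec = rep(c(2, 4, 6), 4), w_sec = 2)
#' tr$r_sec <- krf(tr$s_sec, tr$w_sec, kappa = 0.05, eta = 1)
#' fit_kappa(tr)$kappa_hat # ~0.05
#' @export
fit_kappa <- function(trials, kappa_max = 0.5, n_grid = 200) {
  check_trials(trials, min_rows = 3L)
  check_scalar(kappa_max, "kappa_max", lower = 0, strict_lower = TRUE)
  s <- trials$s_sec
  w <- trials$w_sec
  r <- trials$r_sec
  check_vector(r, "trials$r_sec", lower = 0, strict_lower = TRUE)
  if (length(unique(s)) < 2L) {
    stop_domain("kappa is not identifiable from a single encoded duration")
  }
  sse <- function(k) sum((r - krf(s, w, k, 1))^2)
  opt <- minimise_1d(sse, 0, kappa_max, n_grid = n_grid)
  sse0 <- sse(0)
  if (sse0 <= opt$objective) {
    opt <- list(minimum = 0, objective = sse0)
  }
  structure(
    list(kappa_hat = opt$minimum, sse = opt$objective,
         n_trials = length(r), at_lower_bound = opt$minimum == 0),
    class = "kappa_fit"
  )
}

#' @export
print.kappa_fit <- function(x, ...) {
  cat(sprintf("kappa fit: kappa_hat = %.4f /s (SSE %.4f, %d trials%s)\n",
              x$kappa_hat, x$sse, x$n_trials,
              if (x$at_lower_bound) ", at lower bound 0" else ""))
  invisible(x)
}

#' Estimate the inflow ratio eta for one stimulus condition
#'
#' Step 2 of the DKM estimation: with the subject's \eqn{\kappa} from
#' [fit_kappa()] held fixed, fit the condition-specific inflow ratio
#' \eqn{\eta_v} to that condition's trials. The default method `"lsq"`
#' minimises the sum of squared response residuals over
#' \eqn{\eta \in (0, \eta_{max}]}; method `"invert-mean"` instead averages
#' the exact per-trial inversions [krf_inverse_eta()] (closed form, useful as
#' a diagnostic; the two differ under response noise).
#'
#' @param trials Data frame with columns `s_sec`, `w_sec`, `r_sec`; the trials
#'   of one condition (>= 1 row).
#' @param kappa Outflow rate from step 1, 1/s, >= 0.
#' @param method `"lsq"` (default) or `"invert-mean"`.
#' @param eta_max Upper search bound for the least-squares method.
#' @param n_grid Number of coarse grid points (default 200).
#' @return Object of class `eta_fit`: list with `eta_hat`, `sse`, `n_trials`,
#'   `method`.
#' @examples
#' tr <- data.frame(s_sec = c(2, 4, 6), w_sec = 2)
#' tr$r_sec <- krf(tr$s_sec, tr$w_sec, kappa = 0.03, eta = 1.08)
#' fit_eta(tr, kappa = 0.03)$eta_hat # ~1.08
#' @export
fit_eta <- function(trials, kappa, method = c("lsq", "invert-mean"),
                    eta_max = 10, n_grid = 200) {
  check_trials(trials, min_rows = 1L)
  check_scalar(kappa, "kappa", lower = 0)
  check_scalar(eta_max, "eta_max", lower = 0, strict_lower = TRUE)
  method <- match.arg(method)
  s <- trials$s_sec
  w <- trials$w_sec
  r <- trials$r_sec
  check_vector(r, "trials$r_sec", lower = 0, strict_lower = TRUE)
  sse <- function(e) sum((r - krf(s, w, kappa, e))^2)
  if (method == "lsq") {
    opt <- minimise_1d(sse, eta_max / n_grid, eta_max, n_grid = n_grid)
    eta_hat <- opt$minimum
    obj <- opt$objective
  } else {
    eta_hat <- mean(krf_inverse_eta(r, s, w, kappa))
    obj <- sse(eta_hat)
  }
  structure(
    list(eta_hat = eta_hat, sse = obj, n_trials = length(r), method = method),
    class = "eta_fit"
  )
}

#' Net inflow ratios relative to the neutral condition
#'
#' Step 3 of the DKM estimation: the per-condition inflow levels are only
#' identified up to a common factor, so the stimulus-induced effect is
#' expressed as the ratios \eqn{\eta_{PE} = \eta_P / \eta_E} and
#' \eqn{\eta_{NE} = \eta_N / \eta_E}. Under the null hypothesis of no valence
#' effect both ratios have expected value 1.
#'
#' @param eta A named list or numeric vector with elements `P`, `N`, `E`
#'   (each a positive number, or an `eta_fit` object).
#' @return List with `eta_pe` and `eta_ne`.
#' @examples
#' eta_ratios(c(P = 1.08, N = 1.04, E = 1))
#' @export
eta_ratios <- function(eta) {
  get1 <- function(v) {
    if (!v %in% names(eta)) {
      stop_domain("`eta` must contain an element named '%s'", v)
    }
    x <- eta[[v]]
    if (inherits(x, "eta_fit")) x <- x$eta_hat
    check_scalar(x, paste0("eta$", v), lower = 0, strict_lower = TRUE)
    x
  }
  list(eta_pe = get1("P") / get1("E"), eta_ne = get1("N") / get1("E"))
}

#' Full three-step DKM fit for one subject
#'
#' Convenience wrapper running [fit_kappa()] on the merged trials, then
#' [fit_eta()] separately for the valence conditions P, N and E, then
#' [eta_ratios()].
#'
#' @param trials Data frame with columns `valence` (codes `P`, `N`, `E`),
#'   `s_sec`, `w_sec`, `r_sec`; all trials of one subject.
#' @inheritParams fit_kappa
#' @inheritParams fit_eta
#' @return List with elements `kappa` (`kappa_fit`), `eta` (named list of
#'   `eta_fit`), `eta_pe`, `eta_ne`.
#' @export
fit_subject <- function(trials, kappa_max = 0.5, eta_max = 10,
                        method = c("lsq", "invert-mean"), n_grid = 200) {
  check_trials(trials, cols = c("valence", trial_fit_columns), min_rows = 3L)
  method <- match.arg(method)
  kfit <- fit_kappa(trials, kappa_max = kappa_max, n_grid = n_grid)
  efits <- lapply(stats::setNames(nm = c("P", "N", "E")), function(v) {
    sub <- trials[trials$valence == v, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop_domain("subject has no trials in condition '%s'", v)
    }
    fit_eta(sub, kappa = kfit$kappa_hat, method = method,
            eta_max = eta_max, n_grid = n_grid)
  })
  ratios <- eta_ratios(efits)
  list(kappa = kfit, eta = efits,
       eta_pe = ratios$eta_pe, eta_ne = ratios$eta_ne)
}

#' Screen subjects for exclusion
#'
#' Codifies the cohort-cleaning rules applied before group-level analysis of
#' the model-based measures:
#' \describe{
#'   \item{`over_reproducer_boundary`}{the kappa fit stopped at the lower
#'     bound \eqn{\kappa = 0}, the signature of systematic over-reproduction
#'     that the DKM (with \eqn{\eta = 1}) cannot accommodate;}
#'   \item{`non_responder`}{the least-squares slope of `r` on `s` falls below
#'     `slope_min`, i.e. the responses barely reflect the encoded duration;}
#'   \item{`kappa_outlier`}{among the remaining subjects, `kappa_hat` deviates
#'     from the cohort median by more than `k_mad` (scaled) median absolute
#'     deviations.}
#' }
#' Rules are applied in that order; a subject receives the first matching
#' reason.
#'
#' @param fits Data frame with one row per subject and columns `subject_id`,
#'   `kappa_hat`, `at_lower_bound` (e.g. assembled from [fit_kappa()] calls).
#' @param trials Trial table covering the same subjects (columns `subject_id`,
#'   `s_sec`, `r_sec`), used for the response slope.
#' @param slope_min Minimum slope of r on s for a responder (default 0.15).
#' @param k_mad Outlier threshold in scaled MADs (default 5).
#' @return Data frame with columns `subject_id`, `kappa_hat`, `slope`,
#'   `excluded`, `reason` (one of `none`, `over_reproducer_boundary`,
#'   `non_responder`, `kappa_outlier`).
#' @export
screen_subjects <- function(fits, trials, slope_min = 0.15, k_mad = 5) {
  if (!is.data.frame(fits) ||
      !all(c("subject_id", "kappa_hat", "at_lower_bound") %in% names(fits))) {
    stop_domain(paste("`fits` must be a data.frame with columns subject_id,",
                      "kappa_hat, at_lower_bound"))
  }
  check_trials(trials, cols = c("subject_id", "s_sec", "r_sec"))
  slope <- vapply(fits$subject_id, function(id) {
    sub <- trials[trials$subject_id == id, , drop = FALSE]
    if (nrow(sub) < 2L || stats::var(sub$s_sec) == 0) {
      return(NA_real_)
    }
    stats::cov(sub$s_sec, sub$r_sec) / stats::var(sub$s_sec)
  }, numeric(1))
  reason <- rep("none", nrow(fits))
  reason[!is.na(slope) & slope < slope_min] <- "non_responder"
  reason[fits$at_lower_bound] <- "over_reproducer_boundary"
  ok <- reason == "none"
  if (sum(ok) >= 3L) {
    med <- stats::median(fits$kappa_hat[ok])
    madv <- stats::mad(fits$kappa_hat[ok])
    if (madv > 0) {
      out <- ok & abs(fits$kappa_hat - med) > k_mad * madv
      reason[out] <- "kappa_outlier"
    }
  }
  data.frame(
    subject_id = fits$subject_id,
    kappa_hat = fits$kappa_hat,
    slope = slope,
    excluded = reason != "none",
    reason = reason,
    stringsAsFactors = FALSE
  )
}
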