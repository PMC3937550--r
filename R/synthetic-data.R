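# Seeded synthetic cohorts with the reference study design: 31 subjects,
# 45 trials each, 3 valences (P, N, E) x 3 encoded durations (2, 4, 6 s) x
# 5 stimuli per cell, inter-stimulus pauses drawn from {1.5, 2, 3} s.
# Responses follow the DKM forward model with multiplicative lognormal noise.

#' Stimulus metadata table
#'
#' The packaged affective-sound stimulus set: 45 IADS reference numbers in
#' three valence groups (P, N, E) of three five-sound subgroups (a, b, c)
#' each, with subgroup mean pleasantness and arousal ratings. Used for
#' labelling simulated trials; no audio is involved.
#'
#' @return Data frame with columns `iads_id`, `group`, `subgroup`,
#'   `pleasantness_mean`, `arousal_mean` (45 rows).
#' @export
stimulus_table <- function() {
  utils::read.csv(system.file("extdata", "iads_stimulus_groups.csv",
                              package = "klepsydra"),
                  stringsAsFactors = FALSE,
                  colClasses = c(iads_id = "character"))
}

#' Published grand means of reproduced durations
#'
#' Grand means and standard deviations of the reproduced duration by valence
#' and encoded duration for the 31-subject reference study this package's
#' synthetic design emulates. Rows with `valence == "ALL"` pool the three
#' valences. These printed summary statistics serve as arithmetic reference
#' inputs (e.g. for the pseudo-subject ratio index and the progressive
#' shortening percentages); subject-level raw data are not available.
#'
#' @return Data frame with columns `valence`, `s_sec`, `mean_r_sec`,
#'   `sd_r_sec`.
#' @export
reference_grand_means <- function() {
  utils::read.csv(system.file("extdata", "reference_grand_means.csv",
                              package = "klepsydra"),
                  stringsAsFactors = FALSE)
}

run_seeded <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(seed, code)
  }
}

#' Generate one subject's trial schedule
#'
#' Builds the factorial design of a session: for each valence, the three
#' stimulus subgroups (a, b, c) are randomly assigned to the three encoded
#' durations (counterbalancing is randomised per subject), every stimulus is
#' used exactly once, each trial's inter-stimulus pause is drawn uniformly
#' from `pause_choices`, and the 45 trials are presented in random order.
#'
#' @param seed Integer seed for reproducibility, or `NULL` to use the current
#'   RNG stream.
#' @param durations Encoded durations, seconds (default `c(2, 4, 6)`).
#' @param trials_per_cell Trials per valence x duration cell (default 5).
#' @param valences Valence codes (default `c("P", "N", "E")`).
#' @param pause_choices Possible pauses, seconds (default `c(1.5, 2, 3)`).
#' @return Data frame with columns `trial_index`, `valence`, `stimulus_id`,
#'   `s_sec`, `w_sec`; `length(durations) * length(valences) *
#'   trials_per_cell` rows.
#' @export
make_design <- function(seed = NULL, durations = c(2, 4, 6),
                        trials_per_cell = 5, valences = c("P", "N", "E"),
                        pause_choices = c(1.5, 2, 3)) {
  check_vector(durations, "durations", lower = 0, strict_lower = TRUE,
               min_len = 2L)
  check_vector(pause_choices, "pause_choices", lower = 0)
  check_scalar(trials_per_cell, "trials_per_cell", lower = 1)
  run_seeded(seed, {
    use_iads <- trials_per_cell == 5 && length(durations) == 3 &&
      identical(sort(valences), sort(c("P", "N", "E")))
    stim <- if (use_iads) stimulus_table() else NULL
    per_v <- trials_per_cell * length(durations)
    val <- rep(valences, each = per_v)
    s <- rep(rep(durations, each = trials_per_cell), length(valences))
    ids <- character(length(val))
    for (v in valences) {
      idx <- val == v
      ids[idx] <- if (use_iads) {
        sub_order <- sample(c("a", "b", "c"))
        unlist(lapply(seq_along(durations), function(i) {
          stim$iads_id[stim$group == v & stim$subgroup == sub_order[i]]
        }))
      } else {
        sprintf("%s_s%g_%02d", v,
                rep(durations, each = trials_per_cell),
                rep(seq_len(trials_per_cell), length(durations)))
      }
    }
    w <- sample(pause_choices, length(val), replace = TRUE)
    ord <- sample(length(val))
    data.frame(
      trial_index = seq_along(val),
      valence = val[ord],
      stimulus_id = ids[ord],
      s_sec = s[ord],
      w_sec = w[ord],
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate one subject's responses
#'
#' Forward model for a single subject: each trial's reproduced duration is
#' the DKM prediction [krf()] for the subject's outflow rate and the trial
#' condition's inflow ratio, perturbed by multiplicative lognormal response
#' noise, \eqn{r_t = f(s_t, w_t; \kappa, \eta_{v(t)}) e^{\epsilon_t}},
#' \eqn{\epsilon_t \sim N(0, \sigma_{log}^2)}. Responses are therefore
#' always positive and their spread grows with duration (scalar-timing-like
#' variability).
#'
#' @param kappa Subject outflow rate, 1/s, >= 0.
#' @param eta Named numeric vector of inflow levels per valence, e.g.
#'   `c(P = 1.08, N = 1.04, E = 1)`; all > 0.
#' @param sigma_log Standard deviation of the log response noise, >= 0
#'   (default 0.10).
#' @param design Trial schedule from [make_design()] (default: a fresh one
#'   drawn from the current RNG stream).
#' @param subject_id Subject label (default `"S01"`).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Trial data frame with columns `subject_id`, `trial_index`,
#'   `valence`, `stimulus_id`, `s_sec`, `w_sec`, `r_sec`.
#' @export
simulate_subject <- function(kappa, eta, sigma_log = 0.10, design = NULL,
                             subject_id = "S01", seed = NULL) {
  check_scalar(kappa, "kappa", lower = 0)
  check_scalar(sigma_log, "sigma_log", lower = 0)
  run_seeded(seed, {
    if (is.null(design)) {
      design <- make_design()
    }
    if (!all(design$valence %in% names(eta))) {
      stop_domain("`eta` must be named with all valence codes in the design")
    }
    mu <- numeric(nrow(design))
    for (v in unique(design$valence)) {
      idx <- design$valence == v
      mu[idx] <- krf(design$s_sec[idx], design$w_sec[idx], kappa, eta[[v]])
    }
    r <- mu * exp(stats::rnorm(nrow(design), 0, sigma_log))
    data.frame(subject_id = subject_id, design, r_sec = r,
               stringsAsFactors = FALSE)
  })
}

#' Specification of a synthetic cohort
#'
#' Bundles the generative parameters of a cohort: sample size, the population
#' distribution of the outflow rate kappa (lognormal around a median of
#' 0.03 1/s with geometric SD 2, clipped to the empirically observed range
#' 0.003--0.096 1/s), the true condition inflow ratios (defaults 1.08 for
#' positive and 1.04 for negative valence, neutral fixed at 1), the response
#' noise, and counts of injected anomalous subjects (over-reproducers, whose
#' responses follow \eqn{r = (1+\gamma) s e^\epsilon}, and non-responders,
#' whose responses sit near a constant \eqn{c e^\epsilon} regardless of `s`).
#'
#' @param n_subjects Number of subjects (default 31).
#' @param kappa_median Population median of kappa, 1/s (default 0.03).
#' @param kappa_gsd Geometric standard deviation of kappa (default 2).
#' @param kappa_clip Clipping bounds for kappa, 1/s (default
#'   `c(0.003, 0.096)`).
#' @param eta_pe_true,eta_ne_true True inflow ratios P/E and N/E
#'   (defaults 1.08 and 1.04).
#' @param sigma_log Response noise on the log scale (default 0.10).
#' @param n_over_reproducers,n_non_responders Counts of injected anomalies
#'   (defaults 0).
#' @param over_gamma Over-reproduction factor gamma (default 0.2).
#' @param non_responder_c Constant response level c, seconds (default 3).
#' @param seed Integer seed (default 1).
#' @return Object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_subjects = 31, kappa_median = 0.03, kappa_gsd = 2,
                        kappa_clip = c(0.003, 0.096), eta_pe_true = 1.08,
                        eta_ne_true = 1.04, sigma_log = 0.10,
                        n_over_reproducers = 0, n_non_responders = 0,
                        over_gamma = 0.2, non_responder_c = 3.0, seed = 1) {
  check_scalar(n_subjects, "n_subjects", lower = 1)
  check_scalar(kappa_median, "kappa_median", lower = 0, strict_lower = TRUE)
  check_scalar(kappa_gsd, "kappa_gsd", lower = 1)
  check_vector(kappa_clip, "kappa_clip", lower = 0, min_len = 2L)
  if (kappa_clip[1] > kappa_clip[2] || kappa_clip[2] > 0.5) {
    stop_domain("`kappa_clip` must be increasing and within [0, 0.5]")
  }
  check_scalar(eta_pe_true, "eta_pe_true", lower = 0, strict_lower = TRUE)
  check_scalar(eta_ne_true, "eta_ne_true", lower = 0, strict_lower = TRUE)
  check_scalar(sigma_log, "sigma_log", lower = 0)
  check_scalar(n_over_reproducers, "n_over_reproducers", lower = 0)
  check_scalar(n_non_responders, "n_non_responders", lower = 0)
  if (n_over_reproducers + n_non_responders > n_subjects) {
    stop_domain("more anomalous subjects than subjects")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), kappa_median = kappa_median,
         kappa_gsd = kappa_gsd, kappa_clip = kappa_clip,
         eta_pe_true = eta_pe_true, eta_ne_true = eta_ne_true,
         sigma_log = sigma_log,
         n_over_reproducers = as.integer(n_over_reproducers),
         n_non_responders = as.integer(n_non_responders),
         over_gamma = over_gamma, non_responder_c = non_responder_c,
         seed = seed),
    class = "cohort_spec"
  )
}

#' Simulate a synthetic cohort
#'
#' Draws per-subject parameters from a [cohort_spec()], simulates every
#' subject's session with [simulate_subject()], injects the specified
#' anomalies, and returns both the trial table and the ground-truth parameter
#' table needed for recovery tests. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return List with `trials` (all subjects' trial rows, canonical schema)
#'   and `truth` (data frame `subject_id`, `type`, `kappa_true`, `eta_P`,
#'   `eta_N`, `eta_E`).
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_subjects = 4, seed = 7))
#' table(coh$trials$subject_id)
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop_domain("`spec` must be a cohort_spec object")
  }
  run_seeded(spec$seed, {
    n <- spec$n_subjects
    ids <- sprintf("S%03d", seq_len(n))
    kappa <- exp(stats::rnorm(n, log(spec$kappa_median), log(spec$kappa_gsd)))
    kappa <- pmin(pmax(kappa, spec$kappa_clip[1]), spec$kappa_clip[2])
    type <- rep("normal", n)
    n_anom <- spec$n_over_reproducers + spec$n_non_responders
    if (n_anom > 0) {
      anom <- sample(n, n_anom)
      type[anom[seq_len(spec$n_over_reproducers)]] <- "over_reproducer"
      if (spec$n_non_responders > 0) {
        type[anom[spec$n_over_reproducers + seq_len(spec$n_non_responders)]] <-
          "non_responder"
      }
    }
    eta <- c(P = spec$eta_pe_true, N = spec$eta_ne_true, E = 1)
    trials <- vector("list", n)
    for (i in seq_len(n)) {
      design <- make_design()
      tr <- switch(
        type[i],
        normal = simulate_subject(kappa[i], eta, spec$sigma_log,
                                  design = design, subject_id = ids[i]),
        over_reproducer = {
          mu <- (1 + spec$over_gamma) * design$s_sec
          r <- mu * exp(stats::rnorm(nrow(design), 0, spec$sigma_log))
          data.frame(subject_id = ids[i], design, r_sec = r,
                     stringsAsFactors = FALSE)
        },
        non_responder = {
          r <- spec$non_responder_c *
            exp(stats::rnorm(nrow(design), 0, spec$sigma_log))
          data.frame(subject_id = ids[i], design, r_sec = r,
                     stringsAsFactors = FALSE)
        }
      )
      trials[[i]] <- tr
    }
    list(
      trials = do.call(rbind, trials),
      truth = data.frame(
        subject_id = ids, type = type, kappa_true = kappa,
        eta_P = ifelse(type == "normal", eta[["P"]], NA_real_),
        eta_N = ifelse(type == "normal", eta[["N"]], NA_real_),
        eta_E = ifelse(type == "normal", 1, NA_real_),
        stringsAsFactors = FALSE
      )
    )
  })
}
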