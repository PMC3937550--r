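# Three-step per-subject estimation and the subject screening rules.

test_that("fit_kappa recovers kappa from noiseless trials", {
  tr <- withr::with_seed(11, {
    d <- make_design()
    simulate_subject(0.05, c(P = 1, N = 1, E = 1), sigma_log = 0,
                     design = d)
  })
  fit <- fit_kappa(tr)
  expect_s3_class(fit, "kappa_fit")
  expect_equal(fit$kappa_hat, 0.05, tolerance = 1e-3)
  expect_false(fit$at_lower_bound)
  expect_lt(fit$sse, 1e-10)
  expect_equal(fit$n_trials, 45L)
})

test_that("veridical and over-reproducing data stop at the kappa = 0 bound", {
  tr <- noiseless_trials(kappa = 0)        # r = s exactly
  fit <- fit_kappa(tr)
  expect_equal(fit$kappa_hat, 0)
  expect_true(fit$at_lower_bound)
  expect_equal(fit$sse, 0)
  tr$r_sec <- 1.1 * tr$s_sec               # systematic over-reproduction
  fit <- fit_kappa(tr)
  expect_true(fit$at_lower_bound)
  expect_equal(fit$kappa_hat, 0)
})

test_that("fit_kappa validates its preconditions", {
  tr <- noiseless_trials(0.03)
  expect_error(fit_kappa(tr[1:2, ]), "at least 3")
  one_s <- tr[tr$s_sec == 4, ]
  expect_error(fit_kappa(one_s), "identifiable")
  tr_bad <- tr; tr_bad$r_sec[1] <- -1
  expect_error(fit_kappa(tr_bad), "r_sec")
})

test_that("fit_eta recovers the inflow ratio, by both methods", {
  tr <- noiseless_trials(0.03, eta = c(P = 1.08, N = 1.08, E = 1.08))
  fit <- fit_eta(tr, kappa = 0.03)
  expect_equal(fit$eta_hat, 1.08, tolerance = 1e-4)
  expect_lt(fit$sse, 1e-10)
  fit_im <- fit_eta(tr, kappa = 0.03, method = "invert-mean")
  expect_equal(fit_im$eta_hat, 1.08, tolerance = 1e-6)
  # single-trial least squares equals the closed-form inversion
  one <- data.frame(s_sec = 6, w_sec = 2, r_sec = 5.163516)
  expect_equal(fit_eta(one, 0.03)$eta_hat, 1.08, tolerance = 1e-4)
  expect_equal(fit_eta(one, 0.03, method = "invert-mean")$eta_hat,
               krf_inverse_eta(5.163516, 6, 2, 0.03))
  expect_error(fit_eta(tr[0, ], 0.03), "at least 1")
})

test_that("step 2 with the true kappa is exact for any common inflow scale", {
  for (cc in c(0.5, 1, 2)) {
    eta_true <- cc * c(P = 1.08, N = 1.04, E = 1)
    tr <- noiseless_trials(0.03, eta = eta_true)
    est <- sapply(c("P", "N", "E"), function(v) {
      fit_eta(tr[tr$valence == v, ], kappa = 0.03)$eta_hat
    })
    expect_equal(unname(est), unname(eta_true), tolerance = 1e-6)
    ratios <- eta_ratios(as.list(est))
    expect_equal(ratios$eta_pe, 1.08, tolerance = 1e-6)
    expect_equal(ratios$eta_ne, 1.04, tolerance = 1e-6)
  }
})

test_that("full three-step pipeline is exact on noiseless null cohorts", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 8, sigma_log = 0,
                                     eta_pe_true = 1, eta_ne_true = 1,
                                     seed = 21))
  fits <- fit_cohort(coh$trials)
  err_k <- abs(fits$kappa_hat -
                 coh$truth$kappa_true[match(fits$subject_id,
                                            coh$truth$subject_id)])
  expect_lt(max(err_k), 1e-3)
  expect_lt(max(abs(fits$eta_pe - 1)), 1e-3)
  expect_lt(max(abs(fits$eta_ne - 1)), 1e-3)
  expect_lt(max(abs(c(fits$eta_P, fits$eta_N, fits$eta_E) - 1)), 1e-3)
})

test_that("eta_ratios is scale-invariant and validates its input", {
  expect_equal(eta_ratios(c(P = 1.08, N = 1.04, E = 1)),
               list(eta_pe = 1.08, eta_ne = 1.04))
  expect_equal(eta_ratios(c(P = 2.16, N = 2.08, E = 2)),
               list(eta_pe = 1.08, eta_ne = 1.04))
  expect_equal(eta_ratios(c(P = 1, N = 1, E = 1)),
               list(eta_pe = 1, eta_ne = 1))
  expect_error(eta_ratios(c(P = 1.08, N = 1.04)), "E")
  expect_error(eta_ratios(c(P = 1.08, N = 1.04, E = 0)), "eta")
})

test_that("the least-squares optimum beats every grid point", {
  tr <- withr::with_seed(31, simulate_subject(0.03, c(P = 1.08, N = 1.04,
                                                      E = 1),
                                              sigma_log = 0.1))
  fit <- fit_kappa(tr)
  sse <- function(k) sum((tr$r_sec - krf(tr$s_sec, tr$w_sec, k, 1))^2)
  grid <- seq(0, 0.5, length.out = 200)
  expect_lte(fit$sse, min(vapply(grid, sse, numeric(1))) + 1e-12)
  efit <- fit_eta(tr[tr$valence == "P", ], fit$kappa_hat)
  sse_e <- function(e) {
    sub <- tr[tr$valence == "P", ]
    sum((sub$r_sec - krf(sub$s_sec, sub$w_sec, fit$kappa_hat, e))^2)
  }
  grid_e <- seq(0.05, 10, length.out = 200)
  expect_lte(efit$sse, min(vapply(grid_e, sse_e, numeric(1))) + 1e-12)
})

test_that("screening excludes exactly the injected anomalies (seed 1)", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 31,
                                     n_over_reproducers = 4,
                                     n_non_responders = 1, seed = 1))
  fits <- fit_cohort(coh$trials)
  scr <- screen_subjects(fits, coh$trials)
  expect_equal(sum(scr$excluded), 5L)
  expect_equal(sum(!scr$excluded), 26L)
  truth <- coh$truth[match(scr$subject_id, coh$truth$subject_id), ]
  expect_true(all(scr$excluded[truth$type != "normal"]))
  expect_setequal(scr$reason[truth$type == "over_reproducer"],
                  "over_reproducer_boundary")
  expect_equal(scr$reason[truth$type == "non_responder"], "non_responder")
})

test_that("screening rules produce no false positives on clean fits", {
  # rule-level check: interior kappas, steep slopes -> nothing flagged
  fits <- data.frame(subject_id = sprintf("S%02d", 1:20),
                     kappa_hat = seq(0.01, 0.09, length.out = 20),
                     at_lower_bound = FALSE, stringsAsFactors = FALSE)
  trials <- do.call(rbind, lapply(fits$subject_id, function(id) {
    data.frame(subject_id = id, s_sec = rep(c(2, 4, 6), 5), w_sec = 2,
               r_sec = rep(c(1.9, 3.6, 5.1), 5), stringsAsFactors = FALSE)
  }))
  scr <- screen_subjects(fits, trials)
  expect_false(any(scr$excluded))
  # a flat responder and a wild kappa are both caught
  trials$r_sec[trials$subject_id == "S01"] <- 3.0
  fits$kappa_hat[2] <- 0.45
  scr <- screen_subjects(fits, trials)
  expect_equal(scr$reason[1], "non_responder")
  expect_equal(scr$reason[2], "kappa_outlier")
  expect_equal(sum(scr$excluded), 2L)
  # boundary rule has precedence
  fits$at_lower_bound[1] <- TRUE
  scr <- screen_subjects(fits, trials)
  expect_equal(scr$reason[1], "over_reproducer_boundary")
})
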