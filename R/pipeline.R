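# Orchestration: trial-table I/O with schema validation, the full analysis
# (per-subject fits -> screening -> indices -> group statistics), report
# serialisation, and the command-line front end.

trial_schema_columns <- c("subject_id", "trial_index", "valence",
                          "stimulus_id", "s_sec", "w_sec", "r_sec")

#' Validate a trial table against the canonical schema
#'
#' Checks column presence, numeric types, valence codes and value ranges
#' (`s_sec > 0`, `w_sec >= 0`, `r_sec > 0`, `trial_index >= 1`). Errors name
#' the offending rows.
#'
#' @param trials Data frame to validate.
#' @return The validated data frame, invisibly coerced to canonical column
#'   types.
#' @export
validate_trials <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L) {
    stop_domain("empty input: the trial table has no rows")
  }
  missing <- setdiff(trial_schema_columns, names(trials))
  if (length(missing) > 0L) {
    stop_domain("trial table is missing column(s): %s",
                paste(missing, collapse = ", "))
  }
  trials$subject_id <- as.character(trials$subject_id)
  trials$stimulus_id <- as.character(trials$stimulus_id)
  trials$valence <- as.character(trials$valence)
  bad_rows <- function(ok, what) {
    if (!all(ok)) {
      stop_domain("invalid %s in row(s): %s", what,
                  paste(utils::head(which(!ok), 5), collapse = ", "))
    }
  }
  num_ok <- function(x) is.numeric(x) & is.finite(x)
  bad_rows(num_ok(trials$s_sec) & trials$s_sec > 0, "s_sec (must be > 0)")
  bad_rows(num_ok(trials$w_sec) & trials$w_sec >= 0, "w_sec (must be >= 0)")
  bad_rows(num_ok(trials$r_sec) & trials$r_sec > 0, "r_sec (must be > 0)")
  bad_rows(num_ok(trials$trial_index) & trials$trial_index >= 1,
           "trial_index (must be >= 1)")
  bad_rows(trials$valence %in% c("P", "N", "E"),
           "valence code (must be P, N or E)")
  invisible(trials)
}

#' Read a trial table from CSV
#'
#' Reads the canonical comma-separated trial format (UTF-8, header required,
#' `.` decimal separator) and validates it with [validate_trials()].
#'
#' @param path Path to a CSV file with columns `subject_id`, `trial_index`,
#'   `valence`, `stimulus_id`, `s_sec`, `w_sec`, `r_sec`.
#' @param quiet Suppress the descriptive load message (default `TRUE`).
#' @return Validated trial data frame.
#' @export
load_trials <- function(path, quiet = TRUE) {
  if (!file.exists(path)) {
    stop_domain("input file does not exist: %s", path)
  }
  trials <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_domain("cannot parse %s: %s", path,
                                    conditionMessage(e))
  )
  trials <- validate_trials(trials)
  if (!quiet) {
    message(sprintf("loaded %d trials from %d subject(s)", nrow(trials),
                    length(unique(trials$subject_id))))
  }
  trials
}

#' Write a trial table to CSV
#'
#' @param trials Trial data frame (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' All tunable constants of the pipeline in one declarative object:
#' estimation bounds (`kappa_max`, `eta_max`, grid size), the inflow-ratio
#' method, screening thresholds (`slope_min`, `k_mad`), whether screening is
#' applied at all (`clean`), the KDE bandwidth on the ratio scale
#' (`kde_bandwidth`, default 0.04), and the null value for the one-sample
#' tests (`mu0 = 1`). A run's resolved configuration is embedded in its
#' report.
#'
#' @param kappa_max,eta_max,n_grid See [fit_kappa()] and [fit_eta()].
#' @param eta_method `"lsq"` or `"invert-mean"`.
#' @param slope_min,k_mad See [screen_subjects()].
#' @param clean Apply subject screening before model-based group statistics
#'   (default `TRUE`).
#' @param kde_bandwidth Gaussian kernel bandwidth for ratio distributions.
#' @param mu0 Null expectation for ratio indices and inflow ratios.
#' @param bonferroni Apply a Bonferroni factor to the post-hoc paired tests
#'   (default `FALSE`, mirroring the uncorrected reference analysis).
#' @return Object of class `dkm_config` (a named list).
#' @export
analysis_config <- function(kappa_max = 0.5, eta_max = 10, n_grid = 200,
                            eta_method = c("lsq", "invert-mean"),
                            slope_min = 0.15, k_mad = 5, clean = TRUE,
                            kde_bandwidth = 0.04, mu0 = 1,
                            bonferroni = FALSE) {
  structure(
    list(kappa_max = kappa_max, eta_max = eta_max, n_grid = n_grid,
         eta_method = match.arg(eta_method), slope_min = slope_min,
         k_mad = k_mad, clean = isTRUE(clean),
         kde_bandwidth = kde_bandwidth, mu0 = mu0,
         bonferroni = isTRUE(bonferroni)),
    class = "dkm_config"
  )
}

safe_test <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}

test_as_list <- function(t) {
  if (is.null(t)) return(NULL)
  list(statistic = t$statistic, df = t$df, p_value = t$p_value,
       method = t$method, estimate = t$estimate)
}

group_statistics <- function(subjects, trials, config, label) {
  out <- list(label = label, n_subjects = nrow(subjects))
  measures <- c("a_P", "a_N", "eta_pe", "eta_ne")
  out$means <- lapply(stats::setNames(nm = measures), function(m) {
    mean(subjects[[m]])
  })
  out$t_vs_null <- lapply(stats::setNames(nm = measures), function(m) {
    test_as_list(safe_test(one_sample_t(subjects[[m]], config$mu0)))
  })
  # RM-ANOVA on the 3x3 cell means, factors Valence and Duration.
  cms <- lapply(subjects$subject_id, function(id) {
    cell_means(trials[trials$subject_id == id, , drop = FALSE])$r_bar
  })
  y <- array(NA_real_, c(length(cms), 3, 3))
  for (i in seq_along(cms)) y[i, , ] <- cms[[i]]
  out$anova <- safe_test(rm_anova_gg(y, factor_names = c("valence",
                                                         "duration")))
  # Post-hoc paired t-tests between valences within each duration.
  pairs <- list(c("P", "E"), c("N", "E"), c("P", "N"))
  posthoc <- list()
  for (di in 1:3) {
    for (pr in pairs) {
      vx <- vapply(cms, function(m) m[pr[1], di], numeric(1))
      vy <- vapply(cms, function(m) m[pr[2], di], numeric(1))
      t <- safe_test(paired_t(vx, vy))
      if (!is.null(t) && config$bonferroni) {
        t$p_value <- min(1, t$p_value * length(pairs) * 3)
      }
      posthoc[[sprintf("s%d_%s_vs_%s", c(2, 4, 6)[di], pr[1], pr[2])]] <-
        test_as_list(t)
    }
  }
  out$posthoc <- posthoc
  corr_pairs <- list(c("a_N", "eta_ne"), c("a_P", "eta_pe"),
                     c("a_N", "a_P"), c("eta_ne", "eta_pe"))
  out$correlations <- lapply(
    stats::setNames(corr_pairs,
                    vapply(corr_pairs, paste, "", collapse = "_x_")),
    function(pr) {
      test_as_list(safe_test(pearson_r(subjects[[pr[1]]],
                                       subjects[[pr[2]]])))
    })
  out$kde <- lapply(stats::setNames(nm = measures), function(m) {
    k <- safe_test(gaussian_kde(subjects[[m]],
                                bandwidth = config$kde_bandwidth))
    if (is.null(k)) NULL else list(grid = k$grid, density = k$density,
                                   bandwidth = k$bandwidth)
  })
  out
}

#' Run the full analysis pipeline
#'
#' Executes, deterministically, the complete analysis on a validated trial
#' table: per-subject cell means and aggregate ratio indices; the three-step
#' DKM fit (kappa from all trials with \eqn{\eta = 1}, per-condition inflow
#' ratios, net ratios \eqn{\eta_{PE}}, \eqn{\eta_{NE}}); subject screening;
#' and group statistics (one-sample t-tests of each measure against 1,
#' repeated-measures ANOVA of the cell means with Greenhouse--Geisser
#' correction, post-hoc paired t-tests, Pearson correlations between the
#' model-free and model-based measures, and fixed-bandwidth KDE curves).
#' Group statistics are reported for both the full and the cleaned cohort,
#' since model-free indices are conventionally reported on the full sample
#' and inflow ratios on the cleaned one.
#'
#' @param trials Trial table (canonical schema; validated on entry).
#' @param config An [analysis_config()].
#' @return Object of class `dkm_report`: list with `subjects` (per-subject
#'   measures and exclusion status), `group` (sub-lists `full` and
#'   `cleaned`), `config`, and `versions`.
#' @export
run_analysis <- function(trials, config = analysis_config()) {
  trials <- validate_trials(trials)
  if (!inherits(config, "dkm_config")) {
    stop_domain("`config` must be an analysis_config() object")
  }
  ids <- unique(trials$subject_id)
  if (length(ids) < 2L) {
    stop_domain("at least 2 subjects are required for group statistics")
  }
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- trials[trials$subject_id == ids[i], , drop = FALSE]
    cm <- safe_test(cell_means(sub))
    a_P <- if (is.null(cm)) NA_real_ else
      safe_test(aggregate_ratio(cm, "P"))
    a_N <- if (is.null(cm)) NA_real_ else
      safe_test(aggregate_ratio(cm, "N"))
    fit <- fit_subject(sub, kappa_max = config$kappa_max,
                       eta_max = config$eta_max, method = config$eta_method,
                       n_grid = config$n_grid)
    rows[[i]] <- data.frame(
      subject_id = ids[i],
      n_trials = nrow(sub),
      kappa_hat = fit$kappa$kappa_hat,
      at_lower_bound = fit$kappa$at_lower_bound,
      kappa_sse = fit$kappa$sse,
      eta_P = fit$eta$P$eta_hat, eta_N = fit$eta$N$eta_hat,
      eta_E = fit$eta$E$eta_hat,
      eta_pe = fit$eta_pe, eta_ne = fit$eta_ne,
      a_P = if (is.null(a_P)) NA_real_ else a_P,
      a_N = if (is.null(a_N)) NA_real_ else a_N,
      stringsAsFactors = FALSE
    )
  }
  subjects <- do.call(rbind, rows)
  if (config$clean) {
    screening <- screen_subjects(subjects, trials,
                                 slope_min = config$slope_min,
                                 k_mad = config$k_mad)
  } else {
    screening <- data.frame(subject_id = subjects$subject_id,
                            kappa_hat = subjects$kappa_hat,
                            slope = NA_real_, excluded = FALSE,
                            reason = "none", stringsAsFactors = FALSE)
  }
  subjects$excluded <- screening$excluded[match(subjects$subject_id,
                                                screening$subject_id)]
  subjects$reason <- screening$reason[match(subjects$subject_id,
                                            screening$subject_id)]
  cleaned <- subjects[!subjects$excluded, , drop = FALSE]
  if (nrow(cleaned) == 0L) {
    stop_domain("all subjects were excluded by screening")
  }
  group <- list(
    full = group_statistics(subjects, trials, config, "full"),
    cleaned = group_statistics(cleaned, trials, config, "cleaned")
  )
  structure(
    list(subjects = subjects, group = group,
         config = unclass(config),
         versions = list(
           package = as.character(utils::packageVersion("klepsydra")),
           r = R.version.string
         )),
    class = "dkm_report"
  )
}

#' @export
print.dkm_report <- function(x, ...) {
  cat(render_report_text(x), sep = "\n")
  invisible(x)
}

#' Render a report as display-precision text
#'
#' Formats the headline numbers of a [run_analysis()] report the way they
#' are conventionally printed: means and ratios to 4 decimals, t and F
#' statistics to 3 decimals.
#'
#' @param report A `dkm_report`.
#' @return Character vector of lines.
#' @export
render_report_text <- function(report) {
  lines <- c(sprintf("DKM analysis report (%d subjects, %d excluded)",
                     nrow(report$subjects), sum(report$subjects$excluded)))
  for (coh in report$group) {
    lines <- c(lines, sprintf("-- %s cohort (n = %d)", coh$label,
                              coh$n_subjects))
    for (m in names(coh$means)) {
      t <- coh$t_vs_null[[m]]
      lines <- c(lines, sprintf(
        "   mean %s = %.4f%s", m, coh$means[[m]],
        if (is.null(t)) "" else sprintf(" (t = %.3f, df = %g, p = %.4g)",
                                        t$statistic, t$df, t$p_value)))
    }
    if (!is.null(coh$anova)) {
      for (k in seq_len(nrow(coh$anova))) {
        a <- coh$anova[k, ]
        lines <- c(lines, sprintf(
          "   ANOVA %s: F = %.3f, GG df = (%.2f, %.2f), p = %.4g",
          a$effect, a$F, a$df1_gg, a$df2_gg, a$p_gg))
      }
    }
    for (nm in names(coh$correlations)) {
      ct <- coh$correlations[[nm]]
      if (!is.null(ct)) {
        lines <- c(lines, sprintf("   r(%s) = %.3f (df = %g, p = %.4g)",
                                  sub("_x_", ", ", nm), ct$statistic, ct$df,
                                  ct$p_value))
      }
    }
  }
  lines
}

#' Write report files
#'
#' Serialises a report to `report.json` (machine-readable, full precision),
#' `subjects.csv` (per-subject measures), `kde_curves.csv` (plot data for
#' the ratio distributions) and `summary.txt` (display-precision rendering)
#' in `out_dir`. The JSON contains no timestamps, so identical inputs yield
#' byte-identical output.
#'
#' @param report A `dkm_report` from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!inherits(report, "dkm_report")) {
    stop_domain("`report` must be a dkm_report")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop_domain("cannot create output directory %s", out_dir)
  }
  paths <- c(json = file.path(out_dir, "report.json"),
             subjects = file.path(out_dir, "subjects.csv"),
             kde = file.path(out_dir, "kde_curves.csv"),
             summary = file.path(out_dir, "summary.txt"))
  jsonlite::write_json(unclass(report), paths[["json"]],
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  utils::write.csv(report$subjects, paths[["subjects"]], row.names = FALSE)
  kde_rows <- list()
  for (coh in report$group) {
    for (m in names(coh$kde)) {
      k <- coh$kde[[m]]
      if (!is.null(k)) {
        kde_rows[[length(kde_rows) + 1L]] <- data.frame(
          cohort = coh$label, measure = m, grid = k$grid,
          density = k$density, stringsAsFactors = FALSE)
      }
    }
  }
  utils::write.csv(
    if (length(kde_rows) > 0) do.call(rbind, kde_rows) else
      data.frame(cohort = character(), measure = character(),
                 grid = numeric(), density = numeric()),
    paths[["kde"]], row.names = FALSE)
  writeLines(render_report_text(report), paths[["summary"]])
  invisible(paths)
}

#' Command-line entry point
#'
#' Subcommand-style CLI mirroring the pipeline:
#' \describe{
#'   \item{`simulate`}{generate a synthetic cohort and write `trials.csv`
#'     and `truth.csv`;}
#'   \item{`fit`}{per-subject parameter fits to `subjects.csv`;}
#'   \item{`analyze`}{the full pipeline, writing all report files;}
#'   \item{`report`}{re-render an existing `report.json` as text.}
#' }
#' Run with no arguments for usage. Exits non-zero on validation failure
#' when run non-interactively.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Invisibly, the main result object of the subcommand (`NULL` for
#'   usage).
#' @export
dkm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dkm <simulate|fit|analyze|report> [options]",
    "  simulate --out DIR [--n-subjects N] [--seed S] [--eta-pe X]",
    "           [--eta-ne X] [--sigma-log X] [--over-reproducers N]",
    "           [--non-responders N]",
    "  fit      --input trials.csv --out DIR [--eta-method lsq|invert-mean]",
    "  analyze  --input trials.csv --out DIR [--config config.json]",
    "           [--no-clean] [--eta-method lsq|invert-mean]",
    "  report   --input report.json",
    sep = "\n")
  fail <- function(msg) {
    if (interactive()) {
      stop(msg, call. = FALSE)
    }
    message(msg)
    quit(status = 1L, save = "no")
  }
  if (length(args) < 1L) {
    message(usage)
    return(invisible(NULL))
  }
  cmd <- args[[1]]
  rest <- args[-1]
  opts <- list(
    optparse::make_option("--input", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--n-subjects", type = "integer", default = 31L,
                          dest = "n_subjects"),
    optparse::make_option("--eta-pe", type = "double", default = 1.08,
                          dest = "eta_pe"),
    optparse::make_option("--eta-ne", type = "double", default = 1.04,
                          dest = "eta_ne"),
    optparse::make_option("--sigma-log", type = "double", default = 0.10,
                          dest = "sigma_log"),
    optparse::make_option("--over-reproducers", type = "integer",
                          default = 0L, dest = "over_reproducers"),
    optparse::make_option("--non-responders", type = "integer",
                          default = 0L, dest = "non_responders"),
    optparse::make_option("--no-clean", action = "store_true",
                          default = FALSE, dest = "no_clean"),
    optparse::make_option("--eta-method", type = "character",
                          default = "lsq", dest = "eta_method")
  )
  o <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = opts),
                         args = rest),
    error = function(e) NULL
  )
  if (is.null(o)) {
    return(fail(usage))
  }
  result <- tryCatch(switch(
    cmd,
    simulate = {
      if (is.null(o$out)) stop("simulate requires --out", call. = FALSE)
      coh <- simulate_cohort(cohort_spec(
        n_subjects = o$n_subjects, eta_pe_true = o$eta_pe,
        eta_ne_true = o$eta_ne, sigma_log = o$sigma_log,
        n_over_reproducers = o$over_reproducers,
        n_non_responders = o$non_responders, seed = o$seed))
      dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
      write_trials(coh$trials, file.path(o$out, "trials.csv"))
      utils::write.csv(coh$truth, file.path(o$out, "truth.csv"),
                       row.names = FALSE)
      message(sprintf("wrote %s and %s", file.path(o$out, "trials.csv"),
                      file.path(o$out, "truth.csv")))
      coh
    },
    fit = ,
    analyze = {
      if (is.null(o$input) || is.null(o$out)) {
        stop(sprintf("%s requires --input and --out", cmd), call. = FALSE)
      }
      cfg_args <- if (!is.null(o$config)) {
        jsonlite::read_json(o$config, simplifyVector = TRUE)
      } else {
        list()
      }
      cfg_args$eta_method <- o$eta_method
      if (o$no_clean) cfg_args$clean <- FALSE
      config <- do.call(analysis_config, cfg_args)
      report <- run_analysis(load_trials(o$input, quiet = FALSE), config)
      dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
      if (cmd == "fit") {
        utils::write.csv(report$subjects,
                         file.path(o$out, "subjects.csv"),
                         row.names = FALSE)
        message(sprintf("wrote %s", file.path(o$out, "subjects.csv")))
      } else {
        write_report(report, o$out)
        message(sprintf("wrote report files to %s", o$out))
      }
      report
    },
    report = {
      if (is.null(o$input)) stop("report requires --input", call. = FALSE)
      rep <- jsonlite::read_json(o$input, simplifyVector = TRUE)
      class(rep) <- "dkm_report"
      rep$group <- lapply(rep$group, function(g) g)
      cat(render_report_text(rep), sep = "\n")
      rep
    },
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
  ), error = function(e) {
    fail(conditionMessage(e))
  })
  invisible(result)
}
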