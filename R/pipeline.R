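#' Finite-population Cochran sample size
#'
#' `n = N z^2 p q / (N d^2 + z^2 p q)`, rounded up to an integer, with
#' `q = 1 - p`: the minimum sample for estimating a proportion `p` in a
#' population of size `N` at margin of error `d` and normal quantile `z`.
#'
#' @param N Population size (>= 1).
#' @param p Expected proportion in `(0, 1)` (default 0.5, the conservative
#'   choice).
#' @param z Standard-normal quantile (default 1.96 for 95% confidence).
#' @param d Margin of error (> 0).
#' @return Integer sample size.
#' @export
#' @examples
#' cochran_sample_size(N = 5199, p = 0.5, z = 1.96, d = 0.02) # 1643
cochran_sample_size <- function(N, p = 0.5, z = 1.96, d = 0.02) {
  check_scalar_number(N, "N", lower = 1)
  check_scalar_number(p, "p", lower = 0, upper = 1,
                      closed_lower = FALSE, closed_upper = FALSE)
  check_scalar_number(z, "z", lower = 0, closed_lower = FALSE)
  check_scalar_number(d, "d", lower = 0, closed_lower = FALSE)
  q <- 1 - p
  as.integer(ceiling(N * z^2 * p * q / (N * d^2 + z^2 * p * q)))
}

#' Inflate a sample size for expected participation
#'
#' @param n Minimum sample size.
#' @param participation_rate Expected participation in `(0, 1]`.
#' @return `ceiling(n / participation_rate)` as integer.
#' @export
#' @examples
#' inflate_for_participation(1643, 0.80) # 2054
inflate_for_participation <- function(n, participation_rate) {
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(participation_rate, "participation_rate",
                      lower = 0, upper = 1, closed_lower = FALSE)
  as.integer(ceiling(n / participation_rate))
}

#' Participation rate as a rounded percentage
#'
#' @param completed Number of completed responses.
#' @param invited Number invited/agreed.
#' @return Percentage rounded to the nearest integer.
#' @export
participation_rate <- function(completed, invited) {
  check_scalar_number(completed, "completed", lower = 0)
  check_scalar_number(invited, "invited", lower = 1)
  round(100 * completed / invited)
}

#' Descriptive frequency table of dichotomized constructs
#'
#' Per construct and level: count, percent of the cohort (one decimal) and,
#' when raw totals are supplied, the mean and SD of the raw totals within
#' the level. Missing levels are reported as their own row.
#'
#' @param profiles Tibble of `low`/`high` factor columns (one per
#'   construct), as from [dichotomize_constructs()].
#' @param raw_totals Optional tibble of matching raw-total columns, as from
#'   [construct_totals()].
#' @return Tibble: `construct`, `level`, `n`, `percent`, `mean`, `sd`.
#' @export
frequency_table <- function(profiles, raw_totals = NULL) {
  if (!nrow(profiles)) abort("`profiles` is empty")
  n_total <- nrow(profiles)
  purrr::map_dfr(names(profiles), function(cons) {
    lev <- as.character(profiles[[cons]])
    lev[is.na(lev)] <- "missing"
    present <- intersect(c(BN_STATES, "missing"), unique(lev))
    purrr::map_dfr(present, function(l) {
      idx <- lev == l
      row <- tibble::tibble(
        construct = cons, level = l, n = sum(idx),
        percent = round(100 * sum(idx) / n_total, 1)
      )
      if (!is.null(raw_totals) && cons %in% names(raw_totals) && l != "missing") {
        x <- raw_totals[[cons]][idx]
        row$mean <- mean(x, na.rm = TRUE)
        row$sd <- sd(x, na.rm = TRUE)
      } else {
        row$mean <- NA_real_
        row$sd <- NA_real_
      }
      row
    })
  })
}

# The six evidence scenarios of the standard sensitivity analysis.
sensitivity_scenarios <- function() {
  list(
    ptsd_low = c(PTSD = "low"),
    ptsd_high = c(PTSD = "high"),
    jobstress_low = c(JobStress = "low"),
    jobstress_high = c(JobStress = "high"),
    both_low = c(PTSD = "low", JobStress = "low"),
    both_high = c(PTSD = "high", JobStress = "high")
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole workflow on an item-level cohort: score the
#' instrument battery, dichotomize each construct at its cohort median, fit
#' the network CPTs by EM, run the six standard evidence-propagation
#' scenarios (PTSD low/high, job stress low/high, both low/both high), rank
#' all arcs by influence, and cross-validate the prediction of symptom
#' status. If no cohort is given, a default synthetic cohort is simulated.
#'
#' Note that a cohort-median split allocates roughly half the cohort to each
#' level by construction; supply fixed `thresholds` (e.g.
#' [generating_thresholds()] of a synthetic cohort) to dichotomize at known
#' cut points instead.
#'
#' @param cohort An `msd_cohort`, or a plain item-level data frame in the
#'   [score_cohort()] column layout, or `NULL` to simulate one from
#'   `config`.
#' @param config Ground-truth configuration used when `cohort` is `NULL`.
#' @param thresholds Optional named numeric of fixed cut points passed to
#'   [dichotomize_constructs()]; `NULL` (default) = cohort medians.
#' @param k Cross-validation folds.
#' @param cv_seed Seed for the fold shuffle.
#' @param threshold Classification threshold for the confusion matrix.
#' @param tol,max_iter EM settings.
#' @return Object of class `msd_analysis`: list with `totals`, `profiles`,
#'   `medians`, `frequency`, `fit`, `sensitivity` (named list of
#'   [evidence_delta_profile()] results), `influence`, `cv`, `roc`,
#'   `confusion`, `metrics`, `meta`.
#' @export
run_full_analysis <- function(cohort = NULL, config = default_ground_truth(),
                              thresholds = NULL, k = 10, cv_seed = 1,
                              threshold = 0.5, tol = 1e-4, max_iter = 200L) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  items <- if (inherits(cohort, "msd_cohort")) cohort$items else cohort
  if (!is.data.frame(items) || !nrow(items)) {
    abort("run_full_analysis(): empty or invalid cohort")
  }
  scores <- score_cohort(items)
  totals <- construct_totals(scores)
  profiles <- dichotomize_constructs(totals, thresholds = thresholds)
  medians <- attr(profiles, "thresholds")
  freq <- frequency_table(profiles, totals)

  dag <- firefighter_dag()
  fit <- fit_em(dag, profiles, tol = tol, max_iter = max_iter)
  sens <- lapply(sensitivity_scenarios(), function(ev) {
    evidence_delta_profile(fit$net, ev)
  })
  influence <- rank_arcs(fit$net)
  cv <- cross_validate_msd(dag, profiles, k = k, seed = cv_seed,
                           tol = tol, max_iter = max_iter)
  roc <- roc_and_auc(cv)
  cm <- confusion_at_threshold(cv, threshold)
  metrics <- dplyr::bind_cols(
    confusion_metrics(cm),
    tibble::tibble(auc = roc$auc, threshold = threshold, k = k)
  )
  structure(
    list(
      totals = totals, profiles = profiles, medians = medians,
      frequency = freq, fit = fit, sensitivity = sens,
      influence = influence, cv = cv, roc = roc, confusion = cm,
      metrics = metrics,
      meta = list(
        n = nrow(items), k = k, cv_seed = cv_seed, threshold = threshold,
        cohort_seed = if (inherits(cohort, "msd_cohort")) cohort$config$seed else NA,
        timestamp = format(Sys.time(), tz = "UTC"),
        package_version = as.character(utils::packageVersion("msdbayes"))
      )
    ),
    class = "msd_analysis"
  )
}

#' @export
print.msd_analysis <- function(x, ...) {
  cat(sprintf("<msd_analysis> n = %d respondents\n", x$meta$n))
  cat("\nPrior P(high) of the fitted network:\n")
  pri <- posterior(x$fit$net)
  for (nd in names(pri)) cat(sprintf("  %-24s %.3f\n", nd, pri[[nd]]))
  d_hi <- x$sensitivity$ptsd_high
  cat(sprintf(
    "\nPTSD=high evidence shifts P(MSD=high) by %+.0f%%; PTSD+JobStress=high by %+.0f%%\n",
    100 * d_hi$delta[d_hi$node == "MSD"],
    100 * x$sensitivity$both_high$delta[x$sensitivity$both_high$node == "MSD"]
  ))
  cat("\nTop arcs by average influence:\n")
  top <- head(x$influence, 3)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %s -> %s: %.3f (max %.3f)\n",
                top$parent[i], top$child[i], top$average[i], top$maximum[i]))
  }
  cat(sprintf(
    "\n%d-fold CV: AUC %.3f; sens %.3f, spec %.3f, acc %.3f at threshold %.2f\n",
    x$meta$k, x$metrics$auc, x$metrics$sensitivity, x$metrics$specificity,
    x$metrics$accuracy, x$meta$threshold
  ))
  invisible(x)
}

#' Analysis summary
#' @param x An `msd_analysis`.
#' @param ... Unused.
#' @return One-row tibble of headline metrics.
#' @method glance msd_analysis
#' @export
glance.msd_analysis <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n = x$meta$n), x$metrics)
}
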