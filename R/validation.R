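#' Seeded k-fold assignment
#'
#' Permutes row indices with a seeded uniform shuffle, then cuts the
#' permutation into `k` contiguous chunks whose sizes differ by at most one
#' (the first `n %% k` folds get the extra row).
#'
#' @param n Number of rows.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed.
#' @return List of class `fold_assignment`: `n`, `k`, `seed`,
#'   `fold_of_row` (integer vector in `1..k`).
#' @export
kfold_indices <- function(n, k, seed) {
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(k, "k", lower = 2, upper = n)
  n <- as.integer(n)
  k <- as.integer(k)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold_of_row <- integer(n)
  fold_of_row[perm] <- rep(seq_len(k), times = sizes)
  structure(list(n = n, k = k, seed = seed, fold_of_row = fold_of_row),
            class = "fold_assignment")
}

#' Cross-validated prediction of symptom status
#'
#' For each fold, fits the network by [fit_em()] on the remaining folds and
#' scores every held-out respondent with an observed `MSD` state as
#' `P(MSD = high | their observed non-MSD variables)` by exact inference
#' (missing covariates are marginalized). Rows with missing `MSD` still
#' contribute to training but are not scored. If a training fold never
#' observes some node state, the fit falls back to a small pseudo-count with
#' a warning.
#'
#' @param dag A [bn_dag()] containing an `MSD` node (or set `target`).
#' @param data Cohort table of `low`/`high`/`NA` profiles.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param target Name of the predicted node (default `"MSD"`).
#' @param tol,max_iter EM settings passed to [fit_em()].
#' @return A tibble of class `msd_cv` with columns `row_index`, `true_state`,
#'   `score` and attributes `k`, `seed`.
#' @export
cross_validate_msd <- function(dag, data, k = 10, seed = 1, target = "MSD",
                               tol = 1e-4, max_iter = 200L) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!(target %in% dag$nodes)) abort(sprintf("no '%s' node in the DAG", target))
  folds <- kfold_indices(nrow(data), k, seed)
  covars <- setdiff(dag$nodes, target)
  y01 <- as_state01(data[[target]], target)

  records <- purrr::map_dfr(seq_len(folds$k), function(f) {
    test_idx <- which(folds$fold_of_row == f)
    train <- data[-test_idx, , drop = FALSE]
    # a training split that never sees some node state needs smoothing
    seen_both <- vapply(dag$nodes, function(nd) {
      s <- as_state01(train[[nd]], nd)
      all(c(0L, 1L) %in% s[!is.na(s)])
    }, logical(1))
    pc <- 0
    if (!all(seen_both)) {
      warn(sprintf(
        "fold %d: training data lack a state of node(s) %s; using pseudo_count 0.5",
        f, paste(dag$nodes[!seen_both], collapse = ", ")
      ))
      pc <- 0.5
    }
    fit <- fit_em(dag, train, tol = tol, max_iter = max_iter, pseudo_count = pc)
    # a maximum-likelihood fit can contain structural zeros; if a held-out
    # covariate pattern has probability zero under it, rescore that pattern
    # with a lightly smoothed refit
    fit_smooth <- NULL
    scorable <- test_idx[!is.na(y01[test_idx])]
    if (!length(scorable)) return(NULL)
    # score per unique covariate pattern, not per row
    ev_mat <- vapply(covars, function(nd) as_state01(data[[nd]], nd),
                     integer(nrow(data)))[scorable, , drop = FALSE]
    key <- apply(ev_mat, 1L, paste, collapse = "|")
    first <- !duplicated(key)
    scores_by_pattern <- vapply(which(first), function(i) {
      obs <- ev_mat[i, ]
      obs <- obs[!is.na(obs)]
      ev <- setNames(BN_STATES[obs + 1L], names(obs))
      if (!length(ev)) {
        return(unname(posterior(fit$net, target)))
      }
      tryCatch(
        unname(posterior(fit$net, target, evidence = ev)),
        error = function(e) {
          if (!grepl("probability zero", conditionMessage(e))) stop(e)
          if (is.null(fit_smooth)) {
            warn(sprintf(
              "fold %d: a held-out pattern has probability zero under the fit; rescoring with pseudo_count 0.5",
              f
            ))
            fit_smooth <<- fit_em(dag, train, tol = tol, max_iter = max_iter,
                                  pseudo_count = 0.5)
          }
          unname(posterior(fit_smooth$net, target, evidence = ev))
        }
      )
    }, numeric(1))
    tibble::tibble(
      row_index = scorable,
      true_state = state_factor(y01[scorable]),
      score = scores_by_pattern[match(key, key[first])]
    )
  })
  records <- dplyr::arrange(records, .data$row_index)
  attr(records, "k") <- folds$k
  attr(records, "seed") <- seed
  class(records) <- c("msd_cv", class(records))
  records
}

#' Confusion matrix at a score threshold
#'
#' Predicts `high` when `score >= threshold` (closed on the high side) and
#' tallies against the true states; positive class = `high`.
#'
#' @param records Tibble with `true_state` and `score` columns, as from
#'   [cross_validate_msd()].
#' @param threshold Classification threshold in `[0, 1]` (default 0.5).
#' @return Object of class `bn_confusion`: list `tp`, `fp`, `tn`, `fn`,
#'   `threshold`.
#' @export
confusion_at_threshold <- function(records, threshold = 0.5) {
  if (!nrow(records)) abort("no prediction records to tally")
  check_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  truth <- as_state01(records$true_state, "true_state")
  pred <- as.integer(records$score >= threshold)
  structure(
    list(
      tp = sum(pred == 1L & truth == 1L),
      fp = sum(pred == 1L & truth == 0L),
      tn = sum(pred == 0L & truth == 0L),
      fn = sum(pred == 0L & truth == 1L),
      threshold = threshold
    ),
    class = "bn_confusion"
  )
}

#' Confusion matrix from explicit counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts (positive class = `high`).
#' @return Object of class `bn_confusion`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  for (v in c(tp, fp, tn, fn)) check_scalar_number(v, "count", lower = 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, threshold = NA_real_),
            class = "bn_confusion")
}

#' @export
print.bn_confusion <- function(x, ...) {
  cat("<bn_confusion> predicted state in columns, actual in rows\n")
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(actual = BN_STATES, predicted = BN_STATES))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`,
#' `accuracy = (tp+tn)/total`. Errors (rather than returning `NaN`) when a
#' class is absent.
#'
#' @param cm A `bn_confusion`.
#' @return One-row tibble: `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "bn_confusion"))
  if (cm$tp + cm$fn == 0) abort("no actual positives: sensitivity undefined")
  if (cm$tn + cm$fp == 0) abort("no actual negatives: specificity undefined")
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  tibble::tibble(
    sensitivity = cm$tp / (cm$tp + cm$fn),
    specificity = cm$tn / (cm$tn + cm$fp),
    accuracy = (cm$tp + cm$tn) / total
  )
}

#' @method tidy bn_confusion
#' @export
tidy.bn_confusion <- function(x, ...) {
  tibble::tibble(
    actual = rep(BN_STATES, each = 2L),
    predicted = rep(BN_STATES, 2L),
    n = c(x$tn, x$fp, x$fn, x$tp)
  )
}

#' @method glance bn_confusion
#' @export
glance.bn_confusion <- function(x, ...) {
  dplyr::bind_cols(confusion_metrics(x),
                   tibble::tibble(threshold = x$threshold))
}

#' ROC curve and AUC
#'
#' Sweeps the classification threshold over the distinct scores (ties
#' grouped, one step per distinct score), producing an ROC curve from (0, 0)
#' to (1, 1), and computes the area under it by the trapezoid rule. This
#' equals the rank-statistic (concordance) formulation with ties counted
#' one-half.
#'
#' @param records Tibble with `true_state` and `score`; both classes must be
#'   present.
#' @return Object of class `bn_roc`: list with `points` (tibble `fpr`,
#'   `tpr`, `threshold`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_and_auc <- function(records) {
  truth <- as_state01(records$true_state, "true_state")
  score <- records$score
  keep <- !is.na(truth) & !is.na(score)
  truth <- truth[keep]
  score <- score[keep]
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0 || n_neg == 0) abort("ROC needs both classes present")
  thr <- sort(unique(score), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(truth == 1L & score == t), numeric(1)))
  fp <- cumsum(vapply(thr, function(t) sum(truth == 0L & score == t), numeric(1)))
  points <- tibble::tibble(
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos),
    threshold = c(Inf, thr)
  )
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "bn_roc")
}

#' @export
print.bn_roc <- function(x, ...) {
  cat(sprintf(
    "<bn_roc> AUC %.3f (%d positives, %d negatives, %d threshold steps)\n",
    x$auc, x$n_pos, x$n_neg, nrow(x$points) - 1L
  ))
  invisible(x)
}

#' @method tidy bn_roc
#' @export
tidy.bn_roc <- function(x, ...) x$points

#' @method glance bn_roc
#' @export
glance.bn_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}
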