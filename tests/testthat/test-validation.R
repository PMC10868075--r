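test_that("fold assignment partitions rows into near-equal seeded folds", {
  fa <- kfold_indices(10, 10, seed = 1)
  expect_equal(unname(table(fa$fold_of_row)), rep(1L, 10), ignore_attr = TRUE)

  fa <- kfold_indices(2339, 10, seed = 1)
  sizes <- sort(as.integer(table(fa$fold_of_row)))
  expect_equal(sizes, c(233L, rep(234L, 9)))

  expect_identical(kfold_indices(57, 5, seed = 3)$fold_of_row,
                   kfold_indices(57, 5, seed = 3)$fold_of_row)
  expect_false(identical(kfold_indices(57, 5, seed = 3)$fold_of_row,
                         kfold_indices(57, 5, seed = 4)$fold_of_row))
  expect_error(kfold_indices(5, 6, seed = 1), "k")
})

test_that("confusion tallies follow the closed-on-high threshold rule", {
  recs <- tibble::tibble(
    true_state = factor(c("high", "high", "low", "low"), c("low", "high")),
    score = c(0.9, 0.4, 0.6, 0.2)
  )
  cm <- confusion_at_threshold(recs, 0.5)
  expect_equal(cm[c("tp", "fn", "fp", "tn")], list(tp = 1L, fn = 1L, fp = 1L, tn = 1L))

  # threshold 0: everything predicted high
  cm0 <- confusion_at_threshold(recs, 0)
  expect_equal(cm0$fn + cm0$tn, 0L)

  perfect <- tibble::tibble(
    true_state = factor(rep("high", 3), c("low", "high")),
    score = rep(1, 3)
  )
  cmp <- confusion_at_threshold(perfect, 0.5)
  expect_equal(cmp$tp, 3L)
  expect_equal(cmp$fp + cmp$tn + cmp$fn, 0L)

  # score exactly at the threshold is predicted high
  edge <- tibble::tibble(true_state = factor("low", c("low", "high")), score = 0.5)
  expect_equal(confusion_at_threshold(edge, 0.5)$fp, 1L)

  expect_error(confusion_at_threshold(recs[0, ], 0.5), "records")
})

test_that("raising the threshold never increases tp or fp", {
  set.seed(41)
  recs <- tibble::tibble(
    true_state = factor(sample(c("low", "high"), 200, TRUE), c("low", "high")),
    score = runif(200)
  )
  grid <- seq(0, 1, by = 0.05)
  cms <- lapply(grid, function(t) confusion_at_threshold(recs, t))
  tps <- vapply(cms, `[[`, numeric(1), "tp")
  fps <- vapply(cms, `[[`, numeric(1), "fp")
  expect_true(all(diff(tps) <= 0))
  expect_true(all(diff(fps) <= 0))
})

test_that("confusion metrics match direct arithmetic and guard degenerate input", {
  m <- confusion_metrics(confusion_matrix(tp = 1051, fp = 470, tn = 684, fn = 134))
  expect_equal(round(m$sensitivity, 3), 0.887)
  expect_equal(round(m$specificity, 3), 0.593)
  expect_equal(round(m$accuracy, 3), 0.742)

  perfect <- confusion_metrics(confusion_matrix(tp = 1, fp = 0, tn = 1, fn = 0))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1, accuracy = 1))
  inverted <- confusion_metrics(confusion_matrix(tp = 0, fp = 1, tn = 0, fn = 1))
  expect_equal(unlist(inverted), c(sensitivity = 0, specificity = 0, accuracy = 0))

  expect_error(confusion_metrics(confusion_matrix(0, 5, 3, 0)), "sensitivity undefined")
  expect_error(confusion_metrics(confusion_matrix(4, 0, 0, 1)), "specificity undefined")
})

test_that("accuracy decomposes as prevalence-weighted sensitivity and specificity", {
  set.seed(43)
  for (i in 1:20) {
    cm <- confusion_matrix(
      tp = sample(1:50, 1), fp = sample(1:50, 1),
      tn = sample(1:50, 1), fn = sample(1:50, 1)
    )
    m <- confusion_metrics(cm)
    total <- cm$tp + cm$fp + cm$tn + cm$fn
    prev <- (cm$tp + cm$fn) / total
    expect_equal(m$accuracy, m$sensitivity * prev + m$specificity * (1 - prev))
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
  }
})

test_that("the ROC sweep matches closed forms and the pair-counting oracle", {
  lvl <- c("low", "high")
  sep <- tibble::tibble(
    true_state = factor(c("low", "low", "high", "high"), lvl),
    score = c(0.1, 0.2, 0.8, 0.9)
  )
  expect_equal(roc_and_auc(sep)$auc, 1)

  ties <- tibble::tibble(true_state = factor(c("low", "high", "low", "high"), lvl),
                         score = rep(0.4, 4))
  expect_equal(roc_and_auc(ties)$auc, 0.5)

  # every positive outscores every negative here, so concordance is perfect
  ex <- tibble::tibble(
    true_state = factor(c("low", "high", "low", "high"), lvl),
    score = c(0.1, 0.4, 0.35, 0.8)
  )
  expect_equal(roc_and_auc(ex)$auc, oracle_auc_pairs(c(0, 1, 0, 1), ex$score))
  expect_equal(roc_and_auc(ex)$auc, 1)
  mixed <- tibble::tibble(
    true_state = factor(c("low", "high", "high", "low"), lvl),
    score = c(0.1, 0.4, 0.35, 0.8)
  )
  expect_equal(roc_and_auc(mixed)$auc, oracle_auc_pairs(c(0, 1, 1, 0), mixed$score))
  expect_equal(roc_and_auc(mixed)$auc, 0.5)

  one_class <- tibble::tibble(true_state = factor(rep("high", 3), lvl), score = runif(3))
  expect_error(roc_and_auc(one_class), "both classes")
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  set.seed(47)
  for (i in 1:10) {
    recs <- tibble::tibble(
      true_state = factor(sample(c("low", "high"), 50, TRUE), c("low", "high")),
      score = round(runif(50), 2) # ties present
    )
    roc <- roc_and_auc(recs)
    expect_equal(unlist(roc$points[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(roc$points[nrow(roc$points), c("fpr", "tpr")]),
                 c(fpr = 1, tpr = 1))
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_true(all(diff(roc$points$tpr) >= 0))
  }
})

test_that("trapezoid AUC equals the independent pROC computation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  for (i in 1:5) {
    truth01 <- sample(0:1, 80, TRUE)
    score <- runif(80)
    recs <- tibble::tibble(
      true_state = factor(c("low", "high")[truth01 + 1], c("low", "high")),
      score = score
    )
    ours <- roc_and_auc(recs)$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(truth01, score, quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("cross-validation is deterministic and scores what it should", {
  set.seed(59)
  cfg <- default_ground_truth()
  data <- forward_sample(cfg$net, 400, seed = 95)
  cv1 <- suppressWarnings(cross_validate_msd(firefighter_dag(), data, k = 5, seed = 2))
  cv2 <- suppressWarnings(cross_validate_msd(firefighter_dag(), data, k = 5, seed = 2))
  expect_equal(as.data.frame(cv1), as.data.frame(cv2))
  expect_equal(nrow(cv1), 400)
  expect_true(all(cv1$score >= 0 & cv1$score <= 1))

  # rows with missing target train but are not scored
  data2 <- data
  data2$MSD[1:40] <- NA
  cv3 <- suppressWarnings(cross_validate_msd(firefighter_dag(), data2, k = 5, seed = 2))
  expect_equal(nrow(cv3), 360)
  expect_false(any(cv3$row_index %in% 1:40))
})

test_that("an independent target yields near-constant scores and null AUC", {
  # MSD's CPT rows are all equal: the mediators carry no signal
  dag <- firefighter_dag()
  cfg <- default_ground_truth()
  cpts <- cfg$net$cpts
  cpts$MSD <- bn_cpt("MSD", dag$parents$MSD, rep(0.45, 16))
  net <- discrete_bn(dag, cpts)
  data <- forward_sample(net, 1500, seed = 61)
  cv <- cross_validate_msd(dag, data, k = 10, seed = 3)
  expect_lt(max(cv$score) - min(cv$score), 0.35) # sampling noise only
  expect_lt(sd(cv$score), 0.05)
  auc <- roc_and_auc(cv)$auc
  expect_gt(auc, 0.40)
  expect_lt(auc, 0.60)
})

test_that("a near-deterministic dependence is recovered with high AUC", {
  dag <- firefighter_dag()
  cfg <- default_ground_truth()
  cpts <- cfg$net$cpts
  # P(MSD=high | Depression=high) = 0.95, 0.05 otherwise; Depression is the
  # 4th parent in canonical order (EE, DP, PA, Depression). Depression itself
  # is balanced so both classes of the determinant are well represented.
  cpts$Depression <- bn_cpt("Depression", dag$parents$Depression, rep(0.5, 4))
  grid <- as.matrix(expand.grid(rep(list(0:1), 4)))
  cpts$MSD <- bn_cpt("MSD", dag$parents$MSD, ifelse(grid[, 4] == 1, 0.95, 0.05))
  net <- discrete_bn(dag, cpts)
  data <- forward_sample(net, 2500, seed = 67)
  cv <- cross_validate_msd(dag, data, k = 10, seed = 5)
  expect_gt(roc_and_auc(cv)$auc, 0.9)
})
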