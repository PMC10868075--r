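test_that("the firefighter structure has the published arcs", {
  dag <- firefighter_dag()
  expect_length(dag$nodes, 7)
  expect_equal(nrow(dag$arcs), 13)
  expect_setequal(
    dag$parents$MSD,
    c("Depression", "EmotionalExhaustion", "Depersonalization", "PersonalAccomplishment")
  )
  expect_length(dag$parents$PTSD, 0) # sole root
  expect_setequal(dag$parents$JobStress, "PTSD")
  for (m in c("EmotionalExhaustion", "Depersonalization",
              "PersonalAccomplishment", "Depression")) {
    expect_setequal(dag$parents[[m]], c("PTSD", "JobStress"))
  }
  expect_equal(dag$topo_order[1], "PTSD")
})

test_that("bn_dag validates structure", {
  expect_error(bn_dag(c("A", "B"), list(c("A", "B"), c("B", "A"))), "cycle")
  expect_error(bn_dag("A", list(c("A", "A"))), "self-loop")
  expect_error(bn_dag(c("A", "B"), list(c("A", "C"))), "undeclared")
  expect_error(bn_dag(c("A", "B"), list(c("A", "B"), c("A", "B"))), "duplicate")
})

test_that("bn_cpt validates probability tables", {
  expect_error(bn_cpt("A", character(), c(0.3, 0.4)), "expected 1")
  expect_error(bn_cpt("A", "B", cbind(c(0.5, 0.5), c(0.6, 0.5))), "sum to 1")
  expect_error(bn_cpt("A", character(), 1.4), "outside")
})

test_that("joint probabilities follow the chain rule", {
  # two independent fair coins: every full assignment has probability 1/4
  ind <- discrete_bn(
    bn_dag(c("X", "Y")),
    list(X = bn_cpt("X", character(), 0.5), Y = bn_cpt("Y", character(), 0.5))
  )
  for (x in c("low", "high")) for (y in c("low", "high")) {
    expect_equal(joint_probability(ind, c(X = x, Y = y)), 0.25)
  }

  expect_equal(joint_probability(chain_net(), c(A = "high", B = "high")), 0.27)
  expect_error(joint_probability(chain_net(), c(A = "high")), "every node")

  # normalization over all 2^7 assignments of a random firefighter net,
  # cross-checked entry-wise against the brute-force product
  set.seed(21)
  net <- random_net()
  grid <- expand.grid(rep(list(c("low", "high")), 7), stringsAsFactors = FALSE)
  names(grid) <- net$dag$nodes
  probs <- vapply(seq_len(nrow(grid)), function(i) {
    joint_probability(net, as.list(grid[i, ]))
  }, numeric(1))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  for (i in c(1, 64, 128)) {
    expect_equal(probs[i], oracle_joint(net, as.list(grid[i, ])), tolerance = 1e-12)
  }
})

test_that("posterior reproduces hand-computed chain queries", {
  net <- chain_net()
  expect_equal(unname(posterior(net, "B")), 0.41)
  expect_equal(unname(posterior(net, "A", evidence = c(B = "high"))),
               0.27 / 0.41, tolerance = 1e-12)
  # query == evidence node is rejected
  expect_error(posterior(net, "B", evidence = c(B = "high")), "overlap")
  # impossible evidence fails loudly, not with NaN
  det <- discrete_bn(
    bn_dag(c("A", "B"), list(c("A", "B"))),
    list(A = bn_cpt("A", character(), 1), B = bn_cpt("B", "A", c(0.2, 0.9)))
  )
  expect_error(posterior(det, "B", evidence = c(A = "low")), "probability zero")
})

test_that("evidence in a disconnected component leaves the posterior at the prior", {
  net <- discrete_bn(
    bn_dag(c("A", "B", "C"), list(c("A", "B"))),
    list(
      A = bn_cpt("A", character(), 0.3),
      B = bn_cpt("B", "A", c(0.2, 0.9)),
      C = bn_cpt("C", character(), 0.7)
    )
  )
  expect_equal(unname(posterior(net, "B", evidence = c(C = "high"))),
               unname(posterior(net, "B")), tolerance = 1e-12)
})

test_that("variable elimination and enumeration agree with the brute-force oracle", {
  set.seed(5)
  for (i in 1:10) {
    net <- random_net()
    ev_nodes <- sample(net$dag$nodes, sample(0:2, 1))
    ev <- setNames(sample(c("low", "high"), length(ev_nodes), TRUE), ev_nodes)
    q <- setdiff(net$dag$nodes, ev_nodes)
    p_enum <- posterior(net, q, evidence = if (length(ev)) ev else NULL)
    p_ve <- posterior(net, q, evidence = if (length(ev)) ev else NULL,
                      method = "elimination")
    expect_equal(p_enum, p_ve, tolerance = 1e-10)
    q1 <- q[1]
    expect_equal(unname(p_enum[q1]),
                 oracle_posterior_high(net, q1, as.list(ev)), tolerance = 1e-10)
  }
})

test_that("fit_mle recovers tallied conditional frequencies", {
  dag1 <- bn_dag("A")
  net1 <- fit_mle(dag1, tibble::tibble(A = c("high", "high", "low", "high")))
  expect_equal(unname(net1$cpts$A$prob[1, "high"]), 0.75)

  dag2 <- bn_dag(c("A", "B"), list(c("A", "B")))
  rows <- tibble::tibble(
    A = c("low", "low", "low", "low", "high", "high", "high", "high", "high", "low"),
    B = c("low", "high", "low", "low", "high", "high", "low", "high", "high", "high")
  )
  net2 <- fit_mle(dag2, rows)
  # independent tally oracle
  tal <- table(rows$A, rows$B)
  expect_equal(unname(net2$cpts$B$prob[1, "high"]),
               tal["low", "high"] / sum(tal["low", ]))
  expect_equal(unname(net2$cpts$B$prob[2, "high"]),
               tal["high", "high"] / sum(tal["high", ]))
  expect_equal(unname(net2$cpts$A$prob[1, "high"]), mean(rows$A == "high"))

  # symmetric prior fills an unobserved configuration with (0.5, 0.5)
  rows_onesided <- tibble::tibble(A = rep("low", 4), B = c("low", "high", "low", "low"))
  net3 <- fit_mle(dag2, rows_onesided, pseudo_count = 1)
  expect_equal(unname(net3$cpts$B$prob[2, ]), c(0.5, 0.5), ignore_attr = TRUE)
  # ... and pure MLE warns about the empty configuration
  expect_warning(fit_mle(dag2, rows_onesided), "unobserved")

  expect_error(fit_mle(dag1, tibble::tibble(A = c("high", NA))), "fit_em")
})

test_that("all fitted CPT rows are proper distributions", {
  set.seed(8)
  data <- forward_sample(random_net(), 500, seed = 80)
  net <- fit_mle(firefighter_dag(), data)
  for (cpt in net$cpts) {
    expect_true(all(cpt$prob >= 0))
    expect_equal(unname(rowSums(cpt$prob)), rep(1, nrow(cpt$prob)), tolerance = 1e-12)
  }
})

test_that("EM on complete data equals the MLE exactly", {
  set.seed(13)
  data <- forward_sample(random_net(), 300, seed = 31)
  em <- fit_em(firefighter_dag(), data)
  mle <- suppressWarnings(fit_mle(firefighter_dag(), data)) # rare configs may be absent
  expect_identical(lapply(em$net$cpts, `[[`, "prob"),
                   lapply(mle$cpts, `[[`, "prob"))
  expect_true(em$converged)
})

test_that("single-node EM matches a grid-search maximizer of the observed likelihood", {
  dag <- bn_dag("A")
  fit <- fit_em(dag, tibble::tibble(A = c("high", "high", NA, "low")), tol = 1e-12)
  # independent oracle: observed-data log-likelihood maximized on a fine grid
  grid <- seq(0.001, 0.999, by = 0.001)
  ll <- 2 * log(grid) + log(1 - grid) # missing row contributes log(1) = 0
  expect_equal(unname(fit$net$cpts$A$prob[1, "high"]),
               grid[which.max(ll)], tolerance = 2e-3)
  expect_equal(unname(fit$net$cpts$A$prob[1, "high"]), 2 / 3, tolerance = 1e-6)
})

test_that("the EM log-likelihood trace is non-decreasing under missingness", {
  set.seed(17)
  truth <- random_net()
  data <- blank_profiles(forward_sample(truth, 400, seed = 71), 0.2)
  fit <- fit_em(firefighter_dag(), data, tol = 1e-8, max_iter = 300)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # and the trace matches log_likelihood() evaluated at the returned fit
  expect_equal(fit$loglik, log_likelihood(fit$net, data), tolerance = 1e-6)
})

test_that("EM requires every node to be observed at least once", {
  data <- tibble::tibble(A = c("high", "low"), B = c(NA_character_, NA))
  expect_error(fit_em(bn_dag(c("A", "B"), list(c("A", "B"))), data), "never observed")
})

test_that("log-likelihood handles complete, partial and empty rows", {
  # all CPT entries 1/2 on seven isolated nodes: each complete row has
  # probability 2^-7
  dag <- bn_dag(paste0("N", 1:7))
  net <- discrete_bn(dag, lapply(setNames(dag$nodes, dag$nodes), function(nd) {
    bn_cpt(nd, character(), 0.5)
  }))
  row <- tibble::as_tibble(setNames(as.list(rep("high", 7)), dag$nodes))
  expect_equal(log_likelihood(net, row), log(0.5^7))

  # fully missing row marginalizes to 1
  empty <- tibble::as_tibble(setNames(as.list(rep(NA_character_, 7)), dag$nodes))
  expect_equal(log_likelihood(net, empty), 0)

  # chain with A missing: P(B = high) = 0.41
  chain_row <- tibble::tibble(A = NA_character_, B = "high")
  expect_equal(log_likelihood(chain_net(), chain_row), log(0.41))

  # a zero-probability observation warns and returns -Inf
  det <- discrete_bn(
    bn_dag("A"), list(A = bn_cpt("A", character(), 1))
  )
  expect_warning(
    ll <- log_likelihood(det, tibble::tibble(A = c("high", "low"))),
    "probability zero"
  )
  expect_identical(ll, -Inf)
})

test_that("forward sampling is seeded, exact-frequency and recoverable", {
  one <- discrete_bn(bn_dag("A"), list(A = bn_cpt("A", character(), 0.3)))
  s1 <- forward_sample(one, 1e5, seed = 4)
  s2 <- forward_sample(one, 1e5, seed = 4)
  expect_identical(s1, s2)
  expect_lt(abs(mean(s1$A == "high") - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))

  set.seed(19)
  truth <- random_net(lo = 0.1, hi = 0.9)
  fitted <- fit_mle(firefighter_dag(), forward_sample(truth, 2e4, seed = 91))
  worst <- max(vapply(truth$dag$nodes, function(nd) {
    max(abs(fitted$cpts[[nd]]$prob - truth$cpts[[nd]]$prob))
  }, numeric(1)))
  expect_lt(worst, 0.05) # full 0.01-at-1e5 recovery is checked at acceptance
})

test_that("network JSON serialization round-trips bit-exactly", {
  set.seed(23)
  net <- random_net()
  path <- file.path(withr::local_tempdir(), "net.json")
  bn_to_json(net, path)
  back <- bn_from_json(path)
  expect_identical(lapply(back$cpts, `[[`, "prob"), lapply(net$cpts, `[[`, "prob"))
  expect_identical(back$dag$nodes, net$dag$nodes)
  expect_identical(as.data.frame(back$dag$arcs), as.data.frame(net$dag$arcs))
})

test_that("CPTs supplied with permuted parents are canonicalized", {
  dag <- bn_dag(c("A", "B", "C"), list(c("A", "C"), c("B", "C")))
  p <- c(ll = 0.1, hl = 0.7, lh = 0.4, hh = 0.9) # indexed A-fast
  direct <- discrete_bn(dag, list(
    A = bn_cpt("A", character(), 0.3), B = bn_cpt("B", character(), 0.6),
    C = bn_cpt("C", c("A", "B"), unname(p))
  ))
  swapped <- discrete_bn(dag, list(
    A = bn_cpt("A", character(), 0.3), B = bn_cpt("B", character(), 0.6),
    C = bn_cpt("C", c("B", "A"), c(0.1, 0.4, 0.7, 0.9)) # same table, B-fast
  ))
  expect_equal(direct$cpts$C$prob, swapped$cpts$C$prob)
  expect_equal(posterior(direct, "C"), posterior(swapped, "C"))
})
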