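# Shared fixtures: tiny hand-checkable networks, random parameterizations of
# the firefighter structure, and brute-force oracles kept independent of the
# package's own computation paths.

# Two-node chain A -> B with P(A=high)=0.3, P(B=high|A=low)=0.2,
# P(B=high|A=high)=0.9. Hand arithmetic: P(B=high)=0.41,
# P(A=high|B=high)=0.27/0.41.
chain_net <- function() {
  discrete_bn(
    bn_dag(c("A", "B"), list(c("A", "B"))),
    list(
      A = bn_cpt("A", character(), 0.3),
      B = bn_cpt("B", "A", c(0.2, 0.9))
    )
  )
}

# Random CPTs on a given DAG (probabilities kept away from 0/1 so posterior
# queries stay well-defined).
random_net <- function(dag = firefighter_dag(), lo = 0.05, hi = 0.95) {
  cpts <- lapply(setNames(dag$nodes, dag$nodes), function(nd) {
    k <- length(dag$parents[[nd]])
    bn_cpt(nd, dag$parents[[nd]], runif(2^k, lo, hi))
  })
  discrete_bn(dag, cpts)
}

# Networks for parameter-recovery checks. The precision of a recovered CPT
# entry is limited by the binomial error of its rarest parent configuration,
# so tight absolute tolerances are only meaningful when every configuration
# carries ample probability mass. These designs keep all states near 50/50:
# a five-node DAG with in-degree <= 2 (every config mass >= ~0.2) for the
# 0.01-at-n=1e5 complete-data check, and a five-node chain (config mass
# >= ~0.4) for the 0.02-at-n=2e4 EM check under 10% missingness.
balanced_recovery_net <- function() {
  dag <- bn_dag(c("A", "B", "C", "D", "E"), list(
    c("A", "B"), c("A", "C"), c("B", "C"),
    c("A", "D"), c("B", "D"), c("C", "E"), c("D", "E")
  ))
  cpts <- lapply(setNames(dag$nodes, dag$nodes), function(nd) {
    k <- length(dag$parents[[nd]])
    bn_cpt(nd, dag$parents[[nd]], runif(2^k, 0.45, 0.55))
  })
  discrete_bn(dag, cpts)
}

chain_recovery_net <- function() {
  dag <- bn_dag(c("A", "B", "C", "D", "E"), list(
    c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E")
  ))
  cpts <- lapply(setNames(dag$nodes, dag$nodes), function(nd) {
    k <- length(dag$parents[[nd]])
    bn_cpt(nd, dag$parents[[nd]], runif(2^k, 0.4, 0.6))
  })
  discrete_bn(dag, cpts)
}

worst_cpt_error <- function(fitted_cpts, truth) {
  max(vapply(truth$dag$nodes, function(nd) {
    max(abs(fitted_cpts[[nd]]$prob - truth$cpts[[nd]]$prob))
  }, numeric(1)))
}

# Blank profile-table cells completely at random (for EM tests; item-level
# missingness is the generator's job).
blank_profiles <- function(profiles, rate) {
  for (nd in names(profiles)) {
    hit <- runif(nrow(profiles)) < rate
    profiles[[nd]][hit] <- NA
  }
  profiles
}

# Brute-force joint probability: explicit sum-product over a full assignment
# written without the package's index machinery.
oracle_joint <- function(net, assignment) {
  p <- 1
  for (nd in net$dag$nodes) {
    cpt <- net$cpts[[nd]]
    row <- 1
    for (i in seq_along(cpt$parents)) {
      if (assignment[[cpt$parents[i]]] == "high") row <- row + 2^(i - 1)
    }
    p <- p * cpt$prob[row, assignment[[nd]]]
  }
  unname(p)
}

# Brute-force posterior by summing oracle_joint over all completions.
oracle_posterior_high <- function(net, node, evidence = list()) {
  nodes <- net$dag$nodes
  grids <- expand.grid(rep(list(c("low", "high")), length(nodes)),
                       stringsAsFactors = FALSE)
  names(grids) <- nodes
  keep <- rep(TRUE, nrow(grids))
  for (ev in names(evidence)) keep <- keep & grids[[ev]] == evidence[[ev]]
  num <- den <- 0
  for (i in which(keep)) {
    p <- oracle_joint(net, as.list(grids[i, , drop = FALSE]))
    den <- den + p
    if (grids[[node]][i] == "high") num <- num + p
  }
  unname(num / den)
}

# Concordance-pair AUC: exhaustive cross-class pair counting, ties 1/2.
oracle_auc_pairs <- function(truth01, score) {
  pos <- score[truth01 == 1]
  neg <- score[truth01 == 0]
  conc <- 0
  for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
  conc / (length(pos) * length(neg))
}
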