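# ---- joint-table machinery --------------------------------------------------
#
# All exact computation in this package runs over the explicit joint table of
# the (binary) network: 2^n states with the first node in `dag$nodes` varying
# fastest. With the seven-node model this is 128 states, so enumeration is
# exact and cheap; variable elimination is provided as an independent route
# to the same posteriors.

# 2^n x n matrix of 0/1 states plus, per node, the linear index of each joint
# state into that node's CPT matrix. The index map depends only on the
# structure, the probabilities are re-read from the CPTs on each call.
bn_joint <- function(net) {
  nodes <- net$dag$nodes
  states <- config_grid(length(nodes))
  colnames(states) <- nodes
  lin <- lapply(net$cpts, function(cpt) {
    k <- length(cpt$parents)
    pm <- states[, cpt$parents, drop = FALSE]
    row <- 1L + as.integer(pm %*% 2^(seq_len(k) - 1L))
    row + states[, cpt$node] * (2L^k)
  })
  p <- rep(1, nrow(states))
  for (nd in nodes) p <- p * net$cpts[[nd]]$prob[lin[[nd]]]
  list(states = states, prob = p, lin = lin)
}

# Logical mask of joint states compatible with a partial observation
# (named integer vector of 0/1, NAs and absent nodes unconstrained).
joint_mask <- function(states, obs01) {
  mask <- rep(TRUE, nrow(states))
  for (nd in names(obs01)) {
    if (!is.na(obs01[[nd]])) mask <- mask & states[, nd] == obs01[[nd]]
  }
  mask
}

check_evidence <- function(net, evidence) {
  if (is.null(evidence) || !length(evidence)) return(setNames(integer(0), character(0)))
  evidence <- unlist(as.list(evidence))
  if (is.null(names(evidence)) || any(!nzchar(names(evidence)))) {
    abort("evidence must be a named vector/list, e.g. c(PTSD = 'high')")
  }
  if (anyDuplicated(names(evidence))) abort("a node is fixed twice in the evidence")
  unknown <- setdiff(names(evidence), net$dag$nodes)
  if (length(unknown)) {
    abort(sprintf("evidence on unknown node(s): %s", paste(unknown, collapse = ", ")))
  }
  setNames(as_state01(as.character(evidence), "evidence"), names(evidence))
}

#' Probability of a complete joint assignment
#'
#' The chain-rule product of CPT entries for one full configuration of the
#' network's nodes.
#'
#' @param net A [discrete_bn()].
#' @param assignment Named character vector/list giving `"low"`/`"high"` for
#'   *every* node.
#' @return A probability in `[0, 1]`.
#' @export
joint_probability <- function(net, assignment) {
  assignment <- unlist(as.list(assignment))
  nodes <- net$dag$nodes
  if (!setequal(names(assignment), nodes)) {
    abort("`assignment` must cover every node exactly once")
  }
  s01 <- setNames(as_state01(as.character(assignment[nodes]), "assignment"), nodes)
  if (anyNA(s01)) abort("`assignment` must be complete (no missing states)")
  p <- 1
  for (nd in nodes) {
    cpt <- net$cpts[[nd]]
    row <- config_index(s01[cpt$parents])
    p <- p * cpt$prob[row, s01[[nd]] + 1L]
  }
  unname(p)
}

# ---- variable elimination ---------------------------------------------------
# Factors are (vars, vals) with vals indexed first-var-fastest, like
# config_grid(). A CPT as a factor has vars (parents..., node), which is
# exactly the layout of as.vector(cpt$prob).

f_from_cpt <- function(cpt) {
  list(vars = c(cpt$parents, cpt$node), vals = as.vector(cpt$prob))
}

f_value_on <- function(f, grid, vars) {
  if (!length(f$vars)) return(rep(f$vals, nrow(grid)))
  idx <- 1L + as.integer(grid[, match(f$vars, vars), drop = FALSE] %*%
    2^(seq_along(f$vars) - 1L))
  f$vals[idx]
}

f_prod <- function(f, g) {
  vars <- union(f$vars, g$vars)
  grid <- config_grid(length(vars))
  list(vars = vars, vals = f_value_on(f, grid, vars) * f_value_on(g, grid, vars))
}

f_sumout <- function(f, var) {
  if (!(var %in% f$vars)) return(f)
  keep <- setdiff(f$vars, var)
  grid <- config_grid(length(f$vars))
  if (!length(keep)) return(list(vars = character(0), vals = sum(f$vals)))
  kidx <- 1L + as.integer(grid[, match(keep, f$vars), drop = FALSE] %*%
    2^(seq_along(keep) - 1L))
  list(vars = keep, vals = as.vector(tapply(f$vals, kidx, sum)))
}

f_reduce <- function(f, var, s01) {
  if (!(var %in% f$vars)) return(f)
  grid <- config_grid(length(f$vars))
  sel <- grid[, match(var, f$vars)] == s01
  list(vars = setdiff(f$vars, var), vals = f$vals[sel])
}

ve_posterior_one <- function(net, q, ev01) {
  factors <- lapply(net$cpts, f_from_cpt)
  for (nd in names(ev01)) {
    factors <- lapply(factors, f_reduce, var = nd, s01 = ev01[[nd]])
  }
  elim <- setdiff(rev(net$dag$topo_order), c(q, names(ev01)))
  for (v in elim) {
    has <- vapply(factors, function(f) v %in% f$vars, logical(1))
    merged <- Reduce(f_prod, factors[has])
    factors <- c(factors[!has], list(f_sumout(merged, v)))
  }
  final <- Reduce(f_prod, factors)
  z <- sum(final$vals)
  if (z <= 0) abort("evidence has probability zero")
  sum(final$vals[config_grid(length(final$vars))[, match(q, final$vars)] == 1L]) / z
}

#' Exact posterior probabilities
#'
#' Computes `P(node = high | evidence)` for the query nodes by exact
#' inference. With no evidence this returns the prior marginals. Two routes
#' are available and agree to numerical precision: full enumeration of the
#' `2^n` joint states (default; the seven-node model has only 128) and
#' variable elimination.
#'
#' @param net A [discrete_bn()].
#' @param query Character vector of query nodes; default all non-evidence
#'   nodes.
#' @param evidence Named character vector/list fixing nodes to
#'   `"low"`/`"high"`; `NULL` for none.
#' @param method `"enumeration"` or `"elimination"`.
#' @return Named numeric vector of `P(high | evidence)` for the query nodes.
#' @export
#' @examples
#' net <- discrete_bn(
#'   bn_dag(c("A", "B"), list(c("A", "B"))),
#'   list(A = bn_cpt("A", character(), 0.3),
#'        B = bn_cpt("B", "A", c(0.2, 0.9)))
#' )
#' posterior(net, "B") # 0.41
#' posterior(net, "A", evidence = c(B = "high")) # 0.27/0.41
posterior <- function(net, query = NULL, evidence = NULL,
                      method = c("enumeration", "elimination")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "discrete_bn"))
  ev01 <- check_evidence(net, evidence)
  query <- query %||% setdiff(net$dag$nodes, names(ev01))
  unknown <- setdiff(query, net$dag$nodes)
  if (length(unknown)) abort(sprintf("unknown query node(s): %s", paste(unknown, collapse = ", ")))
  overlap <- intersect(query, names(ev01))
  if (length(overlap)) {
    abort(sprintf("query and evidence overlap: %s", paste(overlap, collapse = ", ")))
  }
  if (method == "elimination") {
    return(vapply(setNames(query, query), ve_posterior_one, numeric(1),
                  net = net, ev01 = ev01))
  }
  j <- bn_joint(net)
  mask <- joint_mask(j$states, ev01)
  z <- sum(j$prob[mask])
  if (z <= 0) abort("evidence has probability zero")
  vapply(setNames(query, query), function(q) {
    sum(j$prob[mask & j$states[, q] == 1L]) / z
  }, numeric(1))
}

# ---- likelihood and sampling ------------------------------------------------

# Group the rows of a low/high/NA cohort table into unique observation
# patterns: returns the pattern matrix (0/1/NA), counts, and for each data
# row the index of its pattern.
pattern_groups <- function(data, nodes) {
  m <- vapply(nodes, function(nd) as_state01(data[[nd]], nd), integer(nrow(data)))
  if (nrow(data) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, nodes))
  key <- apply(m, 1L, paste, collapse = "|")
  first <- !duplicated(key)
  patterns <- m[first, , drop = FALSE]
  pid <- match(key, key[first])
  list(patterns = patterns, counts = tabulate(pid, nbins = sum(first)), pattern_of_row = pid)
}

#' Observed-data log-likelihood of a cohort table
#'
#' Sums, over respondents, the log marginal probability of the observed cells
#' of each row; missing cells are marginalized by exact inference. A row with
#' probability zero contributes `-Inf` (with a warning naming the row).
#'
#' @param net A [discrete_bn()].
#' @param data Cohort table: one column per node, cells `low`/`high`/`NA`.
#' @return The log-likelihood (scalar; may be `-Inf`).
#' @export
log_likelihood <- function(net, data) {
  nodes <- net$dag$nodes
  if (!all(nodes %in% names(data))) abort("`data` must have one column per node")
  if (!nrow(data)) return(0)
  pg <- pattern_groups(data, nodes)
  j <- bn_joint(net)
  ll <- 0
  for (i in seq_len(nrow(pg$patterns))) {
    s <- sum(j$prob[joint_mask(j$states, setNames(pg$patterns[i, ], nodes))])
    if (s <= 0) {
      warn(sprintf(
        "row(s) with observation pattern %d have probability zero under the model",
        which(pg$pattern_of_row == i)[1]
      ))
      return(-Inf)
    }
    ll <- ll + pg$counts[i] * log(s)
  }
  ll
}

#' Ancestral (forward) sampling from a network
#'
#' Samples `n` complete binary profiles by drawing each node given its
#' already-sampled parents, in topological order. Deterministic given `seed`;
#' the session RNG state is left untouched.
#'
#' @param net A [discrete_bn()].
#' @param n Number of rows to sample.
#' @param seed Integer seed (`NULL` = use current RNG state).
#' @return A tibble with one factor column (`low`/`high`) per node.
#' @export
forward_sample <- function(net, n, seed = NULL) {
  check_scalar_number(n, "n", lower = 1)
  n <- as.integer(n)
  with_seed(seed, {
    s <- matrix(NA_integer_, n, length(net$dag$nodes),
                dimnames = list(NULL, net$dag$nodes))
    for (nd in net$dag$topo_order) {
      cpt <- net$cpts[[nd]]
      k <- length(cpt$parents)
      row <- if (k) {
        1L + as.integer(s[, cpt$parents, drop = FALSE] %*% 2^(seq_len(k) - 1L))
      } else {
        rep(1L, n)
      }
      s[, nd] <- as.integer(runif(n) < cpt$prob[row, "high"])
    }
    tibble::as_tibble(as.data.frame(lapply(
      setNames(net$dag$nodes, net$dag$nodes),
      function(nd) state_factor(s[, nd])
    )))
  })
}
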