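# Fold a vector of expected counts over the 2^n joint states into per-node
# (parent-config, state) CPT count matrices, using the precomputed linear
# index maps of bn_joint().
fold_counts <- function(joint, expected) {
  lapply(joint$lin, function(lin) {
    nr <- length(unique(lin)) / 2L
    m <- matrix(0, nr, 2L, dimnames = list(NULL, BN_STATES))
    m[] <- vapply(seq_len(2L * nr), function(i) sum(expected[lin == i]), numeric(1))
    m
  })
}

counts_to_cpts <- function(dag, counts, pseudo_count, warn_empty = TRUE) {
  lapply(setNames(dag$nodes, dag$nodes), function(nd) {
    m <- counts[[nd]] + pseudo_count
    tot <- rowSums(m)
    empty <- tot == 0
    if (any(empty)) {
      if (warn_empty) {
        warn(sprintf(
          "node '%s': %d unobserved parent configuration(s); using uniform rows",
          nd, sum(empty)
        ))
      }
      m[empty, ] <- 0.5
      tot[empty] <- 1
    }
    bn_cpt(nd, dag$parents[[nd]], m / tot)
  })
}

#' Maximum-likelihood CPT estimation from complete data
#'
#' Estimates every CPT entry as `(count + pseudo_count) / (config total +
#' 2 * pseudo_count)` from a cohort table with no missing cells. With
#' `pseudo_count = 0` this is the pure MLE (and can produce the extreme
#' entries 0 and 1 that a positive prior would smooth away); parent
#' configurations never observed then get a uniform row with a warning.
#'
#' @param dag A [bn_dag()].
#' @param data Complete cohort table (one `low`/`high` column per node).
#' @param pseudo_count Non-negative symmetric Dirichlet pseudo-count
#'   (default 0).
#' @return A [discrete_bn()].
#' @export
fit_mle <- function(dag, data, pseudo_count = 0) {
  stopifnot(inherits(dag, "bn_dag"))
  check_scalar_number(pseudo_count, "pseudo_count", lower = 0)
  if (!all(dag$nodes %in% names(data))) abort("`data` must have one column per node")
  if (!nrow(data)) abort("`data` is empty")
  m <- vapply(dag$nodes, function(nd) as_state01(data[[nd]], nd), integer(nrow(data)))
  if (nrow(data) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, dag$nodes))
  if (anyNA(m)) {
    abort("`data` contains missing cells; use fit_em() for incomplete data")
  }
  counts <- lapply(setNames(dag$nodes, dag$nodes), function(nd) {
    parents <- dag$parents[[nd]]
    k <- length(parents)
    row <- if (k) {
      1L + as.integer(m[, parents, drop = FALSE] %*% 2^(seq_len(k) - 1L))
    } else {
      rep(1L, nrow(m))
    }
    cm <- matrix(0, 2L^k, 2L, dimnames = list(NULL, BN_STATES))
    tab <- table(factor(row, levels = seq_len(2L^k)), factor(m[, nd], levels = 0:1))
    cm[] <- as.numeric(tab)
    cm
  })
  discrete_bn(dag, counts_to_cpts(dag, counts, pseudo_count))
}

#' EM parameter learning under missing data
#'
#' Learns the CPTs of `dag` from a cohort table that may contain missing
#' cells, by expectation-maximization at the profile level: the E-step
#' distributes each partially observed row over its completions in proportion
#' to their current joint probability, the M-step re-normalizes the expected
#' counts into CPTs. Iterates until the observed-data log-likelihood improves
#' by less than `tol` or `max_iter` is reached. The log-likelihood trace is
#' non-decreasing (a guaranteed property of EM); on complete data the first
#' M-step already equals the MLE and the algorithm stops after verifying it.
#'
#' @param dag A [bn_dag()].
#' @param data Cohort table (one column per node, cells `low`/`high`/`NA`).
#'   Every node must be observed at least once.
#' @param init `"uniform"` (all CPT entries 1/2) or `"random"` (rows drawn
#'   uniformly, controlled by `seed`).
#' @param seed Integer seed for random initialization.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Iteration cap; non-convergence yields a warning and
#'   `converged = FALSE`.
#' @param pseudo_count Non-negative pseudo-count added to expected counts in
#'   each M-step (default 0, pure maximum likelihood).
#' @return An object of class `bn_fit`: list with `net` (the fitted
#'   [discrete_bn()]), `loglik_trace`, `loglik`, `converged`, `iterations`,
#'   `n` (rows used).
#' @export
fit_em <- function(dag, data, init = c("uniform", "random"), seed = NULL,
                   tol = 1e-6, max_iter = 500L, pseudo_count = 0) {
  init <- match.arg(init)
  stopifnot(inherits(dag, "bn_dag"))
  check_scalar_number(tol, "tol", lower = 0, closed_lower = FALSE)
  check_scalar_number(pseudo_count, "pseudo_count", lower = 0)
  nodes <- dag$nodes
  if (!all(nodes %in% names(data))) abort("`data` must have one column per node")
  if (!nrow(data)) abort("`data` is empty")
  pg <- pattern_groups(data, nodes)
  never_seen <- nodes[colSums(!is.na(pg$patterns) * pg$counts) == 0]
  if (length(never_seen)) {
    abort(sprintf(
      "node(s) never observed: %s", paste(never_seen, collapse = ", ")
    ))
  }

  cpts0 <- with_seed(seed, {
    lapply(setNames(nodes, nodes), function(nd) {
      nr <- 2L^length(dag$parents[[nd]])
      p_high <- if (init == "uniform") rep(0.5, nr) else runif(nr, 0.05, 0.95)
      bn_cpt(nd, dag$parents[[nd]], p_high)
    })
  })
  net <- discrete_bn(dag, cpts0)
  j <- bn_joint(net)
  masks <- lapply(seq_len(nrow(pg$patterns)), function(i) {
    joint_mask(j$states, setNames(pg$patterns[i, ], nodes))
  })

  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step over unique observation patterns
    expected <- numeric(length(j$prob))
    ll <- 0
    for (i in seq_along(masks)) {
      w <- j$prob * masks[[i]]
      s <- sum(w)
      if (s <= 0) {
        abort(sprintf(
          "EM: observation pattern of row %d has probability zero under current parameters",
          which(pg$pattern_of_row == i)[1]
        ))
      }
      expected <- expected + pg$counts[i] * (w / s)
      ll <- ll + pg$counts[i] * log(s)
    }
    trace <- c(trace, ll)
    if (iter > 1L && (ll - trace[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
    # M-step
    net <- discrete_bn(dag, counts_to_cpts(dag, fold_counts(j, expected),
                                           pseudo_count, warn_empty = FALSE))
    j <- bn_joint(net)
  }
  if (!converged) {
    warn(sprintf("EM did not converge within %d iterations", max_iter))
  }
  structure(
    list(
      net = net, loglik_trace = trace, loglik = trace[length(trace)],
      converged = converged, iterations = length(trace), n = nrow(data)
    ),
    class = "bn_fit"
  )
}

#' @export
print.bn_fit <- function(x, ...) {
  cat(sprintf(
    "<bn_fit> EM fit on %d rows: log-likelihood %.4f after %d iteration(s)%s\n",
    x$n, x$loglik, x$iterations, if (x$converged) "" else " (NOT converged)"
  ))
  invisible(x)
}

#' @method tidy bn_fit
#' @export
tidy.bn_fit <- function(x, ...) tidy.discrete_bn(x$net, ...)

#' Fit summary
#' @param x A `bn_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `loglik`, `iterations`, `converged`.
#' @method glance bn_fit
#' @export
glance.bn_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, loglik = x$loglik,
    iterations = x$iterations, converged = x$converged
  )
}
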