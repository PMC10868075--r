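#' Directed acyclic graph over named nodes
#'
#' @param nodes Character vector of node identifiers (unique, non-empty).
#' @param arcs Two-column data frame / matrix (`parent`, `child`) or a list of
#'   length-2 character vectors. Arcs must reference declared nodes, contain
#'   no duplicates, and form no directed cycle.
#' @return An object of class `bn_dag` with fields `nodes`, `arcs` (tibble),
#'   `parents` (named list, parents listed in `nodes` order) and
#'   `topo_order`.
#' @export
#' @examples
#' bn_dag(c("A", "B"), list(c("A", "B")))
bn_dag <- function(nodes, arcs = list()) {
  nodes <- as.character(nodes)
  if (!length(nodes) || anyDuplicated(nodes) || any(!nzchar(nodes))) {
    abort("`nodes` must be unique non-empty identifiers")
  }
  if (is.list(arcs) && !is.data.frame(arcs)) {
    arcs <- if (length(arcs)) {
      do.call(rbind, lapply(arcs, function(a) {
        data.frame(parent = a[[1]], child = a[[2]], stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(parent = character(), child = character())
    }
  }
  arcs <- tibble::as_tibble(arcs)[c("parent", "child")]
  if (nrow(arcs)) {
    unknown <- setdiff(unique(c(arcs$parent, arcs$child)), nodes)
    if (length(unknown)) {
      abort(sprintf("arcs reference undeclared node(s): %s", paste(unknown, collapse = ", ")))
    }
    if (anyDuplicated(paste(arcs$parent, arcs$child, sep = "\r"))) abort("duplicate arcs")
    if (any(arcs$parent == arcs$child)) abort("self-loop arc")
  }
  parents <- lapply(setNames(nodes, nodes), function(nd) {
    p <- arcs$parent[arcs$child == nd]
    nodes[nodes %in% p] # canonical order: position in `nodes`
  })
  # Kahn's algorithm: verifies acyclicity and yields a topological order
  indeg <- vapply(parents, length, integer(1))
  topo <- character(0)
  avail <- nodes[indeg == 0L]
  remaining <- setNames(indeg, nodes)
  while (length(avail)) {
    nd <- avail[1]
    avail <- avail[-1]
    topo <- c(topo, nd)
    for (ch in arcs$child[arcs$parent == nd]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) avail <- c(avail, ch)
    }
  }
  if (length(topo) != length(nodes)) abort("arcs contain a directed cycle")
  structure(
    list(nodes = nodes, arcs = arcs, parents = parents, topo_order = topo),
    class = "bn_dag"
  )
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("<bn_dag> %d nodes, %d arcs\n", length(x$nodes), nrow(x$arcs)))
  for (nd in x$nodes) {
    p <- x$parents[[nd]]
    cat(" ", nd, if (length(p)) paste0("<- {", paste(p, collapse = ", "), "}") else "(root)", "\n")
  }
  invisible(x)
}

#' The firefighter psychosocial network structure
#'
#' The expert-drawn seven-node DAG relating post-traumatic stress and job
#' stress to musculoskeletal symptoms through four mediators (the three
#' burnout dimensions and depression): PTSD is the sole root; PTSD and job
#' stress each point at all four mediators; PTSD also points at job stress;
#' and the four mediators are the parents of the musculoskeletal-symptom node
#' (13 arcs in all).
#'
#' @return A [bn_dag()] with 7 nodes and 13 arcs.
#' @export
firefighter_dag <- function() {
  mediators <- c(
    "EmotionalExhaustion", "Depersonalization",
    "PersonalAccomplishment", "Depression"
  )
  nodes <- c("PTSD", "JobStress", mediators[1:3], "Depression", "MSD")
  arcs <- rbind(
    data.frame(parent = "PTSD", child = c("JobStress", mediators)),
    data.frame(parent = "JobStress", child = mediators),
    data.frame(parent = mediators, child = "MSD")
  )
  bn_dag(nodes, arcs)
}

# Parent-state configurations are indexed with the FIRST parent varying
# fastest: config index = 1 + sum_i state_i * 2^(i-1), states low=0 / high=1.
config_index <- function(states01) {
  if (!length(states01)) return(1L)
  1L + as.integer(states01 %*% 2^(seq_along(states01) - 1L))
}

config_grid <- function(k) {
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  as.matrix(expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE))
}

#' Conditional probability table for one binary node
#'
#' @param node Node identifier.
#' @param parents Character vector of parent node identifiers (possibly
#'   empty).
#' @param prob Numeric matrix with `2^length(parents)` rows and two columns
#'   (`low`, `high`); row *i* is the distribution of `node` given the parent
#'   configuration with index *i* (first parent varying fastest, states
#'   ordered low, high). A vector of `P(high)` values of length
#'   `2^length(parents)` is also accepted.
#' @return An object of class `bn_cpt`.
#' @export
bn_cpt <- function(node, parents, prob) {
  k <- length(parents)
  nr <- 2L^k
  if (is.vector(prob) && is.numeric(prob)) {
    if (length(prob) != nr) abort(sprintf("cpt '%s': expected %d P(high) values", node, nr))
    prob <- cbind(low = 1 - prob, high = prob)
  }
  prob <- as.matrix(prob)
  if (nrow(prob) != nr || ncol(prob) != 2L) {
    abort(sprintf("cpt '%s': prob must be %d x 2", node, nr))
  }
  colnames(prob) <- BN_STATES
  if (any(prob < -1e-12) || any(prob > 1 + 1e-12)) {
    abort(sprintf("cpt '%s': probabilities outside [0, 1]", node))
  }
  if (any(abs(rowSums(prob) - 1) > 1e-9)) {
    abort(sprintf("cpt '%s': rows must sum to 1", node))
  }
  structure(
    list(node = node, parents = as.character(parents), prob = prob),
    class = "bn_cpt"
  )
}

# Reorder a cpt's parents to `new_order` (a permutation of cpt$parents).
reorder_cpt <- function(cpt, new_order) {
  if (identical(cpt$parents, new_order)) return(cpt)
  perm <- match(cpt$parents, new_order)
  grid_new <- config_grid(length(new_order))
  old_idx <- apply(grid_new, 1L, function(s) config_index(s[perm]))
  bn_cpt(cpt$node, new_order, cpt$prob[old_idx, , drop = FALSE])
}

#' Discrete Bayesian network
#'
#' Binds a DAG to one conditional probability table per node. All nodes are
#' binary with states ordered (`low`, `high`). CPT parents are reordered to
#' the DAG's canonical parent order if supplied in a different order.
#'
#' @param dag A [bn_dag()].
#' @param cpts Named list of [bn_cpt()] objects, one per node.
#' @return An object of class `discrete_bn`.
#' @export
discrete_bn <- function(dag, cpts) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!setequal(names(cpts), dag$nodes)) {
    abort("`cpts` must contain exactly one CPT per DAG node")
  }
  cpts <- lapply(setNames(dag$nodes, dag$nodes), function(nd) {
    cpt <- cpts[[nd]]
    stopifnot(inherits(cpt, "bn_cpt"))
    if (!setequal(cpt$parents, dag$parents[[nd]])) {
      abort(sprintf("cpt '%s': parents do not match DAG parents", nd))
    }
    reorder_cpt(cpt, dag$parents[[nd]])
  })
  structure(list(dag = dag, cpts = cpts, state_order = BN_STATES),
            class = "discrete_bn")
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat(sprintf(
    "<discrete_bn> %d nodes, %d arcs; states (%s)\n",
    length(x$dag$nodes), nrow(x$dag$arcs), paste(x$state_order, collapse = ", ")
  ))
  pri <- try(posterior(x), silent = TRUE)
  if (!inherits(pri, "try-error")) {
    cat("  prior P(high):\n")
    for (nd in x$dag$nodes) cat(sprintf("    %-24s %.3f\n", nd, pri[[nd]]))
  }
  invisible(x)
}

#' Tidy a fitted network into a long CPT table
#'
#' One row per CPT entry: the node, its parent configuration (as a single
#' `parent=state` string, empty for roots) and the conditional probability of
#' each state.
#'
#' @param x A `discrete_bn`.
#' @param ... Unused.
#' @return A tibble with columns `node`, `parents`, `p_low`, `p_high`.
#' @method tidy discrete_bn
#' @export
tidy.discrete_bn <- function(x, ...) {
  purrr::map_dfr(x$cpts, function(cpt) {
    grid <- config_grid(length(cpt$parents))
    cfg <- apply(grid, 1L, function(s) {
      paste(sprintf("%s=%s", cpt$parents, BN_STATES[s + 1L]), collapse = ",")
    })
    if (!length(cpt$parents)) cfg <- ""
    tibble::tibble(
      node = cpt$node, parents = cfg,
      p_low = unname(cpt$prob[, "low"]), p_high = unname(cpt$prob[, "high"])
    )
  })
}

#' Serialize a network to JSON
#'
#' The document records nodes, arcs, the state order and every CPT row keyed
#' by its parent-state configuration, at full double precision so that
#' [bn_from_json()] round-trips bit-exactly.
#'
#' @param net A `discrete_bn`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
bn_to_json <- function(net, path = NULL) {
  stopifnot(inherits(net, "discrete_bn"))
  doc <- list(
    nodes = net$dag$nodes,
    arcs = purrr::pmap(net$dag$arcs, function(parent, child) list(parent = parent, child = child)),
    state_order = net$state_order,
    cpts = lapply(net$cpts, function(cpt) {
      grid <- config_grid(length(cpt$parents))
      rows <- lapply(seq_len(nrow(grid)), function(i) {
        list(
          config = as.list(setNames(BN_STATES[grid[i, ] + 1L], cpt$parents)),
          p = list(low = cpt$prob[i, "low"], high = cpt$prob[i, "high"])
        )
      })
      list(parents = cpt$parents, rows = rows)
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Deserialize a network from JSON
#'
#' @param path Path to, or string of, JSON written by [bn_to_json()].
#' @return A `discrete_bn`.
#' @export
bn_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- unlist(doc$nodes)
  arcs <- if (length(doc$arcs)) {
    do.call(rbind, lapply(doc$arcs, function(a) {
      data.frame(parent = a$parent, child = a$child, stringsAsFactors = FALSE)
    }))
  } else {
    list()
  }
  dag <- bn_dag(nodes, arcs)
  if (!identical(unlist(doc$state_order), BN_STATES)) {
    abort("unsupported state order in network JSON")
  }
  cpts <- lapply(setNames(nodes, nodes), function(nd) {
    entry <- doc$cpts[[nd]]
    parents <- as.character(unlist(entry$parents))
    nr <- 2L^length(parents)
    prob <- matrix(NA_real_, nr, 2L, dimnames = list(NULL, BN_STATES))
    for (row in entry$rows) {
      states <- as.integer(unlist(row$config[parents]) == "high")
      i <- config_index(states)
      prob[i, ] <- c(row$p$low, row$p$high)
    }
    if (anyNA(prob)) abort(sprintf("cpt '%s': incomplete rows in JSON", nd))
    bn_cpt(nd, parents, prob)
  })
  discrete_bn(dag, cpts)
}
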