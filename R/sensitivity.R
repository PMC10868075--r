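#' Evidence-propagation sensitivity profile
#'
#' Fixes one or more nodes to an observed state ("evidence with probability
#' 100%") and reports, for every other node, how its posterior probability of
#' being `high` moves relative to the no-evidence baseline. The `delta`
#' column is `conditioned - baseline` in probability points, matching the
#' convention of reporting e.g. a +0.34 shift as "increased by 34%".
#'
#' @param net A [discrete_bn()].
#' @param evidence Named character vector/list, e.g.
#'   `c(PTSD = "high", JobStress = "high")`. Must be non-empty.
#' @return A tibble of class `bn_sensitivity` with columns `node`,
#'   `baseline`, `conditioned`, `delta`; the evidence is stored in the
#'   `"evidence"` attribute.
#' @export
evidence_delta_profile <- function(net, evidence) {
  ev01 <- check_evidence(net, evidence)
  if (!length(ev01)) abort("`evidence` must fix at least one node")
  others <- setdiff(net$dag$nodes, names(ev01))
  base <- posterior(net, others)
  cond <- posterior(net, others, evidence = evidence)
  out <- tibble::tibble(
    node = others,
    baseline = unname(base[others]),
    conditioned = unname(cond[others]),
    delta = unname(cond[others] - base[others])
  )
  attr(out, "evidence") <- setNames(BN_STATES[ev01 + 1L], names(ev01))
  class(out) <- c("bn_sensitivity", class(out))
  out
}

#' Influence of a parent on a child (delta-p)
#'
#' Quantifies the strength of one arc as the change in the child's
#' probability of being `high` when the parent switches from `low` to
#' `high`, read from the child's CPT. With co-parents present, the absolute
#' change is computed for every configuration of the other parents;
#' `maximum` is the largest and `average` the mean weighted by the joint
#' marginal probability of the co-parent configurations (renormalized). For
#' a single-parent arc the two coincide.
#'
#' @param net A [discrete_bn()].
#' @param parent,child Node names; `(parent, child)` must be an arc.
#' @return One-row tibble: `parent`, `child`, `average`, `maximum`.
#' @export
arc_influence <- function(net, parent, child) {
  arcs <- net$dag$arcs
  if (!any(arcs$parent == parent & arcs$child == child)) {
    abort(sprintf("(%s -> %s) is not an arc of the network", parent, child))
  }
  cpt <- net$cpts[[child]]
  others <- setdiff(cpt$parents, parent)
  p_pos <- match(parent, cpt$parents)
  grid <- config_grid(length(cpt$parents))
  hi_rows <- grid[, p_pos] == 1L
  # align each parent=high row with its parent=low partner (same co-parent config)
  co_hi <- grid[hi_rows, -p_pos, drop = FALSE]
  co_lo <- grid[!hi_rows, -p_pos, drop = FALSE]
  stopifnot(identical(co_hi, co_lo))
  delta <- unname(abs(cpt$prob[which(hi_rows), "high"] - cpt$prob[which(!hi_rows), "high"]))
  if (!length(others)) {
    avg <- mx <- delta[1]
  } else {
    # weight co-parent configurations by their joint marginal in the network
    j <- bn_joint(net)
    w <- vapply(seq_len(nrow(co_hi)), function(i) {
      sum(j$prob[joint_mask(j$states, setNames(co_hi[i, ], others))])
    }, numeric(1))
    w <- w / sum(w)
    avg <- sum(w * delta)
    mx <- max(delta)
  }
  tibble::tibble(parent = parent, child = child, average = avg, maximum = mx)
}

#' Rank all arcs by influence
#'
#' Computes [arc_influence()] for every arc and sorts by descending
#' `average`, ties broken by `(parent, child)` lexicographic order.
#'
#' @param net A [discrete_bn()].
#' @return A tibble of class `bn_influence`, one row per arc.
#' @export
rank_arcs <- function(net) {
  out <- purrr::pmap_dfr(net$dag$arcs, function(parent, child) {
    arc_influence(net, parent, child)
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$average), .data$parent, .data$child)
  class(out) <- c("bn_influence", class(out))
  out
}

#' Posterior symptom probability by stress exposure
#'
#' The model gives the musculoskeletal-symptom node the four mediators as
#' parents, so `P(MSD | PTSD, JobStress)` is not a CPT of the network: it is
#' the posterior with the mediators marginalized out. This helper computes
#' that 4-row table (one row per PTSD x JobStress configuration).
#'
#' @param net A [discrete_bn()] over the firefighter node set.
#' @return A tibble with columns `PTSD`, `JobStress`, `p_low`, `p_high`.
#' @export
msd_given_stress_table <- function(net) {
  purrr::map_dfr(c("low", "high"), function(pt) {
    purrr::map_dfr(c("low", "high"), function(js) {
      p <- posterior(net, "MSD", evidence = c(PTSD = pt, JobStress = js))
      tibble::tibble(PTSD = pt, JobStress = js,
                     p_low = 1 - unname(p), p_high = unname(p))
    })
  })
}
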