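# ---- ground truth -----------------------------------------------------------

# Observed level frequencies of the seven constructs in the study cohort
# (counts out of n = 2339), used as the marginal calibration targets of the
# default generating network.
msd_marginal_targets <- function() {
  c(
    PTSD = 680, JobStress = 490, EmotionalExhaustion = 680,
    Depersonalization = 585, PersonalAccomplishment = 838,
    Depression = 580, MSD = 1154
  ) / 2339
}

# Per-arc effect sizes (P(child=high) shift when the parent flips low->high)
# of the default generating network. The upstream arcs use the published
# average influence values; the four symptom arcs are scaled down so that
# the additive CPT rows stay inside [0, 1]. These are fabricated-but-
# calibrated values: the study does not publish its CPTs.
msd_default_effects <- function() {
  list(
    JobStress = c(PTSD = 0.613),
    EmotionalExhaustion = c(PTSD = 0.602, JobStress = 0.174),
    Depersonalization = c(PTSD = 0.548, JobStress = 0.180),
    PersonalAccomplishment = c(PTSD = 0.377, JobStress = 0.094),
    Depression = c(PTSD = 0.304, JobStress = 0.188),
    MSD = c(
      EmotionalExhaustion = 0.17, Depersonalization = 0.15,
      PersonalAccomplishment = 0.12, Depression = 0.20
    )
  )
}

# Build the monotone additive generating network: each child's CPT is
# base + sum(effect_i * parent_state_i), with the base rate solved so that
# the node's marginal P(high) equals its target exactly (the additive form
# makes the marginal depend only on the parents' marginals).
build_ground_truth_net <- function(marginals = msd_marginal_targets(),
                                   effects = msd_default_effects()) {
  dag <- firefighter_dag()
  cpts <- list(PTSD = bn_cpt("PTSD", character(), unname(marginals["PTSD"])))
  for (nd in setdiff(dag$topo_order, "PTSD")) {
    parents <- dag$parents[[nd]]
    eff <- effects[[nd]][parents]
    base <- marginals[[nd]] - sum(eff * marginals[parents])
    grid <- config_grid(length(parents))
    p_high <- base + as.vector(grid %*% eff)
    if (any(p_high < 0) || any(p_high > 1)) {
      abort(sprintf("ground-truth CPT of '%s' leaves [0, 1]; adjust effects", nd))
    }
    cpts[[nd]] <- bn_cpt(nd, parents, p_high)
  }
  discrete_bn(dag, cpts)
}

# Level-conditional raw-total models: truncated discrete normal on each side
# of a fixed generating threshold. Means/SDs are the published per-level
# group statistics; the PTSD means are linearly rescaled from the 17-85
# checklist metric onto the 0-17 binary-item metric used here
# (x' = (x - 17) * 17/68). Thresholds are the rounded midpoints of the level
# means; `side` records which side of the threshold each level occupies
# under the construct's orientation.
msd_default_score_models <- function() {
  list(
    PTSD = list(
      range = c(0, 17), threshold = 8, orientation = "direct",
      low = c(mean = (30.34 - 17) * 17 / 68, sd = 8.95 * 17 / 68),
      high = c(mean = (68.86 - 17) * 17 / 68, sd = 9.09 * 17 / 68)
    ),
    JobStress = list(
      range = c(35, 175), threshold = 96, orientation = "inverted",
      low = c(mean = 119.13, sd = 13.94),
      high = c(mean = 73.18, sd = 8.68)
    ),
    EmotionalExhaustion = list(
      range = c(0, 54), threshold = 27, orientation = "direct",
      low = c(mean = 15.59, sd = 5.39),
      high = c(mean = 38.63, sd = 5.77)
    ),
    Depersonalization = list(
      range = c(0, 30), threshold = 14, orientation = "direct",
      low = c(mean = 8.10, sd = 3.04),
      high = c(mean = 21.06, sd = 2.93)
    ),
    PersonalAccomplishment = list(
      range = c(0, 48), threshold = 24, orientation = "inverted",
      low = c(mean = 31.12, sd = 4.90),
      high = c(mean = 17.45, sd = 4.89)
    ),
    Depression = list(
      range = c(0, 60), threshold = 19, orientation = "direct",
      low = c(mean = 9.91, sd = 7.06),
      high = c(mean = 28.16, sd = 4.56)
    ),
    MSD = list(
      range = c(0, 9), threshold = 0, orientation = "direct",
      low = c(mean = 0, sd = 0),
      high = c(mean = 5.89, sd = 3.25)
    )
  )
}

# Integer support of a level's total distribution: the side of the
# generating threshold that the dichotomization rule maps back to the level.
# Direct: high iff total > t (ties low). Inverted: high iff total < t.
level_support <- function(model, level) {
  t0 <- model$threshold
  lo <- model$range[1]
  hi <- model$range[2]
  if (model$orientation == "direct") {
    if (level == "low") seq(lo, t0) else seq(t0 + 1, hi)
  } else {
    if (level == "low") seq(t0, hi) else seq(lo, t0 - 1)
  }
}

# Probability weights of a discrete normal truncated to `support`, with the
# location parameter shifted so the truncated mean equals `target` (plain
# truncation would bias the mean away from the published group mean).
truncated_weights <- function(target, sd, support) {
  w_at <- function(mu) dnorm(support, mu, sd)
  mean_at <- function(mu) {
    w <- w_at(mu)
    sum(support * w) / sum(w)
  }
  lo <- min(support) - 4 * sd
  hi <- max(support) + 4 * sd
  mu <- if (mean_at(lo) >= target) {
    lo
  } else if (mean_at(hi) <= target) {
    hi
  } else {
    stats::uniroot(function(m) mean_at(m) - target, c(lo, hi), tol = 1e-8)$root
  }
  w_at(mu)
}

# Draw n totals from the truncated discrete normal of one level.
draw_totals <- function(model, level, n) {
  if (!n) return(integer(0))
  support <- level_support(model, level)
  pars <- model[[level]]
  if (pars[["sd"]] <= 0) {
    return(rep(as.integer(round(pars[["mean"]])), n))
  }
  w <- truncated_weights(pars[["mean"]], pars[["sd"]], support)
  if (sum(w) <= 0) w <- rep(1, length(support))
  sample(support, n, replace = TRUE, prob = w)
}

#' Default ground-truth configuration for synthetic cohorts
#'
#' Bundles the generating network and the level-conditional raw-score models
#' used by [simulate_cohort()]. The network has the firefighter structure
#' with monotone CPTs calibrated so every node's marginal `P(high)` equals
#' the study cohort's observed level frequency (e.g. 0.291 for PTSD, 0.493
#' for musculoskeletal symptoms); arc effect sizes follow the published
#' influence ranking where the additive parameterization allows it. The
#' score models reproduce the published per-level means/SDs of the raw
#' totals, truncated to the correct side of a fixed generating threshold so
#' that re-scoring a generated cohort reproduces the generating binary
#' profile exactly.
#'
#' @param n Cohort size (default 2339, the study's sample).
#' @param missing_rate Probability that an individual item cell is blanked
#'   (missing completely at random), in `[0, 1)`.
#' @param seed Integer seed.
#' @return Object of class `msd_ground_truth`: list with `net`,
#'   `score_models`, `n`, `missing_rate`, `seed`.
#' @export
default_ground_truth <- function(n = 2339, missing_rate = 0, seed = 1) {
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(missing_rate, "missing_rate", lower = 0, upper = 1,
                      closed_upper = FALSE)
  structure(
    list(
      net = build_ground_truth_net(),
      score_models = msd_default_score_models(),
      n = as.integer(n), missing_rate = missing_rate, seed = seed
    ),
    class = "msd_ground_truth"
  )
}

#' @export
print.msd_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<msd_ground_truth> n = %d, missing_rate = %g, seed = %s\n",
    x$n, x$missing_rate, format(x$seed)
  ))
  cat("  generating marginals P(high):\n")
  pri <- posterior(x$net)
  for (nd in names(pri)) cat(sprintf("    %-24s %.3f\n", nd, pri[[nd]]))
  invisible(x)
}

# ---- item-level simulation --------------------------------------------------

# Allocate each row's total across n_items items with per-item bounds
# [lo, hi], sequentially sampling each item uniformly over its feasible
# range. Vectorized across rows. totals must be feasible
# (n_items*lo <= total <= n_items*hi).
allocate_items <- function(totals, n_items, lo, hi, construct = "construct") {
  if (any(totals < n_items * lo | totals > n_items * hi)) {
    abort(sprintf("infeasible total for item bounds in '%s'", construct))
  }
  rem <- as.integer(totals)
  out <- matrix(0L, length(totals), n_items)
  for (i in seq_len(n_items)) {
    k <- n_items - i # items still to fill after this one
    lo_i <- pmax(lo, rem - hi * k)
    hi_i <- pmin(hi, rem - lo * k)
    r <- lo_i + as.integer(floor(runif(length(rem)) * (hi_i - lo_i + 1L)))
    r <- pmin(r, hi_i) # guard the measure-zero runif()==1 edge
    out[, i] <- r
    rem <- rem - r
  }
  stopifnot(all(rem == 0L))
  out
}

# Demographic profile frequencies of the study cohort (categories sampled
# independently; no confounding structure is modelled).
simulate_demographics <- function(n) {
  draw <- function(levels, counts) {
    factor(sample(levels, n, replace = TRUE, prob = counts / sum(counts)),
           levels = levels)
  }
  tibble::tibble(
    age_band = draw(c("<30", "30-40", "41-50", ">50"), c(908, 1288, 135, 8)),
    education = draw(
      c("under_diploma", "diploma", "associate", "bachelor", "master_plus"),
      c(555, 766, 867, 149, 2)
    ),
    bmi_band = draw(c("<18.5", "18.5-24.9", "25-30", ">30"), c(78, 1001, 864, 396)),
    second_job = draw(c("no", "yes"), c(1305, 1034)),
    marital_status = draw(c("single", "married"), c(775, 1564)),
    smoking = draw(c("yes", "no"), c(516, 1823))
  )
}

#' Simulate an item-level synthetic cohort with known ground truth
#'
#' Generates a full survey cohort in three steps: (1) sample binary
#' low/high profiles for the seven constructs from the generating network;
#' (2) for each construct draw a raw total from its level-conditional score
#' model (so totals land on the correct side of the generating threshold);
#' (3) allocate each total across the instrument's items uniformly at random
#' subject to the per-item bounds. Symptom region flags are all zero for a
#' `low` symptom profile and sum to the drawn symptom count otherwise.
#' Demographics are sampled from the study cohort's category frequencies.
#' With `missing_rate > 0` item cells are then blanked completely at random
#' via [inject_missingness()]; the truth table is never blanked.
#'
#' @param config A [default_ground_truth()] (or modified copy).
#' @return Object of class `msd_cohort`: list with `items` (item-level
#'   tibble, columns `hse_1..35`, `pcl_1..17`, `mbi_1..22`, `cesd_1..20`,
#'   `nmq_1..9` plus demographics), `truth` (the generating binary profiles),
#'   `config`.
#' @export
simulate_cohort <- function(config = default_ground_truth()) {
  stopifnot(inherits(config, "msd_ground_truth"))
  n <- config$n
  with_seed(config$seed, {
    truth <- forward_sample(config$net, n)
    sm <- config$score_models
    totals <- tibble::as_tibble(lapply(
      setNames(names(sm), names(sm)),
      function(cons) {
        lev <- as.character(truth[[cons]])
        tot <- integer(n)
        for (level in BN_STATES) {
          idx <- which(lev == level)
          tot[idx] <- draw_totals(sm[[cons]], level, length(idx))
        }
        tot
      }
    ))
    items <- tibble::tibble(.rows = n)
    put <- function(m, prefix) {
      colnames(m) <- paste0(prefix, "_", seq_len(ncol(m)))
      tibble::as_tibble(m)
    }
    items <- dplyr::bind_cols(
      put(allocate_items(totals$JobStress, 35, 1, 5, "JobStress"), "hse"),
      put(allocate_items(totals$PTSD, 17, 0, 1, "PTSD"), "pcl"),
      put(cbind(
        allocate_items(totals$EmotionalExhaustion, 9, 0, 6, "EmotionalExhaustion"),
        allocate_items(totals$Depersonalization, 5, 0, 6, "Depersonalization"),
        allocate_items(totals$PersonalAccomplishment, 8, 0, 6, "PersonalAccomplishment")
      ), "mbi"),
      put(allocate_items(totals$Depression, 20, 0, 3, "Depression"), "cesd"),
      put(allocate_items(totals$MSD, 9, 0, 1, "MSD"), "nmq"),
      simulate_demographics(n)
    )
    cohort <- structure(list(items = items, truth = truth, config = config),
                        class = "msd_cohort")
    if (config$missing_rate > 0) {
      cohort <- inject_missingness(cohort, config$missing_rate,
                                   seed = NULL) # inside the seeded stream
    }
    cohort
  })
}

#' @export
print.msd_cohort <- function(x, ...) {
  cat(sprintf(
    "<msd_cohort> %d respondents, %d item columns (+%d demographics); missing_rate %g\n",
    nrow(x$items), sum(grepl("_[0-9]+$", names(x$items))),
    sum(!grepl("_[0-9]+$", names(x$items))), x$config$missing_rate
  ))
  invisible(x)
}

#' Generating thresholds of a synthetic cohort
#'
#' Named vector of the fixed cut points the generator used, suitable for
#' `dichotomize_constructs(totals, thresholds = ...)` to reproduce the truth
#' table exactly (at zero missingness).
#'
#' @param config A [default_ground_truth()].
#' @return Named numeric vector of thresholds.
#' @export
generating_thresholds <- function(config) {
  vapply(config$score_models, function(m) as.numeric(m$threshold), numeric(1))
}

#' Blank item cells completely at random
#'
#' Each instrument item cell is independently set to missing with
#' probability `rate` (missing completely at random); demographics and the
#' ground-truth table are untouched.
#'
#' @param cohort An `msd_cohort`.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed (`NULL` = current RNG state).
#' @return The cohort with blanked item cells.
#' @export
inject_missingness <- function(cohort, rate, seed = NULL) {
  stopifnot(inherits(cohort, "msd_cohort"))
  check_scalar_number(rate, "rate", lower = 0, upper = 1, closed_upper = FALSE)
  if (rate == 0) return(cohort)
  with_seed(seed, {
    item_cols <- grep("^(hse|pcl|mbi|cesd|nmq)_[0-9]+$", names(cohort$items), value = TRUE)
    m <- as.matrix(cohort$items[item_cols])
    m[matrix(runif(length(m)) < rate, nrow(m))] <- NA_integer_
    cohort$items[item_cols] <- tibble::as_tibble(m)
    cohort
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes `items.csv` (empty cell = missing), `truth.csv` and a
#' `config.json` echo (marginals, thresholds, n, missing rate, seed) into
#' `dir`.
#'
#' @param cohort An `msd_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$items, file.path(dir, "items.csv"), na = "")
  readr::write_csv(
    as.data.frame(lapply(cohort$truth, as.character)),
    file.path(dir, "truth.csv"), na = ""
  )
  cfg <- cohort$config
  jsonlite::write_json(
    list(
      n = cfg$n, missing_rate = cfg$missing_rate, seed = cfg$seed,
      marginals = as.list(posterior(cfg$net)),
      thresholds = as.list(generating_thresholds(cfg))
    ),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
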