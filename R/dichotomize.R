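#' Median split of raw scale totals
#'
#' Dichotomizes raw totals at the cohort median. For a `"direct"` construct a
#' respondent is `high` when their total exceeds the median; for an
#' `"inverted"` construct (where the raw scale runs opposite to the construct,
#' e.g. a stress indicator on which high scores mean low stress) a respondent
#' is `high` when their total falls *below* the median. Ties at the median are
#' assigned `low` in both orientations — conservative toward the non-exposed
#' class. Missing totals stay missing; the median is computed over the
#' non-missing totals (mean of the middle pair for an even count).
#'
#' @param totals Numeric vector of raw totals, `NA` = missing.
#' @param orientation `"direct"` or `"inverted"`.
#' @return List with `levels` (factor `low`/`high`, `NA` preserved) and
#'   `median` (the cut point used).
#' @export
#' @examples
#' median_split(c(1, 2, 2, 3, 5), "direct")
median_split <- function(totals, orientation = c("direct", "inverted")) {
  orientation <- match.arg(orientation)
  totals <- as.numeric(totals)
  obs <- totals[!is.na(totals)]
  if (!length(obs)) abort("median_split(): all totals are missing")
  med <- median(obs)
  if (length(unique(obs)) == 1L) {
    warn("median_split(): all totals equal; split is degenerate (everyone 'low')")
  }
  hi <- if (orientation == "direct") totals > med else totals < med
  levels <- factor(
    ifelse(is.na(totals), NA_character_, ifelse(hi, "high", "low")),
    levels = BN_STATES
  )
  list(levels = levels, median = med)
}

#' Musculoskeletal symptom level from body-region flags
#'
#' The symptom construct is not median-split: any affected body region (of the
#' nine surveyed) defines the `high` level, zero affected regions the `low`
#' level.
#'
#' @param region_flags 0/1 vector of length 9 (one flag per body region).
#' @return List with `level` (factor `low`/`high`) and `symptom_count`.
#' @export
nmq_level <- function(region_flags) {
  if (length(region_flags) != 9L) {
    abort("nmq_level(): expected 9 body-region flags")
  }
  if (anyNA(region_flags)) {
    return(list(level = factor(NA_character_, levels = BN_STATES),
                symptom_count = NA_integer_))
  }
  if (!all(region_flags %in% c(0, 1))) {
    abort("nmq_level(): flags must be 0 or 1")
  }
  n <- as.integer(sum(region_flags))
  list(
    level = factor(if (n == 0L) "low" else "high", levels = BN_STATES),
    symptom_count = n
  )
}

#' Construct map of the seven-node model
#'
#' The network's seven constructs and how each is obtained from the
#' instrument battery: which instrument, which subscale (or the total), and
#' the orientation of its median split. The three burnout dimensions are
#' dichotomized independently, each at its own median. Musculoskeletal
#' symptoms (`MSD`) use the any-region rule of [nmq_level()] rather than a
#' median split.
#'
#' @return A tibble with columns `construct`, `instrument`, `score_column`,
#'   `orientation`.
#' @export
construct_map <- function() {
  tibble::tribble(
    ~construct,               ~instrument, ~score_column,                  ~orientation,
    "PTSD",                    "pcl",      "pcl_total",                    "direct",
    "JobStress",               "hse",      "hse_total",                    "inverted",
    "EmotionalExhaustion",     "mbi",      "mbi_emotional_exhaustion",     "direct",
    "Depersonalization",       "mbi",      "mbi_depersonalization",        "direct",
    "PersonalAccomplishment",  "mbi",      "mbi_personal_accomplishment",  "inverted",
    "Depression",              "cesd",     "cesd_total",                   "direct",
    "MSD",                     "nmq",      "nmq_total",                    "direct"
  )
}

#' Extract per-construct raw totals from scored data
#'
#' Renames the relevant columns of a [score_cohort()] result to the seven
#' construct names (for `MSD` the "total" is the symptom count).
#'
#' @param scores Tibble from [score_cohort()].
#' @return Tibble with the seven construct columns of raw totals.
#' @export
construct_totals <- function(scores) {
  cm <- construct_map()
  missing_cols <- setdiff(cm$score_column, names(scores))
  if (length(missing_cols)) {
    abort(sprintf(
      "construct_totals(): missing score columns: %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- scores[cm$score_column]
  names(out) <- cm$construct
  tibble::as_tibble(out)
}

#' Dichotomize construct totals into binary profiles
#'
#' Turns per-respondent raw construct totals into the seven-column table of
#' `low`/`high` levels used by the network. By default each construct (except
#' `MSD`) is split at the cohort median with its orientation from
#' [construct_map()]; alternatively pass explicit `thresholds` (named numeric,
#' e.g. the generating thresholds of a synthetic cohort) to cut at fixed
#' values with the same tie rule (ties -> `low` for direct, `low` for
#' inverted). `MSD` is always the any-symptom rule: count 0 = `low`,
#' count >= 1 = `high`.
#'
#' @param totals Tibble of construct totals from [construct_totals()].
#' @param thresholds Optional named numeric of fixed cut points (per
#'   construct, `MSD` ignored); `NULL` = cohort medians.
#' @return A tibble of factors (`low`/`high`, `NA` = missing), one column per
#'   construct, with attribute `"thresholds"` recording the cut points used.
#' @export
dichotomize_constructs <- function(totals, thresholds = NULL) {
  cm <- construct_map()
  out <- tibble::tibble(.rows = nrow(totals))
  used <- numeric(0)
  for (i in seq_len(nrow(cm))) {
    cons <- cm$construct[i]
    x <- totals[[cons]]
    if (cons == "MSD") {
      lev <- factor(
        ifelse(is.na(x), NA_character_, ifelse(x > 0, "high", "low")),
        levels = BN_STATES
      )
      out[[cons]] <- lev
      next
    }
    if (is.null(thresholds)) {
      ms <- median_split(x, cm$orientation[i])
      out[[cons]] <- ms$levels
      used[cons] <- ms$median
    } else {
      t0 <- thresholds[[cons]]
      if (is.null(t0) || is.na(t0)) {
        abort(sprintf("dichotomize_constructs(): no threshold for '%s'", cons))
      }
      hi <- if (cm$orientation[i] == "direct") x > t0 else x < t0
      out[[cons]] <- factor(
        ifelse(is.na(x), NA_character_, ifelse(hi, "high", "low")),
        levels = BN_STATES
      )
      used[cons] <- t0
    }
  }
  attr(out, "thresholds") <- used
  out
}

#' Write binary profiles with a sidecar of the cut points used
#'
#' Writes the per-respondent levels to CSV (missing as empty cells) and the
#' thresholds/medians to a small JSON sidecar so the dichotomization is fully
#' reproducible.
#'
#' @param profiles Result of [dichotomize_constructs()].
#' @param path CSV output path; the sidecar is written to
#'   `<path without .csv>_thresholds.json`.
#' @return `path`, invisibly.
#' @export
write_binary_profiles <- function(profiles, path) {
  df <- as.data.frame(lapply(profiles, as.character), stringsAsFactors = FALSE)
  readr::write_csv(df, path, na = "")
  thr <- attr(profiles, "thresholds")
  if (!is.null(thr)) {
    side <- sub("\\.csv$", "", path)
    jsonlite::write_json(
      as.list(thr), paste0(side, "_thresholds.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read binary profiles from CSV
#'
#' @param path CSV written by [write_binary_profiles()] (or any CSV with
#'   `low`/`high`/empty cells, one column per node).
#' @return Tibble of `low`/`high` factors with `NA` for empty cells.
#' @export
read_binary_profiles <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "NA"))
  tibble::as_tibble(lapply(df, function(x) factor(x, levels = BN_STATES)))
}
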