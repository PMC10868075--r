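#' Define a questionnaire instrument
#'
#' An instrument specification records how item-level responses of a
#' psychometric questionnaire are turned into a raw total (and subscale
#' totals): the number of items, the per-item response bounds, which items are
#' reverse-scored, how items group into subscales, and the construct
#' orientation — whether a *higher* raw total indicates *more* of the
#' dichotomized construct (`"direct"`) or *less* of it (`"inverted"`, as for
#' occupational-stress indicators where high scores mean low stress).
#'
#' @param name Instrument identifier (e.g. `"hse"`).
#' @param item_count Number of items (positive integer).
#' @param response_min,response_max Integer bounds of a single item response.
#' @param reverse_items Integer vector of 1-based item indices that are
#'   reverse-scored before summation (`r -> response_min + response_max - r`).
#' @param subscales Named list of integer item-index vectors, or `NULL` for an
#'   instrument scored only as a total. When given, the subscales must be
#'   disjoint and jointly cover all items.
#' @param orientation `"direct"` or `"inverted"`.
#'
#' @return An object of class `instrument_spec`.
#' @export
instrument_spec <- function(name, item_count, response_min, response_max,
                            reverse_items = integer(), subscales = NULL,
                            orientation = c("direct", "inverted")) {
  orientation <- match.arg(orientation)
  item_count <- as.integer(item_count)
  if (item_count < 1L) abort("`item_count` must be positive")
  if (response_min >= response_max) abort("`response_min` must be < `response_max`")
  reverse_items <- as.integer(reverse_items)
  if (length(reverse_items) && (any(reverse_items < 1L) || any(reverse_items > item_count))) {
    abort(sprintf("`reverse_items` out of 1..%d for instrument '%s'", item_count, name))
  }
  if (!is.null(subscales)) {
    idx <- unlist(subscales, use.names = FALSE)
    if (anyDuplicated(idx) || !setequal(idx, seq_len(item_count))) {
      abort(sprintf("subscales of '%s' must partition items 1..%d", name, item_count))
    }
  }
  structure(
    list(
      name = name, item_count = item_count,
      response_min = as.integer(response_min),
      response_max = as.integer(response_max),
      reverse_items = sort(unique(reverse_items)),
      subscales = subscales, orientation = orientation
    ),
    class = "instrument_spec"
  )
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf(
    "<instrument_spec> %s: %d items in [%d, %d], orientation %s\n",
    x$name, x$item_count, x$response_min, x$response_max, x$orientation
  ))
  if (!is.null(x$subscales)) {
    cat("  subscales:", paste(sprintf(
      "%s (%d)", names(x$subscales), lengths(x$subscales)
    ), collapse = ", "), "\n")
  }
  if (length(x$reverse_items)) {
    cat("  reverse-scored items:", paste(x$reverse_items, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Standard instrument battery
#'
#' Builds the five instruments of the firefighter psychosocial survey:
#'
#' * `hse` — HSE Management Standards Indicator Tool, 35 items scored 1–5 in
#'   seven subscales (demands 8, control 6, officials' support 5, colleagues'
#'   support 4, relationships 4, role 5, changes 3). Higher totals indicate
#'   *lower* occupational stress, so the construct orientation is inverted.
#' * `pcl` — PTSD Checklist, 17 yes/no items (0/1) in four symptom clusters
#'   (intrusion 5, avoidance 2, numbing 5, hyperarousal 5).
#' * `mbi` — Maslach Burnout Inventory, 22 items scored 0–6 in three
#'   dimensions: emotional exhaustion (9), depersonalization (5), personal
#'   accomplishment (8). Personal accomplishment runs opposite to burnout, so
#'   as a construct it is inverted.
#' * `cesd` — CES-D depression scale, 20 items scored 0–3 (total 0–60).
#' * `nmq` — Nordic Musculoskeletal Questionnaire, 9 body-region yes/no flags.
#'
#' Which HSE items are reverse-scored varies between adaptations and is not
#' fixed here; pass the indices used by your survey via `hse_reverse_items`
#' (default: none).
#'
#' @param hse_reverse_items Integer indices of reverse-scored HSE items.
#' @return Named list of [instrument_spec()] objects
#'   (`hse`, `pcl`, `mbi`, `cesd`, `nmq`).
#' @export
#' @examples
#' specs <- standard_instruments()
#' specs$mbi
standard_instruments <- function(hse_reverse_items = integer()) {
  list(
    hse = instrument_spec(
      "hse", 35, 1, 5,
      reverse_items = hse_reverse_items,
      subscales = list(
        demands = 1:8, control = 9:14, officials_support = 15:19,
        colleagues_support = 20:23, relationships = 24:27,
        role = 28:32, changes = 33:35
      ),
      orientation = "inverted"
    ),
    pcl = instrument_spec(
      "pcl", 17, 0, 1,
      subscales = list(
        intrusion = 1:5, avoidance = 6:7,
        numbing = 8:12, hyperarousal = 13:17
      ),
      orientation = "direct"
    ),
    mbi = instrument_spec(
      "mbi", 22, 0, 6,
      subscales = list(
        emotional_exhaustion = 1:9,
        depersonalization = 10:14,
        personal_accomplishment = 15:22
      ),
      orientation = "direct"
    ),
    cesd = instrument_spec("cesd", 20, 0, 3, orientation = "direct"),
    nmq = instrument_spec("nmq", 9, 0, 1, orientation = "direct")
  )
}

#' Score one respondent on one instrument
#'
#' Reverse-scores the items flagged in the instrument definition, then sums to a total and to
#' per-subscale totals. A missing item response makes the affected totals
#' missing (no pro-rating — imputation, if any, happens at the analysis
#' level, not the item level).
#'
#' @param spec An [instrument_spec()].
#' @param responses Integer vector of length `spec$item_count`; `NA` = missing.
#' @return List with `total` and `subscale_totals` (named numeric, or `NULL`
#'   when the instrument has no subscales).
#' @export
#' @examples
#' cesd <- standard_instruments()$cesd
#' score_instrument(cesd, rep(3, 20))$total # 60
score_instrument <- function(spec, responses) {
  stopifnot(inherits(spec, "instrument_spec"))
  if (length(responses) != spec$item_count) {
    abort(sprintf(
      "instrument '%s' expects %d responses, got %d",
      spec$name, spec$item_count, length(responses)
    ))
  }
  responses <- as.numeric(responses)
  obs <- !is.na(responses)
  bad <- obs & (responses < spec$response_min | responses > spec$response_max |
    responses != round(responses))
  if (any(bad)) {
    abort(sprintf(
      "instrument '%s': response out of range [%d, %d] at item %d",
      spec$name, spec$response_min, spec$response_max, which(bad)[1]
    ))
  }
  if (length(spec$reverse_items)) {
    ri <- spec$reverse_items
    responses[ri] <- spec$response_min + spec$response_max - responses[ri]
  }
  total <- if (all(obs)) sum(responses) else NA_real_
  sub <- NULL
  if (!is.null(spec$subscales)) {
    sub <- vapply(spec$subscales, function(idx) {
      if (anyNA(responses[idx])) NA_real_ else sum(responses[idx])
    }, numeric(1))
  }
  list(total = total, subscale_totals = sub)
}

#' Score a cohort's item table
#'
#' Takes a data frame with one row per respondent and item columns named
#' `<instrument>_<item>` (1-based, e.g. `hse_1` ... `hse_35`) and returns the
#' per-respondent totals and subscale totals for every instrument in `specs`.
#' Empty cells / `NA` propagate to missing totals.
#'
#' @param data Data frame of item responses.
#' @param specs Named list of instrument specs, as from
#'   [standard_instruments()].
#' @return A tibble with one row per respondent: `<instrument>_total` columns
#'   plus `<instrument>_<subscale>` columns.
#' @export
score_cohort <- function(data, specs = standard_instruments()) {
  stopifnot(is.data.frame(data))
  out <- tibble::tibble(.rows = nrow(data))
  for (spec in specs) {
    cols <- paste0(spec$name, "_", seq_len(spec$item_count))
    missing_cols <- setdiff(cols, names(data))
    if (length(missing_cols)) {
      abort(sprintf(
        "item columns missing for instrument '%s': %s",
        spec$name, paste(head(missing_cols, 3), collapse = ", ")
      ))
    }
    m <- as.matrix(data[cols])
    storage.mode(m) <- "numeric"
    rng <- range(m, na.rm = TRUE)
    if (!all(is.na(m)) && (rng[1] < spec$response_min || rng[2] > spec$response_max)) {
      abort(sprintf(
        "instrument '%s': responses outside [%d, %d]",
        spec$name, spec$response_min, spec$response_max
      ))
    }
    if (length(spec$reverse_items)) {
      ri <- spec$reverse_items
      m[, ri] <- spec$response_min + spec$response_max - m[, ri]
    }
    out[[paste0(spec$name, "_total")]] <- rowSums(m)
    for (sub in names(spec$subscales)) {
      out[[paste0(spec$name, "_", sub)]] <-
        rowSums(m[, spec$subscales[[sub]], drop = FALSE])
    }
  }
  out
}
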