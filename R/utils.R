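#' @importFrom rlang %||% abort warn
#' @importFrom stats median rnorm runif dnorm setNames sd
#' @importFrom utils head
NULL

BN_STATES <- c("low", "high")

# Run code with a private RNG stream, restoring the caller's .Random.seed.
# All randomized functions in the package route through this so that a
# user-supplied seed argument never clobbers the session RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Coerce a vector of "low"/"high"/NA (character or factor) to 0/1/NA integers.
as_state01 <- function(x, what = "state") {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    bad <- !(x %in% c(0, 1) | is.na(x))
    if (any(bad)) abort(sprintf("numeric %s values must be 0/1", what))
    return(as.integer(x))
  }
  x[!is.na(x) & x == ""] <- NA
  bad <- !is.na(x) & !(x %in% BN_STATES)
  if (any(bad)) {
    abort(sprintf(
      "invalid %s value(s): %s (expected 'low' or 'high')",
      what, paste(unique(x[bad]), collapse = ", ")
    ))
  }
  ifelse(is.na(x), NA_integer_, as.integer(x == "high"))
}

state_factor <- function(x01) {
  factor(ifelse(is.na(x01), NA_character_, BN_STATES[x01 + 1L]), levels = BN_STATES)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number", name))
  }
  ok_lo <- if (closed_lower) x >= lower else x > lower
  ok_hi <- if (closed_upper) x <= upper else x < upper
  if (!ok_lo || !ok_hi) {
    abort(sprintf("`%s` = %g is outside its valid range", name, x))
  }
  invisible(x)
}
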