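# Audit machinery for manual checks of the detector: stratified random
# sampling of records for hand checking and Bayesian upper bounds on the
# error percentage.

AUDIT_CATEGORIES <- c(
  "excluded_title", "title_no_acronym", "title_with_acronym",
  "abstract_no_acronym", "abstract_with_acronym"
)

# Half-up rounding for table presentation (full precision kept internally).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Bayesian upper bound on an audited error percentage
#'
#' With `x` errors observed in `n` checks and a uniform Beta(1, 1) prior,
#' the error rate has posterior Beta(x + 1, n - x + 1); the bound is 100
#' times its `q`-quantile (default the 95th percentile).
#'
#' @param x number of errors observed (vectorized, `0 <= x <= n`).
#' @param n number of items checked (> 0).
#' @param q posterior quantile in (0, 1), default 0.95.
#' @return upper bound(s) on the error percentage, full precision.
#' @examples
#' beta_upper_bound(1, 300)   # ~1.57, printed as 1.6
#' beta_upper_bound(19, 300)  # ~9.13, printed as 9.1
#' @export
beta_upper_bound <- function(x, n, q = 0.95) {
  if (any(n <= 0) || any(x < 0) || any(x > n)) {
    stop("require 0 <= x <= n and n > 0")
  }
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  100 * stats::qbeta(q, x + 1, n - x + 1)
}

#' Summarize audit categories with average and upper-bound error rates
#'
#' @param counts a data frame with columns `category`, `n` (checked) and
#'   `x` (errors found).
#' @param q posterior quantile for the upper bound (default 0.95).
#' @return a tibble with, per row, `category`, `n_checked`, `x_errors`,
#'   `avg_pct` and `upper_pct` (full precision) and their half-up one-decimal
#'   presentation values `avg_pct_1dp`, `upper_pct_1dp`.
#' @examples
#' audit_summary(data.frame(category = "excluded_title", n = 300, x = 1))
#' @export
audit_summary <- function(counts, q = 0.95) {
  avg <- 100 * counts$x / counts$n
  up <- beta_upper_bound(counts$x, counts$n, q = q)
  tibble::tibble(
    category = counts$category,
    n_checked = as.integer(counts$n),
    x_errors = as.integer(counts$x),
    avg_pct = avg,
    upper_pct = up,
    avg_pct_1dp = round_half_up(avg, 1L),
    upper_pct_1dp = round_half_up(up, 1L)
  )
}

#' Draw a reproducible random sample of records for hand checking
#'
#' Classifies records into audit categories (titles excluded by the filters;
#' included titles/abstracts with and without detected acronyms) and draws a
#' simple random sample without replacement from the requested category.
#'
#' @param records a record tibble.
#' @param category one of `"excluded_title"`, `"title_no_acronym"`,
#'   `"title_with_acronym"`, `"abstract_no_acronym"`,
#'   `"abstract_with_acronym"`.
#' @param n sample size (default 300); when the population is smaller, the
#'   whole population is returned with a warning.
#' @param seed integer seed making the sample reproducible.
#' @param start_year,caps_threshold passed to the exclusion filters.
#' @return character vector of sampled `paper_id`s.
#' @export
sample_for_check <- function(records, category, n = 300L, seed = 1L,
                             start_year = 1950L, caps_threshold = 0.60) {
  category <- match.arg(category, AUDIT_CATEGORIES)
  field <- if (startsWith(category, "abstract")) "abstract" else "title"
  reason <- exclusion_reasons(records, field, start_year, caps_threshold)
  if (category == "excluded_title") {
    pool <- records$paper_id[reason != "included"]
  } else {
    kept <- records[reason == "included", , drop = FALSE]
    st <- acronym_doc_stats(kept[[field]])
    has <- st$n_acronyms > 0L
    pool <- if (endsWith(category, "with_acronym")) {
      kept$paper_id[has]
    } else {
      kept$paper_id[!has]
    }
  }
  if (length(pool) == 0L) {
    stop("no records in audit category '", category, "'")
  }
  if (length(pool) <= n) {
    if (length(pool) < n) {
      warning("population (", length(pool), ") smaller than requested ",
              n, "; returning all", call. = FALSE)
    }
    return(pool)
  }
  withr::with_seed(as.integer(seed), sample(pool, n))
}
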