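# Record-level exclusion filters with conserved per-reason accounting.
#
# Each (record, field) pair is either included or assigned exactly one
# exclusion reason, evaluated in a fixed precedence order so tallies are
# reproducible: metadata problems first (missing date, language, year,
# article type), then content problems (absent, empty, one-word, mostly
# capitals).

EXCLUSION_REASONS <- c(
  "missing_date", "non_english", "pre_start_year", "no_article_type",
  "no_abstract", "empty", "one_word", "mostly_capitals"
)

#' Exclusion reasons for every record in a corpus
#'
#' Vectorized filter: for the chosen field, returns `"included"` or the first
#' exclusion reason that fires, in precedence order: `missing_date`,
#' `non_english`, `pre_start_year` (year < `start_year`), `no_article_type`
#' (titles only), `no_abstract` (abstract field only), `empty`, `one_word`,
#' `mostly_capitals` (fraction of all-capital words >= `caps_threshold`).
#'
#' @param records a record tibble.
#' @param field `"title"` or `"abstract"`.
#' @param start_year first eligible publication year (default 1950).
#' @param caps_threshold minimum fraction of all-capital words that excludes
#'   a text (default 0.60).
#' @return character vector, one element per record.
#' @export
exclusion_reasons <- function(records, field = c("title", "abstract"),
                              start_year = 1950L, caps_threshold = 0.60) {
  field <- match.arg(field)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  hit <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- code
  }
  hit(is.na(records$pub_date), "missing_date")
  hit(is.na(records$language) | records$language != "eng", "non_english")
  hit(records$year < start_year, "pre_start_year")
  if (field == "title") {
    hit(lengths(records$article_types) == 0L, "no_article_type")
  }
  if (field == "abstract") {
    hit(is.na(records$abstract), "no_abstract")
  }
  text <- records[[field]]
  # content checks only where no metadata reason fired (cheaper and the
  # precedence order demands it)
  open <- which(is.na(reason))
  if (length(open) > 0L) {
    st <- acronym_doc_stats(text[open])
    nw <- st$n_words
    caps_frac <- ifelse(nw > 0L, st$n_caps_words / nw, 0)
    sub <- rep(NA_character_, length(open))
    sub[nw == 0L] <- "empty"
    sub[is.na(sub) & nw == 1L] <- "one_word"
    sub[is.na(sub) & caps_frac >= caps_threshold] <- "mostly_capitals"
    reason[open] <- sub
  }
  reason[is.na(reason)] <- "included"
  reason
}

#' Filter a single record for one field
#'
#' Convenience wrapper around [exclusion_reasons()] for one record.
#'
#' @param record a one-row record tibble.
#' @inheritParams exclusion_reasons
#' @return `"included"` or an exclusion reason code.
#' @export
filter_record <- function(record, field = c("title", "abstract"),
                          start_year = 1950L, caps_threshold = 0.60) {
  stopifnot(nrow(record) == 1L)
  exclusion_reasons(record, field = field, start_year = start_year,
                    caps_threshold = caps_threshold)
}

tally_from_reasons <- function(title_reasons, abstract_reasons, n) {
  lvl <- c(EXCLUSION_REASONS, "included")
  out <- tibble::tibble(
    reason = lvl,
    titles = as.integer(table(factor(title_reasons, levels = lvl))),
    abstracts = as.integer(table(factor(abstract_reasons, levels = lvl)))
  )
  dplyr::bind_rows(out, tibble::tibble(
    reason = "total", titles = n, abstracts = n
  ))
}

#' Tabulate exclusion reasons per field
#'
#' Every record contributes to exactly one cell per field (included or a
#' single reason), so grand totals conserve the record count.
#'
#' @inheritParams exclusion_reasons
#' @return a tibble with columns `reason`, `titles`, `abstracts` containing
#'   one row per exclusion reason (in precedence order) plus `included` and
#'   `total`.
#' @export
tally_exclusions <- function(records, start_year = 1950L,
                             caps_threshold = 0.60) {
  tally_from_reasons(
    exclusion_reasons(records, "title", start_year, caps_threshold),
    exclusion_reasons(records, "abstract", start_year, caps_threshold),
    nrow(records)
  )
}

#' Split a corpus into per-field kept subsets
#'
#' @inheritParams exclusion_reasons
#' @return a list with `records` (the input augmented with logical columns
#'   `title_ok`, `abstract_ok`), `title_kept` and `abstract_kept` (filtered
#'   tibbles) and `tally` (the [tally_exclusions()] table).
#' @export
filter_corpus <- function(records, start_year = 1950L,
                          caps_threshold = 0.60) {
  rt <- exclusion_reasons(records, "title", start_year, caps_threshold)
  ra <- exclusion_reasons(records, "abstract", start_year, caps_threshold)
  records$title_ok <- rt == "included"
  records$abstract_ok <- ra == "included"
  list(
    records = records,
    title_kept = records[records$title_ok, , drop = FALSE],
    abstract_kept = records[records$abstract_ok, , drop = FALSE],
    tally = tally_from_reasons(rt, ra, nrow(records))
  )
}
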