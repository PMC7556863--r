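# Corpus-level trend statistics: annual mean acronym densities per 100 words
# (means of per-paper ratios, not pooled token ratios), word-count trends,
# top-N rankings, the acronym frequency spectrum and sensitivity variants.

# Columns of the annual trend table; densities are acronyms per 100 words.
trend_row <- function(year, field, d, words, strata) {
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  half <- if (n > 1L && is.finite(s)) 1.96 * s / sqrt(n) else 0
  tibble::tibble(
    year = year, field = field, n_papers = n,
    mean_density = m, ci_low = m - half, ci_high = m + half,
    degenerate_ci = n <= 1L,
    mean_words = mean(words),
    len2_density = mean(strata$len2),
    len3_density = mean(strata$len3),
    len4_density = mean(strata$len4),
    len5p_density = mean(strata$len5p),
    letters_only_density = mean(strata$letters_only),
    letters_numbers_density = mean(strata$letters_numbers)
  )
}

#' Annual acronym-density trends
#'
#' For each calendar year with at least one eligible record, the mean over
#' papers of the per-paper acronym density (100 x acronym tokens / words),
#' with a normal-approximation 95% confidence interval for the annual mean
#' (`mean +/- 1.96 sd / sqrt(n)`), mean word counts, and density strata by
#' acronym length (2, 3, 4, 5+) and kind (letters only vs letters and
#' numbers), all with the full word count as denominator. Papers with zero
#' words are dropped (they are excluded upstream as empty). Years with no
#' eligible records are omitted, not zero-filled; single-paper years get a
#' degenerate interval equal to the mean, flagged in `degenerate_ci`.
#'
#' @param records a record tibble (already filtered).
#' @param field `"title"` or `"abstract"`.
#' @param mask optional character vector of surfaces never counted as
#'   acronyms (still counted as words) — the popularity sensitivity analysis.
#' @param pooled if `TRUE`, report the pooled token ratio
#'   (total acronyms / total words x 100) instead of the mean of per-paper
#'   ratios (sensitivity variant; the confidence interval then refers to the
#'   per-paper mean and is reported `NA`).
#' @inheritParams is_acronym
#' @return a tibble ordered by year; see Details for columns.
#' @export
annual_trends <- function(records, field = c("title", "abstract"),
                          mask = NULL, min_length = 2L,
                          denominator = c("all", "alphanumeric"),
                          pooled = FALSE) {
  field <- match.arg(field)
  denominator <- match.arg(denominator)
  records <- records[!is.na(records$year), , drop = FALSE]
  years <- sort(unique(records$year))
  out <- lapply(years, function(y) {
    texts <- records[[field]][records$year == y]
    st <- acronym_doc_stats(texts, min_length = min_length,
                            denominator = denominator, mask = mask)
    st <- st[st$n_words > 0L, , drop = FALSE]
    if (nrow(st) == 0L) return(NULL)
    d <- 100 * st$n_acronyms / st$n_words
    strata <- data.frame(
      len2 = 100 * st$len2 / st$n_words,
      len3 = 100 * st$len3 / st$n_words,
      len4 = 100 * st$len4 / st$n_words,
      len5p = 100 * st$len5p / st$n_words,
      letters_only = 100 * st$letters_only / st$n_words,
      letters_numbers = 100 * st$letters_numbers / st$n_words
    )
    row <- trend_row(y, field, d, st$n_words, strata)
    if (pooled) {
      row$mean_density <- 100 * sum(st$n_acronyms) / sum(st$n_words)
      row$ci_low <- NA_real_
      row$ci_high <- NA_real_
    }
    row
  })
  dplyr::bind_rows(out)
}

#' Most frequent acronyms
#'
#' Counts are token occurrences (not per-paper presence) with exact,
#' case-sensitive surface matching ("mRNA" and "MRNA" are distinct). Ties
#' are broken lexicographically so rankings are deterministic.
#'
#' @param records a record tibble.
#' @param field `"both"` (titles and abstracts pooled, the default),
#'   `"title"` or `"abstract"`.
#' @param year optional single year to restrict to.
#' @param n number of rows to return (`n >= 1`); larger than the vocabulary
#'   returns the full ranking.
#' @inheritParams is_acronym
#' @return a tibble `(surface, count)` in rank order.
#' @export
top_acronyms <- function(records, n = 20L,
                         field = c("both", "title", "abstract"),
                         year = NULL, min_length = 2L,
                         denominator = c("all", "alphanumeric")) {
  if (!is.numeric(n) || n < 1L) stop("n must be >= 1")
  field <- match.arg(field)
  if (!is.null(year)) records <- records[!is.na(records$year) &
                                           records$year == year, , drop = FALSE]
  occ <- extract_acronyms(records, field = field, min_length = min_length,
                          denominator = denominator)
  if (nrow(occ) == 0L) return(tibble::tibble(surface = character(),
                                             count = integer()))
  tab <- table(occ$surface)
  out <- tibble::tibble(surface = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$surface), , drop = FALSE]
  utils::head(out, n)
}

#' Per-year top acronym tables
#'
#' The tabular equivalent of an animated per-year ranking: [top_acronyms()]
#' applied within each year.
#'
#' @inheritParams top_acronyms
#' @return a tibble `(year, rank, surface, count)`.
#' @export
top_acronyms_by_year <- function(records, n = 10L,
                                 field = c("both", "title", "abstract")) {
  field <- match.arg(field)
  years <- sort(unique(records$year[!is.na(records$year)]))
  dplyr::bind_rows(lapply(years, function(y) {
    t <- top_acronyms(records, n = n, field = field, year = y)
    if (nrow(t) == 0L) return(NULL)
    tibble::tibble(year = y, rank = seq_len(nrow(t)),
                   surface = t$surface, count = t$count)
  }))
}

#' Annual trends with the most popular acronyms removed
#'
#' Masks the `k` globally most frequent surfaces (they are no longer counted
#' as acronyms but still count as words) and recomputes [annual_trends()] —
#' the sensitivity analysis showing the trend is not driven by a few
#' ubiquitous terms.
#'
#' @inheritParams annual_trends
#' @param k number of top surfaces to mask (`k = 0` reproduces
#'   [annual_trends()] exactly).
#' @param rank_field field used to rank popularity (default `"both"`).
#' @export
trends_excluding_top <- function(records, field = c("title", "abstract"),
                                 k = 100L, rank_field = "both",
                                 min_length = 2L) {
  field <- match.arg(field)
  stopifnot(k >= 0L)
  mask <- NULL
  if (k > 0L) {
    top <- top_acronyms(records, n = k, field = rank_field,
                        min_length = min_length)
    mask <- top$surface
  }
  annual_trends(records, field = field, mask = mask, min_length = min_length)
}

#' Annual trends stratified by article type
#'
#' A record contributes to the series of every listed type it carries.
#'
#' @inheritParams annual_trends
#' @param types character vector of article-type labels.
#' @return a named list of [annual_trends()] tibbles, one per type (empty
#'   tibble, with a warning, for a type no record carries).
#' @export
trends_by_article_type <- function(records, field = c("title", "abstract"),
                                   types) {
  field <- match.arg(field)
  out <- lapply(types, function(tp) {
    has <- vapply(records$article_types, function(x) tp %in% x, logical(1))
    if (!any(has)) {
      warning("no records of article type '", tp, "'", call. = FALSE)
      return(tibble::tibble())
    }
    annual_trends(records[has, , drop = FALSE], field = field)
  })
  names(out) <- types
  out
}

#' Number of possible three-letter acronyms
#'
#' `26^3 = 17576` upper-case letter combinations.
#' @format An integer scalar.
#' @export
N_THREE_LETTER_FORMS <- as.integer(26^3)

#' Acronym frequency spectrum
#'
#' How often each unique acronym surface occurs corpus-wide (titles and
#' abstracts pooled, token occurrences): the fraction occurring exactly once,
#' between two and ten times, and more than 10,000 times, plus the coverage
#' of the 17,576 possible three-letter all-capital forms.
#'
#' @param records a record tibble.
#' @inheritParams is_acronym
#' @return a list with `total_unique`, `frac_once`, `frac_2_to_10`,
#'   `frac_gt_10000`, `three_letter_coverage`, `possible_three_letter`
#'   (17,576) and `counts` (named integer vector of occurrences per surface).
#' @export
frequency_spectrum <- function(records, min_length = 2L,
                               denominator = c("all", "alphanumeric")) {
  occ <- extract_acronyms(records, field = "both", min_length = min_length,
                          denominator = denominator)
  counts <- table(occ$surface)
  total <- length(counts)
  tl <- names(counts)[stringi::stri_detect_regex(names(counts), "^[A-Z]{3}$")]
  list(
    total_unique = total,
    frac_once = if (total > 0) sum(counts == 1L) / total else NA_real_,
    frac_2_to_10 = if (total > 0) sum(counts >= 2L & counts <= 10L) / total
      else NA_real_,
    frac_gt_10000 = if (total > 0) sum(counts > 10000L) / total else NA_real_,
    three_letter_coverage = length(tl) / N_THREE_LETTER_FORMS,
    possible_three_letter = N_THREE_LETTER_FORMS,
    counts = stats::setNames(as.integer(counts), names(counts))
  )
}

#' Annual mean word counts
#'
#' Mean tokens per paper per year for the chosen field; years with no
#' eligible records are omitted.
#'
#' @inheritParams annual_trends
#' @return a tibble `(year, mean_words, n_papers)`.
#' @export
annual_word_counts <- function(records, field = c("title", "abstract")) {
  field <- match.arg(field)
  records <- records[!is.na(records$year), , drop = FALSE]
  years <- sort(unique(records$year))
  dplyr::bind_rows(lapply(years, function(y) {
    texts <- records[[field]][records$year == y]
    nw <- acronym_doc_stats(texts)$n_words
    nw <- nw[nw > 0L]
    if (length(nw) == 0L) return(NULL)
    tibble::tibble(year = y, mean_words = mean(nw), n_papers = length(nw))
  }))
}
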