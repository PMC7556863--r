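# Synthetic corpora with known ground truth.
#
# Titles and abstracts are sequences of lowercase filler words interleaved
# with acronym tokens drawn from a Zipf-distributed vocabulary shared across
# journals. Per-year acronym densities and mean word counts follow linear
# ramps whose defaults match the observed literature-wide trends (title
# density 0.7 -> 2.4 per 100 words over 1950-2019, abstract density
# 0.4 -> 4.1, title length 9.0 -> 14.6 words, abstract length 128 -> 220).
# Contamination records (non-English, all-capital titles, missing abstracts)
# are injected at configured rates with their true exclusion reasons
# recorded, so filter accounting can be checked exactly.

FILLER_LEXICON <- c(
  "the", "of", "and", "in", "for", "with", "study", "analysis", "effect",
  "patients", "results", "using", "between", "clinical", "cells", "growth",
  "response", "treatment", "model", "data", "levels", "during", "after",
  "expression", "function", "disease", "activity", "protein", "human",
  "factors", "novel", "role", "evidence", "methods", "outcomes", "risk",
  "cohort", "trial", "review", "children"
)

#' Configuration for the synthetic-corpus generator
#'
#' Defaults are the study conditions the analysis is designed around:
#' 1950-2019, linear density ramps of 0.7 to 2.4 acronyms per 100 title
#' words and 0.4 to 4.1 per 100 abstract words, mean title length ramping
#' 9.0 to 14.6 words and mean abstract length 128 to 220 words, a Zipfian
#' acronym vocabulary shared across journals, and small contamination rates
#' for the exclusion filters.
#'
#' @param seed integer seed; identical seed and config give an identical
#'   corpus.
#' @param year_range integer vector `c(start, end)`.
#' @param n_journals number of journals (assigned uniformly).
#' @param papers_per_year papers generated per calendar year.
#' @param title_density_ramp,abstract_density_ramp `c(start, end)` expected
#'   acronyms per 100 words in the first/last year (linear in between).
#' @param title_words_ramp,abstract_words_ramp `c(start, end)` mean words.
#' @param vocab_size number of distinct acronym surfaces.
#' @param zipf_exponent exponent of the Zipf rank-frequency law (> 0).
#' @param length_mix named probabilities over acronym length classes
#'   `"2"`, `"3"`, `"4"`, `"5+"` (three-letter forms are modal, as observed).
#' @param digit_kind_frac fraction of vocabulary surfaces that end in a
#'   digit (the letters-and-numbers kind).
#' @param frac_nonenglish,frac_allcaps_titles,frac_no_abstract contamination
#'   probabilities per record.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             year_range = c(1950L, 2019L),
                             n_journals = 20L,
                             papers_per_year = 200L,
                             title_density_ramp = c(0.7, 2.4),
                             abstract_density_ramp = c(0.4, 4.1),
                             title_words_ramp = c(9.0, 14.6),
                             abstract_words_ramp = c(128, 220),
                             vocab_size = 5000L,
                             zipf_exponent = 1.2,
                             length_mix = c("2" = 0.12, "3" = 0.45,
                                            "4" = 0.25, "5+" = 0.18),
                             digit_kind_frac = 0.15,
                             frac_nonenglish = 0.02,
                             frac_allcaps_titles = 0.01,
                             frac_no_abstract = 0.05) {
  cfg <- list(
    seed = as.integer(seed), year_range = as.integer(year_range),
    n_journals = as.integer(n_journals),
    papers_per_year = as.integer(papers_per_year),
    title_density_ramp = title_density_ramp,
    abstract_density_ramp = abstract_density_ramp,
    title_words_ramp = title_words_ramp,
    abstract_words_ramp = abstract_words_ramp,
    vocab_size = as.integer(vocab_size), zipf_exponent = zipf_exponent,
    length_mix = length_mix / sum(length_mix),
    digit_kind_frac = digit_kind_frac,
    frac_nonenglish = frac_nonenglish,
    frac_allcaps_titles = frac_allcaps_titles,
    frac_no_abstract = frac_no_abstract
  )
  probs <- c(cfg$frac_nonenglish, cfg$frac_allcaps_titles,
             cfg$frac_no_abstract)
  if (any(probs < 0 | probs > 1)) stop("contamination fractions must be in [0,1]")
  if (any(c(title_density_ramp, abstract_density_ramp) < 0) ||
      any(c(title_density_ramp, abstract_density_ramp) > 100)) {
    stop("density ramps must lie in [0, 100] acronyms per 100 words")
  }
  if (zipf_exponent <= 0) stop("zipf_exponent must be > 0")
  class(cfg) <- "synthetic_config"
  cfg
}

# Linear interpolation of a ramp across the year range.
ramp_value <- function(ramp, years, year_range) {
  if (year_range[2] == year_range[1]) return(rep(ramp[1], length(years)))
  frac <- (years - year_range[1]) / (year_range[2] - year_range[1])
  ramp[1] + frac * (ramp[2] - ramp[1])
}

# Distinct uppercase acronym surfaces with the configured length mix; a
# digit_kind_frac share carries a trailing digit. Short lengths (2-3) are
# sampled without replacement from the enumerated space of possible forms,
# because the vocabulary can demand a sizeable share of it; longer surfaces
# are drawn freely and deduplicated (their space is effectively infinite).
make_vocab <- function(cfg) {
  n_class <- stats::setNames(
    as.integer(stats::rmultinom(1, cfg$vocab_size, cfg$length_mix)),
    names(cfg$length_mix)
  )
  gen_short <- function(L, k) {
    pool_letters <- apply(
      expand.grid(rep(list(LETTERS), L), stringsAsFactors = FALSE),
      1, paste, collapse = ""
    )
    pool_digit <- as.vector(outer(
      apply(expand.grid(rep(list(LETTERS), L - 1),
                        stringsAsFactors = FALSE), 1, paste, collapse = ""),
      0:9, paste0
    ))
    k_digit <- min(stats::rbinom(1, k, cfg$digit_kind_frac),
                   length(pool_digit))
    k_letters <- k - k_digit
    if (k_letters > length(pool_letters)) {
      stop("length_mix demands more unique length-", L,
           " surfaces than exist; reduce vocab_size or the short-length mix")
    }
    c(sample(pool_letters, k_letters), sample(pool_digit, k_digit))
  }
  gen_long <- function(k, len_draw) {
    lens <- len_draw(k)
    s <- vapply(lens, function(L) {
      paste(sample(LETTERS, L, replace = TRUE), collapse = "")
    }, character(1))
    digit <- stats::runif(k) < cfg$digit_kind_frac
    if (any(digit)) {
      d <- as.character(sample(0:9, sum(digit), replace = TRUE))
      s[digit] <- paste0(substr(s[digit], 1L, nchar(s[digit]) - 1L), d)
    }
    while (anyDuplicated(s) > 0L) {
      bad <- which(duplicated(s))
      s[bad] <- vapply(len_draw(length(bad)), function(L) {
        paste(sample(LETTERS, L, replace = TRUE), collapse = "")
      }, character(1))
    }
    s
  }
  surfaces <- c(
    gen_short(2L, n_class[["2"]]),
    gen_short(3L, n_class[["3"]]),
    gen_long(n_class[["4"]], function(k) rep(4L, k)),
    gen_long(n_class[["5+"]], function(k) sample(5:7, k, replace = TRUE))
  )
  surfaces <- sample(surfaces)  # shuffle so Zipf rank is independent of length
  prob <- (seq_len(cfg$vocab_size))^(-cfg$zipf_exponent)
  tibble::tibble(
    surface = surfaces,
    length = nchar(surfaces),
    kind = ifelse(stringi::stri_detect_regex(surfaces, "^\\p{L}+$"),
                  "letters_only", "letters_and_numbers"),
    prob = prob / sum(prob)
  )
}

# One field's texts for a block of papers: n_words ~ 2 + Poisson(mean - 2)
# (so the mean is exact and no clean text is empty or one word), acronym
# count ~ Binomial(n_words, density/100) truncated below 60% of words so a
# clean record can never trip the capitals filter.
make_texts <- function(n, mean_words, density, vocab) {
  n_words <- 2L + stats::rpois(n, max(mean_words - 2, 0))
  n_acr <- stats::rbinom(n, n_words, density / 100)
  cap <- pmax(ceiling(0.6 * n_words) - 1L, 0L)
  n_acr <- pmin(n_acr, cap)
  n_fill <- n_words - n_acr
  doc <- c(rep.int(seq_len(n), n_acr), rep.int(seq_len(n), n_fill))
  toks <- c(
    sample(vocab$surface, sum(n_acr), replace = TRUE, prob = vocab$prob),
    sample(FILLER_LEXICON, sum(n_fill), replace = TRUE)
  )
  o <- order(doc, stats::runif(length(doc)))
  vapply(split(toks[o], doc[o]), paste, character(1), collapse = " ",
         USE.NAMES = FALSE)
}

#' Generate a synthetic corpus with ground truth
#'
#' @param config a [synthetic_config()].
#' @return a list with `records` (a record tibble, rows shuffled within
#'   year) and `truth`, itself a list: `per_year` (true densities and mean
#'   word counts per year), `vocab` (the acronym vocabulary with Zipf
#'   probabilities), `contamination` (realized per-reason, per-field
#'   exclusion counts) and `config`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    vocab <- make_vocab(config)
    years <- seq(config$year_range[1], config$year_range[2])
    td <- ramp_value(config$title_density_ramp, years, config$year_range)
    ad <- ramp_value(config$abstract_density_ramp, years, config$year_range)
    tw <- ramp_value(config$title_words_ramp, years, config$year_range)
    aw <- ramp_value(config$abstract_words_ramp, years, config$year_range)
    n <- config$papers_per_year
    blocks <- vector("list", length(years))
    contam_noneng <- contam_caps <- contam_noabs <- 0L
    for (i in seq_along(years)) {
      if (n == 0L) next
      y <- years[i]
      titles <- make_texts(n, tw[i], td[i], vocab)
      abstracts <- make_texts(n, aw[i], ad[i], vocab)
      status <- sample(
        c("clean", "noneng", "allcaps", "noabs"), n, replace = TRUE,
        prob = c(1 - config$frac_nonenglish - config$frac_allcaps_titles -
                   config$frac_no_abstract,
                 config$frac_nonenglish, config$frac_allcaps_titles,
                 config$frac_no_abstract)
      )
      language <- ifelse(status == "noneng",
                         sample(c("fre", "ger", "spa"), n, replace = TRUE),
                         "eng")
      titles[status == "allcaps"] <- toupper(titles[status == "allcaps"])
      abstracts[status == "noabs"] <- NA_character_
      contam_noneng <- contam_noneng + sum(status == "noneng")
      contam_caps <- contam_caps + sum(status == "allcaps")
      contam_noabs <- contam_noabs + sum(status == "noabs")
      day0 <- as.Date(sprintf("%d-01-01", y))
      ndays <- as.integer(as.Date(sprintf("%d-12-31", y)) - day0)
      pub_date <- day0 + sample.int(ndays + 1L, n, replace = TRUE) - 1L
      types <- lapply(sample(c("Journal Article", "Clinical Trial",
                               "Case Reports", "Editorial"), n,
                             replace = TRUE,
                             prob = c(0.7, 0.1, 0.1, 0.1)),
                      function(t) unique(c("Journal Article", t)))
      blocks[[i]] <- tibble::tibble(
        paper_id = sprintf("S%04d%05d", y, seq_len(n)),
        year = y,
        pub_date = pub_date,
        journal_id = sprintf("J%03d", sample.int(config$n_journals, n,
                                                 replace = TRUE)),
        title = titles,
        abstract = abstracts,
        language = language,
        article_types = types
      )
    }
    records <- dplyr::bind_rows(blocks)
    if (nrow(records) == 0L) records <- empty_records()
    truth <- list(
      per_year = tibble::tibble(
        year = years, title_density = td, abstract_density = ad,
        title_words = tw, abstract_words = aw
      ),
      vocab = vocab,
      contamination = tibble::tibble(
        reason = c("non_english", "non_english", "mostly_capitals",
                   "no_abstract"),
        field = c("title", "abstract", "title", "abstract"),
        count = c(contam_noneng, contam_noneng, contam_caps, contam_noabs)
      ),
      config = config
    )
    list(records = records, truth = truth)
  })
}

#' Simulate per-journal coining cohorts with exponential re-use times
#'
#' For each cohort year, `n_per_cohort` new acronym surfaces are coined at a
#' uniform date within the year in a uniformly chosen journal, and re-used
#' after an exponential waiting time at the cohort's hazard. Journals stop
#' publishing at `journal_end` (a `Date`, or `NULL` for no censoring);
#' waiting times that overrun the journal's end are right-censored there.
#'
#' @param cohort_years integer vector of coining years.
#' @param n_per_cohort records per cohort (default 500).
#' @param hazard re-use hazard in events per acronym-year: a scalar, or a
#'   vector matched to `cohort_years`. Default 0.105/yr, the hazard at which
#'   10% of a cohort is re-used within one year.
#' @param hazard_by_length optional named hazards over length classes
#'   `"2"`, `"3"`, `"4"`, `"5+"` (overrides `hazard`; used to emulate
#'   shorter acronyms being re-used more).
#' @param length_mix probabilities over length classes.
#' @param n_journals number of journals.
#' @param journal_end common last-issue `Date` for every journal, or `NULL`.
#' @param seed integer seed.
#' @return a tibble shaped like [build_reuse_records()] output, with an
#'   attribute `"truth"` holding the per-cohort hazards and implied true t10
#'   (`-log(0.9) / hazard`).
#' @export
generate_reuse_cohorts <- function(cohort_years, n_per_cohort = 500L,
                                   hazard = 0.105, hazard_by_length = NULL,
                                   length_mix = c("2" = 0.2, "3" = 0.45,
                                                  "4" = 0.2, "5+" = 0.15),
                                   n_journals = 20L, journal_end = NULL,
                                   seed = 1L) {
  stopifnot(all(hazard > 0))
  hz <- rep_len(hazard, length(cohort_years))
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_along(cohort_years), function(i) {
      y <- cohort_years[i]
      n <- n_per_cohort
      if (n == 0L) return(NULL)
      day0 <- as.Date(sprintf("%d-01-01", y))
      first_use <- day0 + sample.int(365L, n, replace = TRUE) - 1L
      cls <- sample(names(length_mix), n, replace = TRUE, prob = length_mix)
      len <- unname(c("2" = 2L, "3" = 3L, "4" = 4L, "5+" = 5L)[cls])
      rate <- if (is.null(hazard_by_length)) rep(hz[i], n) else
        unname(hazard_by_length[cls])
      wait <- stats::rexp(n, rate = rate)
      censor <- if (is.null(journal_end)) rep(Inf, n) else
        pmax(as.numeric(journal_end - first_use) / DAYS_PER_YEAR, 0)
      event <- wait <= censor
      tibble::tibble(
        surface = sprintf("SYN%d%05d", y, seq_len(n)),
        journal_id = sprintf("J%03d", sample.int(n_journals, n,
                                                 replace = TRUE)),
        first_use_date = first_use,
        first_use_year = as.integer(y),
        time_to_event = pmin(wait, censor),
        event = event,
        acronym_length = len
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "truth") <- tibble::tibble(
      cohort_year = cohort_years, hazard = hz, true_t10 = -log(0.9) / hz
    )
    out
  })
}
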