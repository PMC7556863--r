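# Acronym detection: tokenization and the character-case rule.
#
# An acronym is a token of >= `min_length` characters in which upper-case
# letters make up at least half of the characters. Characters include digits
# and internal punctuation, so "mRNA" (3 upper of 4) qualifies while "N95"
# (1 of 3) does not.

#' Strip enclosing punctuation and possessive suffixes from raw tokens
#'
#' Leading/trailing punctuation and symbol characters (quotes, brackets,
#' commas, periods, semicolons, ...) are removed; internal hyphens, slashes
#' and digits are kept. A trailing possessive `'s` is dropped because it is
#' grammatical, not part of the term.
#' @param tokens character vector of raw whitespace-delimited runs.
#' @return character vector of cleaned surfaces (possibly empty strings).
#' @keywords internal
strip_token <- function(tokens) {
  x <- stringi::stri_replace_all_regex(
    tokens, "^[\\p{P}\\p{S}]+|[\\p{P}\\p{S}]+$", ""
  )
  stringi::stri_replace_last_regex(x, "['’]s$", "")
}

#' Tokenize free text
#'
#' Splits on whitespace, strips enclosing punctuation from each run and drops
#' runs that were punctuation only. The word count of a text is the length of
#' its token vector.
#'
#' @param text a single character string (`NA` is treated as empty).
#' @return character vector of token surfaces, in order of appearance.
#' @examples
#' tokenize("the CNNT, the CRN,")  # "the" "CNNT" "the" "CRN"
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text)) return(character(0))
  raw <- stringi::stri_split_regex(text, "\\s+", omit_empty = TRUE)[[1]]
  out <- strip_token(raw)
  out[out != ""]
}

# Vectorized per-surface classification. Works on a vector of already
# stripped token surfaces; returns a data frame of per-token facts.
# `denominator = "all"` counts every character of the surface;
# "alphanumeric" restricts the denominator to letters and digits.
token_facts <- function(surface, denominator = c("all", "alphanumeric")) {
  denominator <- match.arg(denominator)
  n_upper <- stringi::stri_count_charclass(surface, "[\\p{Lu}]")
  n_chars <- if (denominator == "all") {
    stringi::stri_length(surface)
  } else {
    stringi::stri_count_charclass(surface, "[\\p{L}\\p{N}]")
  }
  data.frame(
    surface = surface,
    n_chars = stringi::stri_length(surface),
    n_denom = n_chars,
    n_upper = n_upper,
    letters_only = stringi::stri_detect_regex(surface, "^\\p{L}+$"),
    has_alpha = stringi::stri_detect_charclass(surface, "[\\p{L}]"),
    has_lower = stringi::stri_detect_charclass(surface, "[\\p{Ll}]"),
    stringsAsFactors = FALSE
  )
}

#' Is a token an acronym?
#'
#' A token is an acronym when it has at least `min_length` characters and at
#' least half of its characters are upper-case letters. Digits and internal
#' punctuation count toward the denominator by default.
#'
#' @param token character vector of token surfaces (as produced by
#'   [tokenize()]).
#' @param min_length minimum character count (default 2; single capitals such
#'   as initials are never acronyms).
#' @param denominator `"all"` (every character of the surface, the default) or
#'   `"alphanumeric"` (letters and digits only).
#' @return logical vector.
#' @examples
#' is_acronym(c("mRNA", "N95", "BRCA1", "laser"))  # TRUE FALSE TRUE FALSE
#' @export
is_acronym <- function(token, min_length = 2L,
                       denominator = c("all", "alphanumeric")) {
  tf <- token_facts(token, denominator = match.arg(denominator))
  tf$n_chars >= min_length & tf$n_denom > 0L & 2L * tf$n_upper >= tf$n_denom
}

#' Classify a token as an acronym with length and kind
#'
#' @inheritParams is_acronym
#' @return a tibble with one row per input token that is an acronym:
#'   `surface`, `length` (character count) and `kind`
#'   (`"letters_only"` when every character is an alphabetic letter, else
#'   `"letters_and_numbers"`). Non-acronym tokens yield no row.
#' @examples
#' classify_tokens(c("DNA", "CD4", "of"))
#' @export
classify_tokens <- function(token, min_length = 2L,
                            denominator = c("all", "alphanumeric")) {
  tf <- token_facts(token, denominator = match.arg(denominator))
  acr <- tf$n_chars >= min_length & tf$n_denom > 0L &
    2L * tf$n_upper >= tf$n_denom
  tibble::tibble(
    surface = tf$surface[acr],
    length = tf$n_chars[acr],
    kind = as.character(ifelse(tf$letters_only[acr],
                               "letters_only", "letters_and_numbers"))
  )
}

# Length stratum labels used throughout: 2, 3, 4, 5+.
length_stratum <- function(n) {
  ifelse(n >= 5L, "5+", as.character(n))
}

#' Count words and acronyms in one text
#'
#' @param text a single character string.
#' @inheritParams is_acronym
#' @return a list with `n_words`, `n_acronym_tokens`, `by_length` (named
#'   vector over strata `2`, `3`, `4`, `5+`), `by_kind` (named vector over
#'   `letters_only`, `letters_and_numbers`), `density` (acronyms per 100
#'   words, `NA` for empty text) and `surfaces` (in order of appearance,
#'   duplicates retained).
#' @examples
#' count_acronyms("The DNA of X")  # 4 words, 1 acronym, density 25
#' @export
count_acronyms <- function(text, min_length = 2L,
                           denominator = c("all", "alphanumeric")) {
  toks <- tokenize(text)
  cls <- classify_tokens(toks, min_length = min_length,
                         denominator = denominator)
  by_length <- c("2" = 0L, "3" = 0L, "4" = 0L, "5+" = 0L)
  tab_l <- table(length_stratum(cls$length))
  by_length[names(tab_l)] <- as.integer(tab_l)
  by_kind <- c(letters_only = 0L, letters_and_numbers = 0L)
  tab_k <- table(cls$kind)
  by_kind[names(tab_k)] <- as.integer(tab_k)
  n_words <- length(toks)
  list(
    n_words = n_words,
    n_acronym_tokens = nrow(cls),
    by_length = by_length,
    by_kind = by_kind,
    density = if (n_words > 0) 100 * nrow(cls) / n_words else NA_real_,
    surfaces = cls$surface
  )
}

#' Fraction of words written entirely in capitals
#'
#' The fraction of tokens that contain at least one alphabetic character and
#' whose alphabetic characters are all upper case. Used by the exclusion
#' filter for titles/abstracts set largely in capitals, where acronyms cannot
#' be distinguished from ordinary words.
#'
#' @param text character vector of texts.
#' @return numeric vector of proportions in `[0, 1]`; 0 for empty text.
#' @examples
#' fraction_capital_words("DNA damage in THE CELL")  # 0.6
#' @export
fraction_capital_words <- function(text) {
  vapply(text, function(tx) {
    toks <- tokenize(tx)
    if (length(toks) == 0L) return(0)
    tf <- token_facts(toks)
    mean_caps <- sum(tf$has_alpha & !tf$has_lower) / length(toks)
    mean_caps
  }, numeric(1), USE.NAMES = FALSE)
}

# Fast corpus path: per-document token statistics for a character vector of
# texts. Computes classification on unique surfaces only (corpora repeat the
# same words constantly) and aggregates back per document with tabulate().
# `mask` is a set of surfaces never counted as acronyms (still counted as
# words), used by the sensitivity analysis that removes the most popular
# acronyms.
acronym_doc_stats <- function(texts, min_length = 2L,
                              denominator = c("all", "alphanumeric"),
                              mask = NULL) {
  denominator <- match.arg(denominator)
  n_doc <- length(texts)
  zeros <- integer(n_doc)
  out <- data.frame(
    n_words = zeros, n_acronyms = zeros,
    len2 = zeros, len3 = zeros, len4 = zeros, len5p = zeros,
    letters_only = zeros, letters_numbers = zeros,
    n_caps_words = zeros
  )
  if (n_doc == 0L) return(out)
  texts[is.na(texts)] <- ""
  toks <- stringi::stri_split_regex(texts, "\\s+", omit_empty = TRUE)
  doc <- rep.int(seq_len(n_doc), lengths(toks))
  raw <- unlist(toks, use.names = FALSE)
  if (length(raw) == 0L) return(out)
  # classify unique raw tokens only: corpora repeat the same words constantly
  uraw <- unique(raw)
  ridx <- match(raw, uraw)
  ux <- strip_token(uraw)
  word <- ux != ""  # punctuation-only runs are not words
  keep <- word[ridx]
  doc <- doc[keep]
  idx <- ridx[keep]
  if (length(doc) == 0L) return(out)
  tf <- token_facts(ux, denominator = denominator)
  tf$n_chars[!word] <- 0L  # never counted; masked out by `keep`
  u_acr <- tf$n_chars >= min_length & tf$n_denom > 0L &
    2L * tf$n_upper >= tf$n_denom
  if (!is.null(mask)) u_acr <- u_acr & !(ux %in% mask)
  u_caps <- tf$has_alpha & !tf$has_lower
  u_len <- tf$n_chars
  u_letters <- tf$letters_only

  acr <- u_acr[idx]
  out$n_words <- tabulate(doc, nbins = n_doc)
  out$n_acronyms <- tabulate(doc[acr], nbins = n_doc)
  out$n_caps_words <- tabulate(doc[u_caps[idx]], nbins = n_doc)
  lens <- u_len[idx]
  out$len2 <- tabulate(doc[acr & lens == 2L], nbins = n_doc)
  out$len3 <- tabulate(doc[acr & lens == 3L], nbins = n_doc)
  out$len4 <- tabulate(doc[acr & lens == 4L], nbins = n_doc)
  out$len5p <- tabulate(doc[acr & lens >= 5L], nbins = n_doc)
  lo <- u_letters[idx]
  out$letters_only <- tabulate(doc[acr & lo], nbins = n_doc)
  out$letters_numbers <- tabulate(doc[acr & !lo], nbins = n_doc)
  out
}

#' Extract every acronym occurrence from a corpus
#'
#' @param records a tibble of paper records (see [parse_medline_xml()]).
#' @param field `"title"`, `"abstract"` or `"both"`.
#' @inheritParams is_acronym
#' @return a tibble with one row per acronym token occurrence: `paper_id`,
#'   `field`, `surface`, `length`, `kind`. Duplicate occurrences within a
#'   paper are retained.
#' @export
extract_acronyms <- function(records, field = c("both", "title", "abstract"),
                             min_length = 2L,
                             denominator = c("all", "alphanumeric")) {
  field <- match.arg(field)
  denominator <- match.arg(denominator)
  fields <- if (field == "both") c("title", "abstract") else field
  parts <- lapply(fields, function(f) {
    texts <- records[[f]]
    texts[is.na(texts)] <- ""
    toks <- stringi::stri_split_regex(texts, "\\s+", omit_empty = TRUE)
    doc <- rep.int(seq_len(nrow(records)), lengths(toks))
    raw <- unlist(toks, use.names = FALSE)
    if (length(raw) == 0L) {
      return(tibble::tibble(paper_id = character(), field = character(),
                            surface = character(), length = integer(),
                            kind = character()))
    }
    uraw <- unique(raw)
    idx <- match(raw, uraw)
    ux <- strip_token(uraw)
    tf <- token_facts(ux, denominator = denominator)
    u_acr <- ux != "" & tf$n_chars >= min_length & tf$n_denom > 0L &
      2L * tf$n_upper >= tf$n_denom
    acr <- u_acr[idx]
    tibble::tibble(
      paper_id = records$paper_id[doc[acr]],
      field = f,
      surface = ux[idx[acr]],
      length = tf$n_chars[idx[acr]],
      kind = as.character(ifelse(tf$letters_only[idx[acr]],
                                 "letters_only", "letters_and_numbers"))
    )
  })
  dplyr::bind_rows(parts)
}
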