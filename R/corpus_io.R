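# Corpus I/O: MEDLINE/PubMed citation XML -> tidy records, a JSON-lines
# intermediate format, deduplication, and a TSV summary export.

# Canonical empty record tibble; every reader/generator returns this shape.
empty_records <- function() {
  tibble::tibble(
    paper_id = character(),
    year = integer(),
    pub_date = as.Date(character()),
    journal_id = character(),
    title = character(),
    abstract = character(),
    language = character(),
    article_types = list()
  )
}

MONTHS3 <- c(jan = 1L, feb = 2L, mar = 3L, apr = 4L, may = 5L, jun = 6L,
             jul = 7L, aug = 8L, sep = 9L, oct = 10L, nov = 11L, dec = 12L)

month_number <- function(m) {
  if (is.null(m) || length(m) == 0L || is.na(m)) return(NA_integer_)
  if (is.numeric(m)) return(as.integer(m))
  m <- tolower(as.character(m))
  if (stringi::stri_detect_regex(m, "^\\d+$")) return(as.integer(m))
  key <- substr(m, 1L, 3L)
  if (key %in% names(MONTHS3)) MONTHS3[[key]] else NA_integer_
}

#' Resolve a publication date from raw MEDLINE date parts
#'
#' Returns the earliest defensible calendar date: a missing month is imputed
#' to January and a missing day to the 1st, so downstream re-use intervals
#' are conservative and reproducible. Free-text `medline_date` ranges
#' ("1998 Dec-1999 Jan") resolve to the earliest year/month mentioned.
#'
#' @param parts a named list with any of `year`, `month` (name or number),
#'   `day`, `medline_date` (free text).
#' @return a `Date`, or `NA` (the missing-date sentinel) when no year is
#'   recoverable.
#' @examples
#' resolve_pub_date(list(year = 2005, month = "Jul"))  # 2005-07-01
#' resolve_pub_date(list())                            # NA
#' @export
resolve_pub_date <- function(parts) {
  year <- suppressWarnings(as.integer(parts$year))
  month <- month_number(parts$month)
  day <- suppressWarnings(as.integer(parts$day))
  if ((length(year) == 0L || is.na(year)) &&
      !is.null(parts$medline_date) && !is.na(parts$medline_date)) {
    md <- as.character(parts$medline_date)
    ym <- stringi::stri_match_first_regex(md, "(\\d{4})")
    if (!is.na(ym[1, 2])) year <- as.integer(ym[1, 2])
    mm <- stringi::stri_match_first_regex(
      tolower(md), "(jan|feb|mar|apr|may|jun|jul|aug|sep|oct|nov|dec)")
    if (!is.na(mm[1, 2])) month <- MONTHS3[[mm[1, 2]]]
  }
  if (length(year) == 0L || is.na(year)) return(as.Date(NA))
  if (is.na(month)) month <- 1L
  if (length(day) == 0L || is.na(day)) day <- 1L
  out <- suppressWarnings(as.Date(sprintf("%04d-%02d-%02d", year, month, day)))
  if (is.na(out)) out <- as.Date(sprintf("%04d-01-01", year))
  out
}

xml_text1 <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
}

# One MedlineCitation node -> one-row record, or NULL when essential fields
# are malformed (missing PMID or title element).
parse_citation <- function(cit) {
  pmid <- xml_text1(cit, ".//PMID")
  title <- xml_text1(cit, ".//Article/ArticleTitle")
  if (is.na(pmid) || is.na(title)) return(NULL)
  abs_nodes <- xml2::xml_find_all(cit, ".//Article/Abstract/AbstractText")
  abstract <- if (length(abs_nodes) == 0L) NA_character_ else
    paste(xml2::xml_text(abs_nodes), collapse = " ")
  language <- xml_text1(cit, ".//Article/Language")
  journal <- xml_text1(cit, ".//MedlineJournalInfo/NlmUniqueID")
  if (is.na(journal)) journal <- xml_text1(cit, ".//MedlineJournalInfo/MedlineTA")
  if (is.na(journal)) journal <- xml_text1(cit, ".//Article/Journal/Title")
  types <- xml2::xml_text(
    xml2::xml_find_all(cit, ".//Article/PublicationTypeList/PublicationType"))
  # date precedence: electronic article date > journal issue date > entry date
  date_node <- xml2::xml_find_first(cit, ".//Article/ArticleDate")
  if (inherits(date_node, "xml_missing"))
    date_node <- xml2::xml_find_first(cit, ".//Article/Journal/JournalIssue/PubDate")
  if (inherits(date_node, "xml_missing"))
    date_node <- xml2::xml_find_first(cit, ".//DateCompleted")
  parts <- list()
  if (!inherits(date_node, "xml_missing")) {
    parts <- list(
      year = xml_text1(date_node, "./Year"),
      month = xml_text1(date_node, "./Month"),
      day = xml_text1(date_node, "./Day"),
      medline_date = xml_text1(date_node, "./MedlineDate")
    )
  }
  pdate <- resolve_pub_date(parts)
  tibble::tibble(
    paper_id = pmid,
    year = if (is.na(pdate)) NA_integer_ else
      as.integer(format(pdate, "%Y")),
    pub_date = pdate,
    journal_id = journal,
    title = title,
    abstract = abstract,
    language = language,
    article_types = list(types)
  )
}

#' Parse MEDLINE/PubMed citation XML into paper records
#'
#' Reads a baseline-style citation XML file (optionally gzip-compressed;
#' libxml2 decompresses transparently) and returns one record per citation,
#' in file order. Malformed citations are skipped with a warning rather than
#' aborting the parse; the number skipped is available as
#' `attr(records, "n_skipped")` so that parsed = kept + skipped exactly.
#'
#' @param path path to a MEDLINE citation XML file.
#' @return a tibble with columns `paper_id`, `year`, `pub_date`,
#'   `journal_id`, `title`, `abstract` (`NA` when the citation has none),
#'   `language`, `article_types` (list-column).
#' @export
parse_medline_xml <- function(path) {
  if (!file.exists(path)) stop("cannot read MEDLINE XML: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("not parseable as XML (", conditionMessage(e), "): ", path)
  })
  cits <- xml2::xml_find_all(doc, "//MedlineCitation")
  rows <- vector("list", length(cits))
  n_skipped <- 0L
  for (i in seq_along(cits)) {
    row <- parse_citation(cits[[i]])
    if (is.null(row)) {
      n_skipped <- n_skipped + 1L
      warning("skipping malformed citation #", i, call. = FALSE)
    } else {
      rows[[i]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) out <- empty_records()
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Remove records with duplicated identifiers
#'
#' Keeps the first occurrence of each `paper_id` in input order (a
#' deterministic, order-stable policy).
#'
#' @param records a record tibble.
#' @return a list with `records` (deduplicated tibble) and `n_removed`.
#' @export
dedupe_records <- function(records) {
  dup <- duplicated(records$paper_id)
  list(records = records[!dup, , drop = FALSE], n_removed = sum(dup))
}

#' Write records to / read records from the JSON-lines intermediate format
#'
#' One complete record per line as a self-describing JSON object, so large
#' corpora stream without loading into memory. `read_records(write_records(x))`
#' is the identity field-for-field, including absent abstracts and non-ASCII
#' text.
#'
#' @param records a record tibble.
#' @param path file path.
#' @return `write_records` returns `path` invisibly; `read_records` returns a
#'   record tibble and raises an error naming the line number of any corrupt
#'   line.
#' @export
write_records <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    obj <- list(
      paper_id = records$paper_id[i],
      year = records$year[i],
      pub_date = if (is.na(records$pub_date[i])) NULL else
        format(records$pub_date[i], "%Y-%m-%d"),
      journal_id = records$journal_id[i],
      title = records$title[i],
      abstract = if (is.na(records$abstract[i])) NULL else records$abstract[i],
      language = records$language[i],
      article_types = records$article_types[[i]]
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                digits = NA), con, useBytes = FALSE)
  }
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(obj) || is.null(obj$paper_id)) {
      stop("corrupt record at line ", i, " of ", path)
    }
    rows[[i]] <- tibble::tibble(
      paper_id = as.character(obj$paper_id),
      year = if (is.null(obj$year)) NA_integer_ else as.integer(obj$year),
      pub_date = if (is.null(obj$pub_date)) as.Date(NA) else
        as.Date(obj$pub_date),
      journal_id = if (is.null(obj$journal_id)) NA_character_ else
        as.character(obj$journal_id),
      title = if (is.null(obj$title)) NA_character_ else
        as.character(obj$title),
      abstract = if (is.null(obj$abstract)) NA_character_ else
        as.character(obj$abstract),
      language = if (is.null(obj$language)) NA_character_ else
        as.character(obj$language),
      article_types = list(as.character(unlist(obj$article_types)))
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) out <- empty_records()
  out
}

#' Export a flat per-record word-count summary as TSV
#'
#' Columns: `paper_id`, `year`, `journal_id`, `language`, `n_title_words`,
#' `n_abstract_words` — a spreadsheet-friendly view of the corpus.
#'
#' @param records a record tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_summary_tsv <- function(records, path) {
  tw <- acronym_doc_stats(records$title)$n_words
  aw <- acronym_doc_stats(records$abstract)$n_words
  df <- data.frame(
    paper_id = records$paper_id,
    year = records$year,
    journal_id = records$journal_id,
    language = records$language,
    n_title_words = tw,
    n_abstract_words = aw
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
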