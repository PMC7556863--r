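# Shared fixtures built in code.

# A minimal record tibble with sensible defaults, overridable per field.
make_records <- function(n = 1L, paper_id = as.character(seq_len(n)),
                         year = rep(2000L, n),
                         pub_date = as.Date(sprintf("%d-06-15", year)),
                         journal_id = rep("J001", n),
                         title = rep("a plain title here", n),
                         abstract = rep("a plain abstract with words", n),
                         language = rep("eng", n),
                         article_types = rep(list("Journal Article"), n)) {
  tibble::tibble(
    paper_id = paper_id, year = year, pub_date = pub_date,
    journal_id = journal_id, title = title, abstract = abstract,
    language = language, article_types = article_types
  )
}

# Independent character-counting oracle for the acronym rule: loops over the
# characters of one token, ASCII classification only (fixtures are ASCII).
oracle_is_acronym <- function(surface, min_length = 2L) {
  chars <- strsplit(surface, "", fixed = TRUE)[[1]]
  n_upper <- sum(chars %in% LETTERS)
  length(chars) >= min_length && n_upper >= length(chars) / 2
}

# Independent brute-force product-limit estimator: at each distinct event
# time, multiply by (1 - deaths / at-risk).
oracle_km <- function(time, event) {
  ev_times <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    at_risk <- sum(time >= t)
    deaths <- sum(event & time == t)
    s <- s * (1 - deaths / at_risk)
    out$surv[i] <- s
  }
  out
}

# A small MEDLINE-style citation XML string.
medline_xml <- function(citations) {
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n<PubmedArticleSet>\n",
    paste(citations, collapse = "\n"),
    "\n</PubmedArticleSet>\n"
  )
}

citation_xml <- function(pmid = "100", title = "The DNA study",
                         abstract = NULL, year = "1990", month = NULL,
                         language = "eng", journal = "J0001",
                         types = "Journal Article") {
  abs_xml <- if (is.null(abstract)) "" else paste0(
    "<Abstract><AbstractText>", abstract, "</AbstractText></Abstract>")
  month_xml <- if (is.null(month)) "" else paste0("<Month>", month, "</Month>")
  type_xml <- paste0(
    "<PublicationTypeList>",
    paste0("<PublicationType>", types, "</PublicationType>", collapse = ""),
    "</PublicationTypeList>")
  paste0(
    "<PubmedArticle><MedlineCitation><PMID>", pmid, "</PMID>",
    "<Article><ArticleTitle>", title, "</ArticleTitle>", abs_xml,
    "<Language>", language, "</Language>",
    "<Journal><JournalIssue><PubDate><Year>", year, "</Year>", month_xml,
    "</PubDate></JournalIssue></Journal>", type_xml,
    "</Article>",
    "<MedlineJournalInfo><NlmUniqueID>", journal, "</NlmUniqueID>",
    "</MedlineJournalInfo>",
    "</MedlineCitation></PubmedArticle>")
}
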