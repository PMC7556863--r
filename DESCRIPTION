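Package: acrotrend
Title: Trends in Acronym Use in Scientific Titles and Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for studying acronym use in the
    biomedical literature. Parses MEDLINE/PubMed citation XML into tidy
    records, detects acronyms with a character-case rule (a token of two or
    more characters in which at least half the characters are upper-case
    letters), applies record-level exclusion filters with conserved
    accounting, and computes corpus statistics: annual mean acronym
    densities per 100 words with confidence intervals, length and kind
    stratifications, top-N rankings, the acronym frequency spectrum,
    time-to-re-use survival analysis within journals (Kaplan-Meier, with
    the time for 10% of newly coined acronyms to be re-used), and Bayesian
    upper bounds on audit error rates from a Beta posterior. Includes a
    synthetic-corpus generator with known ground truth (density and
    word-length ramps, Zipfian vocabulary, journal re-use hazards,
    contamination) so the whole pipeline is testable without bulk
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    stringi,
    survival,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
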