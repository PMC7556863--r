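test_that("annual density is the mean of per-paper ratios", {
  rec <- make_records(2, year = c(1990L, 1990L),
                      title = c("one two three four", "DNA two three four"))
  tr <- annual_trends(rec, "title")
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$mean_density, mean(c(0, 25)))  # 12.5 per 100 words
  expect_equal(tr$mean_words, 4)
  expect_true(tr$ci_low <= tr$mean_density && tr$mean_density <= tr$ci_high)
})

test_that("single-paper years get a degenerate, flagged interval", {
  rec <- make_records(1, year = 1991L, title = "DNA in one title")
  tr <- annual_trends(rec, "title")
  expect_true(tr$degenerate_ci)
  expect_equal(tr$ci_low, tr$mean_density)
  expect_equal(tr$ci_high, tr$mean_density)
})

test_that("years with no eligible records are omitted, not zero-filled", {
  rec <- make_records(2, year = c(1990L, 1995L))
  tr <- annual_trends(rec, "title")
  expect_identical(tr$year, c(1990L, 1995L))
})

test_that("annual_trends agrees with a naive per-paper loop", {
  g <- generate_corpus(synthetic_config(seed = 21, papers_per_year = 10,
                                        year_range = c(1990L, 1994L),
                                        frac_nonenglish = 0,
                                        frac_allcaps_titles = 0,
                                        frac_no_abstract = 0))
  rec <- g$records
  for (field in c("title", "abstract")) {
    tr <- annual_trends(rec, field)
    for (y in unique(rec$year)) {
      texts <- rec[[field]][rec$year == y]
      dens <- words <- numeric(0)
      for (tx in texts) {
        toks <- tokenize(tx)
        if (length(toks) == 0) next
        n_acr <- sum(vapply(toks, oracle_is_acronym, logical(1)))
        dens <- c(dens, 100 * n_acr / length(toks))
        words <- c(words, length(toks))
      }
      row <- tr[tr$year == y, ]
      expect_equal(row$mean_density, mean(dens))
      expect_equal(row$mean_words, mean(words))
      expect_equal(row$ci_low,
                   mean(dens) - 1.96 * sd(dens) / sqrt(length(dens)))
    }
  }
})

test_that("density strata are bounded and sum to the total density", {
  g <- generate_corpus(synthetic_config(seed = 4, papers_per_year = 30,
                                        year_range = c(2000L, 2004L)))
  tr <- annual_trends(filter_corpus(g$records)$title_kept, "title")
  expect_true(all(tr$mean_density >= 0 & tr$mean_density <= 100))
  expect_equal(tr$len2_density + tr$len3_density + tr$len4_density +
                 tr$len5p_density, tr$mean_density)
  expect_equal(tr$letters_only_density + tr$letters_numbers_density,
               tr$mean_density)
})

test_that("top_acronyms ranks by count then lexicographically", {
  rec <- make_records(3, title = c("DNA and RNA", "DNA here now",
                                   "CI DNA study"))
  top <- top_acronyms(rec, n = 2, field = "title")
  expect_identical(top$surface, c("DNA", "CI"))
  expect_identical(top$count, c(3L, 1L))
  full <- top_acronyms(rec, n = 100, field = "title")
  expect_identical(full$surface, c("DNA", "CI", "RNA"))  # tie broken C < R
  expect_error(top_acronyms(rec, n = 0), "n must be")
  # case-sensitive exact match
  rec2 <- make_records(1, title = "mRNA MRNA mRNA study")
  expect_identical(top_acronyms(rec2, n = 1, field = "title")$surface, "mRNA")
  # a year with no acronyms gives an empty ranking
  expect_identical(nrow(top_acronyms(make_records(1), n = 5, year = 2000L)),
                   0L)
})

test_that("masking the most popular acronyms only lowers densities", {
  g <- generate_corpus(synthetic_config(seed = 13, papers_per_year = 50,
                                        year_range = c(2000L, 2009L)))
  rec <- filter_corpus(g$records)$title_kept
  t0 <- trends_excluding_top(rec, "title", k = 0)
  expect_equal(t0, annual_trends(rec, "title"))  # k = 0 is the identity
  t100 <- trends_excluding_top(rec, "title", k = 100)
  expect_true(all(t100$mean_density < t0$mean_density))
  # pointwise monotone in k
  t200 <- trends_excluding_top(rec, "title", k = 200)
  expect_true(all(t200$mean_density <= t100$mean_density))
  # one surface carrying all acronyms, masked -> all densities zero
  rec1 <- make_records(2, year = c(1990L, 1991L),
                       title = c("DNA alpha beta", "DNA gamma delta"))
  tm <- trends_excluding_top(rec1, "title", k = 1)
  expect_true(all(tm$mean_density == 0))
})

test_that("article-type series include a record under each of its types", {
  rec <- make_records(2, year = c(2000L, 2000L),
                      title = c("DNA one two three", "no caps here"),
                      article_types = list(c("Journal Article", "Editorial"),
                                           "Journal Article"))
  out <- trends_by_article_type(rec, "title",
                                c("Journal Article", "Editorial"))
  expect_identical(out[["Journal Article"]]$n_papers, 2L)
  expect_identical(out[["Editorial"]]$n_papers, 1L)
  expect_warning(
    empty <- trends_by_article_type(rec, "title", "Letter"),
    "no records")
  expect_identical(nrow(empty$Letter), 0L)
})

test_that("frequency spectrum fractions and three-letter coverage", {
  # counts {AB:1, CD:1, EF:3} -> frac_once = 2/3
  rec <- make_records(1, title = "AB CD EF EF EF", abstract = NA_character_)
  sp <- frequency_spectrum(rec)
  expect_identical(sp$total_unique, 3L)
  expect_equal(sp$frac_once, 2 / 3)
  expect_equal(sp$frac_2_to_10, 1 / 3)
  expect_equal(sp$frac_gt_10000, 0)
  expect_identical(sp$possible_three_letter, 17576L)
  expect_identical(N_THREE_LETTER_FORMS, 17576L)

  # every three-letter combination exactly once -> coverage 1.0
  all3 <- apply(expand.grid(LETTERS, LETTERS, LETTERS), 1, paste,
                collapse = "")
  chunks <- split(all3, ceiling(seq_along(all3) / 200))
  rec3 <- make_records(length(chunks),
                       title = vapply(chunks, paste, character(1),
                                      collapse = " "),
                       abstract = NA_character_)
  sp3 <- frequency_spectrum(rec3)
  expect_equal(sp3$three_letter_coverage, 1.0)
  # mixed-case and digit-bearing surfaces never count toward coverage
  spm <- frequency_spectrum(make_records(1, title = "mRNA CD4 ABC",
                                         abstract = NA_character_))
  expect_equal(spm$three_letter_coverage, 1 / 17576)
})

test_that("annual word counts are per-paper means with empty years omitted", {
  rec <- make_records(2, year = c(1990L, 1990L),
                      title = c("one two three", "one two three four five"))
  wc <- annual_word_counts(rec, "title")
  expect_equal(wc$mean_words, 4)
  rec2 <- make_records(1, year = 1990L, abstract = NA_character_)
  expect_identical(nrow(annual_word_counts(rec2, "abstract")), 0L)
})
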