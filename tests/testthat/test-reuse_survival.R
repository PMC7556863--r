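reuse_corpus <- function(...) {
  # small corpus with explicit dates/journals for re-use bookkeeping
  rows <- list(...)
  make_records(
    length(rows),
    paper_id = vapply(rows, `[[`, character(1), 1),
    pub_date = as.Date(vapply(rows, `[[`, character(1), 2)),
    year = as.integer(substr(vapply(rows, `[[`, character(1), 2), 1, 4)),
    journal_id = vapply(rows, `[[`, character(1), 3),
    title = vapply(rows, `[[`, character(1), 4),
    abstract = NA_character_
  )
}

test_that("re-use and censoring times follow the date arithmetic", {
  rec <- reuse_corpus(
    list("A", "2000-01-01", "J", "the XYZ study"),
    list("B", "2000-07-01", "J", "more XYZ results"),
    list("C", "2001-01-01", "J", "no acronyms here")
  )
  rr <- build_reuse_records(rec)
  xyz <- rr[rr$surface == "XYZ", ]
  expect_true(xyz$event)
  expect_equal(xyz$time_to_event, as.numeric(as.Date("2000-07-01") -
                                               as.Date("2000-01-01")) / 365.25)
  expect_identical(xyz$first_use_year, 2000L)

  # never re-used: censored at the journal's last observed issue
  rec2 <- reuse_corpus(
    list("A", "2000-01-01", "J", "the QQZ study"),
    list("B", "2001-01-01", "J", "unrelated words only")
  )
  rr2 <- build_reuse_records(rec2)
  expect_false(rr2$event)
  expect_equal(rr2$time_to_event, 366 / 365.25)

  # coined on the journal's last date -> censored at time zero
  rec3 <- reuse_corpus(list("A", "2001-01-01", "J", "lone ZZQ use"))
  rr3 <- build_reuse_records(rec3)
  expect_false(rr3$event)
  expect_equal(rr3$time_to_event, 0)
})

test_that("the same surface in two journals yields independent records", {
  rec <- reuse_corpus(
    list("A", "2000-01-01", "J", "an XYZ paper"),
    list("B", "2000-03-01", "K", "another XYZ paper"),
    list("C", "2000-09-01", "K", "XYZ again here")
  )
  rr <- build_reuse_records(rec)
  expect_identical(nrow(rr), 2L)
  expect_setequal(rr$journal_id, c("J", "K"))
  expect_false(rr$event[rr$journal_id == "J"])
  expect_true(rr$event[rr$journal_id == "K"])
  # global-first-use variant keeps only the coining journal
  rg <- build_reuse_records(rec, global_first = TRUE)
  expect_identical(rg$journal_id, "J")
})

test_that("repeat use within the coining paper is not re-use", {
  rec <- reuse_corpus(
    list("A", "2000-01-01", "J", "XYZ and XYZ again"),
    list("B", "2002-01-01", "J", "plain filler words")
  )
  rr <- build_reuse_records(rec)
  expect_false(rr$event[rr$surface == "XYZ"])
})

test_that("undated records violate the precondition", {
  rec <- make_records(1)
  rec$pub_date <- as.Date(NA)
  expect_error(build_reuse_records(rec), "undated")
})

test_that("reuse_fraction_within uses the observable denominator", {
  rr <- tibble::tibble(
    surface = sprintf("S%02d", 1:10), journal_id = "J",
    first_use_date = as.Date("2000-01-01"), first_use_year = 2000L,
    time_to_event = c(0.5, rep(1.2, 9)),
    event = c(TRUE, rep(FALSE, 9)), acronym_length = 3L
  )
  out <- reuse_fraction_within(rr, window = 1)
  expect_equal(out$fraction, 0.1)

  # records censored before the window leave the denominator
  rr$time_to_event <- c(0.5, rep(0.4, 9))
  out2 <- reuse_fraction_within(rr, window = 1)
  expect_identical(out2$n_observable, 1L)
  expect_equal(out2$fraction, 1)

  # all censored early -> fraction is missing
  rr$event <- rep(FALSE, 10)
  rr$time_to_event <- rep(0.4, 10)
  expect_true(is.na(reuse_fraction_within(rr, window = 1)$fraction))
})

test_that("per-length hazard ordering is preserved in re-use fractions", {
  hz <- c("2" = 0.35, "3" = 0.22, "4" = 0.14, "5+" = 0.08)
  rr <- generate_reuse_cohorts(2000, n_per_cohort = 4000,
                               hazard_by_length = hz, seed = 17)
  out <- reuse_fraction_within(rr, window = 1, by_length = TRUE)
  fr <- out$fraction[match(c("2", "3", "4", "5+"), out$length_class)]
  expect_true(all(diff(fr) < 0))
})

test_that("km_curve matches a brute-force product-limit oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    rr <- tibble::tibble(
      surface = sprintf("S%02d", seq_len(n)), journal_id = "J",
      first_use_date = as.Date("2000-06-01"), first_use_year = 2000L,
      time_to_event = round(rexp(n, 0.5), 2),
      event = runif(n) < 0.6, acronym_length = 3L
    )
    if (!any(rr$event)) rr$event[1] <- TRUE
    cv <- km_curve(rr)
    oracle <- oracle_km(rr$time_to_event, rr$event)
    got <- cv$surv[match(oracle$time, cv$time)]
    expect_equal(got, oracle$surv, tolerance = 1e-12)
  }
  # with zero censoring the curve is 1 - ECDF of event times
  rr <- tibble::tibble(
    surface = sprintf("S%02d", 1:12), journal_id = "J",
    first_use_date = as.Date("2000-06-01"), first_use_year = 2000L,
    time_to_event = seq(0.25, 3, by = 0.25), event = TRUE,
    acronym_length = 2L
  )
  cv <- km_curve(rr)
  expect_equal(cv$surv, 1 - seq_len(12) / 12)
})

test_that("t10 is the first time survival reaches 0.90", {
  rr <- tibble::tibble(
    surface = sprintf("S%02d", 1:10), journal_id = "J",
    first_use_date = as.Date("2000-06-01"), first_use_year = 2000L,
    time_to_event = c(2, seq(3, 11)), event = c(TRUE, rep(FALSE, 9)),
    acronym_length = 3L
  )
  cv <- km_curve(rr)
  expect_equal(cv$t10, 2)
  expect_true(cv$t10_ci_low <= cv$t10)

  # no events -> t10 missing
  rr$event <- rep(FALSE, 10)
  expect_true(is.na(km_curve(rr)$t10))
})

test_that("exponential cohorts recover the closed-form t10", {
  lambda <- 0.105
  rr <- generate_reuse_cohorts(2000, n_per_cohort = 500, hazard = lambda,
                               seed = 3)
  cv <- km_curve(rr)
  true_t10 <- -log(0.9) / lambda
  # Monte-Carlo standard error of the 10% quantile of an exponential
  se <- sqrt(0.1 * 0.9 / 500) / (lambda * 0.9)
  expect_lt(abs(cv$t10 - true_t10), 3 * se)
  expect_true(cv$t10_ci_low <= cv$t10 && cv$t10 <= cv$t10_ci_high)
})

test_that("t10 ordering follows cohort hazards and ties are symmetric", {
  rr <- generate_reuse_cohorts(c(2000, 2010), n_per_cohort = 600,
                               hazard = c(0.3, 0.08), seed = 7)
  tt <- t10_by_cohort(rr)
  expect_identical(tt$cohort_year, c(2000L, 2010L))
  expect_lt(tt$t10[1], tt$t10[2])

  # a single censored record cannot reach 0.90
  one <- tibble::tibble(
    surface = "S", journal_id = "J",
    first_use_date = as.Date("2005-06-01"), first_use_year = 2005L,
    time_to_event = 0.5, event = FALSE, acronym_length = 2L
  )
  expect_true(is.na(t10_by_cohort(one)$t10))
})

test_that("extending journal life never shortens censored times", {
  rec <- reuse_corpus(
    list("A", "2000-01-01", "J", "an XYZ paper"),
    list("B", "2000-06-01", "J", "a QQZ paper with XYZ"),
    list("C", "2001-01-01", "J", "plain filler text")
  )
  rr1 <- build_reuse_records(rec)
  rec$pub_date[3] <- as.Date("2003-01-01")
  rec$year[3] <- 2003L
  rr2 <- build_reuse_records(rec)
  m <- match(paste(rr1$surface, rr1$journal_id),
             paste(rr2$surface, rr2$journal_id))
  expect_true(all(rr2$time_to_event[m] >= rr1$time_to_event))
  expect_true(all(rr2$event[m] >= rr1$event))
})
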