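# Time-to-re-use of newly coined acronyms within journals.
#
# The coining of an acronym is its first observed use within a journal
# (title or abstract); the event is re-use by a later, distinct paper in the
# same journal. Unobserved re-uses are right-censored at the journal's last
# observed issue date. The headline estimand is t10 — the time for 10% of a
# yearly cohort of newly coined acronyms to be re-used — read off a
# Kaplan-Meier curve.

DAYS_PER_YEAR <- 365.25

#' Build censored time-to-re-use records
#'
#' For every (acronym surface, journal) pair: the first use is the earliest
#' paper in that journal whose title or abstract contains the surface (ties
#' on the same day broken by `paper_id` so coining is deterministic); the
#' event time is years (days / 365.25) to the next distinct paper in the
#' journal containing it; otherwise the record is censored at the journal's
#' last observed issue date (maximum `pub_date` over all the journal's
#' papers, so a coining on that date is censored at time 0). The same
#' surface in two journals yields two independent records.
#'
#' @param records a record tibble (filtered, dated, with `journal_id`).
#' @param global_first if `TRUE`, keep only the journal in which the surface
#'   first appeared corpus-wide (sensitivity variant; the default treats
#'   first use per journal).
#' @inheritParams is_acronym
#' @return a tibble with one row per (surface, journal):
#'   `surface`, `journal_id`, `first_use_date`, `first_use_year` (cohort
#'   label), `time_to_event` (years), `event` (logical), `acronym_length`.
#' @export
build_reuse_records <- function(records, min_length = 2L,
                                denominator = c("all", "alphanumeric"),
                                global_first = FALSE) {
  if (any(is.na(records$pub_date))) {
    stop("undated records present; filter the corpus first")
  }
  occ <- extract_acronyms(records, field = "both", min_length = min_length,
                          denominator = denominator)
  if (nrow(occ) == 0L) {
    return(tibble::tibble(surface = character(), journal_id = character(),
                          first_use_date = as.Date(character()),
                          first_use_year = integer(),
                          time_to_event = numeric(), event = logical(),
                          acronym_length = integer()))
  }
  meta <- records[match(occ$paper_id, records$paper_id), ]
  occ$journal_id <- meta$journal_id
  occ$pub_date <- meta$pub_date
  occ <- dplyr::distinct(occ, .data$surface, .data$journal_id,
                         .data$paper_id, .keep_all = TRUE)
  last_issue <- tapply(as.numeric(records$pub_date), records$journal_id, max)

  occ <- dplyr::arrange(occ, .data$surface, .data$journal_id,
                        .data$pub_date, .data$paper_id)
  grp <- dplyr::group_by(occ, .data$surface, .data$journal_id)
  out <- dplyr::summarise(
    grp,
    first_use_date = .data$pub_date[1L],
    n_papers = dplyr::n(),
    second_date = if (dplyr::n() >= 2L) .data$pub_date[2L] else as.Date(NA),
    acronym_length = .data$length[1L],
    .groups = "drop"
  )
  event <- !is.na(out$second_date)
  censor_end <- as.Date(last_issue[out$journal_id],
                        origin = "1970-01-01")
  time <- ifelse(
    event,
    as.numeric(out$second_date - out$first_use_date) / DAYS_PER_YEAR,
    as.numeric(censor_end - out$first_use_date) / DAYS_PER_YEAR
  )
  res <- tibble::tibble(
    surface = out$surface,
    journal_id = out$journal_id,
    first_use_date = out$first_use_date,
    first_use_year = as.integer(format(out$first_use_date, "%Y")),
    time_to_event = time,
    event = event,
    acronym_length = out$acronym_length
  )
  if (global_first) {
    res <- dplyr::arrange(res, .data$surface, .data$first_use_date,
                          .data$journal_id)
    res <- res[!duplicated(res$surface), , drop = FALSE]
  }
  res
}

#' Fraction of coined acronyms re-used within a time window
#'
#' Numerator: records re-used (`event`) at or before `window` years.
#' Denominator: records observable to the window — records censored before
#' the window are excluded because their re-use status at the window is
#' unknown.
#'
#' @param reuse a tibble from [build_reuse_records()].
#' @param window window length in years (> 0).
#' @param by_length if `TRUE`, also stratify by acronym length class
#'   (2, 3, 4, 5+).
#' @return a tibble `(length_class, n_observable, n_reused, fraction)`;
#'   `length_class == "all"` is the overall row. `fraction` is `NA` when no
#'   record is observable.
#' @export
reuse_fraction_within <- function(reuse, window = 1.0, by_length = FALSE) {
  stopifnot(window > 0)
  frac_of <- function(df) {
    observable <- (df$event & df$time_to_event <= window) |
      df$time_to_event >= window
    num <- sum(df$event & df$time_to_event <= window)
    den <- sum(observable)
    tibble::tibble(n_observable = den, n_reused = num,
                   fraction = if (den > 0) num / den else NA_real_)
  }
  out <- dplyr::bind_cols(tibble::tibble(length_class = "all"), frac_of(reuse))
  if (by_length) {
    cls <- length_stratum(reuse$acronym_length)
    for (lc in c("2", "3", "4", "5+")) {
      sub <- reuse[cls == lc, , drop = FALSE]
      out <- dplyr::bind_rows(
        out,
        dplyr::bind_cols(tibble::tibble(length_class = lc), frac_of(sub))
      )
    }
  }
  out
}

# Smallest time at which a step function drops to <= level (NA if never).
first_time_below <- function(time, value, level, tol = 1e-12) {
  hit <- which(value <= level + tol)
  if (length(hit) == 0L) NA_real_ else time[hit[1L]]
}

#' Kaplan-Meier curve of time to re-use, with t10
#'
#' Product-limit estimator over the cohort's event/censoring times (via
#' \code{survival::survfit}, Greenwood variance, complementary log-log
#' confidence intervals). `t10` is the smallest time at which estimated
#' survival falls to 0.90 or below; its confidence bounds come from
#' intersecting the confidence envelope with 0.90 (`t10` and bounds are `NA`
#' when the corresponding curve never reaches 0.90).
#'
#' @param reuse a tibble from [build_reuse_records()].
#' @param cohort_year optional cohort (first-use year) to restrict to.
#' @return an object of class `reuse_curve`: a list with `cohort_year`, `n`,
#'   `time`, `surv`, `lower`, `upper` (stepwise estimates), `t10`,
#'   `t10_ci_low`, `t10_ci_high`.
#' @export
km_curve <- function(reuse, cohort_year = NULL) {
  if (!is.null(cohort_year)) {
    reuse <- reuse[reuse$first_use_year == cohort_year, , drop = FALSE]
  }
  if (nrow(reuse) == 0L) stop("no records in cohort")
  fit <- survival::survfit(
    survival::Surv(time_to_event, event) ~ 1,
    data = reuse, conf.type = "log-log"
  )
  lower <- fit$lower
  upper <- fit$upper
  lower[is.na(lower)] <- 0
  upper[is.na(upper)] <- 1
  out <- list(
    cohort_year = cohort_year,
    n = nrow(reuse),
    time = fit$time,
    surv = fit$surv,
    lower = lower,
    upper = upper,
    t10 = first_time_below(fit$time, fit$surv, 0.90),
    # lower envelope reaches 0.90 first (earliest plausible t10), upper last
    t10_ci_low = first_time_below(fit$time, lower, 0.90),
    t10_ci_high = first_time_below(fit$time, upper, 0.90)
  )
  class(out) <- "reuse_curve"
  out
}

#' @export
print.reuse_curve <- function(x, ...) {
  cat("Kaplan-Meier time-to-re-use curve",
      if (!is.null(x$cohort_year)) paste0("(cohort ", x$cohort_year, ")"),
      "\n")
  cat("  n =", x$n, "records,", sum(x$surv < 1), "distinct step times\n")
  cat(sprintf("  t10 = %.3f years [%.3f, %.3f]\n",
              x$t10, x$t10_ci_low, x$t10_ci_high))
  invisible(x)
}

#' Time to 10% re-use per coining cohort
#'
#' One row per cohort year (ordered by year) with the [km_curve()] `t10`
#' and its confidence bounds; `t10` is `NA` for cohorts whose curve never
#' reaches 0.90 (all censored early, or too little re-use).
#'
#' @param reuse a tibble from [build_reuse_records()].
#' @return a tibble `(cohort_year, n, t10, t10_ci_low, t10_ci_high)`.
#' @export
t10_by_cohort <- function(reuse) {
  years <- sort(unique(reuse$first_use_year))
  dplyr::bind_rows(lapply(years, function(y) {
    cv <- km_curve(reuse, cohort_year = y)
    tibble::tibble(cohort_year = y, n = cv$n, t10 = cv$t10,
                   t10_ci_low = cv$t10_ci_low, t10_ci_high = cv$t10_ci_high)
  }))
}
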