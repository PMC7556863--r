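# End-to-end orchestration: parse/load -> dedupe -> filter -> trends /
# rankings / spectrum / re-use, with a serialized run manifest so a run is
# reproducible from its output directory alone.

#' Configuration for a full pipeline run
#'
#' @param input path to a record JSON-lines file (see [write_records()]), a
#'   MEDLINE XML file, or a record tibble.
#' @param out_dir output directory (created if needed).
#' @param start_year first eligible year (default 1950).
#' @param caps_threshold capitals-exclusion threshold (default 0.60).
#' @param fields fields to analyse (default both).
#' @param top_n size of the top-acronym ranking (default 20).
#' @param top_k_mask number of popular acronyms masked in the sensitivity
#'   trend (default 100).
#' @param reuse_window re-use window in years (default 1).
#' @param seed run seed for all randomness (audit sampling).
#' @return a list of class `run_config`.
#' @export
run_config <- function(input, out_dir,
                       start_year = 1950L, caps_threshold = 0.60,
                       fields = c("title", "abstract"),
                       top_n = 20L, top_k_mask = 100L,
                       reuse_window = 1.0, seed = 1L) {
  cfg <- list(
    input = input, out_dir = out_dir, start_year = as.integer(start_year),
    caps_threshold = caps_threshold,
    fields = match.arg(fields, several.ok = TRUE),
    top_n = as.integer(top_n), top_k_mask = as.integer(top_k_mask),
    reuse_window = reuse_window, seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

load_input <- function(input) {
  if (is.data.frame(input)) return(input)
  stopifnot(is.character(input), length(input) == 1L)
  if (grepl("\\.xml(\\.gz)?$", input)) parse_medline_xml(input)
  else read_records(input)
}

#' Run the full analysis pipeline
#'
#' Stages: load -> dedupe -> exclusion filtering -> per-field annual trends
#' (plus the top-k-masked sensitivity series) -> top-N ranking -> frequency
#' spectrum -> re-use survival (records, one-year re-use fractions by
#' length, t10 per cohort). Writes TSV tables and a JSON manifest (config,
#' package version, record counts) into `out_dir`; any stage failure aborts
#' with the stage name.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all computed tables (`records`, `tally`,
#'   `trends`, `trends_masked`, `top`, `spectrum`, `reuse`, `reuse_fractions`,
#'   `t10`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  records <- stage("load", load_input(config$input))
  dd <- stage("dedupe", dedupe_records(records))
  records <- dd$records
  fc <- stage("filter", filter_corpus(records, config$start_year,
                                      config$caps_threshold))
  write_tsv(fc$tally, file.path(config$out_dir, "exclusions.tsv"))

  trends <- list(); trends_masked <- list()
  for (f in config$fields) {
    kept <- if (f == "title") fc$title_kept else fc$abstract_kept
    trends[[f]] <- stage(paste0("trends_", f), annual_trends(kept, f))
    trends_masked[[f]] <- stage(
      paste0("trends_masked_", f),
      trends_excluding_top(kept, f, k = config$top_k_mask)
    )
    write_tsv(trends[[f]], file.path(config$out_dir,
                                     paste0("trends_", f, ".tsv")))
    write_tsv(trends_masked[[f]],
              file.path(config$out_dir, paste0("trends_", f, "_masked.tsv")))
  }

  kept_any <- fc$records[fc$records$title_ok | fc$records$abstract_ok, ]
  kept_any$title[!kept_any$title_ok] <- NA_character_
  kept_any$abstract[!kept_any$abstract_ok] <- NA_character_
  top <- stage("top", top_acronyms(kept_any, n = config$top_n))
  write_tsv(top, file.path(config$out_dir, "top_acronyms.tsv"))
  spec <- stage("spectrum", frequency_spectrum(kept_any))
  jsonlite::write_json(spec[setdiff(names(spec), "counts")],
                       file.path(config$out_dir, "spectrum.json"),
                       auto_unbox = TRUE, digits = NA)

  reuse <- stage("reuse", build_reuse_records(kept_any))
  write_tsv(reuse, file.path(config$out_dir, "reuse_records.tsv"))
  rf <- stage("reuse_fractions",
              reuse_fraction_within(reuse, config$reuse_window,
                                    by_length = TRUE))
  write_tsv(rf, file.path(config$out_dir, "reuse_fractions.tsv"))
  t10 <- stage("t10", t10_by_cohort(reuse))
  write_tsv(t10, file.path(config$out_dir, "t10_by_cohort.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("acrotrend")),
    config = config[setdiff(names(config), "input")],
    input = if (is.character(config$input)) config$input else "<in-memory>",
    n_records = nrow(records),
    n_duplicates_removed = dd$n_removed,
    n_title_kept = nrow(fc$title_kept),
    n_abstract_kept = nrow(fc$abstract_kept)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(records = records, tally = fc$tally, trends = trends,
                 trends_masked = trends_masked, top = top, spectrum = spec,
                 reuse = reuse, reuse_fractions = rf, t10 = t10,
                 manifest = manifest))
}
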