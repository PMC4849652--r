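#' Pipeline configuration
#'
#' @param window_before,window_after Mention context window sizes in
#'   characters (defaults 30 and 100, from the windowed pattern template).
#' @param coreference Run the two-sentence look-ahead co-reference pass
#'   (default TRUE).
#' @param coref_horizon Look-ahead horizon in sentences (default 2).
#' @param physiologic Apply physiologic-consistency constraints (default
#'   TRUE).
#' @param velocity_vs_gradient Apply the dimensionally heterodox
#'   peak-velocity < peak-gradient constraint (default TRUE).
#' @param iqr Apply the corpus-level interquartile-range outlier filter
#'   (default TRUE).
#' @param iqr_k Tukey fence multiplier (default 1.5).
#' @param plausibility Apply per-element plausibility-range flags (default
#'   TRUE).
#' @param variability_warn Relative within-report spread above which a
#'   warn-only `high_variability` flag is set (default 0.2).
#' @return A list of class `echo_config`.
#' @export
echo_config <- function(window_before = 30L, window_after = 100L,
                        coreference = TRUE, coref_horizon = 2L,
                        physiologic = TRUE, velocity_vs_gradient = TRUE,
                        iqr = TRUE, iqr_k = 1.5, plausibility = TRUE,
                        variability_warn = 0.2) {
  structure(
    list(
      window_before = as.integer(window_before),
      window_after = as.integer(window_after),
      coreference = isTRUE(coreference),
      coref_horizon = as.integer(coref_horizon),
      physiologic = isTRUE(physiologic),
      velocity_vs_gradient = isTRUE(velocity_vs_gradient),
      iqr = isTRUE(iqr),
      iqr_k = iqr_k,
      plausibility = isTRUE(plausibility),
      variability_warn = variability_warn
    ),
    class = "echo_config"
  )
}

#' Run the full extraction pipeline over a corpus
#'
#' normalize -> segment -> windowed extraction -> co-reference ->
#' unit canonicalization -> physiologic constraints -> IQR outlier filter
#' -> plausibility flags -> summaries. Reports are processed one at a time
#' (streaming); only the extracted value table is corpus-global (the IQR
#' fences need it). Two runs on the same inputs produce identical outputs.
#'
#' @param corpus Corpus tibble (see [read_corpus()]) or a character vector
#'   of report texts (ids are generated).
#' @param registry An `echo_registry` (default: shipped registry).
#' @param config An `echo_config`.
#' @return An object of class `echo_extraction`: list with `summaries`,
#'   `values`, `mentions`, `flags` (filter report), `missingness`,
#'   `corpus`, `config`.
#' @export
extract_corpus <- function(corpus, registry = load_registry(),
                           config = echo_config()) {
  if (is.character(corpus)) {
    corpus <- tibble::tibble(
      report_id = sprintf("R%05d", seq_along(corpus)),
      patient_id = NA_character_, report_type = "unknown", text = corpus
    )
  }
  stopifnot(inherits(registry, "echo_registry"))

  norm <- normalize_text(corpus$text)
  ## vectorized per-element prefilter: one grepl per element over the corpus
  hits <- vapply(names(registry$specs), function(id) {
    grepl(registry$patterns[[id]], norm, perl = TRUE)
  }, logical(nrow(corpus)))
  if (nrow(corpus) == 1L) hits <- matrix(hits, nrow = 1, dimnames = list(NULL, names(registry$specs)))

  mention_list <- vector("list", nrow(corpus))
  value_list <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    rid <- corpus$report_id[i]
    sentences <- segment_sentences(norm[i], rid)
    sc <- scan_report(rid, norm[i], sentences, registry, config,
                      element_ids = names(registry$specs)[hits[i, ]])
    mention_list[[i]] <- mentions_to_tibble(sc$mentions, rid)
    value_list[[i]] <- values_to_tibble(sc$values, rid)
  }
  mentions <- dplyr::bind_rows(mention_list)
  values <- dplyr::bind_rows(value_list)
  if (!nrow(values)) values <- empty_values()

  values <- canonicalize_values(values, registry)
  if (config$physiologic) {
    values <- check_physiologic(values, config$velocity_vs_gradient)
  }
  if (config$iqr) values <- iqr_outlier_filter(values, config$iqr_k)
  if (config$plausibility) values <- plausible_range_filter(values, registry)

  ## mention universe for missingness: specific mentions + attributed values
  mention_keys <- dplyr::bind_rows(
    if (nrow(mentions)) mentions[, c("report_id", "element_id")] else NULL,
    if (nrow(values)) values[values$via_coreference, c("report_id", "element_id")] else NULL
  )
  if (is.null(mention_keys)) {
    mention_keys <- tibble::tibble(report_id = character(), element_id = character())
  }

  structure(
    list(
      summaries = summarize_values(values, corpus, registry,
                                   variability_warn = config$variability_warn),
      values = values,
      mentions = mentions,
      flags = filter_report(values),
      missingness = missingness(corpus, registry, mention_keys),
      corpus = corpus[, setdiff(names(corpus), "text")],
      config = config
    ),
    class = "echo_extraction"
  )
}

#' @export
print.echo_extraction <- function(x, ...) {
  cat("<echo_extraction>\n")
  cat("  reports:   ", nrow(x$corpus), "\n", sep = "")
  cat("  mentions:  ", if (is.null(x$mentions)) 0L else nrow(x$mentions), "\n", sep = "")
  cat("  values:    ", nrow(x$values), " (kept ", sum(x$values$kept), ")\n", sep = "")
  cat("  flagged:   ", nrow(x$flags), "\n", sep = "")
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Writes `summary.tsv`, `filter_flags.tsv`, `missingness.tsv` and a
#' machine-readable `run_manifest.json` (configuration, package version,
#' content checksum of the summary table).
#'
#' @param result An `echo_extraction`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(result, dir) {
  stopifnot(inherits(result, "echo_extraction"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(result$summaries, file.path(dir, "summary.tsv"))
  write_table(result$flags, file.path(dir, "filter_flags.tsv"))
  write_table(result$missingness, file.path(dir, "missingness.tsv"))
  manifest <- list(
    package = "echosift",
    version = as.character(utils::packageVersion("echosift")),
    n_reports = nrow(result$corpus),
    config = unclass(result$config),
    summary_md5 = unname(tools::md5sum(file.path(dir, "summary.tsv")))
  )
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
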