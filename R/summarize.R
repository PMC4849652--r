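#' Post-processing and structured output
#'
#' After filtering, ranges are collapsed to their means (25 to 30 mmHg
#' becomes 27.5 mmHg) and one summary row per report and element is
#' emitted: the source sentence segments, the ordered list of surviving
#' values, their count, minimum, maximum, and the last value in document
#' order. All of these are emitted because no single mention can be trusted
#' as "the" value: report layouts moved the conclusion section over time,
#' so positional priority is deliberately avoided and the consumer chooses.
#'
#' @name summarizer
NULL

#' Collapse a value range to its mean
#'
#' @param low,high Numeric range endpoints (canonical unit).
#' @return `(low + high) / 2`.
#' @export
collapse_range <- function(low, high) {
  if (any(low > high, na.rm = TRUE)) {
    stop("range with low > high reached collapse_range", call. = FALSE)
  }
  (low + high) / 2
}

format_value <- function(v) {
  vapply(v, function(x) {
    if (is.character(x)) x else format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }, "", USE.NAMES = FALSE)
}

#' Summarize surviving values per report and element
#'
#' @param values Canonicalized/filtered value tibble for a corpus.
#' @param corpus Corpus tibble (defines the report universe).
#' @param registry An `echo_registry` (defines the element universe).
#' @param full_frame Emit an explicit empty summary (`n_values = 0`) for
#'   every report x element combination without surviving values
#'   (default TRUE).
#' @param variability_warn Relative spread `(max - min) / mean` above which
#'   `high_variability` is set for quantitative elements with two or more
#'   values (default 0.2; warn-only, never a removal).
#' @return A tibble with one row per report x element.
#' @export
summarize_values <- function(values, corpus, registry, full_frame = TRUE,
                             variability_warn = 0.2) {
  kept <- values[values$kept & values$kind %in% c("number", "range", "category"), , drop = FALSE]
  if (nrow(kept)) {
    kept <- kept[order(kept$report_id, kept$element_id, kept$span_start), , drop = FALSE]
    grp <- paste(kept$report_id, kept$element_id, sep = "\r")
    rows <- lapply(split(seq_len(nrow(kept)), grp), function(idx) {
      r <- kept[idx, , drop = FALSE]
      is_cat <- r$kind[1] == "category"
      vals <- if (is_cat) r$category else r$value
      nums <- if (is_cat) numeric() else r$value
      hv <- FALSE
      if (!is_cat && length(nums) >= 2 && mean(nums) != 0) {
        hv <- (max(nums) - min(nums)) / mean(nums) > variability_warn
      }
      tibble::tibble(
        report_id = r$report_id[1],
        element_id = r$element_id[1],
        n_values = length(vals),
        values_json = as.character(jsonlite::toJSON(vals, auto_unbox = FALSE, digits = NA)),
        value_min = if (length(nums)) min(nums) else NA_real_,
        value_max = if (length(nums)) max(nums) else NA_real_,
        value_last = format_value(vals[length(vals)]),
        unit = r$unit[1],
        sentence_segments_json = as.character(jsonlite::toJSON(r$source_span, auto_unbox = FALSE)),
        high_variability = hv
      )
    })
    filled <- dplyr::bind_rows(rows)
  } else {
    filled <- tibble::tibble(
      report_id = character(), element_id = character(), n_values = integer(),
      values_json = character(), value_min = numeric(), value_max = numeric(),
      value_last = character(), unit = character(),
      sentence_segments_json = character(), high_variability = logical()
    )
  }
  if (!full_frame) return(filled)
  frame <- tidyr::expand_grid(
    report_id = corpus$report_id,
    element_id = names(registry$specs)
  )
  out <- dplyr::left_join(frame, filled, by = c("report_id", "element_id"))
  out$n_values[is.na(out$n_values)] <- 0L
  out$values_json[is.na(out$values_json)] <- "[]"
  out$value_last[is.na(out$value_last)] <- ""
  out$unit[is.na(out$unit)] <- ""
  out$sentence_segments_json[is.na(out$sentence_segments_json)] <- "[]"
  out$high_variability[is.na(out$high_variability)] <- FALSE
  out
}

#' Write a summary (or any pipeline) table as TSV
#'
#' Columns are stable across runs; list-valued columns are JSON-encoded.
#' Re-running on identical inputs yields a byte-identical file.
#'
#' @param x Tibble to write.
#' @param destination File path.
#' @return `destination`, invisibly.
#' @export
write_table <- function(x, destination) {
  utils::write.table(as.data.frame(x), destination, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(destination)
}

#' Read a summary table written by [write_table()]
#'
#' @param path TSV path.
#' @return A tibble reproducing every summary field.
#' @export
read_summary_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          quote = "", na.strings = character(),
                          colClasses = c(
                            report_id = "character", element_id = "character",
                            n_values = "integer", values_json = "character",
                            value_min = "character", value_max = "character",
                            value_last = "character", unit = "character",
                            sentence_segments_json = "character",
                            high_variability = "logical"
                          ))
  df$value_min <- suppressWarnings(as.numeric(df$value_min))
  df$value_max <- suppressWarnings(as.numeric(df$value_max))
  tibble::as_tibble(df)
}

#' Per-bin report counts for an element's summarized values
#'
#' Counts reports whose summarized value (the last surviving value in
#' document order) falls in each half-open bin `[edge_i, edge_{i+1})`.
#'
#' @param summaries Summary tibble from [summarize_values()].
#' @param element_id A quantitative element.
#' @param breaks Sorted, strictly increasing bin edges.
#' @return Integer vector of per-bin counts (length `length(breaks) - 1`);
#'   the total equals the number of reports whose value lies in the covered
#'   range.
#' @export
value_histogram <- function(summaries, element_id, breaks) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing", call. = FALSE)
  }
  rows <- summaries[summaries$element_id == element_id & summaries$n_values > 0, , drop = FALSE]
  v <- suppressWarnings(as.numeric(rows$value_last))
  v <- v[!is.na(v)]
  if (!length(v)) return(rep(0L, length(breaks) - 1L))
  bin <- findInterval(v, breaks, rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(bin[bin >= 1 & bin <= length(breaks) - 1L], nbins = length(breaks) - 1L)
  as.integer(counts)
}
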