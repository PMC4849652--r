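#' Extraction scoring against gold annotations
#'
#' Scoring is at report x element granularity, the frame used when a
#' fixed test set of reports is annotated for all elements (50 reports x 80
#' elements = 4000 cells). Within a cell, values are matched as multisets
#' with greedy nearest-value pairing: numeric values match within an
#' absolute tolerance after unit canonicalization (default 1e-6),
#' categorical values match on the exact token. A matched pair is a true
#' positive; an unmatched prediction a false positive; an unmatched
#' extractable gold value a false negative; a cell with neither gold nor
#' prediction a true negative. Per-element counts are pooled
#' (micro-averaged) into the overall row.
#'
#' @name evaluator
NULL

#' Harmonic mean of precision and recall
#' @param precision,recall Proportions in `[0, 1]`.
#' @return The F1 score (0 when both are 0).
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

match_multisets <- function(gold, pred, tol) {
  if (is.character(gold) || is.character(pred)) {
    g <- as.character(gold); p <- as.character(pred)
    tp <- 0L
    for (x in unique(c(g, p))) tp <- tp + min(sum(g == x), sum(p == x))
    return(tp)
  }
  g <- sort(as.numeric(gold)); p <- sort(as.numeric(pred))
  tp <- 0L; i <- 1L; j <- 1L
  while (i <= length(g) && j <= length(p)) {
    d <- p[j] - g[i]
    if (abs(d) <= tol) { tp <- tp + 1L; i <- i + 1L; j <- j + 1L }
    else if (d < 0) j <- j + 1L
    else i <- i + 1L
  }
  tp
}

pred_values_by_key <- function(predicted) {
  if (inherits(predicted, "echo_extraction")) {
    v <- predicted$values
    v <- v[v$kept & v$kind %in% c("number", "range", "category"), , drop = FALSE]
    key <- paste(v$report_id, v$element_id, sep = "\r")
    num <- ifelse(v$kind == "category", NA_real_, v$value)
    lapply(split(seq_len(nrow(v)), key), function(idx) {
      if (v$kind[idx[1]] == "category") v$category[idx] else num[idx]
    })
  } else {
    rows <- predicted[predicted$n_values > 0, , drop = FALSE]
    key <- paste(rows$report_id, rows$element_id, sep = "\r")
    out <- lapply(seq_len(nrow(rows)), function(i) {
      x <- jsonlite::fromJSON(rows$values_json[i])
      if (is.character(x)) x else as.numeric(x)
    })
    stats::setNames(out, key)
  }
}

#' Score extraction output against gold annotations
#'
#' @param predicted An `echo_extraction` result, or a summary tibble (as
#'   written by [write_table()] and read back with
#'   [read_summary_table()]).
#' @param gold Gold tibble from [simulate_corpus()] (or read from a
#'   `gold.jsonl`).
#' @param registry An `echo_registry` defining the element universe for
#'   true negatives (default: shipped registry).
#' @param tol Absolute numeric matching tolerance after canonicalization.
#' @param against Score against gold values the pipeline is expected to
#'   keep (`"extractable"`, the default) or against every planted value
#'   regardless of corruption (`"planted"`; used e.g. to measure how
#'   recall degrades with rising noise).
#' @return A tibble with one row per element plus an `overall`
#'   micro-average row: tp, fp, fn, tn, precision, recall, f1,
#'   specificity, npv.
#' @export
score_extraction <- function(predicted, gold, registry = load_registry(),
                             tol = 1e-6, against = c("extractable", "planted")) {
  against <- match.arg(against)
  gkeep <- if (against == "extractable") gold[gold$expected_extractable, , drop = FALSE] else gold
  gvals <- {
    key <- paste(gkeep$report_id, gkeep$element_id, sep = "\r")
    lapply(split(seq_len(nrow(gkeep)), key), function(idx) {
      if (all(is.na(gkeep$value[idx]))) gkeep$category[idx] else gkeep$value[idx]
    })
  }
  pvals <- pred_values_by_key(predicted)

  report_ids <- unique(c(gold$report_id, if (inherits(predicted, "echo_extraction")) {
    predicted$corpus$report_id
  } else {
    predicted$report_id
  }))
  element_ids <- names(registry$specs)

  counts <- matrix(0L, nrow = length(element_ids), ncol = 4,
                   dimnames = list(element_ids, c("tp", "fp", "fn", "tn")))
  keys <- unique(c(names(gvals), names(pvals)))
  key_el <- sub("^.*\r", "", keys)
  for (i in seq_along(keys)) {
    k <- keys[i]; el <- key_el[i]
    if (!el %in% element_ids) next
    g <- gvals[[k]] %||% NULL
    p <- pvals[[k]] %||% NULL
    tp <- if (length(g) && length(p)) match_multisets(g, p, tol) else 0L
    counts[el, "tp"] <- counts[el, "tp"] + tp
    counts[el, "fp"] <- counts[el, "fp"] + length(p) - tp
    counts[el, "fn"] <- counts[el, "fn"] + length(g) - tp
  }
  n_cells <- length(report_ids)
  active <- table(factor(key_el[keys %in% union(names(gvals), names(pvals))],
                         levels = element_ids))
  counts[, "tn"] <- pmax(0L, n_cells - as.integer(active))

  per <- tibble::as_tibble(counts, rownames = "element_id")
  overall <- tibble::tibble(
    element_id = "overall",
    tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn), tn = sum(per$tn)
  )
  out <- dplyr::bind_rows(overall, per)
  out$precision <- ifelse(out$tp + out$fp > 0, out$tp / (out$tp + out$fp), NA_real_)
  out$recall <- ifelse(out$tp + out$fn > 0, out$tp / (out$tp + out$fn), NA_real_)
  out$f1 <- ifelse(!is.na(out$precision) & !is.na(out$recall),
                   f1_score(out$precision, out$recall), NA_real_)
  out$specificity <- ifelse(out$tn + out$fp > 0, out$tn / (out$tn + out$fp), NA_real_)
  out$npv <- ifelse(out$tn + out$fn > 0, out$tn / (out$tn + out$fn), NA_real_)
  out
}

#' Read gold annotations written by [write_synthetic_corpus()]
#' @param path Path to a `gold.jsonl` file.
#' @return Gold tibble.
#' @export
read_gold <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dplyr::bind_rows(lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x$value <- if (is.null(x$value)) NA_real_ else as.numeric(x$value)
    x$category <- if (is.null(x$category)) NA_character_ else as.character(x$category)
    tibble::as_tibble(x)
  }))
}
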