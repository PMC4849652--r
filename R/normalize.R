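#' Text normalization and sentence segmentation
#'
#' Reports exported from EHR databases carry extra whitespace and spurious
#' runs of '.' characters that break sentences apart ("Peak.. velocity
#' across the aortic valve = 5.0 m/s"). Normalization rejoins such
#' fragments without disturbing genuine sentence boundaries, decimal points
#' or unit abbreviations, so that a structured measurement line like
#' "MV E/A: ..0.57....MVA(P1/2T):..1.4 cm....AO V2 MAX:..335 cm/sec...."
#' survives as a single sentence.
#'
#' @name text_normalization
NULL

#' Normalize raw report text
#'
#' Rules, applied in order: unicode ellipsis/dash/apostrophe variants are
#' mapped to ASCII; a dot run inside a split unit ("mm.. Hg") is glued back;
#' a run of two or more dots followed by whitespace and a capital letter is
#' treated as a sentence boundary and collapsed to a single period; any
#' other dot run is EHR-export noise and is replaced by a single space;
#' horizontal whitespace collapses to single spaces and blank-line runs to
#' single line breaks. Sentence-terminal single periods are preserved.
#' Normalization is idempotent. De-identification placeholders
#' (`[**...**]`) pass through verbatim so the extractor can flag them.
#'
#' @param x Character vector of raw report texts.
#' @return Character vector of normalized texts ("" for empty/NA input).
#' @export
normalize_text <- function(x) {
  vapply(x, function(t) {
    if (is.na(t) || !nzchar(t)) return("")
    t <- gsub("…", "...", t)
    t <- gsub("[–—]", "-", t)
    t <- gsub("’", "'", t)
    ## rejoin "mm.. Hg" before boundary handling
    t <- gsub("\\.{2,}(\\s*)(?=[Hh]g(?![a-z0-9]))", " ", t, perl = TRUE)
    ## dot run + whitespace + capital: genuine boundary, keep one period
    t <- gsub("\\.{2,}(?=\\s+[A-Z])", ".", t, perl = TRUE)
    ## remaining dot runs are export noise
    t <- gsub("\\.{2,}", " ", t)
    ## whitespace: collapse, but keep single line breaks as section seams
    t <- gsub("\r\n?", "\n", t)
    t <- gsub("[ \t]+", " ", t)
    t <- gsub(" ?\n ?", "\n", t)
    t <- gsub("\n{2,}", "\n", t)
    trimws(t)
  }, "", USE.NAMES = FALSE)
}

SECTION_HEADER_RX <- "(?i)^(report text|procedure components?|measurements? and calculations?|conclusion|summary|findings)\\b"

#' Segment normalized text into sentences
#'
#' Splits at a period or question mark followed by whitespace and a capital
#' letter, and at line breaks between report sections. Decimal points and
#' unit abbreviations do not trigger splits mid-measurement, and
#' colon-delimited measurement lines stay intact as one sentence. Offsets
#' are 0-based half-open into the normalized text; sentences are
#' non-overlapping, ordered and non-empty. Line-initial section headers are
#' recorded per sentence (extraction treats all sections uniformly).
#'
#' @param text A single normalized report text.
#' @param report_id Report identifier carried onto each sentence.
#' @return A tibble with columns `report_id`, `index`, `text`,
#'   `char_start`, `char_end`, `section`, `structure_class`.
#' @export
segment_sentences <- function(text, report_id = NA_character_) {
  empty <- tibble::tibble(
    report_id = character(), index = integer(), text = character(),
    char_start = integer(), char_end = integer(), section = character(),
    structure_class = character()
  )
  if (is.na(text) || !nzchar(text)) return(empty)

  brk <- gregexpr("(?<=[.?])\\s+(?=[A-Z])|\n+", text, perl = TRUE)[[1]]
  if (brk[1] == -1) {
    starts <- 1L
    ends <- nchar(text)
  } else {
    blen <- attr(brk, "match.length")
    starts <- c(1L, as.integer(brk) + blen)
    ends <- c(as.integer(brk) - 1L, nchar(text))
  }

  section <- NA_character_
  rows <- list()
  idx <- 0L
  for (i in seq_along(starts)) {
    raw <- substr(text, starts[i], ends[i])
    ## trim while keeping offsets honest
    lead <- nchar(sub("^\\s*", "", raw))
    s <- starts[i] + (nchar(raw) - lead)
    raw <- sub("^\\s*", "", raw)
    raw <- sub("\\s*$", "", raw)
    if (!nzchar(raw)) next
    e <- s + nchar(raw) - 1L
    hdr <- regmatches(raw, regexpr(SECTION_HEADER_RX, raw, perl = TRUE))
    if (length(hdr)) section <- tolower(hdr)
    idx <- idx + 1L
    rows[[idx]] <- list(text = raw, char_start = s - 1L, char_end = e, section = section)
  }
  if (!idx) return(empty)
  out <- tibble::tibble(
    report_id = report_id,
    index = seq_len(idx),
    text = vapply(rows, `[[`, "", "text"),
    char_start = vapply(rows, `[[`, 0L, "char_start"),
    char_end = vapply(rows, `[[`, 0L, "char_end"),
    section = vapply(rows, `[[`, "", "section")
  )
  out$structure_class <- classify_structure(out$text)
  out
}

#' Classify a sentence's structure style
#'
#' Three styles occur in echocardiography reports: `structured`
#' (label:value measurement lines, "MV E/A: 0.57 MVA(P1/2T): 1.4 cm ..."),
#' `semi_structured` (a single "phrase = value unit" or "phrase: value
#' unit" assignment), and `unstructured` prose. The classification is a
#' deterministic total function: two or more label:value groups means
#' structured; a lone assignment whose right-hand side is just a value and
#' a short tail means semi-structured; everything else is unstructured.
#'
#' @param text Character vector of sentence texts.
#' @return Character vector over `{structured, semi_structured,
#'   unstructured}`.
#' @export
classify_structure <- function(text) {
  n_groups <- vapply(text, function(s) {
    m <- gregexpr("[A-Za-z0-9)'^]\\s?:\\s*\\S", s, perl = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }, 0L, USE.NAMES = FALSE)
  semi <- grepl(
    "^[A-Za-z][A-Za-z0-9 /()'^-]{0,60}?\\s*[:=]\\s*\\S+(\\s+\\S+){0,3}\\s*\\.?$",
    text, perl = TRUE
  )
  ifelse(n_groups >= 2, "structured",
         ifelse(semi & n_groups <= 1, "semi_structured", "unstructured"))
}

#' Read a report corpus
#'
#' Accepts either a directory of `.txt` files (file name stem becomes the
#' report id) or a single TSV/CSV with columns `report_id`, `patient_id`,
#' `report_type`, `text`.
#'
#' @param path Corpus directory or delimited file.
#' @return A tibble with columns `report_id`, `patient_id`, `report_type`,
#'   `text`.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    return(tibble::tibble(
      report_id = sub("\\.txt$", "", basename(files)),
      patient_id = NA_character_,
      report_type = "unknown",
      text = vapply(files, function(f) paste(readLines(f, warn = FALSE), collapse = "\n"), "")
    ))
  }
  if (!file.exists(path)) stop("corpus not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE, quote = "\"")
  need <- c("report_id", "text")
  if (!all(need %in% names(df))) {
    stop("corpus file must have columns report_id and text", call. = FALSE)
  }
  tibble::tibble(
    report_id = as.character(df$report_id),
    patient_id = as.character(df$patient_id %||% NA_character_),
    report_type = as.character(df$report_type %||% "unknown"),
    text = as.character(df$text)
  )
}

#' Select the reports mentioning an element
#'
#' A report is selected iff any synonym of the element matches its
#' normalized text; multiplicity does not matter (a report is selected once
#' however many sections mention the element). Selection never loses a
#' report in which downstream extraction could succeed, because extraction
#' uses the same synonym patterns.
#'
#' @param corpus Corpus tibble (see [read_corpus()]).
#' @param element_id Element to look for.
#' @param registry An `echo_registry`.
#' @return Character vector of selected `report_id`s.
#' @export
select_reports <- function(corpus, element_id, registry) {
  stopifnot(inherits(registry, "echo_registry"))
  rx <- registry$patterns[[element_id]]
  if (is.null(rx)) stop("unknown element: ", element_id, call. = FALSE)
  hit <- grepl(rx, normalize_text(corpus$text), perl = TRUE)
  corpus$report_id[hit]
}
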