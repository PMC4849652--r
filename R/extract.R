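#' Windowed relationship extraction
#'
#' For every element a single generalizable pattern template is
#' instantiated: the element's synonym alternation plus a context window of
#' 30 characters before and 100 characters after the mention (both
#' config-overridable). Within the window, an additional set of rules
#' recognizes plain numbers with optional units ("5.0 m/s", "335 cm/sec",
#' "2.54"), ranges ("25-30 mmhg", "25 to 30 mmhg"), categorical tokens from
#' the element vocabulary ("moderate-severe"), and missing markers ("??",
#' de-identification placeholders `[**...**]`). Values left of the mention
#' are eligible, which covers label-after-value layouts ("across mitral
#' bioprosthetic valve peak velocity"), unless the mention is itself
#' followed by ':' or '=' (a declared label-before-value layout).
#'
#' A mention strictly contained inside another element's longer mention is
#' suppressed ("ero" inside "av ero"): the longer, more specific synonym
#' owns the span. Numbers adjacent to uncommon character runs ("-->",
#' bracketed placeholders) break the number-unit adjacency rule and are
#' deliberately not extracted.
#'
#' @name extraction
NULL

GENERIC_MEASURES <- c(
  peak_velocity = "peak\\s+velocity",
  mean_velocity = "mean\\s+velocity",
  peak_gradient = "peak\\s+gradient",
  mean_gradient = "mean\\s+gradient"
)

VALVE_ENTITY_RX <- "(?i)(?<![a-z0-9])(aortic|mitral|tricuspid|pulmonic|pulmonary)\\s+(?:position|valve|bioprosthesis|prosthesis)(?![a-z0-9])"

COREF_ELEMENT_MAP <- list(
  aortic = c(peak_velocity = "av_peak_velocity", mean_velocity = "av_mean_velocity",
             peak_gradient = "av_peak_gradient", mean_gradient = "av_mean_gradient"),
  mitral = c(peak_velocity = "mv_peak_velocity", mean_velocity = "mv_mean_velocity",
             peak_gradient = "mv_peak_gradient", mean_gradient = "mv_mean_gradient"),
  tricuspid = c(peak_velocity = "tr_peak_velocity", mean_velocity = "tr_mean_velocity",
                peak_gradient = "tr_peak_gradient", mean_gradient = "tr_mean_gradient"),
  pulmonic = c(peak_velocity = "pv_peak_velocity", mean_velocity = "pv_mean_velocity",
               peak_gradient = "pv_peak_gradient", mean_gradient = "pv_mean_gradient")
)

#' Build the windowed pattern for an element
#'
#' @param element An element spec from the registry (`registry$specs[[id]]`).
#' @param window_before,window_after Context window sizes in characters
#'   (defaults 30 and 100).
#' @return An `echo_pattern` list with the compiled synonym alternation.
#' @export
build_pattern <- function(element, window_before = 30L, window_after = 100L) {
  if (!length(element$synonyms) || all(!nzchar(element$synonyms))) {
    stop("element '", element$element_id, "' has no synonyms", call. = FALSE)
  }
  structure(
    list(
      element_id = element$element_id,
      regex = synonym_regex(element$synonyms),
      window_before = as.integer(window_before),
      window_after = as.integer(window_after)
    ),
    class = "echo_pattern"
  )
}

## record-based mention scan (hot path); returns NULL or a list of
## parallel vectors, offsets 0-based half-open
scan_mentions <- function(report_text, element_id, regex,
                          window_before, window_after, sent_starts) {
  m <- gregexpr(regex, report_text, perl = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  start0 <- as.integer(m) - 1L
  end0 <- start0 + attr(m, "match.length")
  ws0 <- pmax(0L, start0 - window_before)
  we0 <- pmin(nchar(report_text), end0 + window_after)
  list(
    element_id = rep(element_id, length(start0)),
    sentence_index = if (length(sent_starts)) findInterval(start0, sent_starts)
                     else rep(NA_integer_, length(start0)),
    mention_start = start0, mention_end = end0,
    window_start = ws0, window_end = we0,
    window_text = substring(report_text, ws0 + 1L, we0)
  )
}

#' Find all mentions of an element in a normalized report
#'
#' One match per synonym occurrence, with context windows clipped at the
#' text boundaries; mentions in different report sections are all
#' returned. Offsets are 0-based half-open into the normalized text.
#'
#' @param report_text Normalized report text.
#' @param sentences Sentence tibble from [segment_sentences()].
#' @param pattern An `echo_pattern` from [build_pattern()].
#' @return A tibble of span matches (possibly empty).
#' @export
find_mentions <- function(report_text, sentences, pattern) {
  rec <- if (nzchar(report_text)) {
    scan_mentions(report_text, pattern$element_id, pattern$regex,
                  pattern$window_before, pattern$window_after,
                  sentences$char_start)
  }
  rid <- if (nrow(sentences)) sentences$report_id[1] else NA_character_
  if (is.null(rec)) {
    return(tibble::tibble(
      element_id = character(), report_id = character(), sentence_index = integer(),
      mention_start = integer(), mention_end = integer(),
      window_start = integer(), window_end = integer(), window_text = character()
    ))
  }
  tibble::tibble(
    element_id = rec$element_id, report_id = rid,
    sentence_index = rec$sentence_index,
    mention_start = rec$mention_start, mention_end = rec$mention_end,
    window_start = rec$window_start, window_end = rec$window_end,
    window_text = rec$window_text
  )
}

## ---- window-level value scanning ------------------------------------------

## lookarounds: reject digits glued to words or decimals, but allow a
## sentence-terminal period ("= 1.5.")
NUM_RX <- "(?<![\\w.])\\d+(?:\\.\\d+)?(?!\\w|\\.\\d)"
RANGE_RX <- "(?<![\\w.])(\\d+(?:\\.\\d+)?)(?:\\s*-\\s*|\\s+to\\s+)(\\d+(?:\\.\\d+)?)(?!\\w|\\.\\d)"
DEID_RX <- "\\[\\*\\*[^]]*?\\*\\*\\]"

spans_of <- function(rx, text) {
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(cbind(start = integer(), end = integer()))
  cbind(start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
}

overlaps <- function(s, e, spans) {
  if (!nrow(spans)) return(FALSE)
  any(s <= spans[, "end"] & e >= spans[, "start"])
}

mask_spans <- function(text, spans) {
  if (!nrow(spans)) return(text)
  for (i in seq_len(nrow(spans))) {
    substr(text, spans[i, 1], spans[i, 2]) <- strrep("#", spans[i, 2] - spans[i, 1] + 1L)
  }
  text
}

## reject values whose adjacency is broken by arrow runs ("1.6 m/s--> 2.0")
arrow_adjacent <- function(text, s, e) {
  pre <- substr(text, max(1L, s - 3L), s - 1L)
  post <- substr(text, e + 1L, min(nchar(text), e + 3L))
  grepl(">", pre, fixed = TRUE) || grepl("^\\s?-{1,2}>", post, perl = TRUE)
}

unit_after <- function(text, e) {
  tail_txt <- substr(text, e + 1L, min(nchar(text), e + 18L))
  m <- regexpr(paste0("^[ ]{0,2}(?i)", UNIT_TOKEN_RX), tail_txt, perl = TRUE)
  if (m == -1) return(list(unit = "", end = e))
  tok <- trimws(substr(tail_txt, 1L, attr(m, "match.length")))
  list(unit = tok, end = e + attr(m, "match.length"))
}

## core parser for one mention window; scalars in, NULL or record out
parse_window <- function(w, ws0, mention_start0, mention_end0, spec) {
  ms <- mention_start0 - ws0 + 1L         # mention, 1-based in window
  me <- mention_end0 - ws0                # inclusive end

  ## a line break in EHR exports separates fields: the value search never
  ## crosses it, so a neighbouring line's numbers cannot be captured
  nl <- gregexpr("\n", w, fixed = TRUE)[[1]]
  if (nl[1] != -1) {
    nl <- as.integer(nl)
    lb <- nl[nl < ms]
    if (length(lb)) {
      cut <- max(lb)
      w <- substr(w, cut + 1L, nchar(w))
      ws0 <- ws0 + cut; ms <- ms - cut; me <- me - cut
      nl <- nl[nl > cut] - cut
    }
    ra <- nl[nl > me]
    if (length(ra)) w <- substr(w, 1L, min(ra) - 1L)
  }

  rec <- function(kind, number = NA_real_, range_low = NA_real_,
                  range_high = NA_real_, category = NA_character_,
                  unit = "", s = NA_integer_, e = NA_integer_,
                  marker = NA_character_) {
    list(kind = kind, number = number, range_low = range_low,
         range_high = range_high, category = category, unit_as_written = unit,
         source_span = if (is.na(s)) NA_character_ else substr(w, s, e),
         span_start = if (is.na(s)) NA_integer_ else ws0 + s - 1L,
         span_end = if (is.na(e)) NA_integer_ else ws0 + e,
         marker = marker)
  }

  deid_spans <- spans_of(DEID_RX, w)
  ## a declared label:value layout binds the value to the right
  label_before_value <- grepl("^\\s?[:=]", substr(w, me + 1L, me + 2L), perl = TRUE)

  candidates <- list()
  if (spec$value_kind == "quantitative") {
    wm <- mask_spans(w, deid_spans)
    rsp <- spans_of(RANGE_RX, wm)
    for (i in seq_len(nrow(rsp))) {
      s <- rsp[i, 1]; e <- rsp[i, 2]
      if (overlaps(s, e, cbind(start = ms, end = me))) next
      parts <- regmatches(substr(wm, s, e), regexec(RANGE_RX, substr(wm, s, e), perl = TRUE))[[1]]
      lo <- as.numeric(parts[2]); hi <- as.numeric(parts[3])
      if (is.na(lo) || is.na(hi) || lo > hi) next
      u <- unit_after(wm, e)
      if (arrow_adjacent(wm, s, u$end)) next
      candidates[[length(candidates) + 1L]] <- list(
        kind = "range", range_low = lo, range_high = hi,
        unit = u$unit, s = s, e = u$end
      )
    }
    nsp <- spans_of(NUM_RX, wm)
    for (i in seq_len(nrow(nsp))) {
      s <- nsp[i, 1]; e <- nsp[i, 2]
      if (nrow(rsp) && overlaps(s, e, rsp)) next
      if (overlaps(s, e, cbind(start = ms, end = me))) next
      u <- unit_after(wm, e)
      if (arrow_adjacent(wm, s, u$end)) next
      candidates[[length(candidates) + 1L]] <- list(
        kind = "number", number = as.numeric(substr(wm, s, e)),
        unit = u$unit, s = s, e = u$end
      )
    }
  } else {
    vsp <- spans_of(vocab_regex(spec$categorical_vocab), w)
    for (i in seq_len(nrow(vsp))) {
      s <- vsp[i, 1]; e <- vsp[i, 2]
      tok <- tolower(gsub("\\s+", " ", substr(w, s, e)))
      ## negation guard: "no significant stenosis" must not yield a grade
      if (tok != "no") {
        prefix <- substr(w, max(1L, s - 30L), s - 1L)
        if (grepl("(?i)\\b(no|without)\\b(\\s+\\w+){0,2}\\s*$", prefix, perl = TRUE)) next
      }
      candidates[[length(candidates) + 1L]] <- list(kind = "category", category = tok, s = s, e = e)
    }
  }

  if (length(candidates)) {
    dist <- vapply(candidates, function(cc) {
      if (cc$s > me) cc$s - me - 1L
      else if (cc$e < ms) if (label_before_value) NA_integer_ else ms - cc$e - 1L
      else 0L
    }, 0L)
    side <- vapply(candidates, function(cc) if (cc$s > me) 0L else 1L, 0L)
    ok <- which(!is.na(dist))
    if (length(ok)) {
      best <- ok[order(dist[ok], side[ok])][1]
      cc <- candidates[[best]]
      return(rec(
        kind = cc$kind,
        number = cc$number %||% NA_real_,
        range_low = cc$range_low %||% NA_real_,
        range_high = cc$range_high %||% NA_real_,
        category = cc$category %||% NA_character_,
        unit = cc$unit %||% "",
        s = cc$s, e = cc$e
      ))
    }
  }

  ## no value: missing markers ("??", de-id placeholder)
  if (nrow(deid_spans)) {
    return(rec("missing_marker", s = deid_spans[1, 1], e = deid_spans[1, 2],
               marker = "deid"))
  }
  qm <- regexpr("\\?{2,}", w, perl = TRUE)
  if (qm != -1) {
    return(rec("missing_marker", s = as.integer(qm),
               e = as.integer(qm) + attr(qm, "match.length") - 1L, marker = "qq"))
  }
  NULL
}

#' Parse the value of one span match
#'
#' Returns at most one parsed value per mention: the candidate nearest to
#' the mention, preferring rightward over leftward at equal distance
#' (label-then-value dominates report layouts). When the window contains a
#' mention but neither a parsable value nor a missing marker, an empty
#' result is returned (a non-extraction, not an error).
#'
#' @param match One row of the tibble produced by [find_mentions()].
#' @param element The element spec owning the mention.
#' @return A tibble with zero or one parsed value.
#' @export
parse_values <- function(match, element) {
  r <- parse_window(match$window_text, match$window_start,
                    match$mention_start, match$mention_end, element)
  if (is.null(r)) return(empty_values())
  tibble::tibble(
    element_id = match$element_id, report_id = match$report_id,
    sentence_index = match$sentence_index, kind = r$kind,
    number = r$number, range_low = r$range_low, range_high = r$range_high,
    category = r$category, unit_as_written = r$unit_as_written,
    source_span = r$source_span, span_start = r$span_start,
    span_end = r$span_end, via_coreference = FALSE, marker = r$marker
  )
}

empty_values <- function() {
  tibble::tibble(
    element_id = character(), report_id = character(), sentence_index = integer(),
    kind = character(), number = numeric(), range_low = numeric(),
    range_high = numeric(), category = character(), unit_as_written = character(),
    source_span = character(), span_start = integer(), span_end = integer(),
    via_coreference = logical(), marker = character()
  )
}

## drop mentions strictly contained in a longer mention of another element
suppress_contained <- function(men) {
  n <- length(men$mention_start)
  if (n < 2) return(men)
  keep <- rep(TRUE, n)
  len <- men$mention_end - men$mention_start
  for (i in seq_len(n)) {
    cont <- men$element_id != men$element_id[i] &
      men$mention_start <= men$mention_start[i] &
      men$mention_end >= men$mention_end[i] & len > len[i]
    if (any(cont)) keep[i] <- FALSE
  }
  lapply(men, function(col) col[keep])
}

## full per-report scan: mentions (with containment suppression), parsed
## values, and co-reference attributions; record-based for speed
scan_report <- function(report_id, norm_text, sentences, registry, config,
                        element_ids = names(registry$specs)) {
  men <- NULL
  for (id in element_ids) {
    rec <- scan_mentions(norm_text, id, registry$patterns[[id]],
                         config$window_before, config$window_after,
                         sentences$char_start)
    if (is.null(rec)) next
    men <- if (is.null(men)) rec else Map(c, men, rec)
  }
  vals <- list()
  if (!is.null(men)) {
    men <- suppress_contained(men)
    for (k in seq_along(men$mention_start)) {
      r <- parse_window(men$window_text[k], men$window_start[k],
                        men$mention_start[k], men$mention_end[k],
                        registry$specs[[men$element_id[k]]])
      if (is.null(r)) next
      r$element_id <- men$element_id[k]
      r$sentence_index <- men$sentence_index[k]
      r$via_coreference <- FALSE
      vals[[length(vals) + 1L]] <- r
    }
  }
  if (config$coreference) {
    vals <- c(vals, coref_records(norm_text, sentences, men, registry,
                                  config$coref_horizon))
  }
  list(report_id = report_id, mentions = men, values = vals)
}

## co-reference core: record list out
coref_records <- function(report_text, sentences, men, registry, horizon = 2L) {
  out <- list()
  if (!nrow(sentences)) return(out)
  ent_sent <- integer(); ent_start <- integer(); ent_valve <- character()
  for (i in seq_len(nrow(sentences))) {
    m <- gregexpr(VALVE_ENTITY_RX, sentences$text[i], perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (k in seq_along(m)) {
      frag <- substr(sentences$text[i], m[k], m[k] + attr(m, "match.length")[k] - 1L)
      valve <- tolower(regmatches(frag, regexpr("(?i)aortic|mitral|tricuspid|pulmonic|pulmonary", frag, perl = TRUE)))
      if (valve == "pulmonary") valve <- "pulmonic"
      ent_sent <- c(ent_sent, i)
      ent_start <- c(ent_start, sentences$char_start[i] + m[k] - 1L)
      ent_valve <- c(ent_valve, valve)
    }
  }
  if (!length(ent_sent)) return(out)
  spec_spans <- if (!is.null(men) && length(men$mention_start)) {
    cbind(start = men$mention_start, end = men$mention_end - 1L)
  } else {
    cbind(start = integer(), end = integer())
  }
  for (i in seq_len(nrow(sentences))) {
    ## cheap guard: any entity within look-ahead horizon of this sentence?
    if (!any(ent_sent >= i - horizon & ent_sent <= i)) next
    for (meas in names(GENERIC_MEASURES)) {
      rx <- paste0("(?i)(?<![a-z0-9])", GENERIC_MEASURES[[meas]], "(?![a-z0-9])")
      m <- gregexpr(rx, sentences$text[i], perl = TRUE)[[1]]
      if (m[1] == -1) next
      for (k in seq_along(m)) {
        gs0 <- sentences$char_start[i] + m[k] - 1L
        ge0 <- gs0 + attr(m, "match.length")[k]
        if (overlaps(gs0, ge0 - 1L, spec_spans)) next
        elig <- which(ent_sent >= i - horizon & ent_sent <= i &
                        (ent_sent < i | ent_start < gs0))
        if (!length(elig)) next
        best <- elig[order(-ent_sent[elig], -ent_start[elig])][1]
        target_id <- COREF_ELEMENT_MAP[[ent_valve[best]]][[meas]]
        ws0 <- max(0L, gs0 - 30L)
        we0 <- min(nchar(report_text), ge0 + 100L)
        r <- parse_window(substring(report_text, ws0 + 1L, we0), ws0, gs0, ge0,
                          registry$specs[[target_id]])
        if (is.null(r)) next
        r$element_id <- target_id
        r$sentence_index <- i
        r$via_coreference <- TRUE
        out[[length(out) + 1L]] <- r
      }
    }
  }
  out
}

values_to_tibble <- function(vals, report_id) {
  if (!length(vals)) return(empty_values())
  tibble::tibble(
    element_id = vapply(vals, `[[`, "", "element_id"),
    report_id = report_id,
    sentence_index = vapply(vals, function(v) as.integer(v$sentence_index), 0L),
    kind = vapply(vals, `[[`, "", "kind"),
    number = vapply(vals, `[[`, 0, "number"),
    range_low = vapply(vals, `[[`, 0, "range_low"),
    range_high = vapply(vals, `[[`, 0, "range_high"),
    category = vapply(vals, `[[`, "", "category"),
    unit_as_written = vapply(vals, `[[`, "", "unit_as_written"),
    source_span = vapply(vals, `[[`, "", "source_span"),
    span_start = vapply(vals, function(v) as.integer(v$span_start), 0L),
    span_end = vapply(vals, function(v) as.integer(v$span_end), 0L),
    via_coreference = vapply(vals, `[[`, TRUE, "via_coreference"),
    marker = vapply(vals, `[[`, "", "marker")
  )
}

mentions_to_tibble <- function(men, report_id) {
  if (is.null(men) || !length(men$mention_start)) {
    return(tibble::tibble(
      element_id = character(), report_id = character(), sentence_index = integer(),
      mention_start = integer(), mention_end = integer(),
      window_start = integer(), window_end = integer(), window_text = character()
    ))
  }
  tibble::tibble(
    element_id = men$element_id, report_id = report_id,
    sentence_index = men$sentence_index,
    mention_start = men$mention_start, mention_end = men$mention_end,
    window_start = men$window_start, window_end = men$window_end,
    window_text = men$window_text
  )
}

#' Attach generic measurements to a previously established valve entity
#'
#' An unstructured sentence often establishes an entity ("A bioprosthetic
#' valve is seen in the aortic position") and reports measurements only as
#' generic phrases in that sentence or one of the next two ("The peak
#' velocity across this valve is 1.9 m/second.", "The mean gradient is 16
#' mmHg"). Such generic mentions are attributed to the entity's specific
#' element with `via_coreference = TRUE`; the nearest preceding entity
#' wins, the look-ahead horizon is two sentences, and attribution never
#' crosses report boundaries. Generic mentions overlapping a specific
#' synonym match are suppressed (the specific pattern already owns them);
#' generic mentions with no entity in the horizon are dropped.
#'
#' @param report_text Normalized report text.
#' @param sentences Sentence tibble for the report.
#' @param specific_mentions Tibble of specific mentions already found
#'   (used for suppression).
#' @param registry An `echo_registry`.
#' @param horizon Look-ahead horizon in sentences (default 2).
#' @return A tibble of parsed values attributed via co-reference.
#' @export
resolve_coreference <- function(report_text, sentences, specific_mentions,
                                registry, horizon = 2L) {
  men <- if (!is.null(specific_mentions) && nrow(specific_mentions)) {
    list(mention_start = specific_mentions$mention_start,
         mention_end = specific_mentions$mention_end)
  }
  recs <- coref_records(report_text, sentences, men, registry, horizon)
  rid <- if (nrow(sentences)) sentences$report_id[1] else NA_character_
  values_to_tibble(recs, rid)
}

#' Extract all element values from one report
#'
#' Runs normalization, segmentation, per-element windowed matching and
#' co-reference resolution for a single report. Used by [extract_corpus()];
#' exported for inspection and debugging.
#'
#' @param report_id Report identifier.
#' @param text Raw report text.
#' @param registry An `echo_registry`.
#' @param config Pipeline configuration from [echo_config()].
#' @return A list with `norm_text`, `sentences`, `mentions`, `values`.
#' @export
extract_report <- function(report_id, text, registry, config = echo_config()) {
  norm <- normalize_text(text)
  sentences <- segment_sentences(norm, report_id)
  hit <- vapply(names(registry$specs),
                function(id) grepl(registry$patterns[[id]], norm, perl = TRUE),
                TRUE)
  sc <- scan_report(report_id, norm, sentences, registry, config,
                    element_ids = names(registry$specs)[hit])
  list(
    norm_text = norm,
    sentences = sentences,
    mentions = mentions_to_tibble(sc$mentions, report_id),
    values = values_to_tibble(sc$values, report_id)
  )
}
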