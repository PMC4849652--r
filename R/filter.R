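#' Consistency filtering
#'
#' Extracted values pass a sequence of checks modelled on how
#' echocardiography data go wrong in practice: typing errors (a gradient
#' written in cm/s, a velocity with no unit at all), systematic but
#' convertible unit variation (cm/s vs m/sec), anatomically or
#' physiologically impossible combinations (a systolic dimension exceeding
#' the diastolic one), and gross transcription outliers (a septal thickness
#' of "1.2 m"). Flags only ever add; no filter alters a magnitude except
#' the documented unit rescaling. A value is `kept` only while it carries
#' no removal-class flag.
#'
#' @name consistency_filter
NULL

#' Canonicalize units of parsed values
#'
#' Unit spellings are normalized and magnitudes rescaled to each element's
#' canonical unit (cm/s -> m/s, mm -> cm, cm2 -> m2 where applicable). A
#' value with no unit is flagged `no_unit` and retained with `kept = FALSE`
#' pending estimation from a surviving duplicate; a dimensionally
#' incompatible or unknown unit is flagged `wrong_unit`. Dimensionless
#' elements (E/A ratio, dimensionless index) accept bare numbers.
#' Missing-marker rows are passed through with `kept = FALSE` (de-id
#' placeholders flagged `deid_placeholder`).
#'
#' @param values Parsed-value tibble from extraction.
#' @param registry An `echo_registry`.
#' @return The tibble with columns `value` (canonical numeric; ranges
#'   collapsed to their midpoint by [collapse_range()]), `unit`, `flags`,
#'   `kept` added.
#' @export
canonicalize_values <- function(values, registry) {
  n <- nrow(values)
  value <- rep(NA_real_, n)
  unit <- rep("", n)
  flags <- rep("", n)
  kept <- rep(TRUE, n)
  for (i in seq_len(n)) {
    sp <- registry$specs[[values$element_id[i]]]
    kind <- values$kind[i]
    if (kind == "category") {
      next
    }
    if (kind == "missing_marker") {
      kept[i] <- FALSE
      if (identical(values$marker[i], "deid")) flags[i] <- "deid_placeholder"
      next
    }
    raw <- if (kind == "range") {
      collapse_range(values$range_low[i], values$range_high[i])
    } else {
      values$number[i]
    }
    conv <- convert_unit(raw, values$unit_as_written[i], sp$canonical_unit)
    value[i] <- conv$value
    unit[i] <- conv$unit
    if (nzchar(conv$flag)) {
      flags[i] <- conv$flag
      kept[i] <- FALSE
    }
  }
  values$value <- value
  values$unit <- unit
  values$flags <- flags
  values$kept <- kept
  values
}

add_flag <- function(flags, new) {
  ifelse(nzchar(flags), paste(flags, new, sep = ";"), new)
}

## same-valve constraint pairs: smaller element id column 1
PHYSIO_DIMENSION_PAIRS <- cbind(smaller = "lveds", larger = "lvedd")
PHYSIO_VALVES <- c("av", "mv", "tr", "pv", "rvot", "lvot")

physio_pairs <- function(velocity_vs_gradient = TRUE) {
  pairs <- list(c("lveds", "lvedd"))
  for (v in PHYSIO_VALVES) {
    if (velocity_vs_gradient) {
      pairs[[length(pairs) + 1L]] <- paste0(v, c("_peak_velocity", "_peak_gradient"))
    }
    pairs[[length(pairs) + 1L]] <- paste0(v, c("_mean_gradient", "_peak_gradient"))
  }
  pairs
}

#' Flag physiologically inconsistent values within a report
#'
#' Constraints: systolic dimensions are smaller than diastolic dimensions
#' (LVEDs < LVEDd); each valve's peak velocity is less than its peak
#' gradient (compared on canonical magnitudes, m/s against mmHg, exactly as
#' stated — numerically valid for physiologic values via the Bernoulli
#' relation and switchable off because it is dimensionally heterodox); and
#' each valve's mean gradient is less than its peak gradient. A violated
#' pair flags BOTH members `physiologic_inconsistent` (symmetric). A report
#' holding only one member of a pair is vacuously consistent.
#'
#' @param values Canonicalized value tibble (one or many reports).
#' @param velocity_vs_gradient Apply the peak-velocity < peak-gradient
#'   constraint (default TRUE).
#' @return The tibble with flags/kept updated.
#' @export
check_physiologic <- function(values, velocity_vs_gradient = TRUE) {
  pairs <- physio_pairs(velocity_vs_gradient)
  usable <- which(values$kept & !is.na(values$value))
  if (!length(usable)) return(values)
  key <- split(usable, paste(values$report_id[usable], values$element_id[usable], sep = "\r"))
  for (rep_id in unique(values$report_id[usable])) {
    for (p in pairs) {
      ia <- key[[paste(rep_id, p[1], sep = "\r")]]
      ib <- key[[paste(rep_id, p[2], sep = "\r")]]
      if (is.null(ia) || is.null(ib)) next
      bad_a <- logical(length(ia)); bad_b <- logical(length(ib))
      for (x in seq_along(ia)) for (y in seq_along(ib)) {
        if (!(values$value[ia[x]] < values$value[ib[y]])) {
          bad_a[x] <- TRUE; bad_b[y] <- TRUE
        }
      }
      for (i in c(ia[bad_a], ib[bad_b])) {
        values$flags[i] <- add_flag(values$flags[i], "physiologic_inconsistent")
        values$kept[i] <- FALSE
      }
    }
  }
  values
}

#' Quartiles by the median-of-halves rule
#'
#' Q1 is the median of the lower half and Q3 the median of the upper half
#' of the sorted sample; with an odd sample size the overall median belongs
#' to neither half.
#'
#' @param x Numeric vector (NAs removed).
#' @return Named numeric vector `c(q1, q3)`.
#' @export
tukey_quartiles <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 2L) return(c(q1 = if (n) x else NA_real_, q3 = if (n) x else NA_real_))
  lower <- x[seq_len(floor(n / 2))]
  upper <- x[seq.int(ceiling(n / 2) + 1L, n)]
  c(q1 = stats::median(lower), q3 = stats::median(upper))
}

#' Flag interquartile-range outliers per element across a corpus
#'
#' Values outside the inclusive fences `[Q1 - k*IQR, Q3 + k*IQR]` are
#' flagged `iqr_outlier` with `kept = FALSE`; `k = 1.5` by default (Tukey
#' convention). Elements with fewer than four usable values are left
#' untouched. With IQR = 0 the fences degenerate to the quartile point and
#' equal values remain inside. Fences depend only on the per-element value
#' multiset, so the filter is invariant to report order.
#'
#' @param values Canonicalized value tibble for the whole corpus.
#' @param k Fence multiplier (default 1.5).
#' @return The tibble with flags/kept updated.
#' @export
iqr_outlier_filter <- function(values, k = 1.5) {
  usable <- which(values$kept & !is.na(values$value))
  if (!length(usable)) return(values)
  for (el in unique(values$element_id[usable])) {
    idx <- usable[values$element_id[usable] == el]
    if (length(idx) < 4L) next
    q <- tukey_quartiles(values$value[idx])
    iqr <- q[["q3"]] - q[["q1"]]
    lo <- q[["q1"]] - k * iqr
    hi <- q[["q3"]] + k * iqr
    out <- idx[values$value[idx] < lo | values$value[idx] > hi]
    for (i in out) {
      values$flags[i] <- add_flag(values$flags[i], "iqr_outlier")
      values$kept[i] <- FALSE
    }
  }
  values
}

#' Flag values outside an element's plausibility range
#'
#' @param values Canonicalized value tibble.
#' @param registry An `echo_registry`.
#' @return The tibble with flags/kept updated.
#' @export
plausible_range_filter <- function(values, registry) {
  for (i in which(!is.na(values$value))) {
    pr <- registry$specs[[values$element_id[i]]]$plausible_range
    if (length(pr) == 2 && (values$value[i] < pr[1] || values$value[i] > pr[2])) {
      values$flags[i] <- add_flag(values$flags[i], "out_of_plausible_range")
      values$kept[i] <- FALSE
    }
  }
  values
}

#' Quantify the burden of missing data
#'
#' Per element, counts the reports without any mention (specific synonym
#' match or co-reference attribution) of that element.
#'
#' @param corpus Corpus tibble.
#' @param registry An `echo_registry`.
#' @param mentions Mention tibble pooled over the corpus (plus attributed
#'   values; any tibble with `report_id` and `element_id` columns works).
#' @return A tibble with `element_id`, `n_reports_total`,
#'   `n_reports_without_mention`, `fraction_missing`.
#' @export
missingness <- function(corpus, registry, mentions) {
  n_total <- nrow(corpus)
  ids <- names(registry$specs)
  with_mention <- if (nrow(mentions)) {
    tapply(mentions$report_id, mentions$element_id, function(x) length(unique(x)))
  } else {
    integer()
  }
  n_with <- vapply(ids, function(id) {
    v <- with_mention[id]
    if (is.na(v)) 0L else as.integer(v)
  }, 0L)
  tibble::tibble(
    element_id = ids,
    n_reports_total = n_total,
    n_reports_without_mention = n_total - n_with,
    fraction_missing = if (n_total) (n_total - n_with) / n_total else NA_real_
  )
}

#' Tabulate flagged values for the filter report
#'
#' @param values Canonicalized and filtered value tibble.
#' @return One row per flagged value: report, element, raw value text,
#'   written unit, flags and kind.
#' @export
filter_report <- function(values) {
  fl <- values[nzchar(values$flags), , drop = FALSE]
  tibble::tibble(
    report_id = fl$report_id,
    element_id = fl$element_id,
    source_span = fl$source_span,
    unit_as_written = fl$unit_as_written,
    value = fl$value,
    flags = fl$flags,
    kind = fl$kind
  )
}
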