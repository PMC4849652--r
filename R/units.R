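#' Measurement-unit homogenization
#'
#' Echocardiography reports write the same dimension with dissimilar but
#' consistent unit spellings (cm/s, m/sec, mm/s; mmhg, mm Hg; cm2, sq. cm).
#' The unit table below maps every accepted spelling to a physical dimension
#' and a factor relative to that dimension's base unit, so values can be
#' rescaled onto each element's canonical unit (cm/s -> m/s is /100, mm ->
#' cm is /10, cm2 -> m2 is /10000, ...). Spellings not in the table are
#' unknown; known spellings of a different dimension than the element's
#' canonical unit are dimensionally incompatible. Both cases are flagged by
#' the consistency filter, never crashed on.
#'
#' @name units
NULL

## dimension base units: velocity m/s, pressure mmHg, length cm, area cm^2,
## time ms, percent %, volume ml, volume_index ml/m^2
UNIT_TABLE <- local({
  u <- function(dimension, factor) list(dimension = dimension, factor = factor)
  list(
    "m/s" = u("velocity", 1), "m/sec" = u("velocity", 1),
    "m/second" = u("velocity", 1), "m per sec" = u("velocity", 1),
    "cm/s" = u("velocity", 1 / 100), "cm/sec" = u("velocity", 1 / 100),
    "cm/second" = u("velocity", 1 / 100),
    "mm/s" = u("velocity", 1 / 1000), "mm/sec" = u("velocity", 1 / 1000),
    "mmhg" = u("pressure", 1), "mm hg" = u("pressure", 1),
    "mm of hg" = u("pressure", 1),
    "cm" = u("length", 1), "cms" = u("length", 1),
    "mm" = u("length", 1 / 10), "m" = u("length", 100),
    "cm2" = u("area", 1), "cm^2" = u("area", 1),
    "sq cm" = u("area", 1), "sq. cm" = u("area", 1), "sqcm" = u("area", 1),
    "mm2" = u("area", 1 / 100), "mm^2" = u("area", 1 / 100),
    "m2" = u("area", 10000), "m^2" = u("area", 10000), "sq m" = u("area", 10000),
    "ms" = u("time", 1), "msec" = u("time", 1),
    "millisecond" = u("time", 1), "milliseconds" = u("time", 1),
    "%" = u("percent", 1), "percent" = u("percent", 1),
    "ml" = u("volume", 1), "cc" = u("volume", 1),
    "cm3" = u("volume", 1), "cm^3" = u("volume", 1),
    "ml/m2" = u("volume_index", 1), "ml/m^2" = u("volume_index", 1),
    "cc/m2" = u("volume_index", 1),
    ## Table-1 spelling of the LA volume index unit
    "cm/m2" = u("volume_index", 1), "cm/m^2" = u("volume_index", 1)
  )
})

normalize_unit_spelling <- function(unit) {
  u <- tolower(gsub("\\s+", " ", trimws(unit)))
  sub("\\.$", "", u)
}

#' Look up a unit spelling
#' @param unit A unit string as written in a report.
#' @return `NULL` for unknown spellings, else a list with `dimension` and
#'   `factor` (multiplier to the dimension's base unit).
#' @keywords internal
unit_info <- function(unit) {
  if (!nzchar(unit)) return(NULL)
  UNIT_TABLE[[normalize_unit_spelling(unit)]]
}

## Regex that captures a unit token immediately after a number; longest
## spellings first so "m/s" beats "m" and "mm hg" beats "mm". The trailing
## generic alternatives catch unit-like typos ("am2", "cm2/m2") so they can
## be flagged wrong_unit instead of silently dropped.
UNIT_TOKEN_RX <- paste0(
  "(?:",
  "mm\\s?of\\s?hg|mm\\s?hg|mmhg",
  "|m\\s?per\\s?sec|m/s(?:econd|ec)?|cm/s(?:econd|ec)?|mm/s(?:ec)?",
  "|ml/m\\^?2|cc/m\\^?2|cm/m\\^?2|cm\\^?2/m\\^?2",
  "|sq\\.?\\s?cm|sq\\.?\\s?m|cm\\^?2|mm\\^?2|m\\^?2|cm\\^?3",
  "|milliseconds?|msec|ms|cms|cm|mm|ml|cc|m",
  "|%|percent",
  "|[a-z]{1,4}\\^?\\d(?:/[a-z]+\\^?\\d?)?",
  ")(?![a-z0-9/])"
)

#' Convert a written magnitude to an element's canonical unit
#'
#' @param value Numeric magnitude as written.
#' @param unit_as_written Unit spelling as written ("" for none).
#' @param canonical_unit The element's canonical unit ("" for
#'   dimensionless).
#' @return A list with `value` (canonical magnitude or `NA`), `unit`
#'   (canonical spelling) and `flag` ("" if clean, else "no_unit" or
#'   "wrong_unit").
#' @keywords internal
convert_unit <- function(value, unit_as_written, canonical_unit) {
  if (!nzchar(canonical_unit)) {
    ## dimensionless element: a written unit is itself an inconsistency
    if (nzchar(unit_as_written)) {
      return(list(value = value, unit = "", flag = "wrong_unit"))
    }
    return(list(value = value, unit = "", flag = ""))
  }
  if (!nzchar(unit_as_written)) {
    return(list(value = value, unit = canonical_unit, flag = "no_unit"))
  }
  wi <- unit_info(unit_as_written)
  ci <- unit_info(canonical_unit)
  if (is.null(wi) || is.null(ci) || wi$dimension != ci$dimension) {
    return(list(value = value, unit = unit_as_written, flag = "wrong_unit"))
  }
  list(value = value * wi$factor / ci$factor, unit = canonical_unit, flag = "")
}
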