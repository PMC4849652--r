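#' Element registry
#'
#' The registry is the single source of truth for the 80 echocardiographic
#' data elements the pipeline targets: 59 quantitative and 21 qualitative,
#' organised in the seven anatomical categories (left ventricle, right
#' ventricle, aortic valve, mitral valve, tricuspid/pulmonic valves, atria,
#' miscellaneous). Each element carries a stable id, a display name, its
#' value kind, a canonical unit (empty for qualitative and dimensionless
#' elements), an ordered categorical vocabulary for qualitative elements
#' (trace < mild < mild-moderate < moderate < moderate-severe < severe for
#' stenosis/regurgitation severity), surface synonyms, and a plausibility
#' range in the canonical unit for quantitative elements.
#'
#' @name registry
NULL

REGISTRY_CATEGORIES <- c(
  "left_ventricle", "right_ventricle", "aortic_valve", "mitral_valve",
  "tricuspid_pulmonic", "atria", "miscellaneous"
)

#' Path of the registry configuration shipped with the package
#' @return File path of the default `elements.yaml`.
#' @export
default_registry_path <- function() {
  system.file("extdata", "elements.yaml", package = "echosift", mustWork = TRUE)
}

fold_term <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

regex_escape <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

## One alternation per element: case-insensitive, flexible internal
## whitespace, token boundaries that tolerate punctuation ("(ava" matches).
synonym_regex <- function(synonyms) {
  syns <- synonyms[order(-nchar(synonyms))]
  alts <- vapply(regex_escape(syns), function(s) gsub(" +", "\\\\s+", s), "")
  paste0("(?i)(?<![a-z0-9])(?:", paste(alts, collapse = "|"), ")(?![a-z0-9])")
}

## Ordered vocabulary alternation; hyphen and dash spellings interchange.
vocab_regex <- function(vocab) {
  toks <- vocab[order(-nchar(vocab))]
  alts <- vapply(regex_escape(toks), function(s) {
    s <- gsub("-", "[-–—]", s, fixed = TRUE)
    gsub(" +", "\\\\s+", s)
  }, "")
  paste0("(?i)(?<![a-z0-9-])(?:", paste(alts, collapse = "|"), ")(?![a-z0-9-])")
}

#' Load the element registry from a configuration file
#'
#' Parses and validates the YAML registry. Validation collects every
#' violation (duplicate ids, ambiguous synonyms, malformed ranges, missing
#' vocabularies, unknown units or categories) and aborts with a diagnostic
#' naming each offending element.
#'
#' @param source Path to a registry YAML file; defaults to the configuration
#'   shipped with the package.
#' @return An object of class `echo_registry`: a list with `version`, an
#'   `elements` tibble, per-element spec list `specs`, and precompiled
#'   synonym patterns.
#' @export
load_registry <- function(source = default_registry_path()) {
  if (!file.exists(source)) {
    stop("registry file not found: ", source, call. = FALSE)
  }
  cfg <- tryCatch(
    yaml::read_yaml(source),
    error = function(e) stop("registry parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(cfg$elements) || !length(cfg$elements)) {
    stop("registry parse error: no 'elements' entry in ", source, call. = FALSE)
  }

  specs <- lapply(cfg$elements, function(e) {
    list(
      element_id = as.character(e$element_id %||% ""),
      display_name = as.character(e$display_name %||% e$element_id %||% ""),
      category = as.character(e$category %||% ""),
      value_kind = as.character(e$value_kind %||% ""),
      canonical_unit = as.character(e$canonical_unit %||% ""),
      synonyms = trimws(unlist(e$synonyms %||% character())),
      categorical_vocab = as.character(unlist(e$categorical_vocab %||% character())),
      plausible_range = as.numeric(unlist(e$plausible_range %||% numeric())),
      table1_cell = as.character(e$table1_cell %||% "")
    )
  })

  problems <- character()
  ids <- vapply(specs, `[[`, "", "element_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate element_id: ", paste(dup, collapse = ", ")))
  }
  for (sp in specs) {
    id <- sp$element_id
    if (!nzchar(id)) problems <- c(problems, "element with empty element_id")
    if (!sp$category %in% REGISTRY_CATEGORIES) {
      problems <- c(problems, paste0(id, ": unknown category '", sp$category, "'"))
    }
    if (!sp$value_kind %in% c("quantitative", "qualitative")) {
      problems <- c(problems, paste0(id, ": value_kind must be quantitative or qualitative"))
    }
    if (!length(sp$synonyms) || any(!nzchar(sp$synonyms))) {
      problems <- c(problems, paste0(id, ": empty synonym"))
    }
    if (sp$value_kind == "qualitative") {
      if (!length(sp$categorical_vocab)) {
        problems <- c(problems, paste0(id, ": qualitative element without categorical_vocab"))
      }
      if (nzchar(sp$canonical_unit)) {
        problems <- c(problems, paste0(id, ": qualitative element must have empty canonical_unit"))
      }
    } else if (sp$value_kind == "quantitative") {
      if (length(sp$plausible_range) != 2 ||
          !(sp$plausible_range[1] < sp$plausible_range[2])) {
        problems <- c(problems, paste0(id, ": plausible_range must be [low, high] with low < high"))
      }
      if (nzchar(sp$canonical_unit) && is.null(unit_info(sp$canonical_unit))) {
        problems <- c(problems, paste0(id, ": unknown canonical_unit '", sp$canonical_unit, "'"))
      }
    }
  }
  syn_tab <- data.frame(
    synonym = fold_term(unlist(lapply(specs, `[[`, "synonyms"))),
    element_id = rep(ids, vapply(specs, function(s) length(s$synonyms), 0L)),
    stringsAsFactors = FALSE
  )
  amb <- tapply(syn_tab$element_id, syn_tab$synonym, function(x) unique(x))
  bad <- amb[vapply(amb, length, 0L) > 1]
  if (length(bad)) {
    problems <- c(problems, vapply(seq_along(bad), function(i) {
      paste0("ambiguous synonym '", names(bad)[i], "' maps to: ",
             paste(bad[[i]], collapse = ", "))
    }, ""))
  }
  if (length(problems)) {
    stop("registry validation failed:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }

  elements <- tibble::tibble(
    element_id = ids,
    display_name = vapply(specs, `[[`, "", "display_name"),
    category = vapply(specs, `[[`, "", "category"),
    value_kind = vapply(specs, `[[`, "", "value_kind"),
    canonical_unit = vapply(specs, `[[`, "", "canonical_unit"),
    n_synonyms = vapply(specs, function(s) length(s$synonyms), 0L)
  )
  names(specs) <- ids
  patterns <- vapply(specs, function(s) synonym_regex(s$synonyms), "")

  structure(
    list(
      version = as.character(cfg$version %||% "unversioned"),
      elements = elements,
      specs = specs,
      patterns = patterns,
      synonym_map = stats::setNames(syn_tab$element_id, syn_tab$synonym),
      config = cfg
    ),
    class = "echo_registry"
  )
}

#' Write a registry back to a YAML file
#'
#' The written file reloads to a registry equal field-for-field to the
#' original (round-trip contract).
#'
#' @param registry An `echo_registry`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "echo_registry"))
  yaml::write_yaml(registry$config, path)
  invisible(path)
}

#' Resolve a surface phrase to its owning element
#'
#' Case-insensitive and flexible about runs of internal whitespace; returns
#' `NA_character_` when no synonym matches (the miss signal — never an
#' error).
#'
#' @param registry An `echo_registry`.
#' @param surface Character vector of surface phrases.
#' @return Character vector of element ids (`NA` for misses).
#' @export
resolve_term <- function(registry, surface) {
  stopifnot(inherits(registry, "echo_registry"))
  out <- unname(registry$synonym_map[fold_term(surface)])
  as.character(out)
}

#' Count registry elements by value kind and category
#'
#' @param registry An `echo_registry`.
#' @return A list with `total`, `by_kind` and `by_category` counts; the
#'   per-kind and per-category counts each sum to `total`.
#' @export
registry_counts <- function(registry) {
  stopifnot(inherits(registry, "echo_registry"))
  el <- registry$elements
  by_kind <- table(factor(el$value_kind, levels = c("quantitative", "qualitative")))
  by_cat <- table(factor(el$category, levels = REGISTRY_CATEGORIES))
  list(
    total = nrow(el),
    by_kind = stats::setNames(as.integer(by_kind), names(by_kind)),
    by_category = stats::setNames(as.integer(by_cat), names(by_cat))
  )
}

#' @export
print.echo_registry <- function(x, ...) {
  cts <- registry_counts(x)
  cat("<echo_registry> version ", x$version, "\n", sep = "")
  cat("  elements: ", cts$total,
      " (quantitative ", cts$by_kind[["quantitative"]],
      ", qualitative ", cts$by_kind[["qualitative"]], ")\n", sep = "")
  cat("  synonyms: ", length(x$synonym_map), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
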