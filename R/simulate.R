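#' Synthetic echocardiography report generator
#'
#' Generates seeded synthetic reports with exact gold annotations so every
#' pipeline stage is testable without protected health information. The
#' generator emulates what makes real report text hard: the three sentence
#' styles (structured label:value lines, single "phrase = value unit"
#' assignments, narrative prose), EHR-export ellipsis noise, synonym
#' variation, unit-spelling variation (cm/s for a velocity stored in m/s),
#' entity/measurement co-reference chains, duplicate mentions across
#' sections, the pre/post-2008 conclusion-position toggle, and the
#' documented corruption modes (typos in element phrases, "-->" arrow runs,
#' de-identification placeholders, wrong or missing units, value ranges).
#'
#' Value laws are truncated normals (mean +/- 2 sd, clipped to the
#' element's plausibility range); same-valve gradients derive from a latent
#' peak velocity through the Bernoulli relation (peak = 4 v^2, mean = 0.6
#' peak) and LVEDs from LVEDd, so clean reports are physiologically
#' consistent by construction and legitimate values sit inside the Tukey
#' fences of the outlier filter.
#'
#' @name synthetic_corpus
NULL

#' Noise-rate configuration for the generator
#'
#' Probabilities per planted value that a given corruption is applied (at
#' most one corruption per value; ellipsis insertion is cosmetic and
#' independent). `expected_extractable` in the gold is FALSE exactly for
#' typo, arrow, de-id, wrong-unit and no-unit corruptions.
#'
#' @param ellipsis,typo,wrong_unit,no_unit,deid,arrow,range Probabilities
#'   in `[0, 1]`.
#' @return Named list of rates.
#' @export
noise_rates <- function(ellipsis = 0.30, typo = 0.02, wrong_unit = 0.01,
                        no_unit = 0.03, deid = 0.01, arrow = 0.01,
                        range = 0.10) {
  r <- list(ellipsis = ellipsis, typo = typo, wrong_unit = wrong_unit,
            no_unit = no_unit, deid = deid, arrow = arrow, range = range)
  bad <- names(r)[vapply(r, function(x) !is.numeric(x) || x < 0 || x > 1, TRUE)]
  if (length(bad)) stop("noise rates must be in [0, 1]: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  r
}

#' Zero-noise rates (clean corpus)
#' @return Named list of all-zero rates.
#' @export
noise_free <- function() {
  noise_rates(ellipsis = 0, typo = 0, wrong_unit = 0, no_unit = 0,
              deid = 0, arrow = 0, range = 0)
}

#' Generator configuration
#'
#' @param seed Integer seed; same seed and config give a byte-identical
#'   corpus and gold.
#' @param n_reports Number of reports.
#' @param prevalence Per-element probability of appearing in a report
#'   (scalar, or named vector by element id; default 0.25).
#' @param structure_mix Proportions of structured / semi_structured /
#'   unstructured renderings (must sum to 1).
#' @param coref_rate Probability that an eligible valve measurement is
#'   rendered via an entity + look-ahead co-reference chain.
#' @param repeat_rate Probability an element is mentioned a second time in
#'   the conclusion section.
#' @param noise Noise rates from [noise_rates()] (or [noise_free()]).
#' @param population Value-law preset: `"default"`, `"severe_as"` (severe
#'   aortic stenosis) or `"post_avr"` (after aortic valve replacement).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_reports = 100L, prevalence = 0.25,
                         structure_mix = c(structured = 0.4,
                                           semi_structured = 0.3,
                                           unstructured = 0.3),
                         coref_rate = 0.15, repeat_rate = 0.10,
                         noise = noise_rates(),
                         population = c("default", "severe_as", "post_avr")) {
  population <- match.arg(population)
  if (abs(sum(structure_mix) - 1) > 1e-8) {
    stop("structure_mix proportions must sum to 1", call. = FALSE)
  }
  probs <- c(unlist(noise), coref_rate = coref_rate, repeat_rate = repeat_rate,
             prevalence = unname(prevalence))
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_reports = as.integer(n_reports),
         prevalence = prevalence, structure_mix = structure_mix,
         coref_rate = coref_rate, repeat_rate = repeat_rate,
         noise = noise, population = population),
    class = "synth_config"
  )
}

## valve latent peak-velocity laws (m/s); population presets shift the
## aortic valve (severe AS: high-gradient jet; post-AVR: normalized)
valve_velocity_laws <- function(population) {
  ## mean/sd ratios >= 5 so the Bernoulli-squared gradient support also
  ## stays inside the Tukey fences (support of 4 v^2 must sit below
  ## Q3 + 1.5 IQR of the transformed law)
  laws <- list(
    av = c(2.0, 0.4), mv = c(1.2, 0.24), tr = c(2.4, 0.45),
    pv = c(0.9, 0.18), rvot = c(0.9, 0.18), lvot = c(1.0, 0.2)
  )
  if (population == "severe_as") laws$av <- c(4.2, 0.4)
  if (population == "post_avr") laws$av <- c(2.0, 0.4)
  laws
}

NORMAL_LAWS <- list(
  lvef = c(58, 7), septal_thickness = c(1.0, 0.15),
  posterior_wall_thickness = c(1.0, 0.15), e_e_prime_ratio = c(9, 2.5),
  rv_basal_dimension = c(3.5, 0.4), tapse = c(2.2, 0.3), rvef = c(55, 7),
  rvot_diameter = c(2.8, 0.35), rvot_vti = c(15, 2.5),
  lvot_diameter = c(2.1, 0.2), lvot_vti = c(20, 3), av_vti = c(25, 5),
  ao_diameter = c(3.2, 0.35), ascending_aorta_diameter = c(3.3, 0.4),
  ava = c(1.8, 0.4), dimensionless_index = c(0.45, 0.1),
  av_pressure_half_time = c(400, 80), av_ero_area = c(25, 8),
  av_regurgitant_fraction = c(30, 8), e_a_ratio = c(1.2, 0.3),
  mv_e_velocity = c(0.9, 0.2), mv_a_velocity = c(0.7, 0.15),
  mv_vti = c(25, 5), mv_pressure_half_time = c(90, 20),
  mv_ero_area = c(20, 6), mv_regurgitant_fraction = c(30, 8),
  mva = c(3.0, 0.7), pasp = c(30, 8), la_diameter = c(3.8, 0.5),
  la_volume_index = c(30, 7), la_volume = c(60, 14),
  ivc_diameter = c(1.8, 0.3), bsa = c(1.9, 0.25)
)

QUAL_WEIGHTS <- list(
  sev6 = c(0.10, 0.30, 0.10, 0.25, 0.10, 0.15),
  leaflet = c(0.5, 0.3, 0.2)
)

UNIT_VARIANTS <- list(
  "m/s" = list(c("m/s", 1), c("m/sec", 1), c("cm/s", 100), c("cm/sec", 100)),
  "mmHg" = list(c("mmHg", 1), c("mmhg", 1), c("mm Hg", 1)),
  "cm" = list(c("cm", 1), c("mm", 10)),
  "cm^2" = list(c("cm2", 1), c("sq cm", 1)),
  "mm^2" = list(c("mm2", 1)),
  "m^2" = list(c("m2", 1)),
  "ms" = list(c("ms", 1), c("msec", 1)),
  "%" = list(c("%", 1)),
  "ml" = list(c("ml", 1), c("cc", 1)),
  "ml/m^2" = list(c("ml/m2", 1), c("cc/m2", 1))
)

unit_digits <- function(canonical_unit) {
  switch(canonical_unit,
         "m/s" = 2L, "mmHg" = 1L, "cm" = 2L, "cm^2" = 2L, "mm^2" = 0L,
         "m^2" = 2L, "ms" = 0L, "%" = 0L, "ml" = 0L, "ml/m^2" = 0L, 2L)
}

## truncated normal: mean +/- 2 sd (then clipped to the plausibility range)
rtrunc2 <- function(m, s) {
  u <- stats::runif(1, stats::pnorm(-2), stats::pnorm(2))
  m + s * stats::qnorm(u)
}

FILLER <- c(
  "The study was technically adequate.",
  "Images were obtained in standard views.",
  "Sinus rhythm was seen throughout the examination.",
  "Prior imaging was unavailable for comparison.",
  "Doppler interrogation was performed in multiple windows."
)

COREF_ELIGIBLE <- as.character(unlist(COREF_ELEMENT_MAP))
VALVE_OF <- stats::setNames(
  rep(names(COREF_ELEMENT_MAP), each = 4),
  as.character(unlist(COREF_ELEMENT_MAP))
)

sample_value <- function(id, spec, latents, nlaws) {
  vm <- regmatches(id, regexec("^(av|mv|tr|pv|rvot|lvot)_(peak_velocity|mean_velocity|peak_gradient|mean_gradient)$", id))[[1]]
  v <- if (length(vm)) {
    valve <- vm[2]
    switch(vm[3],
           peak_velocity = latents[[valve]],
           mean_velocity = 0.7 * latents[[valve]],
           peak_gradient = 4 * latents[[valve]]^2,
           mean_gradient = 0.6 * 4 * latents[[valve]]^2)
  } else if (id == "lvedd") {
    latents$lvedd
  } else if (id == "lveds") {
    latents$lvedd * latents$lveds_ratio
  } else {
    law <- nlaws[[id]]
    rtrunc2(law[1], law[2])
  }
  pr <- spec$plausible_range
  round(min(max(v, pr[1]), pr[2]), unit_digits(spec$canonical_unit))
}

sample_category <- function(spec) {
  vocab <- spec$categorical_vocab
  w <- if (length(vocab) == 6) QUAL_WEIGHTS$sev6
  else if (identical(vocab, c("normal", "thickened", "calcified"))) QUAL_WEIGHTS$leaflet
  else rep(1, length(vocab))
  sample(vocab, 1, prob = w)
}

inject_typo <- function(phrase, registry) {
  alpha <- gregexpr("[a-zA-Z]", phrase)[[1]]
  if (alpha[1] == -1 || length(alpha) < 5) return(NULL)
  for (try in 1:5) {
    pos <- sample(as.integer(alpha), 1)
    repl <- sample(setdiff(letters, tolower(substr(phrase, pos, pos))), 1)
    cand <- phrase
    substr(cand, pos, pos) <- repl
    still <- any(vapply(registry$patterns,
                        function(rx) grepl(rx, paste0(" ", cand, " "), perl = TRUE),
                        TRUE))
    if (!still) return(cand)
  }
  NULL
}

add_ellipsis <- function(sentence) {
  m <- gregexpr(" [a-z0-9]", sentence, perl = TRUE)[[1]]
  if (m[1] == -1) return(sentence)
  pos <- sort(sample(as.integer(m), min(length(m), sample(1:2, 1))), decreasing = TRUE)
  for (p in pos) {
    sentence <- paste0(substr(sentence, 1, p - 1), "..", substr(sentence, p, nchar(sentence)))
  }
  sentence
}

#' Generate a synthetic corpus with gold annotations
#'
#' @param config A [synth_config()].
#' @return A list with `corpus` (tibble: report_id, patient_id,
#'   report_type, text) and `gold` (tibble: report_id, element_id, value,
#'   category, unit, style, corruption, expected_extractable, via_coref).
#'   Reproducible: the same config yields byte-identical output; the gold's
#'   `expected_extractable` is set by the corruption rule, never by running
#'   the extractor.
#' @export
simulate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  registry <- load_registry()
  laws <- valve_velocity_laws(config$population)
  nlaws <- NORMAL_LAWS
  if (config$population == "severe_as") {
    nlaws$ava <- c(0.8, 0.15)
  } else if (config$population == "post_avr") {
    nlaws$ava <- c(1.6, 0.3)
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old_seed, envir = .GlobalEnv)
    }
  })
  set.seed(config$seed)

  ids <- names(registry$specs)
  prev <- if (length(config$prevalence) == 1) {
    stats::setNames(rep(config$prevalence, length(ids)), ids)
  } else {
    p <- rep(0, length(ids)); names(p) <- ids
    p[names(config$prevalence)] <- config$prevalence
    p
  }
  nz <- config$noise

  reports <- vector("list", config$n_reports)
  gold_rows <- vector("list", config$n_reports)

  for (ri in seq_len(config$n_reports)) {
    rid <- sprintf("R%05d", ri)
    pid <- sprintf("P%04d", sample.int(max(2L, config$n_reports %/% 3L), 1))
    rtype <- sample(c("doppler", "transesophageal", "transthoracic", "stress"),
                    1, prob = c(0.70, 0.23, 0.07, 0.06))
    latents <- lapply(laws, function(l) rtrunc2(l[1], l[2]))
    latents$lvedd <- rtrunc2(4.8, 0.5)
    ## fixed systolic/diastolic fraction: keeps LVEDs a pure rescaling of
    ## the bounded LVEDd law (product laws would grow tails past the
    ## outlier fences) while guaranteeing LVEDs < LVEDd
    latents$lveds_ratio <- 0.66

    planted <- ids[stats::runif(length(ids)) < prev[ids]]
    g <- list()
    rendered <- list(structured = character(), semi = character(),
                     unstr = character(), coref = list())

    plant_one <- function(id, in_conclusion = FALSE, forced_value = NULL) {
      spec <- registry$specs[[id]]
      qual <- spec$value_kind == "qualitative"
      value <- NULL; category <- NA_character_
      if (qual) category <- if (is.null(forced_value)) sample_category(spec) else forced_value
      else value <- if (is.null(forced_value)) sample_value(id, spec, latents, nlaws) else forced_value

      style <- sample(names(config$structure_mix), 1, prob = config$structure_mix)
      coref <- !qual && !in_conclusion && id %in% COREF_ELIGIBLE &&
        stats::runif(1) < config$coref_rate
      if (coref) style <- "coref"

      ## at most one corruption per value; chains are kept clean
      corruption <- "none"
      if (!coref) {
        u <- stats::runif(5)
        if (u[1] < nz$typo) corruption <- "typo"
        else if (!qual && u[2] < nz$arrow) corruption <- "arrow"
        else if (u[3] < nz$deid) corruption <- "deid"
        else if (!qual && nzchar(spec$canonical_unit) && u[4] < nz$wrong_unit) corruption <- "wrong_unit"
        else if (!qual && nzchar(spec$canonical_unit) && u[5] < nz$no_unit) corruption <- "no_unit"
        else if (!qual && stats::runif(1) < nz$range) corruption <- "range"
      }

      syn <- sample(spec$synonyms, 1)
      digs <- unit_digits(spec$canonical_unit)
      uv <- if (nzchar(spec$canonical_unit)) {
        vs <- UNIT_VARIANTS[[spec$canonical_unit]]
        vs[[sample.int(length(vs), 1)]]
      } else c("", 1)
      fac <- as.numeric(uv[2])
      fmt <- function(x, f = fac) {
        format(round(x * f, max(0L, digs - as.integer(round(log10(max(f, 1)))))),
               scientific = FALSE, trim = TRUE)
      }

      value_txt <- NULL
      gold_value <- if (qual) NA_real_ else value
      if (!qual) {
        if (corruption == "range") {
          d <- max(10^(-digs), abs(value) * 0.08)
          lo <- round(value - d, digs); hi <- round(value + d, digs)
          joiner <- sample(c("-", " to "), 1)
          value_txt <- paste0(format(lo, scientific = FALSE, trim = TRUE), joiner,
                              format(hi, scientific = FALSE, trim = TRUE),
                              if (nzchar(spec$canonical_unit)) paste0(" ", spec$canonical_unit) else "")
          gold_value <- (lo + hi) / 2
        } else if (corruption == "wrong_unit") {
          dim_now <- unit_info(spec$canonical_unit)$dimension
          bad <- if (dim_now == "pressure") "cm/s" else "mmhg"
          value_txt <- paste(fmt(value, 1), bad)
        } else if (corruption == "no_unit") {
          value_txt <- fmt(value, 1)
        } else if (corruption == "deid") {
          value_txt <- "[**12-02**]"
        } else {
          value_txt <- paste0(fmt(value), if (nzchar(uv[1])) paste0(" ", uv[1]) else "")
          gold_value <- round(value * fac, max(0L, digs - as.integer(round(log10(max(fac, 1)))))) / fac
        }
      } else if (corruption == "deid") {
        value_txt <- "[**Name (NamePattern1)**]"
      } else {
        value_txt <- category
      }

      phrase <- syn
      if (corruption == "typo") {
        tsyn <- spec$synonyms[which.max(nchar(spec$synonyms))]
        typo <- inject_typo(tsyn, registry)
        if (is.null(typo)) corruption <- "none" else phrase <- typo
      }

      sent <- NULL
      if (style == "coref") {
        rendered$coref[[length(rendered$coref) + 1L]] <<- list(
          id = id, valve = VALVE_OF[[id]],
          measure = sub("^(av|mv|tr|pv)_", "", id), value_txt = value_txt
        )
      } else if (style == "structured") {
        rendered$structured <<- c(rendered$structured, paste0(toupper(phrase), ": ", value_txt))
      } else if (style == "semi_structured") {
        first_up <- paste0(toupper(substr(phrase, 1, 1)), substr(phrase, 2, nchar(phrase)))
        sent <- paste0(first_up, " = ", value_txt, ".")
      } else {
        sent <- if (corruption == "arrow") {
          prior <- fmt(if (qual) 1 else value * 0.8)
          paste0("The ", phrase, " has increased from ", prior,
                 if (nzchar(uv[1])) paste0(" ", uv[1]), "--> ", value_txt, ".")
        } else if (qual) {
          ## severity-like grades read naturally before the phrase; other
          ## vocabularies ("basal septal", "thickened") go after the copula
          if (corruption != "deid" &&
              value_txt %in% c("trace", "mild", "mild-moderate", "moderate",
                               "moderate-severe", "severe")) {
            paste0("There is ", value_txt, " ", phrase, ".")
          } else {
            paste0("The ", phrase, " is ", value_txt, ".")
          }
        } else {
          paste0("The ", phrase, " is ", value_txt, ".")
        }
      }
      if (!is.null(sent)) {
        if (stats::runif(1) < nz$ellipsis) {
          sent <- add_ellipsis(sent)
          if (corruption == "none") corruption <- "ellipsis"
        }
        if (in_conclusion || style == "unstructured") rendered$unstr <<- c(rendered$unstr, sent)
        else rendered$semi <<- c(rendered$semi, sent)
      }

      g[[length(g) + 1L]] <<- tibble::tibble(
        report_id = rid, element_id = id, value = gold_value,
        category = category, unit = spec$canonical_unit, style = style,
        corruption = corruption,
        expected_extractable = !corruption %in% c("typo", "arrow", "deid", "wrong_unit", "no_unit"),
        via_coref = style == "coref"
      )
      invisible(NULL)
    }

    for (id in planted) plant_one(id)
    ## duplicate mentions in the conclusion section
    for (id in planted) {
      if (stats::runif(1) < config$repeat_rate) {
        same <- stats::runif(1) < 0.5
        prior <- g[[which(vapply(g, function(x) x$element_id, "") == id)[1]]]
        forced <- if (!same) NULL
        else if (registry$specs[[id]]$value_kind == "qualitative") prior$category
        else prior$value
        plant_one(id, in_conclusion = TRUE, forced_value = forced)
      }
    }

    ## co-reference chains, grouped per valve, contiguous sentences
    coref_sents <- character()
    if (length(rendered$coref)) {
      by_valve <- split(rendered$coref, vapply(rendered$coref, `[[`, "", "valve"))
      for (valve in names(by_valve)) {
        items <- by_valve[[valve]]
        coref_sents <- c(coref_sents, paste0(
          "A bioprosthetic valve is seen in the ", valve, " position, which is well seated."
        ))
        meas <- stats::setNames(
          vapply(items, `[[`, "", "value_txt"),
          vapply(items, `[[`, "", "measure")
        )
        vel <- intersect(c("peak_velocity", "mean_velocity"), names(meas))
        grad <- intersect(c("mean_gradient", "peak_gradient"), names(meas))
        if (length(vel)) {
          parts <- vapply(vel, function(mn) {
            lbl <- sub("_", " ", mn)
            if (mn == vel[1]) paste0("The ", lbl, " across this valve is ", meas[[mn]])
            else paste0("the ", lbl, " is ", meas[[mn]])
          }, "")
          coref_sents <- c(coref_sents, paste0(paste(parts, collapse = " and "), "."))
        }
        if (length(grad)) {
          parts <- vapply(grad, function(mn) {
            lbl <- sub("_", " ", mn)
            paste0("the ", lbl, " is ", meas[[mn]])
          }, "")
          parts[1] <- paste0("T", substr(parts[1], 2, nchar(parts[1])))
          coref_sents <- c(coref_sents, paste0(paste(parts, collapse = " and "), "."))
        }
      }
    }

    meas_section <- c(
      "MEASUREMENTS AND CALCULATIONS:",
      if (length(rendered$structured)) paste(rendered$structured, collapse = " "),
      rendered$semi
    )
    concl_section <- c("CONCLUSION:", rendered$unstr, coref_sents,
                       sample(FILLER, 1))
    head_section <- c("REPORT TEXT:", sample(FILLER, 2))
    body <- if (stats::runif(1) < 0.3) {
      c(head_section, concl_section, meas_section)   # pre-2008 layout
    } else {
      c(head_section, meas_section, concl_section)
    }
    reports[[ri]] <- tibble::tibble(
      report_id = rid, patient_id = pid, report_type = rtype,
      text = paste(body, collapse = "\n")
    )
    gold_rows[[ri]] <- if (length(g)) dplyr::bind_rows(g) else NULL
  }

  gold <- dplyr::bind_rows(gold_rows)
  if (is.null(gold) || !nrow(gold)) {
    gold <- tibble::tibble(
      report_id = character(), element_id = character(), value = numeric(),
      category = character(), unit = character(), style = character(),
      corruption = character(), expected_extractable = logical(),
      via_coref = logical()
    )
  }
  list(corpus = dplyr::bind_rows(reports), gold = gold)
}

#' Write a synthetic corpus to disk
#'
#' Writes one `.txt` per report plus `gold.jsonl` (JSON-lines gold
#' annotations) into a directory.
#'
#' @param sim Result of [simulate_corpus()].
#' @param dir Destination directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_corpus <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(sim$corpus))) {
    writeLines(sim$corpus$text[i],
               file.path(dir, paste0(sim$corpus$report_id[i], ".txt")))
  }
  con <- file(file.path(dir, "gold.jsonl"), "w")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(sim$gold))) {
    writeLines(as.character(jsonlite::toJSON(as.list(sim$gold[i, ]),
                                             auto_unbox = TRUE, digits = NA,
                                             na = "null")), con)
  }
  invisible(dir)
}
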