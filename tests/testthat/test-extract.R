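test_that("pattern templates are generalizable across analogous elements", {
  pav <- build_pattern(REG$specs$av_peak_velocity)
  pmv <- build_pattern(REG$specs$mv_peak_velocity)
  expect_s3_class(pav, "echo_pattern")
  expect_equal(pav$window_before, 30L)
  expect_equal(pav$window_after, 100L)
  # same template, synonym alternation substituted
  expect_false(identical(pav$regex, pmv$regex))
  expect_match(pav$regex, "ao\\s+v2\\s+max", fixed = TRUE)
  p1 <- build_pattern(list(element_id = "x", synonyms = "x"))
  m <- find_mentions("value of X here", segment_sentences("value of X here", "r"), p1)
  expect_equal(nrow(m), 1L)
  expect_error(build_pattern(list(element_id = "bad", synonyms = character())),
               "no synonyms")
})

test_that("find_mentions returns every synonym occurrence with clipped windows", {
  pat <- build_pattern(REG$specs$ava)
  n1 <- normalize_text("ava 0.53 am2.")
  m1 <- find_mentions(n1, segment_sentences(n1, "r"), pat)
  expect_equal(nrow(m1), 1L)
  expect_gte(m1$window_start, 0L)
  expect_lte(m1$window_end, nchar(n1))

  two <- normalize_text(paste(
    "MEASUREMENTS AND CALCULATIONS:\nAORTIC VALVE AREA: 0.9 cm2",
    "CONCLUSION:\nThe aortic valve area is severely reduced at 0.9 cm2.",
    sep = "\n"
  ))
  m2 <- find_mentions(two, segment_sentences(two, "r"), pat)
  expect_equal(nrow(m2), 2L)

  m0 <- find_mentions("nothing relevant", segment_sentences("nothing relevant", "r"), pat)
  expect_equal(nrow(m0), 0L)
})

test_that("windows parse numbers, ranges, categories and missing markers", {
  v <- run_snippet(FIX$range_gradient)
  expect_equal(v$element_id, "av_mean_gradient")
  expect_equal(v$kind, "range")
  expect_equal(v$range_low, 25)
  expect_equal(v$range_high, 30)
  expect_equal(tolower(v$unit_as_written), "mmhg")

  v2 <- run_snippet(FIX$categorical)
  expect_equal(v2$element_id, "aortic_regurgitation")
  expect_equal(v2$category, "moderate-severe")

  # "a to b" ranges and categorical tokens never outside the vocabulary
  v3 <- run_snippet("the mean gradient across the aortic valve is 25 to 30 mmhg.")
  expect_equal(v3$range_low, 25)

  r4 <- extract_corpus(one_report_corpus("Pressure half time…??"), REG)
  expect_equal(r4$values$kind, "missing_marker")
  expect_equal(nrow(kept_values(r4)), 0L)

  # plain number with no unit is parsed (the filter decides its fate)
  r5 <- extract_corpus(one_report_corpus("AV peak velocity ..2.54"), REG)
  expect_equal(r5$values$kind, "number")
  expect_equal(r5$values$number, 2.54)
  expect_equal(r5$values$unit_as_written, "")
})

test_that("negation suppresses qualitative grades and arrows break adjacency", {
  v <- run_snippet("There is no severe aortic stenosis.")
  expect_equal(nrow(v), 0L)
  v2 <- run_snippet("There is severe aortic stenosis.")
  expect_equal(v2$category, "severe")
  # arrow-adjacent numbers rejected on both sides
  v3 <- run_snippet("The peak velocity across the aortic valve increased from 1.6 m/s--> 2.0 m/s")
  expect_equal(nrow(v3), 0L)
})

test_that("look-ahead co-reference attributes generic measurements", {
  res <- extract_corpus(one_report_corpus(FIX$coref), REG)
  v <- kept_values(res)
  expect_setequal(v$element_id, c("av_peak_velocity", "av_mean_gradient", "av_peak_gradient"))
  expect_true(all(v$via_coreference))
  expect_equal(v$value[v$element_id == "av_peak_velocity"], 1.9)
  expect_equal(v$value[v$element_id == "av_mean_gradient"], 16)
  expect_equal(v$value[v$element_id == "av_peak_gradient"], 27)

  # no antecedent within two sentences: the generic value is dropped
  far <- paste(
    "A bioprosthetic valve is seen in the aortic position.",
    "The study was technically adequate.",
    "Images were obtained in standard views.",
    "The rhythm was regular.",
    "The mean gradient is 10 mmHg."
  )
  expect_equal(nrow(kept_values(extract_corpus(one_report_corpus(far), REG))), 0L)
  expect_equal(nrow(kept_values(extract_corpus(one_report_corpus("The mean gradient is 10 mmHg."), REG))), 0L)

  # the nearest preceding entity wins
  near <- paste(
    "A bioprosthetic valve is seen in the aortic position.",
    "A second prosthesis is seen in the mitral position.",
    "The mean gradient is 5.1 mmHg."
  )
  vn <- kept_values(extract_corpus(one_report_corpus(near), REG))
  expect_equal(vn$element_id, "mv_mean_gradient")
})

test_that("provenance spans are verbatim substrings of the normalized text", {
  sim <- simulate_corpus(synth_config(seed = 21, n_reports = 15))
  res <- extract_corpus(sim$corpus, REG)
  norm <- stats::setNames(normalize_text(sim$corpus$text), sim$corpus$report_id)
  v <- res$values[!is.na(res$values$span_start), ]
  recovered <- substring(norm[v$report_id], v$span_start + 1L, v$span_end)
  expect_identical(unname(recovered), v$source_span)
  # categories always come from the element vocabulary
  vc <- v[v$kind == "category", ]
  ok <- vapply(seq_len(nrow(vc)), function(i) {
    vc$category[i] %in% REG$specs[[vc$element_id[i]]]$categorical_vocab
  }, TRUE)
  expect_true(all(ok))
})
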