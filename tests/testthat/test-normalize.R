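test_that("normalization removes export noise and is idempotent", {
  expect_equal(normalize_text("Peak.. velocity across the aortic valve = 5.0 m/s"),
               "Peak velocity across the aortic valve = 5.0 m/s")
  expect_equal(normalize_text("a  b   c"), "a b c")
  # misspellings pass through untouched
  expect_equal(
    normalize_text("The .. forward flow across the bopprosthetic valve is 3.7 m/s"),
    "The forward flow across the bopprosthetic valve is 3.7 m/s"
  )
  # split units are glued back
  expect_equal(normalize_text("28 mm.. Hg"), "28 mm Hg")
  expect_equal(normalize_text(""), "")
  expect_equal(normalize_text(NA_character_), "")
  # idempotence over generated report texts
  sim <- simulate_corpus(synth_config(seed = 11, n_reports = 15))
  n1 <- normalize_text(sim$corpus$text)
  expect_identical(normalize_text(n1), n1)
})

test_that("segmentation keeps measurement lines whole and splits prose", {
  n <- normalize_text(FIX$structured)
  s <- segment_sentences(n, "r")
  expect_equal(nrow(s), 1L)
  expect_match(s$text, "MV E/A: 0.57", fixed = TRUE)
  expect_match(s$text, "AO V2 MAX: 335 cm/sec", fixed = TRUE)

  s3 <- segment_sentences(normalize_text(FIX$coref), "r")
  expect_equal(nrow(s3), 3L)
  expect_match(s3$text[1], "bioprosthetic valve")
  expect_match(s3$text[2], "^The peak velocity")

  expect_equal(nrow(segment_sentences("", "r")), 0L)
})

test_that("sentence offsets are 0-based, ordered, in-bounds and faithful", {
  sim <- simulate_corpus(synth_config(seed = 12, n_reports = 10))
  for (txt in sim$corpus$text[1:5]) {
    n <- normalize_text(txt)
    s <- segment_sentences(n, "r")
    expect_true(all(s$char_start >= 0 & s$char_end <= nchar(n)))
    expect_true(all(diff(s$char_start) > 0))
    expect_true(all(s$char_end[-nrow(s)] <= s$char_start[-1]))  # non-overlap
    # each sentence text is the exact slice of the normalized report
    expect_identical(substring(n, s$char_start + 1L, s$char_end), s$text)
    expect_true(all(nzchar(trimws(s$text))))
  }
})

test_that("structure classification matches the three report styles", {
  expect_equal(classify_structure("MV E/A: 0.57 MVA(P1/2T): 1.4 cm AO V2 MAX: 335 cm/sec"),
               "structured")
  expect_equal(classify_structure("Peak velocity across the aortic valve = 5.0 m/s"),
               "semi_structured")
  expect_equal(classify_structure(
    "The forward flow across the aortic valve is increased at 3.4 m/s with a mean gradient of 28 mm Hg"
  ), "unstructured")
  # total function over generated sentences
  sim <- simulate_corpus(synth_config(seed = 13, n_reports = 10))
  cls <- classify_structure(unlist(lapply(normalize_text(sim$corpus$text),
                                          function(n) segment_sentences(n, "r")$text)))
  expect_true(all(cls %in% c("structured", "semi_structured", "unstructured")))
})

test_that("document selection finds exactly the reports mentioning an element", {
  sim <- simulate_corpus(synth_config(seed = 14, n_reports = 100, noise = noise_free()))
  sel <- select_reports(sim$corpus, "ava", REG)
  planted <- unique(sim$gold$report_id[sim$gold$element_id == "ava"])
  expect_setequal(sel, planted)
  # selection is a superset of reports where extraction succeeds
  res <- extract_corpus(sim$corpus, REG)
  extracted <- unique(res$values$report_id[res$values$element_id == "ava" & res$values$kept])
  expect_true(all(extracted %in% sel))
  expect_length(select_reports(one_report_corpus("No relevant content."), "ava", REG), 0)
})

test_that("corpus readers accept directories and delimited files", {
  dir <- tempfile()
  sim <- simulate_corpus(synth_config(seed = 15, n_reports = 4))
  write_synthetic_corpus(sim, dir)
  corp <- read_corpus(dir)
  expect_equal(nrow(corp), 4L)
  expect_setequal(corp$report_id, sim$corpus$report_id)
  expect_equal(normalize_text(corp$text[order(corp$report_id)]),
               normalize_text(sim$corpus$text[order(sim$corpus$report_id)]))
})
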