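test_that("perfect agreement scores P = R = F1 = 1", {
  sim <- simulate_corpus(synth_config(seed = 51, n_reports = 30, noise = noise_free()))
  # the distribution-level IQR fence needs corpus-scale samples; at 30
  # reports it is underpowered, so score the deterministic filters only
  res <- extract_corpus(sim$corpus, REG, echo_config(iqr = FALSE))
  sc <- score_extraction(res, sim$gold)
  ov <- sc[sc$element_id == "overall", ]
  expect_equal(ov$precision, 1)
  expect_equal(ov$recall, 1)
  expect_equal(ov$f1, 1)
  expect_equal(ov$fp, 0L)
  expect_equal(ov$fn, 0L)
  # micro-average pools per-element counts
  per <- sc[sc$element_id != "overall", ]
  expect_equal(sum(per$tp), ov$tp)
  expect_equal(sum(per$tn), ov$tn)
  # true negatives live on the report x element grid
  expect_true(all(per$tn <= 30L))
  expect_equal(ov$specificity, 1)
  expect_equal(ov$npv, 1)
})

test_that("a hand-counted confusion matrix is scored exactly", {
  gold <- tibble::tibble(
    report_id = c("A", "A", "B"),
    element_id = "lvef",
    value = c(55, 60, 40),
    category = NA_character_, unit = "%", style = "structured",
    corruption = "none", expected_extractable = TRUE, via_coref = FALSE
  )
  pred <- tibble::tibble(
    report_id = c("A", "B"),
    element_id = "lvef",
    n_values = c(2L, 1L),
    values_json = c("[55,60]", "[70]")
  )
  # tp: A/55, A/60; fp: B/70 (mismatch); fn: B/40
  sc <- score_extraction(pred, gold, REG)
  el <- sc[sc$element_id == "lvef", ]
  expect_equal(el$tp, 2L)
  expect_equal(el$fp, 1L)
  expect_equal(el$fn, 1L)
  expect_equal(el$precision, 2 / 3)
  expect_equal(el$recall, 2 / 3)
  expect_equal(el$f1, 2 / 3)
})

test_that("scoring is invariant to record order", {
  sim <- simulate_corpus(synth_config(seed = 52, n_reports = 25))
  res <- extract_corpus(sim$corpus, REG)
  sc1 <- score_extraction(res, sim$gold)
  shuffled <- sim$gold[sample(nrow(sim$gold)), ]
  sc2 <- score_extraction(res, shuffled)
  expect_equal(sc1, sc2)
})

test_that("the F1 formula is consistent with a reference operating point", {
  # harmonic-mean identity on a reference overall precision/recall pair
  expect_equal(round(100 * f1_score(0.9406, 0.9221), 2), 93.13, tolerance = 0.011)
  expect_lt(abs(100 * f1_score(0.9406, 0.9221) - 93.12), 0.01)
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(0.5, 1), 2 / 3)
})

test_that("numeric matching respects the canonicalization tolerance", {
  gold <- tibble::tibble(
    report_id = "A", element_id = "av_peak_velocity", value = 3.35,
    category = NA_character_, unit = "m/s", style = "structured",
    corruption = "none", expected_extractable = TRUE, via_coref = FALSE
  )
  res <- extract_corpus(one_report_corpus("AO V2 MAX: 335 cm/sec", "A"), REG)
  sc <- score_extraction(res, gold)
  expect_equal(sc$recall[sc$element_id == "overall"], 1)
  # loose tolerance pairs nearby values; tight tolerance refuses
  sc2 <- score_extraction(res, dplyr::mutate(gold, value = 3.4), tol = 0.1)
  expect_equal(sc2$tp[sc2$element_id == "overall"], 1L)
  sc3 <- score_extraction(res, dplyr::mutate(gold, value = 3.4))
  expect_equal(sc3$tp[sc3$element_id == "overall"], 0L)
})
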