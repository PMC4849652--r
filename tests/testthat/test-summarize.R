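test_that("ranges collapse to their mean", {
  expect_equal(collapse_range(25, 30), 27.5)
  expect_equal(collapse_range(5, 5), 5)
  expect_equal(collapse_range(1.0, 1.4), 1.2)
  expect_error(collapse_range(3, 2), "low > high")
})

test_that("summaries report count, min, max and document-order last", {
  corp <- one_report_corpus(paste(
    "MEASUREMENTS AND CALCULATIONS:\nAV PEAK VELOCITY: 2.0 m/s",
    "CONCLUSION:\nThe av peak velocity is 1.6 m/s.", sep = "\n"))
  res <- extract_corpus(corp, REG)
  s <- res$summaries[res$summaries$n_values > 0, ]
  expect_equal(s$element_id, "av_peak_velocity")
  expect_equal(s$n_values, 2L)
  expect_equal(s$value_min, 1.6)
  expect_equal(s$value_max, 2.0)
  expect_equal(s$value_last, "1.6")   # positional, not the extreme
  expect_equal(jsonlite::fromJSON(s$values_json), c(2.0, 1.6))

  one <- run_snippet(FIX$coref)
  res1 <- extract_corpus(one_report_corpus(FIX$coref), REG)
  s1 <- res1$summaries[res1$summaries$element_id == "av_peak_velocity", ]
  expect_equal(s1$n_values, 1L)
  expect_equal(s1$value_min, 1.9)
  expect_equal(s1$value_max, 1.9)
  expect_equal(s1$value_last, "1.9")

  # empty summaries are explicit
  empty <- res1$summaries[res1$summaries$element_id == "lvef", ]
  expect_equal(empty$n_values, 0L)
  expect_equal(empty$values_json, "[]")
  expect_true(is.na(empty$value_min))
})

test_that("every summarized value's provenance is among its sentence segments", {
  sim <- simulate_corpus(synth_config(seed = 41, n_reports = 10, noise = noise_free()))
  res <- extract_corpus(sim$corpus, REG)
  s <- res$summaries[res$summaries$n_values > 0, ]
  segs <- lapply(s$sentence_segments_json, jsonlite::fromJSON)
  expect_true(all(lengths(segs) == s$n_values))
})

test_that("the summary table round-trips through TSV byte-identically", {
  sim <- simulate_corpus(synth_config(seed = 42, n_reports = 8))
  res <- extract_corpus(sim$corpus, REG)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_table(res$summaries, f1)
  back <- read_summary_table(f1)
  expect_equal(nrow(back), nrow(res$summaries))
  expect_equal(back$values_json, res$summaries$values_json)
  expect_equal(back$value_min, res$summaries$value_min)
  expect_equal(back$value_last, res$summaries$value_last)
  expect_equal(back$n_values, res$summaries$n_values)
  # re-running and re-writing is byte-identical
  res2 <- extract_corpus(sim$corpus, REG)
  write_table(res2$summaries, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("value histograms bin summarized values half-open", {
  s <- tibble::tibble(
    report_id = as.character(1:3), element_id = "ava", n_values = 1L,
    value_last = c("1", "2", "3")
  )
  expect_equal(value_histogram(s, "ava", c(0, 2, 4)), c(1L, 2L))
  expect_equal(value_histogram(s[0, ], "ava", c(0, 2, 4)), c(0L, 0L))
  expect_error(value_histogram(s, "ava", c(2, 0)), "strictly increasing")
})

test_that("aortic gradient histograms shift down after simulated valve replacement", {
  cfg_as <- synth_config(seed = 43, n_reports = 150, noise = noise_free(),
                         prevalence = 0.5, population = "severe_as")
  cfg_avr <- synth_config(seed = 43, n_reports = 150, noise = noise_free(),
                          prevalence = 0.5, population = "post_avr")
  res_as <- extract_corpus(simulate_corpus(cfg_as)$corpus, REG)
  res_avr <- extract_corpus(simulate_corpus(cfg_avr)$corpus, REG)
  breaks <- c(0, 20, 40, 60, 120)
  h_as <- value_histogram(res_as$summaries, "av_mean_gradient", breaks)
  h_avr <- value_histogram(res_avr$summaries, "av_mean_gradient", breaks)
  # severe AS mass sits above 20 mmHg, post-AVR mass below
  expect_gt(sum(h_as[-1]), sum(h_as[1]))
  expect_gt(h_avr[1], sum(h_avr[-1]))
})
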