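test_that("unit canonicalization homogenizes, flags and never crashes", {
  v <- run_snippet("AO V2 MAX:..335 cm/sec….")
  expect_equal(v$element_id, "av_peak_velocity")
  expect_equal(v$value, 3.35)
  expect_equal(v$unit, "m/s")

  # no unit of measure
  r <- extract_corpus(one_report_corpus("AV peak velocity ..2.54"), REG)
  expect_equal(r$values$flags, "no_unit")
  expect_false(r$values$kept)

  # dimensionally incompatible unit on a gradient
  r2 <- extract_corpus(one_report_corpus("MV mean gradient …21.54 cm/s"), REG)
  expect_match(r2$values$flags, "wrong_unit")
  expect_false(r2$values$kept)

  # unknown unit string flags, never crashes
  r3 <- extract_corpus(one_report_corpus("ava 0.53 am2."), REG)
  expect_match(r3$values$flags[r3$values$element_id == "ava"], "wrong_unit")

  # mm -> cm and mm Hg spelling homogenization
  v4 <- run_snippet("The septal thickness is 10.4 mm.")
  expect_equal(v4$value, 1.04)
  expect_equal(v4$unit, "cm")
  v5 <- run_snippet("The av mean gradient is 12 mm Hg.")
  expect_equal(v5$value, 12)
  expect_equal(v5$unit, "mmHg")
})

test_that("physiologic constraints flag both members of a violated pair", {
  txt <- "LVEDS: 6.0 cm LVEDD: 4.5 cm"
  res <- extract_corpus(one_report_corpus(txt), REG)
  expect_setequal(res$flags$element_id, c("lvedd", "lveds"))
  expect_true(all(grepl("physiologic_inconsistent", res$flags$flags)))

  # consistent gradients raise no flag
  ok <- extract_corpus(one_report_corpus(
    "AV mean gradient = 16 mmHg. AV peak gradient = 27 mmHg."), REG)
  expect_equal(nrow(ok$flags), 0L)
  expect_equal(sort(kept_values(ok)$value), c(16, 27))

  # a lone member of a pair is vacuously consistent
  lone <- extract_corpus(one_report_corpus("LVEDS: 6.0 cm"), REG)
  expect_equal(nrow(lone$flags), 0L)

  # velocity-vs-gradient constraint is switchable
  vio <- one_report_corpus("MV peak velocity = 3.9 m/s. MV peak gradient = 3.0 mmHg.")
  on_ <- extract_corpus(vio, REG, echo_config(iqr = FALSE))
  expect_true(all(grepl("physiologic_inconsistent", on_$flags$flags)))
  expect_equal(nrow(on_$flags), 2L)
  off <- extract_corpus(vio, REG, echo_config(velocity_vs_gradient = FALSE, iqr = FALSE))
  expect_equal(nrow(off$flags), 0L)
})

test_that("quartiles follow the median-of-halves rule", {
  expect_equal(tukey_quartiles(c(1, 2, 3, 4)), c(q1 = 1.5, q3 = 3.5))
  expect_equal(tukey_quartiles(c(1, 2, 3, 4, 5)), c(q1 = 1.5, q3 = 4.5))
  expect_equal(tukey_quartiles(c(7, 1, 5, 3, 9, 11)), c(q1 = 3, q3 = 9))
})

test_that("IQR fences flag unit-magnitude transcription outliers", {
  # septal thicknesses around 1 cm plus a mis-entered "1.2 m" (= 120 cm)
  vals <- tibble::tibble(
    element_id = "septal_thickness",
    report_id = sprintf("R%02d", 1:9),
    kind = "number",
    value = c(0.9, 1.0, 1.1, 1.2, 1.0, 0.95, 1.05, 1.1, 120),
    flags = "", kept = TRUE
  )
  out <- iqr_outlier_filter(vals)
  expect_equal(out$flags[out$value == 120], "iqr_outlier")
  expect_false(out$kept[out$value == 120])
  expect_true(all(out$kept[out$value != 120]))

  # identical values: IQR = 0, fences degenerate, nothing flagged
  same <- tibble::tibble(element_id = "x", report_id = as.character(1:6),
                         kind = "number", value = rep(2.5, 6),
                         flags = "", kept = TRUE)
  expect_true(all(iqr_outlier_filter(same)$kept))

  # fewer than four values: no-op
  few <- same[1:3, ]
  expect_true(all(iqr_outlier_filter(few)$kept))

  # a 10-sigma point planted in a normal sample is caught
  set.seed(42)
  x <- stats::rnorm(200, mean = 10, sd = 1)
  planted <- 10 + 10 * 1
  nv <- tibble::tibble(element_id = "x", report_id = as.character(1:201),
                       kind = "number", value = c(x, planted),
                       flags = "", kept = TRUE)
  out2 <- iqr_outlier_filter(nv)
  expect_match(out2$flags[201], "iqr_outlier")
})

test_that("filtering is report-order invariant and only ever adds flags", {
  sim <- simulate_corpus(synth_config(seed = 31, n_reports = 40))
  res1 <- extract_corpus(sim$corpus, REG)
  perm <- sim$corpus[rev(seq_len(nrow(sim$corpus))), ]
  res2 <- extract_corpus(perm, REG)
  k <- c("report_id", "element_id", "span_start", "value", "flags", "kept")
  a <- dplyr::arrange(res1$values[, k], report_id, element_id, span_start)
  b <- dplyr::arrange(res2$values[, k], report_id, element_id, span_start)
  expect_equal(a, b)
  # magnitudes only change through documented unit rescaling
  raw_num <- res1$values$number[res1$values$kind == "number" &
                                  res1$values$unit_as_written %in% c("", "m/s", "mmHg", "mmhg", "cm", "%")]
  can_num <- res1$values$value[res1$values$kind == "number" &
                                 res1$values$unit_as_written %in% c("", "m/s", "mmHg", "mmhg", "cm", "%")]
  expect_equal(raw_num, can_num)
})

test_that("missingness counts reports without any mention", {
  sim <- simulate_corpus(synth_config(seed = 32, n_reports = 60, noise = noise_free()))
  res <- extract_corpus(sim$corpus, REG)
  planted <- table(factor(unique(sim$gold[, c("report_id", "element_id")])$element_id,
                          levels = names(REG$specs)))
  ms <- res$missingness
  expect_equal(nrow(ms), 80L)
  expect_true(all(ms$fraction_missing >= 0 & ms$fraction_missing <= 1))
  expect_true(all(ms$n_reports_without_mention <= ms$n_reports_total))
  # planted-in-none elements are 100% missing; mentions never undercount gold
  absent <- names(planted)[planted == 0]
  expect_true(all(ms$fraction_missing[ms$element_id %in% absent] == 1))
  with_mention <- ms$n_reports_total - ms$n_reports_without_mention
  expect_true(all(with_mention >= as.integer(planted)[match(ms$element_id, names(planted))]))
})
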