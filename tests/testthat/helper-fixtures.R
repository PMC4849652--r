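# Shared fixtures: the worked example sentences used across the suite and
# small corpus constructors. All fixtures are built in code.

REG <- load_registry()

# structured / semi-structured / unstructured example sentences with
# EHR-export ellipsis noise, and the three-sentence co-reference passage
FIX <- list(
  structured = "MV E/A: ..0.57….MVA(P1/2T):..1.4 cm….AO V2 MAX:..335 cm/sec….",
  semi = "Peak.. velocity across the aortic valve = 5.0 m/s",
  unstructured = "The forward flow across the aortic valve is ..increased at 3.4 m/s with a mean gradient of 28 mm.. Hg",
  coref = paste(
    "A bioprosthetic valve is seen in the aortic position, which is well seated.",
    "The…peak velocity across this valve is 1.9 m/second.",
    "The mean gradient is 16 mmHg ..and peak gradient is 27 mmHg."
  ),
  range_gradient = "the mean gradient across the aortic valve is 25–30 mmhg.",
  categorical = "moderate-severe aortic regurgitation is present."
)

# the six documented failure modes of non-standardized reporting, with the
# element(s) whose value must NOT be extracted from each row
FAIL_ELEMENTS <- list(
  arrow = c("av_peak_velocity", "mv_peak_velocity"),
  missing_phrase = c("av_mean_gradient", "av_peak_gradient"),
  misspelling = c("av_peak_velocity", "av_mean_gradient", "mv_peak_velocity"),
  bracket_digits = "av_mean_gradient",
  bad_area_unit = "ava",
  rare_phrasing = c("aortic_stenosis", "aortic_regurgitation")
)
FAIL_ROWS <- c(
  arrow = "The ..velocity across the AV bioprosthesis has increased.. from 1.6 m/s--> 2.0 m/s",
  missing_phrase = "A bioprosthetic valve ..is present in the aortic position. Maximum ..gradient of 24 mm Hg, mean 13 mm Hg",
  misspelling = "The .. forward flow across the bopprosthetic valve is 3.7 m/s with a mean .. gradient of 30 mm Hg",
  bracket_digits = "across the aortic valve is increased with a mean gradient of [**12–02**] mmhg",
  bad_area_unit = "ava 0.53 am2. (ava index is 0.3 cm2/m2) dimensionless index (tvi ratio) = 0.19",
  rare_phrasing = "there is a well seated, ..well functioning stentless porcine aortic valve. There.. is no significant stenosis or regurgitation of the ..prosthesis"
)

one_report_corpus <- function(text, id = "R00001") {
  tibble::tibble(report_id = id, patient_id = NA_character_,
                 report_type = "unknown", text = text)
}

kept_values <- function(res) {
  res$values[res$values$kept & res$values$kind %in% c("number", "range", "category"), ]
}

# run the pipeline on a single sentence/passage and return kept values
run_snippet <- function(text, config = echo_config()) {
  kept_values(extract_corpus(one_report_corpus(text), REG, config))
}
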