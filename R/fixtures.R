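#' Built-in outcome associations: rs4988235 and neurodegenerative disease
#'
#' Per-study summary statistics for the lactase-persistence variant rs4988235
#' (LCT-13910 C > T) against four neurodegenerative diseases, as released by
#' the source GWAS consortia: multiple sclerosis (IMSGC GWAS and Immunochip),
#' Alzheimer's disease (IGAP and FinnGen R4), Parkinson's disease (PDWBS and
#' PDGene) and amyotrophic lateral sclerosis. Betas are log-odds per T allele;
#' effect-allele frequencies were not released with these single-variant
#' records and are stored as `NA`.
#'
#' @return A validated association tibble (see [read_associations()] for the
#'   column contract) with 7 rows and a `disease` grouping column mapping each
#'   study to its outcome.
#' @examples
#' milk_mr_studies()
#' @export
milk_mr_studies <- function() {
  tbl <- tibble::tibble(
    study_label = c("MS GWAS", "MS Immunochip", "IGAP", "FinnGen",
                    "PDWBS", "PDGene", "ALS GWAS"),
    disease = c("Multiple sclerosis", "Multiple sclerosis",
                "Alzheimer's disease", "Alzheimer's disease",
                "Parkinson's disease", "Parkinson's disease",
                "Amyotrophic lateral sclerosis"),
    variant_id = "rs4988235",
    effect_allele = "T",
    other_allele = "C",
    eaf = NA_real_,
    beta = c(-0.054, -0.063, -0.028, -0.048, 0.048, 0.117, -0.028),
    se = c(0.025, 0.020, 0.016, 0.029, 0.021, 0.020, 0.019),
    p = c(2.93e-2, 1.97e-3, 7.88e-2, 9.76e-2, 2.37e-2, 7.41e-9, 1.35e-1),
    n_cases = c(14802L, 14498L, 21982L, 3060L, 6476L, 13708L, 20806L),
    n_controls = c(26703L, 24091L, 41944L, 173839L, 302042L, 95282L, 59804L)
  )
  validate_associations(tbl, provenance = "builtin:milk_mr_studies")
}

#' Built-in milk-intake instrument records for rs4988235
#'
#' The per-T-allele effect of rs4988235 on habitual milk intake, on two
#' published scales: 17.1 g/day (95% CI 10.6-23.6; EPIC-InterAct) and 0.58
#' glasses/week (95% CI 0.49-0.68; Danish cohorts, n = 73,715). Standard
#' errors are recovered from the CI half-widths. The variant's reported
#' instrument strength (r2 = 0.02, F = 515) is attached to the glasses/week
#' record, whose source cohort reported it.
#'
#' @param units `"g/day"` (default) or `"glasses/week"`.
#' @return An instrument record, see [instrument_record()].
#' @examples
#' milk_instrument()
#' milk_instrument("glasses/week")
#' @export
milk_instrument <- function(units = c("g/day", "glasses/week")) {
  units <- match.arg(units)
  z <- ci_z(0.95)
  if (units == "g/day") {
    instrument_record(
      variant_id = "rs4988235", effect_allele = "T", other_allele = "C",
      beta_exposure = 17.1, se_exposure = (23.6 - 10.6) / (2 * z),
      units = "g/day"
    )
  } else {
    instrument_record(
      variant_id = "rs4988235", effect_allele = "T", other_allele = "C",
      beta_exposure = 0.58, se_exposure = (0.68 - 0.49) / (2 * z),
      units = "glasses/week", r2 = 0.02, n_exposure = 73715L
    )
  }
}
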