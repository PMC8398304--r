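test_that("built-in study fixture carries the seven published records unchanged", {
  tbl <- milk_mr_studies()
  expect_equal(nrow(tbl), 7L)
  expect_true(all(tbl$variant_id == "rs4988235"))
  expect_true(all(tbl$effect_allele == "T"))
  expect_true(all(is.na(tbl$eaf)))

  # frozen field-for-field contents (fixture immutability)
  expect_equal(tbl$study_label,
               c("MS GWAS", "MS Immunochip", "IGAP", "FinnGen",
                 "PDWBS", "PDGene", "ALS GWAS"))
  expect_identical(tbl$beta,
                   c(-0.054, -0.063, -0.028, -0.048, 0.048, 0.117, -0.028))
  expect_identical(tbl$se,
                   c(0.025, 0.020, 0.016, 0.029, 0.021, 0.020, 0.019))
  expect_identical(tbl$n_cases,
                   c(14802L, 14498L, 21982L, 3060L, 6476L, 13708L, 20806L))
  expect_identical(tbl$n_controls,
                   c(26703L, 24091L, 41944L, 173839L, 302042L, 95282L, 59804L))

  pdgene <- dplyr::filter(tbl, study_label == "PDGene")
  expect_equal(pdgene$beta, 0.117)
  expect_equal(pdgene$se, 0.020)
  als <- dplyr::filter(tbl, study_label == "ALS GWAS")
  expect_equal(als$beta, -0.028)
  expect_equal(als$se, 0.019)

  # two calls agree exactly
  expect_identical(as.data.frame(tbl), as.data.frame(milk_mr_studies()))
})

test_that("write/read round-trip is the identity on every field", {
  for (tbl in list(milk_mr_studies(),
                   random_assoc_table(5, seed = 42))) {
    path <- withr::local_tempfile(fileext = ".tsv")
    quietly(write_associations)(tbl, path)
    back <- quietly(read_associations)(path)
    for (f in c("beta", "se", "eaf", "p")) {
      expect_equal(back[[f]], tbl[[f]], tolerance = 1e-12, label = f)
    }
    expect_identical(back$study_label, tbl$study_label)
    expect_identical(back$effect_allele, tbl$effect_allele)
    expect_identical(back$n_cases, tbl$n_cases)
    expect_identical(back$n_controls, tbl$n_controls)
  }
  # absent optional fields written as empty cells and read back as absent
  path <- withr::local_tempfile(fileext = ".tsv")
  quietly(write_associations)(make_assoc(0.1, 0.05), path)
  line2 <- readLines(path)[2]
  expect_match(line2, "\t\t", fixed = TRUE)  # empty eaf cell
  expect_true(is.na(quietly(read_associations)(path)$eaf))
})

test_that("reader applies dialects, flags bad rows by line, and errors on bad files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tEffect\tStdErr",
               "rs1\tT\tC\t-0.054\t0.025",
               "rs1\tT\tC\t0.1\t0",       # se = 0: invariant violation
               "rs1\tT\tC\t0.2\t0.1"), path)
  dial <- default_dialect(variant_id = "SNP", effect_allele = "EA",
                          other_allele = "OA", beta = "Effect", se = "StdErr")
  # study_label column missing entirely -> configuration error
  expect_error(quietly(read_associations)(path, dialect = dial),
               "study_label")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("study_label\tvariant_id\teffect_allele\tother_allele\tbeta\tse",
               "a\trs1\tT\tC\t-0.054\t0.025",
               "b\trs1\tT\tC\t0.1\t0",
               "c\trs1\tT\tC\t0.2\t0.1"), path2)
  expect_warning(tbl <- quietly(read_associations)(path2),
                 "row 2: se must be > 0")
  expect_equal(tbl$study_label, c("a", "c"))

  # header-only file: zero records plus a warning
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("study_label\tvariant_id\teffect_allele\tother_allele\tbeta\tse",
             path3)
  expect_warning(empty <- quietly(read_associations)(path3), "header only")
  expect_equal(nrow(empty), 0L)

  # unparseable numeric names the line
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("study_label\tvariant_id\teffect_allele\tother_allele\tbeta\tse",
               "a\trs1\tT\tC\tnot_a_number\t0.025"), path4)
  expect_error(quietly(read_associations)(path4), "line\\(s\\): 2")

  expect_error(quietly(read_associations)("/nonexistent/file.tsv"), "not found")
})

test_that("odds-ratio input columns are log-transformed at load with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study_label,variant_id,effect_allele,other_allele,beta,se",
               "a,rs1,T,C,0.95,0.025"), path)
  expect_warning(tbl <- quietly(read_associations)(path, or_scale = TRUE),
                 "log-transformed")
  expect_equal(tbl$beta, log(0.95))
})

test_that("validation enforces the record contract", {
  base <- tibble::tibble(study_label = "a", variant_id = "rs1",
                         effect_allele = "T", other_allele = "C",
                         beta = 0.1, se = 0.05)
  expect_error(validate_associations(dplyr::select(base, -beta)), "beta")
  expect_error(quietly(validate_associations)(
    dplyr::bind_rows(base, base)), "unique")
  expect_warning(quietly(validate_associations)(
    dplyr::mutate(base, other_allele = "T")), "equals")
  expect_warning(quietly(validate_associations)(
    dplyr::mutate(base, eaf = 1.4)), "eaf")

  # p consistent with beta/se on the z scale passes quietly...
  ok <- dplyr::mutate(base, p = 2 * pnorm(-abs(beta) / se))
  expect_silent(validate_associations(ok))
  # ...a p from a different test statistic is flagged
  expect_warning(validate_associations(dplyr::mutate(base, p = 0.5)),
                 "inconsistent")
  # the published fixture itself must load without consistency warnings
  expect_silent(milk_mr_studies())
})

test_that("yaml config round-trips dialect, instrument and grouping blocks", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("io:",
               "  dialect:",
               "    beta: Effect",
               "instrument:",
               "  variant_id: rs4988235",
               "  effect_allele: T",
               "  other_allele: C",
               "  beta_exposure: 17.1",
               "  se_exposure: 3.32",
               "  units: g/day",
               "meta:",
               "  'MS GWAS': Multiple sclerosis",
               "  'MS Immunochip': Multiple sclerosis"), path)
  cfg <- read_mr_config(path)
  expect_equal(unname(cfg$io$dialect["beta"]), "Effect")
  expect_s3_class(cfg$instrument, "instrument_record")
  expect_equal(cfg$instrument$beta_exposure, 17.1)
  expect_equal(unname(cfg$meta["MS GWAS"]), "Multiple sclerosis")
})
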