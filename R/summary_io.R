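#' Default column dialect for summary-statistics files
#'
#' A dialect maps the package's canonical field names to the header names
#' used in a particular file, so GWAS-SSF-like, PLINK-like and bespoke
#' exports all load through the same reader. Override any subset, e.g.
#' `default_dialect(beta = "Effect", se = "StdErr")`. Mapping `beta` to a
#' column that holds odds ratios is supported via `or_scale = TRUE` in
#' [read_associations()].
#'
#' @param ... Named overrides, canonical name = file column name.
#' @return Named character vector of canonical -> file column names.
#' @export
default_dialect <- function(...) {
  d <- c(study_label = "study_label", variant_id = "variant_id",
         effect_allele = "effect_allele", other_allele = "other_allele",
         eaf = "eaf", beta = "beta", se = "se", p = "p",
         n_cases = "n_cases", n_controls = "n_controls")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(d))
    if (length(bad)) {
      abort(paste0("Unknown dialect field(s): ", paste(bad, collapse = ", ")))
    }
    d[names(over)] <- over
  }
  d
}

# Canonical fields that must be present in every association table.
MANDATORY_FIELDS <- c("study_label", "variant_id", "effect_allele",
                      "other_allele", "beta", "se")
OPTIONAL_FIELDS <- c("eaf", "p", "n_cases", "n_controls")

#' Validate a table of single-variant association records
#'
#' Enforces the per-record contract: alleles are single A/C/G/T bases and
#' differ within a record; `se > 0`; `eaf` (if present) lies in \[0, 1\];
#' `p` (if present) lies in (0, 1\]; study labels are unique. Rows violating
#' a hard invariant are dropped with a row-numbered warning naming the
#' invariant. If `p` is present it is cross-checked against `|beta|/se` on
#' the z-score scale; disagreement beyond 10% relative error raises a
#' validation warning (rounded published inputs commonly drift this much on
#' the p scale, so the comparison uses z, not p).
#'
#' @param data A data frame with the canonical columns (mandatory:
#'   study_label, variant_id, effect_allele, other_allele, beta, se).
#' @param provenance Free-text origin stamp stored as an attribute.
#' @return A tibble of the surviving records, `provenance` attribute set.
#' @export
validate_associations <- function(data, provenance = "unspecified") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  missing_cols <- setdiff(MANDATORY_FIELDS, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- tibble::as_tibble(data)
  for (f in OPTIONAL_FIELDS) if (!f %in% names(tbl)) tbl[[f]] <- NA
  tbl$eaf <- as.numeric(tbl$eaf)
  tbl$p <- as.numeric(tbl$p)
  tbl$n_cases <- as.integer(tbl$n_cases)
  tbl$n_controls <- as.integer(tbl$n_controls)

  problems <- character(0)
  bad <- rep(FALSE, nrow(tbl))
  flag <- function(idx, why) {
    if (any(idx, na.rm = TRUE)) {
      rows <- which(idx)
      problems <<- c(problems,
                     sprintf("row %d: %s", rows,
                             rep(why, length(rows))))
      bad[idx] <<- TRUE
    }
  }
  flag(!tbl$effect_allele %in% VALID_BASES, "effect_allele not one of A/C/G/T")
  flag(!tbl$other_allele %in% VALID_BASES, "other_allele not one of A/C/G/T")
  flag(tbl$effect_allele == tbl$other_allele, "effect_allele equals other_allele")
  flag(is.na(tbl$beta), "beta missing or unparseable")
  flag(is.na(tbl$se) | tbl$se <= 0, "se must be > 0")
  flag(!is.na(tbl$eaf) & (tbl$eaf < 0 | tbl$eaf > 1), "eaf outside [0, 1]")
  flag(!is.na(tbl$p) & (tbl$p <= 0 | tbl$p > 1), "p outside (0, 1]")
  flag(!is.na(tbl$n_cases) & tbl$n_cases < 0, "n_cases negative")
  flag(!is.na(tbl$n_controls) & tbl$n_controls < 0, "n_controls negative")

  if (length(problems)) {
    warn(paste0("Rejected ", sum(bad), " record(s):\n  ",
                paste(problems, collapse = "\n  ")))
    tbl <- tbl[!bad, , drop = FALSE]
  }
  if (anyDuplicated(tbl$study_label)) {
    abort("`study_label` must be unique within an association table.")
  }

  ok <- !is.na(tbl$p)
  if (any(ok)) {
    z_obs <- abs(tbl$beta[ok]) / tbl$se[ok]
    z_p <- -qnorm(tbl$p[ok] / 2)
    # relative on z for informative z, absolute below z = 1 (a z difference
    # under 0.1 is never scientifically meaningful)
    rel <- abs(z_obs - z_p) / pmax(z_p, 1)
    off <- rel > 0.10
    if (any(off)) {
      warn(sprintf(
        "p inconsistent with |beta|/se (>10%% on z scale) for: %s",
        paste(tbl$study_label[ok][off], collapse = ", ")))
    }
  }
  attr(tbl, "provenance") <- provenance
  tbl
}

#' Read single-variant association records from delimited text
#'
#' Reads a TSV (default) or CSV file with a mandatory header row, renames
#' columns through a dialect mapping, validates records, and reports
#' row-numbered diagnostics for rejected rows. Betas for binary outcomes are
#' expected on the log-odds scale; if the input column holds odds ratios set
#' `or_scale = TRUE` and they are log-transformed at load with a warning.
#'
#' @param path Path to the delimited file.
#' @param dialect Canonical -> file column mapping, see [default_dialect()].
#' @param delim Field delimiter; `NULL` (default) picks `","` for `.csv`
#'   paths and tab otherwise.
#' @param or_scale Is the effect column an odds ratio rather than log-odds?
#' @return A validated association tibble; zero rows (with a warning) for a
#'   header-only file.
#' @export
read_associations <- function(path, dialect = default_dialect(),
                              delim = NULL, or_scale = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- delim %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    na = c("", "NA", "."))

  present <- dialect[dialect %in% names(raw)]
  missing_mand <- setdiff(MANDATORY_FIELDS, names(present))
  if (length(missing_mand)) {
    abort(paste0("Configuration error: mapped column(s) absent from file: ",
                 paste(dialect[missing_mand], collapse = ", ")))
  }
  tbl <- raw[, unname(present), drop = FALSE]
  names(tbl) <- names(present)

  # parse numerics with row-numbered errors
  for (f in intersect(c("eaf", "beta", "se", "p"), names(tbl))) {
    val <- suppressWarnings(as.numeric(tbl[[f]]))
    bad <- !is.na(tbl[[f]]) & is.na(val)
    if (any(bad)) {
      abort(sprintf("Unparseable numeric in column '%s' (file column '%s'), line(s): %s",
                    f, present[[f]],
                    paste(which(bad) + 1L, collapse = ", ")))
    }
    tbl[[f]] <- val
  }
  for (f in intersect(c("n_cases", "n_controls"), names(tbl))) {
    val <- suppressWarnings(as.integer(gsub(",", "", tbl[[f]], fixed = TRUE)))
    bad <- !is.na(tbl[[f]]) & is.na(val)
    if (any(bad)) {
      abort(sprintf("Unparseable count in column '%s', line(s): %s",
                    f, paste(which(bad) + 1L, collapse = ", ")))
    }
    tbl[[f]] <- val
  }
  if (or_scale) {
    if (any(tbl$beta <= 0, na.rm = TRUE)) {
      abort("or_scale = TRUE but non-positive values in the effect column.")
    }
    warn("Effect column read as odds ratios; log-transformed to the log-odds scale.")
    tbl$beta <- log(tbl$beta)
  }
  if (nrow(tbl) == 0L) warn(paste0("No records in ", path, " (header only)."))
  out <- validate_associations(tbl, provenance = path)
  inform(sprintf("Read %d association record(s) from %s", nrow(out), path))
  out
}

#' Write association records to delimited text
#'
#' Full-precision writer: numeric fields are serialised with 17 significant
#' digits so that `read_associations(write_associations(x))` is the identity
#' on every field. Missing optional values become empty cells.
#'
#' @param data A validated association tibble.
#' @param path Output path; `.csv` selects comma delimiting, otherwise TSV.
#' @return `path`, invisibly.
#' @export
write_associations <- function(data, path) {
  data <- validate_associations(data, provenance = attr(data, "provenance") %||% "write")
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- data[, c(MANDATORY_FIELDS[1:4], "eaf",
                  MANDATORY_FIELDS[5:6], "p", "n_cases", "n_controls")]
  for (f in c("eaf", "beta", "se", "p")) {
    out[[f]] <- ifelse(is.na(out[[f]]), "",
                       formatC(out[[f]], digits = 17, format = "g"))
  }
  tryCatch(
    readr::write_delim(out, path, delim = delim, na = ""),
    error = function(e) abort(paste0("Cannot write ", path, ": ",
                                     conditionMessage(e)))
  )
  inform(sprintf("Wrote %d association record(s) to %s", nrow(out), path))
  invisible(path)
}

#' Read an analysis configuration file
#'
#' YAML with up to three blocks: `io` (dialect overrides, delimiter), and
#' `instrument` (fields of [instrument_record()]), `meta` (study_label ->
#' disease grouping map). Absent blocks default sensibly; the default `meta`
#' grouping is the built-in study-to-disease pairing of [milk_mr_studies()].
#'
#' @param path YAML file path.
#' @return List with elements `io`, `instrument` (an instrument record or
#'   `NULL`), and `meta` (named character vector, study_label -> disease).
#' @export
read_mr_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config not found: ", path))
  cfg <- yaml::read_yaml(path)
  io <- cfg$io %||% list()
  dialect <- do.call(default_dialect, as.list(io$dialect %||% list()))
  instrument <- NULL
  if (!is.null(cfg$instrument)) {
    instrument <- do.call(instrument_record, cfg$instrument)
  }
  meta_map <- unlist(cfg$meta %||% split(milk_mr_studies()$disease,
                                         milk_mr_studies()$study_label))
  list(io = list(dialect = dialect, delim = io$delim %||% NULL),
       instrument = instrument, meta = meta_map)
}
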