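COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic_pair <- function(a, b) COMPLEMENT[a] == b

#' Align outcome records to the instrument's effect allele
#'
#' Every Wald ratio requires the outcome beta to refer to the same allele as
#' the exposure beta. Records already on the instrument's effect/other pair
#' pass unchanged; records with the alleles swapped get `beta` negated and
#' `eaf` replaced by `1 - eaf`; records on the opposite strand are base-
#' complemented first (possibly then swapped). Palindromic records (A/T or
#' C/G) are strand-ambiguous: they are kept only when both the record and
#' the instrument carry an allele frequency, both frequencies are farther
#' than `palindromic_eaf_threshold` from 0.5, and their orientation is
#' consistent; otherwise they are dropped. Records whose allele pair cannot
#' be reconciled with the instrument are dropped with a note, never an
#' error, so batch runs survive stray rows.
#'
#' @param data A validated association tibble (see [validate_associations()]).
#' @param effect_allele,other_allele The instrument's allele pair (single
#'   bases), e.g. `"T"`, `"C"` for rs4988235.
#' @param instrument_eaf Effect-allele frequency in the exposure sample, used
#'   only to resolve palindromic records; `NULL` drops all palindromic rows.
#' @param palindromic_eaf_threshold Minimum |eaf - 0.5| required on both
#'   sides before a palindromic record is trusted (default 0.08).
#' @return The harmonized tibble. The per-record action is recorded in an
#'   `action` column; the tally (an `harmonization_report`) is attached as
#'   attribute `"report"` and retrievable with [harmonization_report()].
#' @examples
#' h <- harmonize_to_instrument(milk_mr_studies(), "T", "C")
#' harmonization_report(h)
#' @export
harmonize_to_instrument <- function(data, effect_allele, other_allele,
                                    instrument_eaf = NULL,
                                    palindromic_eaf_threshold = 0.08) {
  assert_allele(effect_allele, "effect_allele")
  assert_allele(other_allele, "other_allele")
  if (effect_allele == other_allele) {
    abort("Instrument effect and other alleles must differ.")
  }
  data <- validate_associations(data,
    provenance = attr(data, "provenance") %||% "harmonize")

  ie <- effect_allele; io <- other_allele
  notes <- character(0)

  classify <- function(ea, oa, eaf, label) {
    # returns list(action, flip_sign)
    if (is_palindromic_pair(ea, oa)) {
      # palindromic record: complement == swap, orientation only resolvable
      # through allele frequencies
      if (!setequal(c(ea, oa), c(ie, io))) {
        return(list(action = "dropped_irreconcilable",
                    note = sprintf("%s: allele pair %s/%s does not match instrument %s/%s",
                                   label, ea, oa, ie, io)))
      }
      if (is.null(instrument_eaf) || is.na(eaf) ||
          abs(eaf - 0.5) <= palindromic_eaf_threshold ||
          abs(instrument_eaf - 0.5) <= palindromic_eaf_threshold) {
        return(list(action = "dropped_palindromic",
                    note = sprintf("%s: palindromic %s/%s not resolvable by allele frequency",
                                   label, ea, oa)))
      }
      # orientation consistent if the frequencies sit on the expected sides
      same_label <- ea == ie
      consistent <- if (same_label) {
        (eaf > 0.5) == (instrument_eaf > 0.5)
      } else {
        (eaf > 0.5) == (instrument_eaf < 0.5)
      }
      if (!consistent) {
        return(list(action = "dropped_palindromic",
                    note = sprintf("%s: palindromic %s/%s frequency orientation inconsistent",
                                   label, ea, oa)))
      }
      return(list(action = if (same_label) "unchanged" else "sign_flipped"))
    }
    if (ea == ie && oa == io) return(list(action = "unchanged"))
    if (ea == io && oa == ie) return(list(action = "sign_flipped"))
    cea <- unname(COMPLEMENT[ea]); coa <- unname(COMPLEMENT[oa])
    if (cea == ie && coa == io) return(list(action = "strand_flipped"))
    if (cea == io && coa == ie) return(list(action = "strand_and_sign_flipped"))
    list(action = "dropped_irreconcilable",
         note = sprintf("%s: allele pair %s/%s irreconcilable with instrument %s/%s",
                        label, ea, oa, ie, io))
  }

  acts <- character(nrow(data))
  for (i in seq_len(nrow(data))) {
    cl <- classify(data$effect_allele[i], data$other_allele[i],
                   data$eaf[i], data$study_label[i])
    acts[i] <- cl$action
    if (!is.null(cl$note)) notes <- c(notes, cl$note)
  }

  out <- data
  swap <- acts %in% c("sign_flipped", "strand_and_sign_flipped")
  comp <- acts %in% c("strand_flipped", "strand_and_sign_flipped")
  out$effect_allele[comp] <- unname(COMPLEMENT[out$effect_allele[comp]])
  out$other_allele[comp] <- unname(COMPLEMENT[out$other_allele[comp]])
  if (any(swap)) {
    tmp <- out$effect_allele[swap]
    out$effect_allele[swap] <- out$other_allele[swap]
    out$other_allele[swap] <- tmp
    out$beta[swap] <- -out$beta[swap]
    out$eaf[swap] <- 1 - out$eaf[swap]
  }
  # palindromic survivors that matched by label already have the right pair
  keep <- !acts %in% c("dropped_palindromic", "dropped_irreconcilable")
  out <- out[keep, , drop = FALSE]
  out$action <- acts[keep]
  stopifnot(all(out$effect_allele == ie))

  report <- structure(list(
    n_input = nrow(data),
    n_unchanged = sum(acts == "unchanged"),
    n_sign_flipped = sum(acts == "sign_flipped"),
    n_strand_flipped = sum(acts == "strand_flipped"),
    n_strand_and_sign_flipped = sum(acts == "strand_and_sign_flipped"),
    n_dropped_palindromic = sum(acts == "dropped_palindromic"),
    n_dropped_irreconcilable = sum(acts == "dropped_irreconcilable"),
    notes = notes), class = "harmonization_report")
  stopifnot(sum(unlist(report[2:7])) == report$n_input)
  if (length(notes)) inform(paste0("harmonize: ", paste(notes, collapse = "; ")))
  attr(out, "report") <- report
  out
}

#' @rdname harmonize_to_instrument
#' @param x A tibble returned by [harmonize_to_instrument()].
#' @export
harmonization_report <- function(x) {
  rep <- attr(x, "report")
  if (is.null(rep)) abort("No harmonization report attached; was this table harmonized?")
  rep
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("Harmonization report:", x$n_input, "record(s)\n")
  cat(sprintf("  unchanged %d | sign-flipped %d | strand-flipped %d | strand+sign %d\n",
              x$n_unchanged, x$n_sign_flipped, x$n_strand_flipped,
              x$n_strand_and_sign_flipped))
  cat(sprintf("  dropped: palindromic %d, irreconcilable %d\n",
              x$n_dropped_palindromic, x$n_dropped_irreconcilable))
  for (n in x$notes) cat("  -", n, "\n")
  invisible(x)
}

#' @method tidy harmonization_report
#' @export
tidy.harmonization_report <- function(x, ...) {
  tibble::tibble(
    action = c("unchanged", "sign_flipped", "strand_flipped",
               "strand_and_sign_flipped", "dropped_palindromic",
               "dropped_irreconcilable"),
    n = c(x$n_unchanged, x$n_sign_flipped, x$n_strand_flipped,
          x$n_strand_and_sign_flipped, x$n_dropped_palindromic,
          x$n_dropped_irreconcilable))
}
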