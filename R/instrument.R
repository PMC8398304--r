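#' Variance in the exposure explained by a diallelic variant
#'
#' Under Hardy-Weinberg equilibrium the allele dosage has variance
#' `2·eaf·(1 - eaf)`, so a per-allele effect `beta` explains
#' `2·eaf·(1 - eaf)·beta² / sd²` of the exposure variance, where `sd` is the
#' total phenotypic standard deviation of the exposure.
#'
#' @param beta_exposure Per-allele effect on the exposure.
#' @param eaf Effect-allele frequency, strictly inside (0, 1).
#' @param exposure_sd Total (phenotypic) SD of the exposure, > 0.
#' @return The explained variance proportion; values computing to ≥ 1 are
#'   clipped to 1 with a warning (the stated effect and SD are then
#'   incompatible).
#' @examples
#' variance_explained(17.1, eaf = 0.7, exposure_sd = 120)
#' @export
variance_explained <- function(beta_exposure, eaf, exposure_sd) {
  assert_scalar_number(beta_exposure, "beta_exposure")
  assert_scalar_number(eaf, "eaf")
  assert_scalar_number(exposure_sd, "exposure_sd", positive = TRUE)
  if (eaf <= 0 || eaf >= 1) {
    abort("Degenerate variant: `eaf` must be strictly inside (0, 1).")
  }
  r2 <- 2 * eaf * (1 - eaf) * beta_exposure^2 / exposure_sd^2
  if (r2 >= 1) {
    warn("Computed r2 >= 1; clipped. The per-allele effect is incompatible with the stated exposure SD.")
    r2 <- 1
  }
  r2
}

#' First-stage F statistic from variance explained
#'
#' `F = r2·(n - k - 1) / (k·(1 - r2))` for `k` instruments (here k = 1); the
#' conventional weak-instrument screen is F > 10.
#'
#' @param r2 Variance explained, in (0, 1).
#' @param n First-stage sample size, must exceed `k + 1`.
#' @param k Number of instruments (default 1).
#' @return The F statistic.
#' @examples
#' f_statistic(0.02, n = 73715)
#' @export
f_statistic <- function(r2, n, k = 1) {
  assert_scalar_number(r2, "r2")
  if (r2 <= 0 || r2 >= 1) abort("`r2` must be strictly inside (0, 1).")
  if (n <= k + 1) abort("`n` must exceed k + 1.")
  r2 * (n - k - 1) / (k * (1 - r2))
}

#' @rdname f_statistic
#' @param f An F statistic, > 0 (inverse mapping back to r2).
#' @export
r2_from_f <- function(f, n, k = 1) {
  assert_scalar_number(f, "f", positive = TRUE)
  if (n <= k + 1) abort("`n` must exceed k + 1.")
  f * k / (f * k + n - k - 1)
}

#' Instrument-strength report
#'
#' Either carries strength figures as published (`source = "reported"`) or
#' computes them from first principles (`source = "computed"`) via
#' [variance_explained()] and [f_statistic()]. Published r2 and F pairs are
#' carried verbatim and deliberately NOT forced to satisfy
#' `F = r2(n-2)/(1-r2)`: consortia often report the two from different
#' underlying regressions, and the report flags such inconsistency instead
#' of silently reconciling it (the built-in milk instrument is one example:
#' r2 = 0.02 at n = 73,715 implies F ≈ 1504, while the published F is 515).
#'
#' @param r2,f_stat,n Reported values (reported mode).
#' @param beta_exposure,eaf,exposure_sd,n_computed Inputs for computed mode.
#' @return A one-row tibble: `r2`, `f_stat`, `n`, `source`, `consistent`.
#' @examples
#' instrument_strength(r2 = 0.02, f_stat = 515, n = 73715)
#' instrument_strength(beta_exposure = 17.1, eaf = 0.7, exposure_sd = 120,
#'                     n_computed = 20000)
#' @export
instrument_strength <- function(r2 = NULL, f_stat = NULL, n = NULL,
                                beta_exposure = NULL, eaf = NULL,
                                exposure_sd = NULL, n_computed = NULL) {
  reported <- !is.null(r2) && !is.null(f_stat)
  if (reported) {
    if (is.null(n)) abort("Reported mode needs `n`.")
    implied_f <- f_statistic(r2, n)
    consistent <- abs(implied_f - f_stat) / f_stat < 0.10
    if (!consistent) {
      inform(sprintf(
        "Reported r2 = %g at n = %d implies F = %.0f, but reported F = %.0f: the two figures come from different regressions.",
        r2, as.integer(n), implied_f, f_stat))
    }
    return(tibble::tibble(r2 = r2, f_stat = f_stat, n = as.integer(n),
                          source = "reported", consistent = consistent))
  }
  if (is.null(beta_exposure) || is.null(eaf) || is.null(exposure_sd) ||
      is.null(n_computed)) {
    abort("Computed mode needs beta_exposure, eaf, exposure_sd and n_computed.")
  }
  r2c <- variance_explained(beta_exposure, eaf, exposure_sd)
  tibble::tibble(r2 = r2c, f_stat = f_statistic(r2c, n_computed),
                 n = as.integer(n_computed), source = "computed",
                 consistent = TRUE)
}
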