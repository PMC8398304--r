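#' Construct an exposure instrument record
#'
#' Bundles the variant-exposure association that anchors every Wald ratio:
#' the per-effect-allele beta on the exposure scale, its standard error, and
#' the units those numbers are in, plus optional instrument-strength
#' metadata (variance explained, first-stage sample size).
#'
#' @param variant_id Variant identifier, e.g. `"rs4988235"`.
#' @param effect_allele,other_allele Single bases A/C/G/T.
#' @param beta_exposure Exposure change per effect allele.
#' @param se_exposure Its standard error (> 0).
#' @param units Text, e.g. `"g/day"`.
#' @param r2 Optional variance in the exposure explained by the variant.
#' @param n_exposure Optional first-stage sample size.
#' @return An object of class `instrument_record`.
#' @export
instrument_record <- function(variant_id, effect_allele, other_allele,
                              beta_exposure, se_exposure, units,
                              r2 = NULL, n_exposure = NULL) {
  assert_allele(effect_allele, "effect_allele")
  assert_allele(other_allele, "other_allele")
  if (effect_allele == other_allele) {
    abort("`effect_allele` and `other_allele` must differ.")
  }
  assert_scalar_number(beta_exposure, "beta_exposure")
  assert_scalar_number(se_exposure, "se_exposure", positive = TRUE)
  if (!is.null(r2)) {
    assert_scalar_number(r2, "r2")
    if (r2 < 0 || r2 > 1) abort("`r2` must lie in [0, 1].")
  }
  structure(list(variant_id = variant_id, effect_allele = effect_allele,
                 other_allele = other_allele,
                 beta_exposure = beta_exposure, se_exposure = se_exposure,
                 units = units, r2 = r2,
                 n_exposure = if (is.null(n_exposure)) NULL else as.integer(n_exposure)),
            class = "instrument_record")
}

#' @export
print.instrument_record <- function(x, ...) {
  cat(sprintf("Instrument %s (%s/%s): %.4g %s per %s allele (SE %.4g)\n",
              x$variant_id, x$effect_allele, x$other_allele,
              x$beta_exposure, x$units, x$effect_allele, x$se_exposure))
  if (!is.null(x$r2)) cat(sprintf("  reported r2 = %g\n", x$r2))
  invisible(x)
}

new_mr_estimates <- function(tbl) {
  stopifnot(all(abs(tbl$or - exp(tbl$beta)) < 1e-12 * pmax(1, tbl$or)),
            all(tbl$ci_low < tbl$or & tbl$or < tbl$ci_high),
            all(tbl$se > 0))
  class(tbl) <- c("mr_estimates", class(tbl))
  tbl
}

estimate_from_beta <- function(label, beta, se, confidence, scale, units) {
  z <- ci_z(confidence)
  tibble::tibble(
    label = label, beta = beta, se = se,
    or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    p = z_pvalue(beta, se), scale = scale, units = units,
    confidence = confidence, weight = 1 / se^2)
}

#' Per-allele odds ratios from harmonized outcome associations
#'
#' For each record the per-effect-allele odds ratio is `exp(beta)`, with a
#' normal-theory confidence interval `exp(beta ± z·se)` and a two-sided
#' normal p-value — the scale on which single-variant MR results against
#' binary outcomes are conventionally reported. z is the exact standard
#' normal quantile for the requested confidence (1.959964... at 95%), not
#' 1.96.
#'
#' @param data Harmonized association tibble (betas on the log-odds scale).
#' @param confidence Two-sided confidence level in (0, 1); default 0.95.
#' @return An `mr_estimates` tibble, one row per study: `label`, `beta`,
#'   `se`, `or`, `ci_low`, `ci_high`, `p`, `scale` (`"per_allele"`),
#'   `weight` (inverse variance).
#' @examples
#' per_allele_estimates(milk_mr_studies())
#' @export
per_allele_estimates <- function(data, confidence = 0.95) {
  data <- validate_associations(data,
    provenance = attr(data, "provenance") %||% "per_allele")
  out <- estimate_from_beta(data$study_label, data$beta, data$se,
                            confidence, "per_allele", "allele")
  if ("disease" %in% names(data)) out$disease <- data$disease
  new_mr_estimates(out)
}

#' Wald-ratio causal estimates per unit of exposure
#'
#' The single-instrument causal estimate: the variant-outcome log-odds beta
#' divided by the variant-exposure beta, interpreted as log-odds of outcome
#' per unit of exposure. The standard error is either first-order
#' (`se_outcome / |beta_exposure|`, exposure beta treated as fixed) or
#' second-order (delta method, propagating the exposure SE:
#' `sqrt(se_y^2/bx^2 + by^2 * se_x^2 / bx^4)`). The second-order SE is never
#' smaller than the first-order one.
#'
#' @inheritParams per_allele_estimates
#' @param instrument An [instrument_record()].
#' @param se_method `"first_order"` (default) or `"second_order"`.
#' @return An `mr_estimates` tibble with `scale = "per_exposure_unit"` and
#'   `units` taken from the instrument.
#' @examples
#' wald_ratio(milk_mr_studies(), milk_instrument())
#' @export
wald_ratio <- function(data, instrument, se_method = c("first_order", "second_order"),
                       confidence = 0.95) {
  se_method <- match.arg(se_method)
  if (!inherits(instrument, "instrument_record")) {
    abort("`instrument` must be an instrument_record.")
  }
  bx <- instrument$beta_exposure
  if (bx == 0) abort("Degenerate instrument: beta_exposure is 0.")
  data <- validate_associations(data,
    provenance = attr(data, "provenance") %||% "wald_ratio")
  misaligned <- data$effect_allele != instrument$effect_allele
  if (any(misaligned)) {
    abort(paste0("Records not harmonized to the instrument's effect allele: ",
                 paste(data$study_label[misaligned], collapse = ", "),
                 ". Run harmonize_to_instrument() first."))
  }
  beta <- data$beta / bx
  se <- switch(se_method,
    first_order = data$se / abs(bx),
    second_order = sqrt(data$se^2 / bx^2 +
                        data$beta^2 * instrument$se_exposure^2 / bx^4))
  out <- estimate_from_beta(data$study_label, beta, se,
                            confidence, "per_exposure_unit", instrument$units)
  if ("disease" %in% names(data)) out$disease <- data$disease
  new_mr_estimates(out)
}

#' Rescale estimates to a different exposure unit
#'
#' Multiplies beta and SE by `factor` — e.g. `factor = 100` turns a per-g/day
#' estimate into per-100-g/day — and recomputes OR, CI and p. The z-score,
#' hence the p-value, is unchanged up to floating-point error.
#'
#' @param estimates An `mr_estimates` tibble.
#' @param factor Positive rescaling factor.
#' @param new_units Label for the rescaled unit.
#' @return The rescaled `mr_estimates` tibble.
#' @export
rescale_estimates <- function(estimates, factor, new_units) {
  assert_scalar_number(factor, "factor", positive = TRUE)
  if (!inherits(estimates, "mr_estimates")) {
    abort("`estimates` must be an mr_estimates tibble.")
  }
  out <- estimate_from_beta(estimates$label,
                            estimates$beta * factor, estimates$se * factor,
                            estimates$confidence[1], estimates$scale[1],
                            new_units)
  extra <- setdiff(names(estimates), names(out))
  for (f in extra) out[[f]] <- estimates[[f]]
  new_mr_estimates(out)
}

#' @export
print.mr_estimates <- function(x, digits = 2, ...) {
  cat(sprintf("MR estimates (%s scale, %g%% CI):\n",
              x$scale[1], 100 * x$confidence[1]))
  fmt <- sprintf("%%-%ds OR %%.%df (%%.%df-%%.%df)  p = %%.3g\n",
                 max(nchar(x$label)) + 2L, digits, digits, digits)
  for (i in seq_len(nrow(x))) {
    cat(sprintf(fmt, x$label[i], x$or[i], x$ci_low[i], x$ci_high[i], x$p[i]))
  }
  invisible(x)
}
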