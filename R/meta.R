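assert_estimates <- function(estimates) {
  if (is.data.frame(estimates) && !"label" %in% names(estimates) &&
      "study_label" %in% names(estimates)) {
    estimates$label <- estimates$study_label   # accept raw association tables
  }
  need <- c("label", "beta", "se")
  if (!is.data.frame(estimates) || !all(need %in% names(estimates))) {
    abort("`estimates` must be a data frame with columns label (or study_label), beta, se.")
  }
  if (nrow(estimates) == 0L) abort("`estimates` is empty.")
  if ("scale" %in% names(estimates) && length(unique(estimates$scale)) > 1L) {
    abort("Estimates on mixed scales cannot be combined; rescale first.")
  }
  if (any(estimates$se <= 0)) abort("All standard errors must be > 0.")
  estimates
}

#' Cochran's Q and I-squared for a set of estimates
#'
#' Q is the inverse-variance-weighted sum of squared deviations of the study
#' betas from the combined beta; its reference distribution under
#' homogeneity is chi-square with k - 1 degrees of freedom.
#' I² = max(0, (Q - df)/Q)·100 expresses the share of total variability
#' attributable to between-study heterogeneity; it floors at 0 exactly when
#' Q ≤ df. The heterogeneity p-value is reported even when I² floors at 0.
#'
#' @param estimates Data frame with `beta` and `se` columns (≥ 2 rows for a
#'   meaningful statistic; with fewer a degenerate Q = 0, df = 0, I² = 0 is
#'   returned with a warning).
#' @param beta_combined The fixed-effects combined beta; computed from
#'   `estimates` when omitted.
#' @return A one-row tibble: `q_stat`, `q_df`, `p_het`, `i2_percent`.
#' @export
heterogeneity <- function(estimates, beta_combined = NULL) {
  estimates <- assert_estimates(estimates)
  k <- nrow(estimates)
  if (k < 2L) {
    warn("Heterogeneity is undefined for fewer than 2 estimates; returning Q = 0.")
    return(tibble::tibble(q_stat = 0, q_df = 0L, p_het = 1, i2_percent = 0))
  }
  w <- 1 / estimates$se^2
  if (is.null(beta_combined)) beta_combined <- sum(w * estimates$beta) / sum(w)
  q <- sum(w * (estimates$beta - beta_combined)^2)
  df <- k - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  tibble::tibble(q_stat = q, q_df = df,
                 p_het = pchisq(q, df, lower.tail = FALSE),
                 i2_percent = i2)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines independent estimates of one quantity with weights `1/se²`:
#' the combined beta is the weighted mean, its standard error
#' `(Σ wᵢ)^(-1/2)`, and OR/CI/p follow by the same exponential transform as
#' the member estimates. A single estimate passes through unchanged with
#' `q_df = 0`. Fixed effects only — a common true effect is assumed
#' regardless of the observed I².
#'
#' @param estimates An `mr_estimates` tibble (or any data frame with
#'   `label`, `beta`, `se`), all on the same scale.
#' @param label Label for the combined estimate (e.g. the disease).
#' @param confidence Two-sided confidence level; defaults to the members'.
#' @return An object of class `mr_meta`; see [tidy.mr_meta()] and
#'   [glance.mr_meta()].
#' @examples
#' ms <- dplyr::filter(per_allele_estimates(milk_mr_studies()),
#'                     disease == "Multiple sclerosis")
#' fixed_effects_meta(ms, label = "Multiple sclerosis")
#' @export
fixed_effects_meta <- function(estimates, label, confidence = NULL) {
  estimates <- assert_estimates(estimates)
  confidence <- confidence %||%
    (if ("confidence" %in% names(estimates)) estimates$confidence[1] else 0.95)
  w <- 1 / estimates$se^2
  beta_c <- sum(w * estimates$beta) / sum(w)
  se_c <- 1 / sqrt(sum(w))
  het <- if (nrow(estimates) >= 2L) {
    heterogeneity(estimates, beta_c)
  } else {
    tibble::tibble(q_stat = 0, q_df = 0L, p_het = 1, i2_percent = 0)
  }
  combined <- estimate_from_beta(
    label, beta_c, se_c, confidence,
    if ("scale" %in% names(estimates)) estimates$scale[1] else "per_allele",
    if ("units" %in% names(estimates)) estimates$units[1] else NA_character_)
  members <- tibble::as_tibble(estimates)
  members$weight_percent <- 100 * w / sum(w)
  structure(list(label = label, members = members, combined = combined,
                 het = het, confidence = confidence),
            class = "mr_meta")
}

#' @export
print.mr_meta <- function(x, digits = 2, ...) {
  cat(sprintf("Fixed-effects meta-analysis: %s (k = %d)\n",
              x$label, nrow(x$members)))
  for (i in seq_len(nrow(x$members))) {
    cat(sprintf("  %-16s OR %.2f (%.2f-%.2f)  weight %.1f%%\n",
                x$members$label[i], exp(x$members$beta[i]),
                exp(x$members$beta[i] - ci_z(x$confidence) * x$members$se[i]),
                exp(x$members$beta[i] + ci_z(x$confidence) * x$members$se[i]),
                x$members$weight_percent[i]))
  }
  cat(sprintf("  Combined         OR %.2f (%.2f-%.2f)  p = %.3g\n",
              x$combined$or, x$combined$ci_low, x$combined$ci_high,
              x$combined$p))
  cat(sprintf("  Heterogeneity: Q = %.3f (df %d), p = %.3f, I2 = %.0f%%\n",
              x$het$q_stat, x$het$q_df, x$het$p_het, x$het$i2_percent))
  if (x$het$i2_percent > 50) {
    cat("  NOTE: substantial heterogeneity; the fixed-effect assumption of a\n",
        "  single common effect is questionable for this pair.\n", sep = "")
  }
  invisible(x)
}

#' Tidy a fixed-effects meta-analysis
#'
#' One row per member study plus one summary row, forest-table style:
#' `label`, `or`, `ci_low`, `ci_high`, `p`, `weight_percent` (members only),
#' `is_summary`.
#'
#' @param x An `mr_meta` object.
#' @param ... Unused.
#' @method tidy mr_meta
#' @export
tidy.mr_meta <- function(x, ...) {
  z <- ci_z(x$confidence)
  m <- x$members
  tibble::tibble(
    label = c(m$label, x$label),
    beta = c(m$beta, x$combined$beta),
    se = c(m$se, x$combined$se),
    or = exp(c(m$beta, x$combined$beta)),
    ci_low = exp(c(m$beta - z * m$se, x$combined$beta - z * x$combined$se)),
    ci_high = exp(c(m$beta + z * m$se, x$combined$beta + z * x$combined$se)),
    p = c(z_pvalue(m$beta, m$se), x$combined$p),
    weight_percent = c(m$weight_percent, NA_real_),
    is_summary = c(rep(FALSE, nrow(m)), TRUE))
}

#' One-row summary of a fixed-effects meta-analysis
#'
#' @param x An `mr_meta` object.
#' @param ... Unused.
#' @return A one-row tibble with the combined estimate and the
#'   heterogeneity statistics (`q_stat`, `q_df`, `p_het`, `i2_percent`).
#' @method glance mr_meta
#' @export
glance.mr_meta <- function(x, ...) {
  tibble::tibble(
    label = x$label, k = nrow(x$members),
    beta = x$combined$beta, se = x$combined$se,
    or = x$combined$or, ci_low = x$combined$ci_low,
    ci_high = x$combined$ci_high, p = x$combined$p,
    q_stat = x$het$q_stat, q_df = x$het$q_df,
    p_het = x$het$p_het, i2_percent = x$het$i2_percent)
}

#' @method autoplot mr_meta
#' @export
autoplot.mr_meta <- function(object, ...) {
  plot_forest(tidy.mr_meta(object), ...)
}
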