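# Builders for small association tables used across tests.

make_assoc <- function(beta, se, label = paste0("study", seq_along(beta)),
                       effect = "T", other = "C", eaf = NA_real_, p = NA_real_) {
  quietly(validate_associations)(tibble::tibble(
    study_label = label, variant_id = "rs_test",
    effect_allele = effect, other_allele = other,
    eaf = eaf, beta = beta, se = se, p = p,
    n_cases = NA_integer_, n_controls = NA_integer_))
}

# run f with messages suppressed (readers/harmonizer log record counts)
quietly <- function(f) function(...) suppressMessages(f(...))

# random association tables for property-style loops
random_assoc_table <- function(n, seed) {
  set.seed(seed)
  make_assoc(beta = rnorm(n, 0, 0.2),
             se = runif(n, 0.01, 0.5),
             eaf = runif(n, 0.05, 0.95))
}

# exact standard-normal 95% quantile used throughout the package
Z95 <- qnorm(0.975)
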