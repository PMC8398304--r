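#' Define a synthetic two-sample MR scenario
#'
#' Parameterises the data-generating process the Wald-ratio analysis
#' assumes: a diallelic variant under Hardy-Weinberg equilibrium (dosage
#' `G ~ Binomial(2, eaf)`), a continuous exposure
#' `X = beta_gx·G + Normal(0, exposure_sd)`, and a binary outcome whose
#' log-odds are `alpha + theta·X + pleiotropy_beta·G`. Exposure and outcome
#' are observed in two non-overlapping samples; the outcome sample is
#' ascertained case-control. Setting `pleiotropy_beta != 0` deliberately
#' violates the exclusion-restriction (third IV) assumption, for
#' sensitivity studies.
#'
#' Defaults mirror the milk-intake instrument: effect-allele frequency 0.7
#' (European-like placeholder), 17.1 exposure units (g/day) per allele,
#' residual SD 120 g/day, baseline log-odds -2.2 (about 10% background
#' risk), and a null causal effect.
#'
#' @param eaf Instrument effect-allele frequency, in (0, 1).
#' @param beta_gx Exposure units per effect allele.
#' @param exposure_sd Residual SD of the exposure, > 0.
#' @param theta Causal log-odds of outcome per exposure unit.
#' @param alpha Baseline log-odds of outcome.
#' @param n_exposure_sample Exposure-sample size.
#' @param n_cases,n_controls Outcome-sample quotas.
#' @param pleiotropy_beta Direct variant-to-outcome log-odds per allele.
#' @param seed Integer seed governing all randomness downstream.
#' @param draw_cap Maximum population draws before the case-control
#'   ascertainment gives up (guards scenarios where cases are essentially
#'   unobtainable).
#' @return A validated `sim_scenario` object (a named list).
#' @export
sim_scenario <- function(eaf = 0.7, beta_gx = 17.1, exposure_sd = 120,
                         theta = 0, alpha = -2.2,
                         n_exposure_sample = 10000,
                         n_cases = 2000, n_controls = 2000,
                         pleiotropy_beta = 0, seed = 1L,
                         draw_cap = 1e8) {
  assert_scalar_number(eaf, "eaf")
  if (eaf <= 0 || eaf >= 1) abort("`eaf` must be strictly inside (0, 1).")
  assert_scalar_number(beta_gx, "beta_gx")
  assert_scalar_number(exposure_sd, "exposure_sd", positive = TRUE)
  assert_scalar_number(theta, "theta")
  assert_scalar_number(alpha, "alpha")
  assert_scalar_number(pleiotropy_beta, "pleiotropy_beta")
  for (nm in c("n_exposure_sample", "n_cases", "n_controls")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1) {
      abort(sprintf("`%s` must be a count >= 1.", nm))
    }
  }
  structure(list(eaf = eaf, beta_gx = beta_gx, exposure_sd = exposure_sd,
                 theta = theta, alpha = alpha,
                 n_exposure_sample = as.integer(n_exposure_sample),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 pleiotropy_beta = pleiotropy_beta,
                 seed = as.integer(seed), draw_cap = draw_cap),
            class = "sim_scenario")
}

# Expand one master seed into n reproducible, effectively independent
# substream seeds (documented counter scheme: seed the generator with the
# master and draw n integers below 2^31 - 1).
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

sim_assoc_row <- function(label, eaf_hat, beta, se, n_cases = NA_integer_,
                          n_controls = NA_integer_) {
  tibble::tibble(
    study_label = label, variant_id = "rs_sim",
    effect_allele = "T", other_allele = "C",
    eaf = eaf_hat, beta = beta, se = se, p = z_pvalue(beta, se),
    n_cases = n_cases, n_controls = n_controls)
}

#' Simulate the exposure-sample GWAS of a scenario
#'
#' Draws the exposure sample, regresses exposure on allele dosage by
#' ordinary least squares, and returns the variant-exposure association as
#' a standard association record. Deterministic given the seed.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Seed override; defaults to the scenario's.
#' @return A one-row association tibble (`study_label = "sim exposure"`).
#' @export
simulate_exposure_gwas <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(as.integer(seed))
  n <- scenario$n_exposure_sample
  g <- rbinom(n, 2L, scenario$eaf)
  x <- scenario$beta_gx * g + rnorm(n, 0, scenario$exposure_sd)
  fit <- lm(x ~ g)
  validate_associations(
    sim_assoc_row("sim exposure", mean(g) / 2,
                  unname(coef(fit)[2]),
                  sqrt(vcov(fit)[2, 2])),
    provenance = "simulate_exposure_gwas")
}

#' Simulate the outcome-sample case-control GWAS of a scenario
#'
#' Draws population individuals (genotype, latent exposure, Bernoulli
#' disease status with probability `plogis(alpha + theta·X +
#' pleiotropy_beta·G)`) and keeps them until the case and control quotas are
#' both filled — the same ascertainment a case-control GWAS applies. The
#' per-allele log-odds ratio is then estimated by logistic regression of
#' status on allele dosage, fitted by iteratively reweighted least squares
#' (convergence tolerance 1e-10, at most 50 iterations) on the
#' genotype-collapsed data, which carries the identical likelihood.
#'
#' @inheritParams simulate_exposure_gwas
#' @return A one-row association tibble with the realised case/control
#'   counts.
#' @export
simulate_outcome_gwas <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(as.integer(seed))
  need_cases <- scenario$n_cases
  need_controls <- scenario$n_controls
  case_g <- integer(3)    # genotype counts 0/1/2 among kept cases
  control_g <- integer(3)
  drawn <- 0
  batch <- max(10000L, 4L * (need_cases + need_controls))
  while (need_cases > 0L || need_controls > 0L) {
    if (drawn >= scenario$draw_cap) {
      abort(sprintf(
        "Draw cap (%g) reached with %d case(s) and %d control(s) still needed: case probability is likely ~0 or ~1 under this scenario.",
        scenario$draw_cap, need_cases, need_controls))
    }
    m <- as.integer(min(batch, scenario$draw_cap - drawn))
    drawn <- drawn + m
    g <- rbinom(m, 2L, scenario$eaf)
    x <- scenario$beta_gx * g + rnorm(m, 0, scenario$exposure_sd)
    pr <- stats::plogis(scenario$alpha + scenario$theta * x +
                        scenario$pleiotropy_beta * g)
    status <- rbinom(m, 1L, pr)
    # keep individuals in draw order until each quota fills; draws are iid,
    # so truncation does not bias the genotype mix
    take_c <- head(which(status == 1L), need_cases)
    take_t <- head(which(status == 0L), need_controls)
    case_g <- case_g + tabulate(g[take_c] + 1L, 3L)
    control_g <- control_g + tabulate(g[take_t] + 1L, 3L)
    need_cases <- scenario$n_cases - sum(case_g)
    need_controls <- scenario$n_controls - sum(control_g)
  }

  dat <- data.frame(g = 0:2, cases = case_g, controls = control_g)
  dat <- dat[dat$cases + dat$controls > 0, , drop = FALSE]
  fit <- suppressWarnings(
    glm(cbind(cases, controls) ~ g, family = binomial(), data = dat,
        control = stats::glm.control(epsilon = 1e-10, maxit = 50)))
  if (!fit$converged || abs(coef(fit)[2]) > 15) {
    # IRLS either hit maxit or walked the slope to the boundary; either way
    # a finite MLE does not exist for this draw
    abort("Logistic fit did not converge; complete separation of genotype groups is the likely cause.")
  }
  out <- validate_associations(
    sim_assoc_row("sim outcome",
                  (sum(control_g * 0:2)) / (2 * sum(control_g)),
                  unname(coef(fit)[2]), sqrt(vcov(fit)[2, 2]),
                  n_cases = sum(case_g), n_controls = sum(control_g)),
    provenance = "simulate_outcome_gwas")
  attr(out, "genotype_table") <- dat  # collapsed data behind the fit
  out
}

#' Simulate both samples of a two-sample MR study
#'
#' @inheritParams simulate_exposure_gwas
#' @return A list with `exposure_assoc`, `outcome_assoc` (independent
#'   samples drawn from derived substream seeds) and `truths` (the
#'   scenario).
#' @export
simulate_two_sample <- function(scenario, seed = scenario$seed) {
  seeds <- derive_seeds(seed, 2L)
  list(exposure_assoc = simulate_exposure_gwas(scenario, seeds[1]),
       outcome_assoc = simulate_outcome_gwas(scenario, seeds[2]),
       truths = scenario)
}

#' Population marginal per-allele log-odds ratio of a scenario
#'
#' The per-allele logistic coefficient that the outcome GWAS estimates is
#' NOT `theta·beta_gx` exactly: the odds ratio is non-collapsible, so
#' marginalising the latent exposure out of the logistic model attenuates
#' the slope. This function computes the true marginal per-allele log-OR by
#' numerical integration: genotype-conditional case probabilities
#' `p_g = E_X[logistic(alpha + theta·X + pleiotropy_beta·g)]` under
#' `X | G = g ~ Normal(beta_gx·g, exposure_sd)`, expected case-control
#' genotype composition under HWE and the scenario's quotas, and the
#' maximum-likelihood dosage slope on that expected table.
#'
#' @param scenario A [sim_scenario()].
#' @return The marginal per-allele log-OR (a single number).
#' @export
marginal_log_or <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  p_g <- vapply(0:2, function(g) {
    integrate(function(x) {
      stats::plogis(scenario$alpha + scenario$theta * x +
                    scenario$pleiotropy_beta * g) *
        stats::dnorm(x, scenario$beta_gx * g, scenario$exposure_sd)
    }, -Inf, Inf, rel.tol = 1e-12)$value
  }, numeric(1))
  f_g <- stats::dbinom(0:2, 2, scenario$eaf)
  case_w <- f_g * p_g / sum(f_g * p_g)
  control_w <- f_g * (1 - p_g) / sum(f_g * (1 - p_g))
  cases <- scenario$n_cases * case_w
  controls <- scenario$n_controls * control_w
  nll <- function(par) {
    eta <- par[1] + par[2] * (0:2)
    -sum(cases * stats::plogis(eta, log.p = TRUE) +
         controls * stats::plogis(-eta, log.p = TRUE))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  opt$par[2]
}

#' Replicate a scenario end to end and summarise parameter recovery
#'
#' For each replicate the full pipeline runs: simulate the two samples,
#' harmonize the outcome record to the instrument alleles, form the Wald
#' ratio against the replicate's own estimated exposure beta
#' (delta-method/second-order SE by default), and record estimate, SE and
#' CI. The summary compares the mean estimate against both the nominal
#' `theta` and the non-collapsibility-aware truth
#' `marginal_log_or(scenario) / beta_gx`, and reports the empirical CI
#' coverage of `theta`. Fully reproducible: replicate seeds are substreams
#' derived from the scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @param n_replicates Number of replicates (>= 2).
#' @param se_method Passed to [wald_ratio()]; default `"second_order"`.
#' @param confidence CI level for coverage; default 0.95.
#' @return An `mr_recovery` object: `$summary` (one-row tibble with
#'   `mean_estimate`, `bias_theta`, `bias_marginal`, `relative_bias_marginal`,
#'   `empirical_se`, `mean_se`, `coverage`), `$replicates` (per-replicate
#'   tibble), `$scenario`.
#' @export
run_recovery_experiment <- function(scenario, n_replicates,
                                    se_method = "second_order",
                                    confidence = 0.95) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (n_replicates < 2) abort("`n_replicates` must be at least 2.")
  seeds <- derive_seeds(scenario$seed, n_replicates)
  z <- ci_z(confidence)
  reps <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    sim <- simulate_two_sample(scenario, seed = seeds[i])
    outcome <- harmonize_to_instrument(sim$outcome_assoc, "T", "C",
                                       instrument_eaf = sim$exposure_assoc$eaf)
    inst <- instrument_record(
      variant_id = "rs_sim", effect_allele = "T", other_allele = "C",
      beta_exposure = sim$exposure_assoc$beta,
      se_exposure = sim$exposure_assoc$se, units = "exposure unit")
    est <- wald_ratio(outcome, inst, se_method = se_method,
                      confidence = confidence)
    tibble::tibble(replicate = i, estimate = est$beta, se = est$se,
                   ci_low = est$beta - z * est$se,
                   ci_high = est$beta + z * est$se)
  })
  truth_marginal <- marginal_log_or(scenario) / scenario$beta_gx
  summary <- tibble::tibble(
    n_replicates = n_replicates,
    theta = scenario$theta,
    truth_marginal = truth_marginal,
    mean_estimate = mean(reps$estimate),
    bias_theta = mean(reps$estimate) - scenario$theta,
    bias_marginal = mean(reps$estimate) - truth_marginal,
    relative_bias_marginal = if (truth_marginal != 0) {
      (mean(reps$estimate) - truth_marginal) / truth_marginal
    } else NA_real_,
    empirical_se = stats::sd(reps$estimate),
    mean_se = mean(reps$se),
    coverage = mean(reps$ci_low <= scenario$theta &
                    scenario$theta <= reps$ci_high))
  structure(list(summary = summary, replicates = reps, scenario = scenario),
            class = "mr_recovery")
}

#' @export
print.mr_recovery <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Recovery experiment: %d replicates, theta = %g\n",
              s$n_replicates, s$theta))
  cat(sprintf("  mean estimate %.5g (marginal truth %.5g)\n",
              s$mean_estimate, s$truth_marginal))
  cat(sprintf("  bias vs theta %.3g | vs marginal truth %.3g\n",
              s$bias_theta, s$bias_marginal))
  cat(sprintf("  empirical SE %.3g | mean model SE %.3g | CI coverage of theta %.3f\n",
              s$empirical_se, s$mean_se, s$coverage))
  invisible(x)
}

#' @method glance mr_recovery
#' @export
glance.mr_recovery <- function(x, ...) x$summary

#' @method tidy mr_recovery
#' @export
tidy.mr_recovery <- function(x, ...) x$replicates
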