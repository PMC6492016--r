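#' Configuration of the two-SNP case-control correlation study
#'
#' Defaults mirror the reference design: samples of 10,000 individuals,
#' 1,000 simulations per grid cell, odds ratios spanning 1 to 4, MAFs 0.2
#' and 0.3, and balanced retrospective sampling from a population with
#' prevalence 0.01 (a schizophrenia-like disease; see the methods vignette
#' for why a rare-disease prevalence is needed for within-group
#' independence of the sampled loci).
#'
#' @param n_individuals Sample size per simulation.
#' @param n_sims Simulations per grid cell.
#' @param or_grid Odds ratios (each >= 1; inverse effects are handled by
#'   flipping the counted allele).
#' @param maf_set Allele frequencies.
#' @param prevalence Population prevalence K.
#' @param case_fraction Case fraction of each retrospective sample.
#' @param seed Root seed.
#' @return An object of class `two_snp_config`.
#' @export
two_snp_config <- function(n_individuals = 10000, n_sims = 1000,
                           or_grid = c(1, 1.5, 2, 2.5, 3, 3.5, 4),
                           maf_set = c(0.2, 0.3), prevalence = 0.01,
                           case_fraction = 0.5, seed = 1L) {
  n_individuals <- check_count(n_individuals, "n_individuals")
  n_sims <- check_count(n_sims, "n_sims")
  if (!length(or_grid) || any(or_grid < 1)) {
    stop_input("or_grid must be non-empty with every OR >= 1")
  }
  check_prob(maf_set, "maf_set")
  check_prob(prevalence, "prevalence")
  check_prob(case_fraction, "case_fraction")
  structure(list(n_individuals = n_individuals, n_sims = n_sims,
                 or_grid = as.numeric(or_grid), maf_set = as.numeric(maf_set),
                 prevalence = prevalence, case_fraction = case_fraction,
                 seed = as.integer(seed)),
            class = "two_snp_config")
}

#' Simulate a retrospective case-control sample of independent risk SNPs
#'
#' Population genotypes at `n_snps` loci are independent with
#' Hardy-Weinberg proportions at the given MAF; disease status follows the
#' additive logistic model with every per-allele effect equal to
#' `log(or_value)` and intercept solved for the prevalence; the sample is
#' then drawn retrospectively to the case/control quotas.
#'
#' @param or_value Per-allele odds ratio shared by all SNPs.
#' @param maf Allele frequency shared by all SNPs.
#' @param n Sample size.
#' @param prevalence Population prevalence K.
#' @param case_fraction Case fraction of the sample.
#' @param seed Integer seed.
#' @param n_snps Number of independent risk SNPs (default 2).
#' @return List with `genotypes` (n x n_snps integer matrix), `phenotype`
#'   (0/1), and `beta0`.
#' @export
simulate_two_snp_cohort <- function(or_value, maf, n, prevalence = 0.01,
                                    case_fraction = 0.5, seed = 1L,
                                    n_snps = 2L) {
  check_prob(maf, "maf")
  check_prob(prevalence, "prevalence")
  n_cases <- round(n * case_fraction)
  betas <- rep(log(or_value), n_snps)
  beta0 <- solve_intercept(rep(maf, n_snps), betas, list(), prevalence)
  res <- with_seed(seed, {
    sample_until_quota(rep(maf, n_snps), betas, list(), beta0,
                       n_cases, n - n_cases)
  })
  list(genotypes = res$genotypes, phenotype = res$phenotype, beta0 = beta0)
}

#' Pearson correlation of two SNPs overall and by status group
#'
#' @param g1,g2 Allele-count vectors.
#' @param phenotype 0/1 labels; both groups must be non-empty.
#' @return List with `r_all`, `r_cases`, `r_controls`; a correlation is
#'   `NA` (flagged, not zero) when a genotype has zero variance in that
#'   subset.
#' @export
correlation_by_group <- function(g1, g2, phenotype) {
  if (length(g1) != length(g2) || length(g1) != length(phenotype)) {
    stop_input("length mismatch")
  }
  if (!any(phenotype == 1L) || !any(phenotype == 0L)) {
    stop_input("both cases and controls must be present")
  }
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
      stats::cor(a, b)
  }
  ca <- phenotype == 1L
  list(r_all = safe_cor(g1, g2),
       r_cases = safe_cor(g1[ca], g2[ca]),
       r_controls = safe_cor(g1[!ca], g2[!ca]))
}

#' Mean induced correlation across an OR-by-MAF grid
#'
#' For every (OR, MAF) cell, simulates `n_sims` retrospective case-control
#' samples of two independent risk SNPs and averages the whole-sample,
#' cases-only and controls-only Pearson correlations, with Monte-Carlo
#' standard errors. Deterministic given the config seed.
#'
#' @param config A [two_snp_config()].
#' @return Data frame of class `correlation_grid` with one row per cell:
#'   `or`, `maf`, `mean_r_all`, `mean_r_cases`, `mean_r_controls`, matching
#'   `se_*` columns, and `n_sims`.
#' @export
run_correlation_grid <- function(config = two_snp_config()) {
  cells <- expand.grid(or = config$or_grid, maf = config$maf_set)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r_all <- r_ca <- r_co <- numeric(config$n_sims)
    for (s in seq_len(config$n_sims)) {
      sim <- simulate_two_snp_cohort(
        cells$or[i], cells$maf[i], config$n_individuals,
        config$prevalence, config$case_fraction,
        seed = derive_seed(config$seed, sprintf("grid_%d_%d", i, s)))
      r <- correlation_by_group(sim$genotypes[, 1], sim$genotypes[, 2],
                                sim$phenotype)
      r_all[s] <- r$r_all; r_ca[s] <- r$r_cases; r_co[s] <- r$r_controls
    }
    mc_se <- function(x) stats::sd(x, na.rm = TRUE) /
      sqrt(sum(!is.na(x)))
    out[[i]] <- data.frame(
      or = cells$or[i], maf = cells$maf[i],
      mean_r_all = mean(r_all, na.rm = TRUE),
      mean_r_cases = mean(r_ca, na.rm = TRUE),
      mean_r_controls = mean(r_co, na.rm = TRUE),
      se_r_all = mc_se(r_all), se_r_cases = mc_se(r_ca),
      se_r_controls = mc_se(r_co), n_sims = config$n_sims)
  }
  structure(do.call(rbind, out), class = c("correlation_grid", "data.frame"))
}

#' PRS versus multivariate-regression p-values on simulated risk SNPs
#'
#' Per simulation, draws a retrospective case-control sample of `n_snps`
#' independent equal-effect risk SNPs and computes two association
#' p-values: the 1-df Wald test of the single aggregated score predictor
#' (with equal true effects the unweighted allele sum, to which the p-value
#' of the score coefficient is invariant up to scale), and the `n_snps`-df
#' likelihood-ratio test of the joint logistic model with every SNP as a
#' separate predictor against the intercept-only model.
#'
#' @param or_value Shared per-allele odds ratio (default 1.2).
#' @param maf Shared allele frequency (default 0.3).
#' @param config A [two_snp_config()] providing sample size, simulation
#'   count, prevalence, case fraction and seed.
#' @param n_snps Number of equal-effect risk SNPs (default 2).
#' @return Data frame with one row per simulation: `p_prs`,
#'   `p_multivariate`, and `log10_ratio` (`log10(p_prs / p_multivariate)`).
#' @export
pvalue_comparison <- function(or_value = 1.2, maf = 0.3,
                              config = two_snp_config(), n_snps = 2L) {
  p_prs <- p_multi <- numeric(config$n_sims)
  for (s in seq_len(config$n_sims)) {
    sim <- simulate_two_snp_cohort(
      or_value, maf, config$n_individuals, config$prevalence,
      config$case_fraction,
      seed = derive_seed(config$seed, sprintf("pv_%d_%d", n_snps, s)),
      n_snps = n_snps)
    score <- rowSums(sim$genotypes)
    fit1 <- stats::glm(sim$phenotype ~ score, family = stats::binomial())
    p_prs[s] <- summary(fit1)$coefficients["score", 4]
    fitk <- stats::glm(sim$phenotype ~ sim$genotypes,
                       family = stats::binomial())
    p_multi[s] <- stats::pchisq(fitk$null.deviance - fitk$deviance,
                                df = n_snps, lower.tail = FALSE)
  }
  data.frame(sim = seq_len(config$n_sims), p_prs = p_prs,
             p_multivariate = p_multi,
             log10_ratio = log10(p_prs / p_multi))
}
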