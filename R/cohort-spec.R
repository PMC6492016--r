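#' Specification of a simulated case-control cohort
#'
#' Defines the genetic architecture and sampling design of a synthetic
#' cohort: per-SNP log-odds-ratio effects on a logistic liability scale,
#' optional pairwise XOR interaction terms, a target population prevalence,
#' retrospective case/control quotas, and an entry-wise missingness rate.
#'
#' @param n_cases,n_controls Case and control quotas filled by retrospective
#'   sampling from the population model.
#' @param n_snps Number of SNPs.
#' @param mafs Per-SNP counted-allele frequencies in (0, 1); recycled from
#'   `maf_range` by even spacing when not given explicitly.
#' @param maf_range Length-2 numeric in (0, 1); used when `mafs` is `NULL`.
#' @param causal_betas Per-SNP log odds ratios (0 for null SNPs).
#' @param epistatic_pairs List of `list(a, b, theta)` interaction terms: on
#'   the log-odds scale, `theta` multiplies `XOR(carrier_a, carrier_b)` where
#'   a carrier holds at least one copy of the counted allele.
#' @param prevalence Population disease prevalence K in (0, 1).
#' @param missing_rate Entry-wise missing-completely-at-random rate.
#' @param seed Root seed; every sub-draw of the cohort derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, n_snps,
                        mafs = NULL, maf_range = c(0.1, 0.5),
                        causal_betas = numeric(n_snps),
                        epistatic_pairs = list(),
                        prevalence = 0.01, missing_rate = 0, seed = 1L) {
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  n_snps <- check_count(n_snps, "n_snps")
  if (is.null(mafs)) {
    check_prob(maf_range, "maf_range")
    mafs <- if (n_snps == 1L) mean(maf_range) else
      seq(maf_range[1], maf_range[2], length.out = n_snps)
  }
  check_prob(mafs, "mafs")
  if (length(mafs) != n_snps) stop_input("mafs length != n_snps")
  if (length(causal_betas) != n_snps) stop_input("causal_betas length != n_snps")
  check_prob(prevalence, "prevalence")
  check_prob(missing_rate, "missing_rate", open = FALSE)
  for (pr in epistatic_pairs) {
    if (length(pr) < 3L) stop_input("each epistatic pair needs (a, b, theta)")
    a <- pr[[1]]; b <- pr[[2]]
    if (a == b) stop_input("epistatic pair indices must be distinct")
    if (any(c(a, b) < 1) || any(c(a, b) > n_snps)) {
      stop_input("epistatic pair index out of range")
    }
  }
  structure(list(n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
                 mafs = as.numeric(mafs), causal_betas = as.numeric(causal_betas),
                 epistatic_pairs = epistatic_pairs,
                 prevalence = prevalence, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' MAF that nulls the marginal effects of an XOR locus
#'
#' With dominant carrier coding, a carrier probability of exactly 1/2 makes
#' the marginal single-locus effects of a pure XOR interaction vanish. Under
#' Hardy-Weinberg proportions the carrier probability is `1 - (1 - maf)^2`,
#' so the nulling allele frequency is `1 - sqrt(1/2)`.
#'
#' @return The marginal-nulling allele frequency (about 0.2929).
#' @export
xor_null_maf <- function() 1 - sqrt(0.5)
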