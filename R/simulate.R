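#' Sample genotypes under Hardy-Weinberg proportions
#'
#' Each genotype is the sum of two independent Bernoulli(MAF) allele draws,
#' so genotype classes follow Hardy-Weinberg proportions in expectation and
#' SNPs are mutually independent (no LD).
#'
#' @param n_individuals Number of individuals (rows).
#' @param mafs Per-SNP counted-allele frequencies, each strictly in (0, 1).
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with default metadata.
#' @export
sample_genotypes <- function(n_individuals, mafs, seed = 1L) {
  n_individuals <- check_count(n_individuals, "n_individuals")
  check_prob(mafs, "mafs")
  values <- with_seed(seed, {
    matrix(stats::rbinom(n_individuals * length(mafs), 2L,
                         rep(mafs, each = n_individuals)),
           nrow = n_individuals)
  })
  genotype_matrix(values)
}

# Linear predictor of the disease model (without intercept): additive
# per-allele effects plus XOR(carrier, carrier) interaction terms.
risk_linear_predictor <- function(values, causal_betas, epistatic_pairs) {
  lp <- as.numeric(values %*% causal_betas)
  for (pr in epistatic_pairs) {
    a <- pr[[1]]; b <- pr[[2]]; theta <- pr[[3]]
    xa <- values[, a] >= 1L
    xb <- values[, b] >= 1L
    lp <- lp + theta * as.numeric(xor(xa, xb))
  }
  lp
}

#' Solve the disease-model intercept for a target prevalence
#'
#' Finds the intercept `beta0` such that the expected penetrance over the
#' population genotype distribution,
#' `E[plogis(beta0 + sum(beta_j g_j) + sum(theta XOR))]`, equals the target
#' prevalence `K`. With at most three loci carrying effects the expectation
#' is computed by exact enumeration of genotype combinations; otherwise by a
#' fixed 200,000-draw Monte-Carlo estimate with an internal fixed seed, so
#' the solved intercept is deterministic for a given architecture.
#'
#' @param mafs Per-SNP allele frequencies.
#' @param causal_betas Per-SNP log odds ratios.
#' @param epistatic_pairs List of `list(a, b, theta)` XOR terms.
#' @param prevalence Target prevalence K in (0, 1).
#' @return The intercept `beta0` (log-odds), accurate to |error| < 1e-8 on
#'   the enumeration path.
#' @export
solve_intercept <- function(mafs, causal_betas, epistatic_pairs = list(),
                            prevalence = 0.1) {
  check_prob(prevalence, "prevalence")
  check_prob(mafs, "mafs")
  active <- sort(unique(c(which(causal_betas != 0),
                          unlist(lapply(epistatic_pairs,
                                        function(pr) c(pr[[1]], pr[[2]]))))))
  if (length(active) == 0L) return(stats::qlogis(prevalence))

  if (length(active) <= 3L) {
    # exact enumeration over 3^k genotype cells of the active loci
    cells <- expand.grid(rep(list(0:2), length(active)))
    gfull <- matrix(0L, nrow(cells), length(mafs))
    gfull[, active] <- as.matrix(cells)
    probs <- rep(1, nrow(cells))
    for (j in seq_along(active)) {
      probs <- probs * stats::dbinom(cells[[j]], 2, mafs[active[j]])
    }
    lp <- risk_linear_predictor(gfull, causal_betas, epistatic_pairs)
    pen <- function(b0) sum(probs * stats::plogis(b0 + lp)) - prevalence
  } else {
    gdraw <- with_seed(760813L, {
      matrix(stats::rbinom(200000L * length(mafs), 2L,
                           rep(mafs, each = 200000L)), nrow = 200000L)
    })
    lp <- risk_linear_predictor(gdraw, causal_betas, epistatic_pairs)
    pen <- function(b0) mean(stats::plogis(b0 + lp)) - prevalence
  }
  root <- tryCatch(
    stats::uniroot(pen, lower = -40, upper = 40, extendInt = "yes",
                   tol = 1e-12),
    error = function(e) stop_input("no intercept root found: %s",
                                   conditionMessage(e)))
  root$root
}

#' Assign phenotypes under an additive logistic disease model
#'
#' Each individual is a case with probability
#' `plogis(beta0 + sum(beta_j g_ij))`, independently.
#'
#' @param genotypes A [genotype_matrix()] with no missing entries.
#' @param causal_betas Per-SNP log odds ratios, aligned to SNP columns.
#' @param beta0 Intercept (log-odds), e.g. from [solve_intercept()].
#' @param seed Integer seed.
#' @return Integer 0/1 phenotype vector (1 = case) aligned to individuals.
#' @export
assign_phenotype_additive <- function(genotypes, causal_betas, beta0,
                                      seed = 1L) {
  if (length(causal_betas) != n_snps(genotypes)) {
    stop_input("causal_betas length (%d) != number of SNPs (%d)",
               length(causal_betas), n_snps(genotypes))
  }
  p <- stats::plogis(beta0 + as.numeric(genotypes$values %*% causal_betas))
  with_seed(seed, stats::rbinom(length(p), 1L, p))
}

#' Assign phenotypes under a two-locus XOR disease model
#'
#' Case probability is `plogis(beta0 + theta * XOR(carrier_a, carrier_b))`
#' with dominant carrier coding (carrier = at least one counted allele).
#' At the marginal-nulling allele frequency [xor_null_maf()] the carrier
#' probability is 1/2 and the single-locus marginal effects are exactly
#' null; at other frequencies marginal effects are nonzero by design.
#'
#' @param genotypes A [genotype_matrix()].
#' @param pair Integer pair `c(a, b)` of distinct SNP column indices.
#' @param theta Interaction effect on the log-odds scale.
#' @param beta0 Intercept (log-odds).
#' @param seed Integer seed.
#' @return Integer 0/1 phenotype vector (1 = case).
#' @export
assign_phenotype_xor <- function(genotypes, pair, theta, beta0, seed = 1L) {
  if (length(pair) != 2L || pair[1] == pair[2]) {
    stop_input("`pair` must be two distinct SNP indices")
  }
  if (any(pair < 1) || any(pair > n_snps(genotypes))) {
    stop_input("pair index out of range (1..%d)", n_snps(genotypes))
  }
  xa <- genotypes$values[, pair[1]] >= 1L
  xb <- genotypes$values[, pair[2]] >= 1L
  p <- stats::plogis(beta0 + theta * as.numeric(xor(xa, xb)))
  with_seed(seed, stats::rbinom(length(p), 1L, p))
}

# Chunked retrospective sampler: draws population individuals under the full
# disease model and retains them until both quotas are exactly filled.
# Returns genotype rows, phenotypes, and the number of population draws used.
sample_until_quota <- function(mafs, causal_betas, epistatic_pairs, beta0,
                               n_cases, n_controls, max_draws = 2e8) {
  p <- length(mafs)
  need_case <- n_cases
  need_ctrl <- n_controls
  K_hat <- stats::plogis(beta0)  # rough chunk sizing only
  geno_keep <- vector("list", 64L)
  phen_keep <- vector("list", 64L)
  ki <- 0L
  drawn <- 0
  while (need_case > 0L || need_ctrl > 0L) {
    if (drawn >= max_draws) {
      stop_input(paste0("attempt budget exceeded after %.0f population draws",
                        " (%d cases, %d controls still required)"),
                 drawn, need_case, need_ctrl)
    }
    chunk <- ceiling(1.25 * max(need_case / max(K_hat, 1e-6),
                                need_ctrl / max(1 - K_hat, 1e-6)))
    chunk <- min(max(chunk, 1000), 500000, max_draws - drawn)
    g <- matrix(stats::rbinom(chunk * p, 2L, rep(mafs, each = chunk)),
                nrow = chunk)
    pr <- stats::plogis(beta0 + risk_linear_predictor(g, causal_betas,
                                                      epistatic_pairs))
    y <- stats::rbinom(chunk, 1L, pr)
    drawn <- drawn + chunk
    keep_case <- which(y == 1L)[seq_len(min(need_case, sum(y == 1L)))]
    keep_ctrl <- which(y == 0L)[seq_len(min(need_ctrl, sum(y == 0L)))]
    keep <- sort(c(keep_case, keep_ctrl))
    if (length(keep)) {
      ki <- ki + 1L
      geno_keep[[ki]] <- g[keep, , drop = FALSE]
      phen_keep[[ki]] <- y[keep]
      need_case <- need_case - length(keep_case)
      need_ctrl <- need_ctrl - length(keep_ctrl)
    }
  }
  list(genotypes = do.call(rbind, geno_keep[seq_len(ki)]),
       phenotype = unlist(phen_keep[seq_len(ki)]),
       n_draws = drawn)
}

#' Draw a retrospective case-control cohort from a population model
#'
#' Repeatedly samples individuals from the logistic population disease model
#' defined by a [cohort_spec()], retaining cases and controls until both
#' quotas are exactly filled (retrospective ascertainment, which enriches
#' cases relative to the population prevalence). Rows are then shuffled so
#' that sample order carries no label information.
#'
#' @param spec A [cohort_spec()].
#' @param seed Root seed; defaults to `spec$seed`.
#' @return An object of class `simulated_cohort`: list with `genotypes`
#'   (a [genotype_matrix()], missing entries injected at `spec$missing_rate`),
#'   `phenotype` (0/1), and `truth` (the spec plus the solved intercept
#'   `beta0` and the realized population draw count).
#' @export
sample_case_control <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  beta0 <- solve_intercept(spec$mafs, spec$causal_betas,
                           spec$epistatic_pairs, spec$prevalence)
  res <- with_seed(derive_seed(seed, "sample_case_control"), {
    out <- sample_until_quota(spec$mafs, spec$causal_betas,
                              spec$epistatic_pairs, beta0,
                              spec$n_cases, spec$n_controls)
    ord <- sample.int(nrow(out$genotypes))
    out$genotypes <- out$genotypes[ord, , drop = FALSE]
    out$phenotype <- out$phenotype[ord]
    out
  })
  geno <- genotype_matrix(res$genotypes)
  if (spec$missing_rate > 0) {
    geno <- inject_missing(geno, spec$missing_rate,
                           seed = derive_seed(seed, "inject_missing"))
  }
  truth <- c(unclass(spec),
             list(beta0 = beta0, n_population_draws = res$n_draws,
                  realized_prevalence = stats::plogis(beta0)))
  structure(list(genotypes = geno, phenotype = res$phenotype, truth = truth),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("simulated_cohort: %d cases / %d controls, %d SNPs (beta0 = %.4f)\n",
              sum(x$phenotype == 1L), sum(x$phenotype == 0L),
              n_snps(x$genotypes), x$truth$beta0))
  invisible(x)
}

#' Inject missing genotypes completely at random
#'
#' Sets each entry of the matrix to missing independently with the given
#' rate; all other entries are untouched.
#'
#' @param genotypes A [genotype_matrix()].
#' @param missing_rate Probability in \[0, 1\].
#' @param seed Integer seed.
#' @return The contaminated [genotype_matrix()].
#' @export
inject_missing <- function(genotypes, missing_rate, seed = 1L) {
  check_prob(missing_rate, "missing_rate", open = FALSE)
  if (missing_rate == 0) return(genotypes)
  v <- genotypes$values
  mask <- with_seed(seed,
                    stats::runif(length(v)) < missing_rate)
  v[mask] <- NA_integer_
  genotype_matrix(v, genotypes$snp_meta, genotypes$sample_ids)
}

#' Truth table of a simulated cohort
#'
#' @param cohort A `simulated_cohort` from [sample_case_control()].
#' @return Data frame with one row per SNP: id, true beta, MAF, epistatic
#'   partner id (or `"."`), and theta.
#' @export
cohort_truth_table <- function(cohort) {
  tr <- cohort$truth
  meta <- cohort$genotypes$snp_meta
  partner <- rep(".", length(tr$mafs))
  theta <- rep(0, length(tr$mafs))
  for (pr in tr$epistatic_pairs) {
    partner[pr[[1]]] <- meta$id[pr[[2]]]
    partner[pr[[2]]] <- meta$id[pr[[1]]]
    theta[c(pr[[1]], pr[[2]])] <- pr[[3]]
  }
  data.frame(id = meta$id, beta = tr$causal_betas, maf = tr$mafs,
             epistatic_partner = partner, theta = theta,
             stringsAsFactors = FALSE)
}
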