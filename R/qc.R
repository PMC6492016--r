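#' Quality-control configuration
#'
#' Thresholds for the genotype QC stack: hard-calling, per-SNP missingness,
#' minor allele frequency, Hardy-Weinberg equilibrium, fixed region
#' exclusion (default: the extended MHC, chr6:25-34 Mb, a closed interval in
#' 1-based base pairs), and association-aware LD pruning.
#'
#' @param max_missing_rate SNPs with missing fraction `>=` this are removed.
#' @param min_maf SNPs with MAF `<` this are removed (boundary kept).
#' @param hwe_alpha SNPs with HWE goodness-of-fit p `<` this are removed.
#' @param hwe_scope `"controls"` (default) computes the HWE test in controls
#'   only; `"all"` uses every sample.
#' @param excluded_regions List of `c(chr, start, end)` closed intervals.
#' @param hard_call_threshold Genotype-probability threshold; the most
#'   probable genotype is called only when its probability strictly exceeds
#'   this.
#' @param prune_window LD-pruning window in base pairs around retained SNPs.
#' @param prune_r2 Squared-correlation threshold above which a neighbour of
#'   a retained SNP is removed.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(max_missing_rate = 0.02, min_maf = 0.10,
                      hwe_alpha = 1e-4, hwe_scope = c("controls", "all"),
                      excluded_regions = list(c(6, 25000000, 34000000)),
                      hard_call_threshold = 0.9,
                      prune_window = 500000, prune_r2 = 0.1) {
  check_prob(max_missing_rate, "max_missing_rate", open = FALSE)
  check_prob(min_maf, "min_maf", open = FALSE)
  if (hwe_alpha < 0 || hwe_alpha > 1) stop_input("hwe_alpha must be in [0, 1]")
  check_prob(hard_call_threshold, "hard_call_threshold")
  check_prob(prune_r2, "prune_r2", open = FALSE)
  if (prune_window < 0) stop_input("prune_window must be >= 0")
  structure(list(max_missing_rate = max_missing_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, hwe_scope = match.arg(hwe_scope),
                 excluded_regions = excluded_regions,
                 hard_call_threshold = hard_call_threshold,
                 prune_window = prune_window, prune_r2 = prune_r2),
            class = "qc_config")
}

qc_step <- function(genotypes, stage, removed_ids, n_in) {
  report <- data.frame(stage = stage, n_in = n_in,
                       n_out = n_in - length(removed_ids),
                       n_removed = length(removed_ids),
                       removed_ids = paste(removed_ids, collapse = ","),
                       stringsAsFactors = FALSE)
  list(genotypes = genotypes, report = report)
}

#' Hard-call genotypes from probability triples
#'
#' Converts per-entry genotype probability triples `(p0, p1, p2)` to the
#' most probable genotype when its probability strictly exceeds the
#' threshold, and to missing otherwise.
#'
#' @param prob_array Numeric array `n x p x 3`; each triple must sum to
#'   1 within 1e-6.
#' @param threshold Calling threshold (strict inequality).
#' @return Integer matrix of genotypes in `{0, 1, 2, NA}`.
#' @export
hard_call <- function(prob_array, threshold = 0.9) {
  d <- dim(prob_array)
  if (length(d) != 3L || d[3] != 3L) {
    stop_input("prob_array must be an n x p x 3 array")
  }
  sums <- prob_array[, , 1] + prob_array[, , 2] + prob_array[, , 3]
  if (any(abs(sums - 1) > 1e-6)) {
    stop_input("genotype probability triples must sum to 1 (max |error| %.2e)",
               max(abs(sums - 1)))
  }
  m <- cbind(as.vector(prob_array[, , 1]), as.vector(prob_array[, , 2]),
             as.vector(prob_array[, , 3]))
  call <- max.col(m, ties.method = "first") - 1L
  call[m[cbind(seq_len(nrow(m)), call + 1L)] <= threshold] <- NA_integer_
  matrix(as.integer(call), d[1], d[2])
}

#' Remove SNPs with excessive missingness
#'
#' @param genotypes A [genotype_matrix()].
#' @param max_missing_rate SNPs with missing fraction `>=` this are removed.
#' @return List with the filtered `genotypes` and a one-row `report`.
#' @export
filter_missingness <- function(genotypes, max_missing_rate = 0.02) {
  miss <- colMeans(is.na(genotypes$values))
  drop <- miss >= max_missing_rate
  qc_step(subset_snps(genotypes, !drop), "missingness",
          genotypes$snp_meta$id[drop], n_snps(genotypes))
}

#' Remove SNPs with low minor allele frequency
#'
#' MAF is computed over non-missing entries; the boundary is inclusive
#' (MAF exactly at `min_maf` is kept).
#'
#' @inheritParams filter_missingness
#' @param min_maf Minimum MAF retained.
#' @return List with the filtered `genotypes` and a one-row `report`.
#' @export
filter_maf <- function(genotypes, min_maf = 0.10) {
  maf <- minor_allele_freq(genotypes)
  drop <- is.na(maf) | maf < min_maf
  qc_step(subset_snps(genotypes, !drop), "maf",
          genotypes$snp_meta$id[drop], n_snps(genotypes))
}

# 1-df chi-square goodness of fit of genotype counts against
# Hardy-Weinberg proportions at the observed allele frequency.
hwe_pvalue <- function(g) {
  g <- g[!is.na(g)]
  n <- length(g)
  if (n == 0L) return(NA_real_)
  obs <- tabulate(g + 1L, 3L)
  f <- (2 * obs[3] + obs[2]) / (2 * n)
  exp <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
  use <- exp > 0
  x2 <- sum((obs[use] - exp[use])^2 / exp[use])
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Remove SNPs violating Hardy-Weinberg equilibrium
#'
#' A 1-df chi-square goodness-of-fit test of genotype counts against
#' Hardy-Weinberg proportions, computed in controls only by default
#' (standard GWAS practice, since ascertained cases can deviate from HWE at
#' true risk loci); SNPs with p below `hwe_alpha` are removed.
#'
#' @inheritParams filter_missingness
#' @param phenotype 0/1 phenotype vector (needed when `scope = "controls"`).
#' @param hwe_alpha Removal threshold on the HWE p-value.
#' @param scope `"controls"` or `"all"`.
#' @return List with the filtered `genotypes` and a one-row `report`.
#' @export
filter_hwe <- function(genotypes, phenotype = NULL, hwe_alpha = 1e-4,
                       scope = c("controls", "all")) {
  scope <- match.arg(scope)
  v <- genotypes$values
  if (scope == "controls") {
    if (is.null(phenotype) || length(phenotype) != nrow(v)) {
      stop_input("aligned `phenotype` required for control-only HWE testing")
    }
    v <- v[phenotype == 0L, , drop = FALSE]
  }
  pv <- apply(v, 2, hwe_pvalue)
  drop <- !is.na(pv) & pv < hwe_alpha
  qc_step(subset_snps(genotypes, !drop), "hwe",
          genotypes$snp_meta$id[drop], n_snps(genotypes))
}

#' Remove SNPs inside excluded genomic regions
#'
#' @inheritParams filter_missingness
#' @param regions List of `c(chr, start, end)` closed intervals in 1-based
#'   base pairs.
#' @return List with the filtered `genotypes` and a one-row `report`.
#' @export
exclude_region <- function(genotypes,
                           regions = list(c(6, 25000000, 34000000))) {
  meta <- genotypes$snp_meta
  drop <- rep(FALSE, nrow(meta))
  for (r in regions) {
    drop <- drop | (!is.na(meta$chr) & meta$chr == r[1] &
                      !is.na(meta$pos) & meta$pos >= r[2] & meta$pos <= r[3])
  }
  qc_step(subset_snps(genotypes, !drop), "region",
          meta$id[drop], n_snps(genotypes))
}

#' Association-aware LD pruning
#'
#' Greedy pass over SNPs in ascending association p-value order: each
#' retained SNP removes every not-yet-retained SNP on the same chromosome
#' within `prune_window` base pairs whose genotype correlation r-squared
#' with it exceeds `prune_r2`. Ties in p-value are broken deterministically
#' by (p, chromosome, position, id). Pairs with an undefined correlation
#' (a monomorphic SNP) are treated as not in LD.
#'
#' @inheritParams filter_missingness
#' @param snp_pvalues Per-SNP association p-values aligned to columns.
#' @param prune_window Window in base pairs.
#' @param prune_r2 r-squared removal threshold (strict inequality).
#' @return List with the pruned `genotypes` and a one-row `report`.
#' @export
ld_prune <- function(genotypes, snp_pvalues, prune_window = 500000,
                     prune_r2 = 0.1) {
  p <- n_snps(genotypes)
  if (length(snp_pvalues) != p) stop_input("snp_pvalues length != n SNPs")
  meta <- genotypes$snp_meta
  ord <- order(snp_pvalues, meta$chr, meta$pos, meta$id)
  status <- rep("pending", p)  # pending / kept / removed
  for (j in ord) {
    if (status[j] != "pending") next
    status[j] <- "kept"
    cand <- which(status == "pending" & meta$chr == meta$chr[j] &
                    abs(meta$pos - meta$pos[j]) <= prune_window)
    if (!length(cand)) next
    r <- suppressWarnings(
      stats::cor(genotypes$values[, j],
                 genotypes$values[, cand, drop = FALSE],
                 use = "pairwise.complete.obs"))
    hit <- !is.na(r) & r^2 > prune_r2
    status[cand[hit]] <- "removed"
  }
  keep <- status == "kept"
  qc_step(subset_snps(genotypes, keep), "ld_prune",
          meta$id[!keep], p)
}

#' Impute missing genotypes from per-SNP multinomial frequencies
#'
#' For each SNP the observed genotype class frequencies define a 3-class
#' multinomial distribution; every missing entry is replaced by an
#' independent draw from it. Observed entries are never altered and no
#' missing values remain.
#'
#' @inheritParams filter_missingness
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with no missing entries.
#' @export
impute_missing_multinomial <- function(genotypes, seed = 1L) {
  v <- genotypes$values
  if (!anyNA(v)) return(genotypes)
  fully_missing <- colSums(!is.na(v)) == 0L
  if (any(fully_missing)) {
    stop_input("SNP(s) with zero observed genotypes, frequencies undefined: %s",
               paste(utils::head(genotypes$snp_meta$id[fully_missing], 5),
                     collapse = ", "))
  }
  v <- with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      miss <- which(is.na(v[, j]))
      if (!length(miss)) next
      counts <- tabulate(v[!is.na(v[, j]), j] + 1L, 3L)
      v[miss, j] <- sample.int(3L, length(miss), replace = TRUE,
                               prob = counts / sum(counts)) - 1L
    }
    v
  })
  genotype_matrix(v, genotypes$snp_meta, genotypes$sample_ids)
}

#' Apply the full genotype QC stack
#'
#' Runs, in order: missingness filter, MAF filter, HWE filter, region
#' exclusion, association-aware LD prune (p-values from a per-SNP logistic
#' regression on the supplied phenotype unless given), and multinomial
#' imputation of the remaining missing genotypes. Hard-calling from
#' probability triples, when needed, precedes this stack via [hard_call()].
#' Applying the stack twice is a no-op on its own output.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype 0/1 phenotype vector (for control-only HWE and for the
#'   LD-prune association p-values).
#' @param config A [qc_config()].
#' @param snp_pvalues Optional externally supplied association p-values for
#'   LD pruning (e.g. from GWAS summary statistics).
#' @param seed Seed for the imputation draws.
#' @return List with `genotypes` (QC'd, imputation-complete) and `report`
#'   (one row per stage; removal counts reconcile exactly).
#' @export
qc_pipeline <- function(genotypes, phenotype, config = qc_config(),
                        snp_pvalues = NULL, seed = 1L) {
  s1 <- filter_missingness(genotypes, config$max_missing_rate)
  s2 <- filter_maf(s1$genotypes, config$min_maf)
  s3 <- filter_hwe(s2$genotypes, phenotype, config$hwe_alpha,
                   scope = config$hwe_scope)
  s4 <- exclude_region(s3$genotypes, config$excluded_regions)
  if (is.null(snp_pvalues)) {
    pv <- per_snp_logistic(impute_missing_multinomial(s4$genotypes,
                                                      derive_seed(seed, "qc_assoc")),
                           phenotype)$p
  } else {
    idx <- match(s4$genotypes$snp_meta$id, genotypes$snp_meta$id)
    pv <- snp_pvalues[idx]
  }
  s5 <- ld_prune(s4$genotypes, pv, config$prune_window, config$prune_r2)
  imputed <- impute_missing_multinomial(s5$genotypes,
                                        derive_seed(seed, "qc_impute"))
  report <- rbind(s1$report, s2$report, s3$report, s4$report, s5$report)
  list(genotypes = imputed, report = report)
}
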