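test_that("hard-calling takes the most probable genotype above the threshold", {
  probs <- array(0, c(1, 4, 3))
  probs[1, 1, ] <- c(0.95, 0.04, 0.01)   # -> 0
  probs[1, 2, ] <- c(0.50, 0.40, 0.10)   # -> missing
  probs[1, 3, ] <- c(0.05, 0.05, 0.90)   # -> missing (strict > 0.9)
  probs[1, 4, ] <- c(0.04, 0.05, 0.91)   # -> 2
  called <- hard_call(probs)
  expect_identical(called[1, ], c(0L, NA_integer_, NA_integer_, 2L))

  probs[1, 1, ] <- c(0.8, 0.3, 0.1)      # sums to 1.2
  expect_error(hard_call(probs), "sum to 1")
})

test_that("missingness and MAF filters remove exactly the known violators", {
  toy <- make_qc_toy()
  s1 <- filter_missingness(toy$genotypes, 0.02)
  expect_setequal(strsplit(s1$report$removed_ids, ",")[[1]],
                  c("miss3pct", "miss2pct"))
  expect_equal(s1$report$n_in - s1$report$n_removed, s1$report$n_out)

  s2 <- filter_maf(s1$genotypes, 0.10)
  expect_setequal(strsplit(s2$report$removed_ids, ",")[[1]],
                  c("rare", "mono"))
  expect_true("maf10" %in% s2$genotypes$snp_meta$id)  # boundary kept
})

test_that("HWE filter tests controls only and matches the chi-square oracle", {
  # exact HWE proportions for allele frequency 0.3 in 1,000 controls
  g_ok <- geno_block(490, 420, 90)
  expect_equal(prsvm:::hwe_pvalue(g_ok), 1)

  # (600, 200, 200): oracle chi-square computed here independently
  g_bad <- geno_block(600, 200, 200)
  f <- (2 * 200 + 200) / 2000
  expo <- 1000 * c((1 - f)^2, 2 * f * (1 - f), f^2)
  p_oracle <- pchisq(sum((c(600, 200, 200) - expo)^2 / expo), 1,
                     lower.tail = FALSE)
  expect_equal(prsvm:::hwe_pvalue(g_bad), p_oracle)
  expect_lt(p_oracle, 1e-4)

  toy <- make_qc_toy()
  s <- filter_hwe(toy$genotypes, toy$phenotype, 1e-4)
  expect_identical(strsplit(s$report$removed_ids, ",")[[1]], "hwe_bad_ctrl")
  expect_true("hwe_bad_case" %in% s$genotypes$snp_meta$id)

  # alpha = 0 removes nothing
  s0 <- filter_hwe(toy$genotypes, toy$phenotype, 0)
  expect_equal(s0$report$n_removed, 0L)
})

test_that("region exclusion treats bounds as a closed interval", {
  toy <- make_qc_toy()
  s <- exclude_region(toy$genotypes)
  expect_setequal(strsplit(s$report$removed_ids, ",")[[1]],
                  c("mhc_start", "mhc_end", "mhc_mid"))
  expect_true("near_mhc" %in% s$genotypes$snp_meta$id)
})

test_that("LD pruning keeps the most associated SNP and respects the window", {
  # duplicated column, distinct p: smaller p retained
  v <- cbind(geno_block(49, 42, 9), geno_block(49, 42, 9))
  meta <- data.frame(id = c("a", "b"), chr = 1, pos = c(1e6, 1.2e6),
                     allele1 = "A", allele2 = "G")
  g <- genotype_matrix(v, meta)
  pruned <- ld_prune(g, c(0.5, 1e-4))
  expect_identical(pruned$genotypes$snp_meta$id, "b")

  # same pair 600 kb apart: both retained (outside window)
  meta$pos <- c(1e6, 1.6e6)
  pruned2 <- ld_prune(genotype_matrix(v, meta), c(0.5, 1e-4))
  expect_equal(n_snps(pruned2$genotypes), 2)

  # A-B-C triple: r2(A,B) = r2(B,C) = 1, all within the window;
  # greedy by p (A=.001, C=.005, B=.01) keeps A, removes B and C
  set.seed(31)
  a <- rbinom(200, 2, 0.4)
  v3 <- cbind(a, a, a)
  meta3 <- data.frame(id = c("A", "B", "C"), chr = 2,
                      pos = c(1e6, 1.2e6, 1.4e6),
                      allele1 = "A", allele2 = "G")
  pruned3 <- ld_prune(genotype_matrix(v3, meta3), c(0.001, 0.01, 0.005))
  expect_identical(pruned3$genotypes$snp_meta$id, "A")

  # same triple but C uncorrelated with A and B: A and C survive
  c_ind <- rbinom(200, 2, 0.4)
  v4 <- cbind(a, a, c_ind)
  stopifnot(cor(a, c_ind)^2 < 0.1)
  pruned4 <- ld_prune(genotype_matrix(v4, meta3), c(0.001, 0.01, 0.005))
  expect_setequal(pruned4$genotypes$snp_meta$id, c("A", "C"))
})

test_that("multinomial imputation draws from observed class frequencies", {
  toy <- make_qc_toy()
  complete <- filter_missingness(toy$genotypes, 0.005)$genotypes
  expect_identical(impute_missing_multinomial(complete, 1)$values,
                   complete$values)

  # SNP observed only as genotype 0: every missing entry becomes 0
  v <- matrix(c(0L, 0L, NA, NA, 1L, 2L, 0L, 1L), ncol = 2)
  g <- genotype_matrix(v)
  imp <- impute_missing_multinomial(g, 5)
  expect_identical(unname(imp$values[, 1]), rep(0L, 4))
  # observed entries untouched
  expect_identical(unname(imp$values[!is.na(v)]), unname(v[!is.na(v)]))

  # fully missing SNP is a diagnostic failure
  v[, 1] <- NA_integer_
  expect_error(impute_missing_multinomial(genotype_matrix(v), 1),
               "zero observed")
})

test_that("the full QC stack removes exactly the violators and reconciles", {
  toy <- make_qc_toy()
  res <- qc_pipeline(toy$genotypes, toy$phenotype,
                     snp_pvalues = toy$snp_pvalues, seed = 99)
  expect_setequal(res$genotypes$snp_meta$id, toy$expected_kept)
  expect_false(anyNA(res$genotypes$values))
  # counts reconcile stage by stage
  expect_true(all(res$report$n_in - res$report$n_removed == res$report$n_out))
  expect_equal(res$report$n_in[-1], res$report$n_out[-nrow(res$report)])
})
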