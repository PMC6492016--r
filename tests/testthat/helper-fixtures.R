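# Fixture builders shared across test files. Everything is constructed in
# code; no data files.

# Sorted-block genotype column: n0 zeros, n1 ones, n2 twos.
geno_block <- function(n0, n1, n2) c(rep(0L, n0), rep(1L, n1), rep(2L, n2))

# Exact Hardy-Weinberg column for allele frequency f over n individuals
# (n * HWE proportions must be whole numbers).
hwe_block <- function(n, f) {
  counts <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
  stopifnot(all(abs(counts - round(counts)) < 1e-9))
  geno_block(round(counts)[1], round(counts)[2], round(counts)[3])
}

# A small imputation-complete case-control cohort with additive signal.
make_additive_cohort <- function(n_cases = 500, n_controls = 500,
                                 n_snps = 10, or = 1.5, maf = 0.3,
                                 seed = 1L) {
  spec <- cohort_spec(n_cases, n_controls, n_snps, mafs = rep(maf, n_snps),
                      causal_betas = rep(log(or), n_snps), seed = seed)
  sample_case_control(spec)
}

# The 30-SNP QC toy: every filter has known violators, and the surviving
# set is pre-computed from the construction itself (count oracle), never by
# running the pipeline. 500 controls then 500 cases.
make_qc_toy <- function() {
  n <- 1000L
  ctrl <- 1:500
  case <- 501:1000
  ids <- character(0); cols <- list(); chr <- integer(0); pos <- integer(0)
  add <- function(id, column, chrom, posn) {
    ids <<- c(ids, id); cols[[length(cols) + 1L]] <<- column
    chr <<- c(chr, chrom); pos <<- c(pos, posn)
  }
  hwe_col <- function() c(hwe_block(500, 0.3), hwe_block(500, 0.3))

  # 14 well-behaved SNPs, 1 Mb apart on chr 1
  for (i in 1:14) add(sprintf("norm%02d", i), hwe_col(), 1L, i * 1000000L)
  # missingness violators (missing entries placed in cases; controls full)
  m3 <- hwe_col(); m3[case[1:30]] <- NA_integer_
  add("miss3pct", m3, 1L, 40000000L)                 # 3% >= 2% -> removed
  m2 <- hwe_col(); m2[case[1:20]] <- NA_integer_
  add("miss2pct", m2, 1L, 41000000L)                 # exactly 2% -> removed
  m1 <- hwe_col(); m1[case[1:10]] <- NA_integer_
  add("miss1pct", m1, 1L, 42000000L)                 # 1% -> kept, imputed
  # MAF violators
  # allele frequency 0.05 overall, near-HWE in controls (f = 0.05 is not an
  # exact multiple of 1/500, so counts are rounded)
  add("rare", c(geno_block(452, 47, 1), geno_block(453, 43, 4)),
      1L, 43000000L)                                 # MAF 0.05 -> removed
  add("maf10", c(hwe_block(500, 0.1), hwe_block(500, 0.1)),
      1L, 44000000L)                                 # exactly 0.10 -> kept
  add("mono", rep(0L, n), 1L, 45000000L)             # MAF 0 -> removed
  # HWE violators (tested in controls only)
  add("hwe_bad_ctrl", c(geno_block(300, 0, 200), hwe_block(500, 0.4)),
      1L, 46000000L)                                 # removed
  add("hwe_bad_case", c(hwe_block(500, 0.4), geno_block(300, 0, 200)),
      1L, 47000000L)                                 # kept (controls fine)
  # region exclusion (extended MHC, chr6 25-34 Mb closed)
  add("mhc_start", hwe_col(), 6L, 25000000L)         # boundary -> removed
  add("mhc_end", hwe_col(), 6L, 34000000L)           # boundary -> removed
  add("mhc_mid", hwe_col(), 6L, 30000000L)           # removed
  add("near_mhc", hwe_col(), 6L, 24999999L)          # 1 bp outside -> kept
  # LD cluster on chr 2; ldA/ldB/ldC identical columns, ldD identical but
  # 1 Mb away (outside the 500 kb window)
  lda <- hwe_col()
  add("ldA", lda, 2L, 10000000L)                     # p = 1e-8 -> kept
  add("ldB", lda, 2L, 10200000L)                     # r2 = 1 with ldA -> removed
  add("ldC", lda, 2L, 10400000L)                     # r2 = 1 with ldA -> removed
  add("ldD", lda, 2L, 11000000L)                     # outside window -> kept
  # pad to 30 SNPs with more well-behaved chr 3 SNPs
  for (i in 1:8) add(sprintf("pad%02d", i), hwe_col(), 3L, i * 2000000L)

  values <- do.call(cbind, cols)
  meta <- data.frame(id = ids, chr = chr, pos = pos,
                     allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  pvals <- rep(0.5, length(ids))
  pvals[ids == "ldA"] <- 1e-8
  pvals[ids == "ldC"] <- 1e-7
  pvals[ids == "ldB"] <- 1e-6
  pvals[ids == "ldD"] <- 1e-5
  expected_removed <- c("miss3pct", "miss2pct", "rare", "mono",
                        "hwe_bad_ctrl", "mhc_start", "mhc_end", "mhc_mid",
                        "ldB", "ldC")
  list(genotypes = genotype_matrix(values, meta),
       phenotype = c(rep(0L, 500), rep(1L, 500)),
       snp_pvalues = pvals,
       expected_kept = setdiff(ids, expected_removed),
       expected_removed = expected_removed)
}

# Brute-force all-pairs AUC oracle: ties counted one half.
auc_bruteforce <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}
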