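#' Write a genotype matrix in the PLINK .raw-style dialect
#'
#' Tab-delimited with header
#' `FID IID PAT MAT SEX PHENOTYPE <snp>_<allele1> ...`, one row per
#' individual, allele counts 0/1/2, missing as `NA`. On disk the phenotype
#' is coded 1 = control, 2 = case (PLINK convention); internally 0/1.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype Integer 0/1 vector (1 = case), or `NA`s.
#' @param path Output file path.
#' @export
write_raw <- function(genotypes, phenotype, path) {
  if (length(phenotype) != n_samples(genotypes)) {
    stop_input("phenotype length != number of individuals")
  }
  meta <- genotypes$snp_meta
  header <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
              paste0(meta$id, "_", meta$allele1))
  pheno_disk <- ifelse(is.na(phenotype), "NA", as.character(phenotype + 1L))
  gchar <- genotypes$values
  body <- cbind(genotypes$sample_ids, genotypes$sample_ids, "0", "0", "0",
                pheno_disk,
                matrix(ifelse(is.na(gchar), "NA", as.character(gchar)),
                       nrow = nrow(gchar)))
  lines <- c(paste(header, collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PLINK .raw-style genotype file
#'
#' Parses the dialect written by [write_raw()]. Any malformed header, ragged
#' row, or genotype token outside `{0, 1, 2, NA}` is a parse failure naming
#' the offending line.
#'
#' @param path Path to a `.raw`-style file.
#' @param bim Optional path to a `.bim`-like metadata table ([read_bim()]);
#'   when given, chromosome/position/alleles are attached to the SNPs.
#' @return List with `genotypes` (a [genotype_matrix()]) and `phenotype`
#'   (0/1 integer vector, `NA` where unknown on disk).
#' @export
read_raw <- function(path, bim = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop_input("%s: empty file", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (length(header) < 7L || !identical(header[1:6], fixed)) {
    stop_input("%s: malformed header at line 1 (expected FID IID PAT MAT SEX PHENOTYPE ...)",
               path)
  }
  snp_cols <- header[-(1:6)]
  m <- regmatches(snp_cols, regexpr("_[^_]+$", snp_cols))
  if (length(m) != length(snp_cols)) {
    stop_input("%s: SNP header fields must be <id>_<allele> at line 1", path)
  }
  ids <- substr(snp_cols, 1L, nchar(snp_cols) - nchar(m))
  alleles <- substring(m, 2L)
  p <- length(ids)
  n <- length(lines) - 1L
  values <- matrix(NA_integer_, n, p)
  phenotype <- integer(n)
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    tok <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(tok) != 6L + p) {
      stop_input("%s: ragged row at line %d (%d fields, expected %d)",
                 path, i + 1L, length(tok), 6L + p)
    }
    sample_ids[i] <- tok[2]
    ph <- tok[6]
    phenotype[i] <- if (ph %in% c("NA", "-9", "0")) NA_integer_ else
      if (ph == "1") 0L else if (ph == "2") 1L else
        stop_input("%s: bad phenotype token '%s' at line %d", path, ph, i + 1L)
    g <- tok[-(1:6)]
    bad <- !(g %in% c("0", "1", "2", "NA"))
    if (any(bad)) {
      stop_input("%s: bad genotype token '%s' at line %d",
                 path, g[which(bad)[1]], i + 1L)
    }
    values[i, ] <- suppressWarnings(as.integer(g))
  }
  meta <- default_snp_meta(p)
  meta$id <- ids
  meta$allele1 <- alleles
  if (!is.null(bim)) {
    bm <- if (is.character(bim)) read_bim(bim) else bim
    idx <- match(ids, bm$id)
    if (anyNA(idx)) {
      stop_input("SNP(s) absent from .bim table: %s",
                 paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
    }
    meta$chr <- bm$chr[idx]
    meta$pos <- bm$pos[idx]
    meta$allele2 <- bm$allele2[idx]
    mism <- meta$allele1 != bm$allele1[idx]
    if (any(mism)) {
      stop_input(".raw counted allele disagrees with .bim allele1 for: %s",
                 paste(utils::head(ids[mism], 5), collapse = ", "))
    }
  }
  list(genotypes = genotype_matrix(values, meta, sample_ids),
       phenotype = phenotype)
}

#' Write / read a .bim-like SNP metadata table
#'
#' Six tab-separated columns, no header: chromosome, SNP id, 0 (genetic
#' distance placeholder), 1-based position, allele1 (counted), allele2.
#'
#' @param genotypes A [genotype_matrix()] (for writing).
#' @param path File path.
#' @return `read_bim` returns a data frame with columns `chr`, `id`, `pos`,
#'   `allele1`, `allele2`.
#' @export
write_bim <- function(genotypes, path) {
  meta <- genotypes$snp_meta
  utils::write.table(
    data.frame(meta$chr, meta$id, 0L, meta$pos, meta$allele1, meta$allele2),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bim
#' @export
read_bim <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chr", "id", "cm", "pos",
                                        "allele1", "allele2"))
  df[, c("chr", "id", "pos", "allele1", "allele2")]
}

#' Read / write GWAS summary statistics
#'
#' Tab-separated with header columns `SNP`, `A1` (effect allele), `BETA`
#' (log odds ratio) or `OR` (converted by `log`), optionally `SE`, and `P`.
#' A file carrying both `BETA` and `OR`, or neither, is rejected. Rows with
#' `OR <= 0` or `P` outside (0, 1] are rejected with a diagnostic.
#'
#' @param path File path.
#' @return `read_summary_stats` returns a `snp_stats` data frame with
#'   columns `snp_id`, `effect_allele`, `beta`, `se`, `p`.
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(df)
  if (!all(c("SNP", "A1", "P") %in% nm)) {
    stop_input("%s: summary statistics need columns SNP, A1, P", path)
  }
  has_beta <- "BETA" %in% nm
  has_or <- "OR" %in% nm
  if (has_beta == has_or) {
    stop_input("%s: exactly one of BETA or OR must be present (found %s)",
               path, paste(intersect(nm, c("BETA", "OR")), collapse = ", "))
  }
  if (has_or) {
    bad <- !is.finite(df$OR) | df$OR <= 0
    if (any(bad)) stop_input("%s: OR <= 0 at row %d", path, which(bad)[1])
    beta <- log(df$OR)
  } else beta <- df$BETA
  bad_p <- !is.finite(df$P) | df$P <= 0 | df$P > 1
  if (any(bad_p)) stop_input("%s: P outside (0, 1] at row %d",
                             path, which(bad_p)[1])
  snp_stats(snp_id = df$SNP, effect_allele = df$A1, beta = beta,
            se = if ("SE" %in% nm) df$SE else rep(NA_real_, nrow(df)),
            p = df$P)
}

#' @rdname read_summary_stats
#' @param stats A `snp_stats` data frame.
#' @export
write_summary_stats <- function(stats, path) {
  out <- data.frame(SNP = stats$snp_id, A1 = stats$effect_allele,
                    BETA = stats$beta, SE = stats$se, P = stats$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a per-SNP effect-estimate table
#'
#' @param snp_id,effect_allele,beta,se,p Aligned per-SNP vectors; `beta` is
#'   the log odds ratio of the effect allele.
#' @param flag Optional character diagnostics (e.g. `"separation"`).
#' @return A data frame of class `snp_stats`.
#' @export
snp_stats <- function(snp_id, effect_allele, beta, se, p,
                      flag = rep("", length(snp_id))) {
  if (any(!is.na(se) & se <= 0)) stop_input("se must be > 0 where present")
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop_input("p must lie in (0, 1]")
  structure(data.frame(snp_id = snp_id, effect_allele = effect_allele,
                       beta = beta, se = se, p = p, flag = flag,
                       stringsAsFactors = FALSE),
            class = c("snp_stats", "data.frame"))
}
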