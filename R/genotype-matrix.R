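#' Genotype matrix container
#'
#' Holds an individuals-by-SNPs matrix of additive allele counts (0, 1, 2,
#' or `NA` for missing) together with per-SNP metadata. Counts refer to the
#' `allele1` (counted/effect) allele of each SNP.
#'
#' @param values Integer matrix, individuals in rows, SNPs in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param snp_meta Data frame with one row per SNP: columns `id`, `chr`,
#'   `pos` (1-based base pairs), `allele1` (the counted allele), `allele2`.
#' @param sample_ids Character vector of per-individual identifiers; defaults
#'   to `ind000001 ...`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, snp_meta = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  ok <- is.na(values) | values %in% c(0, 1, 2)
  if (!all(ok)) {
    stop_input("genotype values must be 0, 1, 2 or NA (found %s)",
               paste(utils::head(unique(values[!ok]), 3), collapse = ", "))
  }
  storage.mode(values) <- "integer"
  p <- ncol(values)
  if (is.null(snp_meta)) snp_meta <- default_snp_meta(p)
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  need <- c("id", "chr", "pos", "allele1", "allele2")
  if (!all(need %in% names(snp_meta))) {
    stop_input("snp_meta must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(snp_meta) != p) stop_input("snp_meta rows (%d) != SNP columns (%d)",
                                      nrow(snp_meta), p)
  if (anyDuplicated(snp_meta$id)) stop_input("SNP ids must be unique")
  if (any(!is.na(snp_meta$pos) & snp_meta$pos < 1)) {
    stop_input("SNP positions must be positive")
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(values))) rownames(values) else
      sprintf("ind%06d", seq_len(nrow(values)))
  }
  if (length(sample_ids) != nrow(values)) {
    stop_input("sample_ids length != number of individuals")
  }
  dimnames(values) <- list(sample_ids, snp_meta$id)
  structure(list(values = values, snp_meta = snp_meta,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

# Evenly spaced placeholder metadata: one SNP per megabase on chromosome 1,
# so simulated loci fall outside each other's LD-pruning window by default.
default_snp_meta <- function(p) {
  data.frame(id = sprintf("snp%04d", seq_len(p)),
             chr = rep(1L, p),
             pos = as.integer(seq_len(p)) * 1000000L,
             allele1 = rep("A", p), allele2 = rep("G", p),
             stringsAsFactors = FALSE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%d missing entries)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

n_snps <- function(x) ncol(x$values)
n_samples <- function(x) nrow(x$values)

# Column subset preserving metadata alignment.
subset_snps <- function(x, keep) {
  genotype_matrix(x$values[, keep, drop = FALSE],
                  x$snp_meta[keep, , drop = FALSE],
                  x$sample_ids)
}

subset_samples <- function(x, keep) {
  genotype_matrix(x$values[keep, , drop = FALSE], x$snp_meta,
                  x$sample_ids[keep])
}

#' Per-SNP counted-allele frequency
#'
#' Frequency of `allele1` at each SNP, computed over non-missing entries.
#'
#' @param x A [genotype_matrix()].
#' @return Named numeric vector of allele-1 frequencies.
#' @export
allele_freq <- function(x) {
  colMeans(x$values, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#'
#' @param x A [genotype_matrix()].
#' @return Named numeric vector, `pmin(f, 1 - f)` of the counted-allele
#'   frequency `f`.
#' @export
minor_allele_freq <- function(x) {
  f <- allele_freq(x)
  pmin(f, 1 - f)
}
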