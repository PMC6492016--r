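# Univariable logistic fit (intercept + allele count) via iteratively
# reweighted least squares; returns beta, Wald se and p. Perfect separation
# inflates |beta| without bound, so estimates beyond `cap` are capped and
# flagged.
logistic_single <- function(g, y, cap = 15) {
  x <- cbind(1, g)
  fit <- suppressWarnings(stats::glm.fit(x, y, family = stats::binomial()))
  beta <- fit$coefficients[2]
  w <- fit$weights
  flag <- ""
  info <- crossprod(x * sqrt(w))
  cov <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  se <- if (is.null(cov)) NA_real_ else sqrt(cov[2, 2])
  if (!is.finite(beta) || abs(beta) > cap || !fit$converged) {
    beta <- sign(beta) * min(abs(beta), cap)
    flag <- "separation"
  }
  p <- if (is.na(se) || se <= 0) NA_real_ else
    2 * stats::pnorm(-abs(beta / se))
  c(beta = unname(beta), se = unname(se), p = unname(p),
    flagged = as.numeric(nzchar(flag)))
}

#' Per-SNP univariable logistic association scan
#'
#' Fits one logistic regression per SNP (intercept plus allele count) of
#' case/control status on genotype, reporting the log odds ratio of the
#' counted allele, its Wald standard error and two-sided Wald p-value.
#'
#' @param genotypes A [genotype_matrix()] with no missing entries
#'   (post-imputation).
#' @param phenotype 0/1 vector aligned to individuals.
#' @return A [snp_stats()] data frame; SNPs with (near-)separated fits carry
#'   a capped `beta` and `flag = "separation"`.
#' @export
per_snp_logistic <- function(genotypes, phenotype) {
  v <- genotypes$values
  if (anyNA(v)) stop_input("missing genotypes present; impute first")
  if (length(phenotype) != nrow(v)) stop_input("phenotype length mismatch")
  if (length(unique(phenotype)) < 2L) stop_input("both classes required")
  res <- apply(v, 2, logistic_single, y = phenotype)
  snp_stats(snp_id = genotypes$snp_meta$id,
            effect_allele = genotypes$snp_meta$allele1,
            beta = res["beta", ], se = res["se", ], p = res["p", ],
            flag = ifelse(res["flagged", ] > 0, "separation", ""))
}

#' Select score SNPs by association p-value
#'
#' Keeps SNPs with `p <= p_threshold`, then at most `max_snps` with the
#' smallest p; ties are broken deterministically by (p, id).
#'
#' @param stats A [snp_stats()] table.
#' @param p_threshold Inclusion threshold (inclusive).
#' @param max_snps Cap on the number of selected SNPs.
#' @return The selected subset, ordered by (p, id). An empty selection is
#'   returned with a warning.
#' @export
select_snps <- function(stats, p_threshold = 1, max_snps = Inf) {
  keep <- !is.na(stats$p) & stats$p <= p_threshold
  sel <- stats[keep, , drop = FALSE]
  sel <- sel[order(sel$p, sel$snp_id), , drop = FALSE]
  if (nrow(sel) > max_snps) sel <- sel[seq_len(max_snps), , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no SNPs pass p <= ", p_threshold, call. = FALSE)
  }
  sel
}

#' Compute polygenic risk scores
#'
#' The score of individual i is `sum_j beta_j * g_ij`, where `g_ij` counts
#' the effect allele of SNP j. When the target matrix counts the other
#' allele, the count is flipped to `2 - g`; an allele that matches neither
#' side of the target SNP is irreconcilable and an error.
#'
#' @param genotypes Target [genotype_matrix()] with no missing entries.
#' @param stats A [snp_stats()] table of score SNPs and weights.
#' @return Named numeric vector of per-individual scores.
#' @export
compute_prs <- function(genotypes, stats) {
  meta <- genotypes$snp_meta
  idx <- match(stats$snp_id, meta$id)
  if (anyNA(idx)) {
    stop_input("score SNP(s) absent from target genotypes: %s",
               paste(utils::head(stats$snp_id[is.na(idx)], 5), collapse = ", "))
  }
  g <- genotypes$values[, idx, drop = FALSE]
  if (anyNA(g)) stop_input("missing genotypes present; impute first")
  same <- stats$effect_allele == meta$allele1[idx]
  flip <- stats$effect_allele == meta$allele2[idx]
  if (any(!same & !flip)) {
    bad <- stats$snp_id[!same & !flip]
    stop_input("irreconcilable effect allele for SNP(s): %s",
               paste(utils::head(bad, 5), collapse = ", "))
  }
  g[, flip] <- 2L - g[, flip, drop = FALSE]
  scores <- as.numeric(g %*% stats$beta)
  names(scores) <- genotypes$sample_ids
  scores
}

#' Area under the ROC curve by the midrank convention
#'
#' Equals the probability that a uniformly chosen case outranks a uniformly
#' chosen control, with ties counted one half (equivalently the normalized
#' Mann-Whitney U statistic with midranks).
#'
#' @param scores Numeric classifier scores (larger = more case-like).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_input("length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop_input("both classes must be present")
  r <- rank(scores)  # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate polygenic scores against case/control status
#'
#' Fits `status ~ score` by logistic regression and reports the Wald
#' p-value of the score coefficient together with the AUC-ROC of the score.
#'
#' @param scores Per-individual polygenic scores.
#' @param phenotype 0/1 labels.
#' @return List of class `prs_result`: `scores`, `auc`, `logistic_p`,
#'   `coef` (score log-odds coefficient), and `flag` (`"degenerate"` for
#'   constant scores, where the coefficient is undefined and AUC is 0.5).
#' @export
evaluate_prs <- function(scores, phenotype) {
  auc <- compute_auc(scores, phenotype)
  if (stats::sd(scores) == 0) {
    res <- list(scores = scores, auc = auc, logistic_p = NA_real_,
                coef = NA_real_, flag = "degenerate")
  } else {
    fit <- stats::glm(phenotype ~ scores, family = stats::binomial())
    sm <- summary(fit)$coefficients
    res <- list(scores = scores, auc = auc, logistic_p = sm["scores", 4],
                coef = sm["scores", 1], flag = "")
  }
  structure(res, class = "prs_result")
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("prs_result: AUC = %.4f, score p = %.3g%s\n", x$auc,
              x$logistic_p,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}
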