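#' One shared train/test split evaluated by every method
#'
#' Splits the cohort once (stratified, default 75%/25%), then fits and
#' evaluates each requested method on that same split: PRS weights are
#' per-SNP logistic betas estimated on the training side; SVM features are
#' standardized with training-side parameters; all methods are scored by
#' AUC-ROC of their continuous test-set scores.
#'
#' @param genotypes Imputation-complete [genotype_matrix()].
#' @param phenotype 0/1 labels.
#' @param methods Character subset of `c("prs", "svm_linear", "svm_rbf")`.
#' @param split_seed Seed of the stratified split.
#' @param test_fraction Held-out fraction (default 0.25).
#' @param svm_configs Named list of [svm_config()]s for `svm_linear` /
#'   `svm_rbf`; defaults to the tuned values reported for this protocol
#'   (linear `C = 1`; RBF `C = 0.5`, `gamma = 0.02`).
#' @param p_threshold,max_snps Passed to [select_snps()] for the PRS.
#' @return List with `auc` (named per-method vector), `test_ids`
#'   (identifiers of held-out individuals, identical across methods), and
#'   `n_score_snps` for the PRS.
#' @export
run_split <- function(genotypes, phenotype,
                      methods = c("prs", "svm_linear", "svm_rbf"),
                      split_seed = 1L, test_fraction = 0.25,
                      svm_configs = default_svm_configs(),
                      p_threshold = 1, max_snps = Inf) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (anyNA(genotypes$values)) stop_input("impute missing genotypes first")
  test <- with_seed(split_seed, stratified_test_mask(phenotype, test_fraction))
  if (length(unique(phenotype[test])) < 2L ||
      length(unique(phenotype[!test])) < 2L) {
    stop_input("a class is absent from one side of the split")
  }
  g_train <- subset_samples(genotypes, !test)
  g_test <- subset_samples(genotypes, test)
  y_train <- phenotype[!test]
  y_test <- phenotype[test]
  auc <- c()
  n_score_snps <- NA_integer_
  if ("prs" %in% methods) {
    stats <- per_snp_logistic(g_train, y_train)
    sel <- select_snps(stats, p_threshold, max_snps)
    n_score_snps <- nrow(sel)
    scores <- compute_prs(g_test, sel)
    auc["prs"] <- compute_auc(scores, y_test)
  }
  svm_methods <- intersect(methods, c("svm_linear", "svm_rbf"))
  if (length(svm_methods)) {
    std <- standardize_features(g_train$values, list(test = g_test$values))
    for (m in svm_methods) {
      model <- train_svm(std$train, y_train, svm_configs[[m]])
      auc[m] <- compute_auc(decision_scores(model, std$other$test), y_test)
    }
  }
  list(auc = auc[methods], test_ids = genotypes$sample_ids[test],
       n_score_snps = n_score_snps)
}

#' Default SVM configurations for the repeated-split comparison
#'
#' The near-optimal values selected by the Monte-Carlo search in the
#' reference protocol: linear kernel `C = 1`; RBF kernel `C = 0.5`,
#' `gamma = 0.02`.
#'
#' @return Named list of [svm_config()]s.
#' @export
default_svm_configs <- function() {
  list(svm_linear = svm_config("linear", C = 1),
       svm_rbf = svm_config("rbf", C = 0.5, gamma = 0.02))
}

#' Repeated-split method comparison
#'
#' Repeats [run_split()] `n_reps` times (replicate r uses
#' `split_seed = base_seed + r`), aggregating per-method AUC distributions
#' and their boxplot summaries (median, quartiles, extremes).
#'
#' @inheritParams run_split
#' @param n_reps Number of repeated splits.
#' @param base_seed Base of the per-replicate seed ladder.
#' @return An object of class `experiment_result`: `replicates` (one row
#'   per replicate x method), `summary` (per-method median, quartiles,
#'   min, max), and `seed_ledger` (replicate seeds, re-runnable in
#'   isolation).
#' @export
run_experiment <- function(genotypes, phenotype,
                           methods = c("prs", "svm_linear", "svm_rbf"),
                           n_reps = 100, base_seed = 1L,
                           test_fraction = 0.25,
                           svm_configs = default_svm_configs(),
                           p_threshold = 1, max_snps = Inf) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sp <- run_split(genotypes, phenotype, methods,
                    split_seed = base_seed + r,
                    test_fraction = test_fraction,
                    svm_configs = svm_configs,
                    p_threshold = p_threshold, max_snps = max_snps)
    rows[[r]] <- data.frame(replicate = r, method = methods,
                            auc = unname(sp$auc), stringsAsFactors = FALSE)
  }
  replicates <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(methods, function(m) {
    a <- replicates$auc[replicates$method == m]
    data.frame(method = m, median = stats::median(a),
               q1 = unname(stats::quantile(a, 0.25)),
               q3 = unname(stats::quantile(a, 0.75)),
               min = min(a), max = max(a), n_reps = length(a),
               stringsAsFactors = FALSE)
  }))
  structure(list(replicates = replicates, summary = summ,
                 seed_ledger = data.frame(replicate = seq_len(n_reps),
                                          split_seed = base_seed +
                                            seq_len(n_reps))),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result over", max(x$replicates$replicate), "splits:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare two methods' AUC distributions
#'
#' Two-sample t-test on replicate AUC vectors; Welch (unequal variance) by
#' default, Student or split-paired alternatives by flag.
#'
#' @param auc_a,auc_b Replicate AUC vectors.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @param paired Pair replicates (valid when both vectors come from the
#'   same splits in order).
#' @return List with `mean_diff` (a minus b), `t`, `p`, and `df`.
#' @export
compare_methods <- function(auc_a, auc_b, var_equal = FALSE, paired = FALSE) {
  tt <- stats::t.test(auc_a, auc_b, var.equal = var_equal, paired = paired)
  list(mean_diff = mean(auc_a) - mean(auc_b),
       t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Compare one method across two cohort sizes
#'
#' The same Welch t-test applied to one method's replicate AUC vectors from
#' experiments on cohorts of different sample size.
#'
#' @param result_small,result_large [run_experiment()] results.
#' @param method Method name present in both.
#' @param ... Passed to [compare_methods()].
#' @return As [compare_methods()], with `mean_diff = large - small`.
#' @export
compare_sample_sizes <- function(result_small, result_large, method, ...) {
  a <- result_large$replicates$auc[result_large$replicates$method == method]
  b <- result_small$replicates$auc[result_small$replicates$method == method]
  if (!length(a) || !length(b)) stop_input("method '%s' absent", method)
  compare_methods(a, b, ...)
}
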