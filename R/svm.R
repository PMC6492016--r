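#' Soft-margin SVM configuration
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param C Positive margin-violation penalty.
#' @param gamma Positive RBF curvature parameter (RBF kernel only).
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(kernel = c("linear", "rbf"), C = 1, gamma = NULL) {
  kernel <- match.arg(kernel)
  if (!is.numeric(C) || C <= 0) stop_input("C must be > 0")
  if (kernel == "rbf") {
    if (is.null(gamma) || gamma <= 0) stop_input("gamma must be > 0 for rbf")
  } else gamma <- NULL
  structure(list(kernel = kernel, C = C, gamma = gamma),
            class = "svm_config")
}

#' Monte-Carlo hyperparameter search specification
#'
#' Candidate hyperparameters are drawn from exponential distributions:
#' `C ~ Exponential(scale = c_scale)` and, for the RBF kernel,
#' `gamma ~ Exponential(scale = gamma_scale)`. The scale (mean)
#' parameterization is the default; `param_as = "rate"` reads the same
#' numbers as rates instead.
#'
#' @param n_draws Number of candidate configurations.
#' @param folds Cross-validation folds used to score each candidate.
#' @param c_scale,gamma_scale Exponential scale parameters (defaults 1 and
#'   0.01).
#' @param param_as `"scale"` (default) or `"rate"`.
#' @param seed Integer seed governing both the draws and the CV folds.
#' @return An object of class `search_spec`.
#' @export
search_spec <- function(n_draws = 25, folds = 4, c_scale = 1,
                        gamma_scale = 0.01, param_as = c("scale", "rate"),
                        seed = 1L) {
  n_draws <- check_count(n_draws, "n_draws")
  folds <- check_count(folds, "folds")
  if (folds < 2L) stop_input("folds must be >= 2")
  if (c_scale <= 0 || gamma_scale <= 0) stop_input("scales must be > 0")
  structure(list(n_draws = n_draws, folds = folds, c_scale = c_scale,
                 gamma_scale = gamma_scale, param_as = match.arg(param_as),
                 seed = as.integer(seed)),
            class = "search_spec")
}

#' Standardize feature matrices with training-set parameters
#'
#' Column means and standard deviations are fitted on the training matrix
#' only and applied to every matrix, so no information leaks from held-out
#' data. Columns with zero training variance are dropped from all matrices
#' and reported.
#'
#' @param train Numeric training matrix (individuals x features).
#' @param other Named list of further matrices to transform with the
#'   training parameters (e.g. a test matrix).
#' @return List with `train`, `other`, `center`, `scale`, and `dropped`
#'   (names/indices of zero-variance columns).
#' @export
standardize_features <- function(train, other = list()) {
  train <- as.matrix(train)
  if (anyNA(train)) stop_input("missing values present; impute first")
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  dropped <- which(scl == 0)
  keep <- scl > 0
  tx <- scale(train[, keep, drop = FALSE], center = ctr[keep],
              scale = scl[keep])
  ox <- lapply(other, function(m) {
    m <- as.matrix(m)
    if (anyNA(m)) stop_input("missing values present; impute first")
    scale(m[, keep, drop = FALSE], center = ctr[keep], scale = scl[keep])
  })
  list(train = tx, other = ox, center = ctr[keep], scale = scl[keep],
       dropped = dropped)
}

#' Train a soft-margin SVM
#'
#' Fits a C-classification support vector machine (libsvm via e1071) with
#' the linear or RBF kernel on pre-standardized features, exposing
#' continuous decision scores oriented so that larger values favour cases.
#'
#' @param features Numeric matrix (already standardized; no missing values).
#' @param labels 0/1 vector; both classes must be present.
#' @param config An [svm_config()].
#' @return An object of class `prsvm_svm`.
#' @export
train_svm <- function(features, labels, config) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop_input("features must be finite")
  if (length(unique(labels)) < 2L) stop_input("both classes must be present")
  kern <- if (config$kernel == "linear") "linear" else "radial"
  fit <- e1071::svm(features, factor(labels, levels = c(0, 1)),
                    kernel = kern, cost = config$C,
                    gamma = if (is.null(config$gamma)) 1 / ncol(features)
                            else config$gamma,
                    scale = FALSE)
  structure(list(fit = fit, config = config), class = "prsvm_svm")
}

#' Continuous decision scores of a trained SVM
#'
#' @param model A `prsvm_svm` from [train_svm()].
#' @param features New feature matrix on the training standardization.
#' @return Numeric vector; larger values indicate the case class.
#' @export
decision_scores <- function(model, features) {
  pred <- stats::predict(model$fit, as.matrix(features),
                         decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm orients the decision value toward the first class of "A/B"
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (first == "1") dv[, 1] else -dv[, 1]
}

#' Cross-validated AUC of an SVM configuration
#'
#' Stratified k-fold assignment; per-fold AUC of held-out decision scores
#' via [compute_auc()]; the mean across folds is returned.
#'
#' @param features Standardized feature matrix.
#' @param labels 0/1 labels.
#' @param config An [svm_config()].
#' @param folds Number of folds.
#' @param seed Seed for the fold assignment.
#' @return Mean held-out AUC across folds.
#' @export
cv_score <- function(features, labels, config, folds = 4, seed = 1L) {
  fold <- with_seed(seed, stratified_folds(labels, folds))
  aucs <- vapply(seq_len(folds), function(k) {
    tr <- fold != k
    m <- train_svm(features[tr, , drop = FALSE], labels[tr], config)
    compute_auc(decision_scores(m, features[!tr, , drop = FALSE]),
                labels[!tr])
  }, numeric(1))
  mean(aucs)
}

#' Monte-Carlo random hyperparameter search
#'
#' Draws `n_draws` candidate configurations from the exponential priors of
#' a [search_spec()], scores each by [cv_score()] on a fixed fold
#' assignment, and returns the best. Ties are broken toward smaller `C`,
#' then smaller `gamma`.
#'
#' @param features Standardized feature matrix.
#' @param labels 0/1 labels.
#' @param kernel `"linear"` or `"rbf"`.
#' @param spec A [search_spec()].
#' @return List with `best` (an [svm_config()]), `best_score`, and `trace`
#'   (data frame of every candidate with its CV AUC).
#' @export
mc_hyperparameter_search <- function(features, labels, kernel, spec) {
  rate_c <- if (spec$param_as == "scale") 1 / spec$c_scale else spec$c_scale
  rate_g <- if (spec$param_as == "scale") 1 / spec$gamma_scale else spec$gamma_scale
  draws <- with_seed(derive_seed(spec$seed, "mc_draws"), {
    data.frame(C = stats::rexp(spec$n_draws, rate = rate_c),
               gamma = if (kernel == "rbf")
                 stats::rexp(spec$n_draws, rate = rate_g) else NA_real_)
  })
  fold_seed <- derive_seed(spec$seed, "mc_folds")
  score <- vapply(seq_len(spec$n_draws), function(i) {
    cfg <- svm_config(kernel, C = draws$C[i],
                      gamma = if (kernel == "rbf") draws$gamma[i] else NULL)
    cv_score(features, labels, cfg, folds = spec$folds, seed = fold_seed)
  }, numeric(1))
  trace <- cbind(draws, cv_auc = score)
  gam_key <- ifelse(is.na(draws$gamma), 0, draws$gamma)
  ord <- order(-score, draws$C, gam_key)
  best_i <- ord[1]
  list(best = svm_config(kernel, C = draws$C[best_i],
                         gamma = if (kernel == "rbf") draws$gamma[best_i]
                                 else NULL),
       best_score = score[best_i], trace = trace)
}

#' Two-phase hyperparameter tuning
#'
#' Reserves a stratified holdout (default 10%) for verification, runs the
#' Monte-Carlo cross-validated search on the remaining tuning split, and
#' reports the holdout AUC of the selected configuration. The selected
#' configuration is intended for reuse across subsequent repeated
#' train/test splits.
#'
#' @param features Feature matrix (raw counts; standardization is fitted on
#'   the tuning split internally).
#' @param labels 0/1 labels.
#' @param kernel `"linear"` or `"rbf"`.
#' @param spec A [search_spec()].
#' @param holdout_fraction Fraction kept out of the search (default 0.1).
#' @return List with `best`, `best_cv_score`, `holdout_auc`, and `trace`.
#' @export
tune_svm <- function(features, labels, kernel, spec,
                     holdout_fraction = 0.1) {
  test <- with_seed(derive_seed(spec$seed, "tune_holdout"),
                    stratified_test_mask(labels, holdout_fraction))
  std <- standardize_features(features[!test, , drop = FALSE],
                              list(holdout = features[test, , drop = FALSE]))
  search <- mc_hyperparameter_search(std$train, labels[!test], kernel, spec)
  model <- train_svm(std$train, labels[!test], search$best)
  holdout_auc <- compute_auc(decision_scores(model, std$other$holdout),
                             labels[test])
  list(best = search$best, best_cv_score = search$best_score,
       holdout_auc = holdout_auc, trace = search$trace)
}
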