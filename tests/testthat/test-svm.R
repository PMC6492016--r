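test_that("standardization fits on the training matrix only", {
  train <- cbind(c(0, 1, 2, 1), c(1, 1, 1, 1), c(0, 2, 0, 2))
  test <- cbind(c(2, 2), c(1, 0), c(1, 1))
  std <- standardize_features(train, list(test = test))
  expect_equal(unname(colMeans(std$train)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(std$train, 2, sd)), c(1, 1), tolerance = 1e-10)
  # constant column dropped everywhere and reported
  expect_equal(unname(std$dropped), 2)
  expect_equal(ncol(std$other$test), 2)
  # test transformed with train parameters, not its own
  own <- scale(test[, c(1, 3)])
  expect_false(isTRUE(all.equal(unname(std$other$test), unname(own))))
})

test_that("linear SVM separates separable data; only RBF solves XOR", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
  y_sep <- c(0, 0, 1, 1)
  xs <- scale(x)
  m_lin <- train_svm(xs, y_sep, svm_config("linear", C = 1))
  expect_true(all((decision_scores(m_lin, xs) > 0) == (y_sep == 1)))

  y_xor <- c(0, 1, 1, 0)
  m_rbf <- train_svm(xs, y_xor, svm_config("rbf", C = 1, gamma = 1))
  expect_true(all((decision_scores(m_rbf, xs) > 0) == (y_xor == 1)))
  m_lin2 <- train_svm(xs, y_xor, svm_config("linear", C = 1))
  expect_lte(sum((decision_scores(m_lin2, xs) > 0) == (y_xor == 1)), 3)

  expect_error(train_svm(matrix(c(1, NA), 2, 1), c(0, 1),
                         svm_config("linear")), "finite")
})

test_that("decision scores are invariant to sample order", {
  coh <- make_additive_cohort(n_cases = 100, n_controls = 100, n_snps = 6,
                              seed = 23)
  std <- standardize_features(coh$genotypes$values)
  m <- train_svm(std$train, coh$phenotype, svm_config("rbf", C = 1,
                                                      gamma = 0.05))
  sc <- decision_scores(m, std$train)
  perm <- sample(seq_along(sc))
  expect_equal(unname(decision_scores(m, std$train[perm, ])),
               unname(sc[perm]))
})

test_that("cross-validated AUC behaves at the null and on separable data", {
  set.seed(24)
  x_null <- matrix(rnorm(200 * 5), 200, 5)
  y <- rep(c(0, 1), 100)
  cfg <- svm_config("linear", C = 1)
  auc_null <- cv_score(x_null, y, cfg, folds = 4, seed = 25)
  expect_lt(abs(auc_null - 0.5), 0.15)

  x_sep <- x_null
  x_sep[, 1] <- x_sep[, 1] + 3 * y
  expect_gt(cv_score(x_sep, y, cfg, folds = 4, seed = 25), 0.95)

  # same seed, same folds, same score
  expect_identical(cv_score(x_sep, y, cfg, folds = 4, seed = 26),
                   cv_score(x_sep, y, cfg, folds = 4, seed = 26))
})

test_that("Monte-Carlo search returns the best traced configuration", {
  set.seed(27)
  x <- matrix(rnorm(120 * 4), 120, 4)
  y <- rep(c(0, 1), 60)
  x[, 1] <- x[, 1] + 2 * y
  sp1 <- search_spec(n_draws = 1, seed = 28)
  res1 <- mc_hyperparameter_search(x, y, "linear", sp1)
  expect_equal(nrow(res1$trace), 1)
  expect_equal(res1$best$C, res1$trace$C[1])

  sp <- search_spec(n_draws = 6, seed = 29)
  res <- mc_hyperparameter_search(x, y, "rbf", sp)
  expect_equal(res$best_score, max(res$trace$cv_auc))
  best_row <- which(res$trace$cv_auc == res$best_score)
  expect_true(res$best$C %in% res$trace$C[best_row])
})

test_that("search selections are near-optimal relative to the protocol's chosen values", {
  # the accuracy surface over C is nearly flat for the linear kernel, so
  # the informative trend check is that the searched configuration scores
  # within noise of the protocol's chosen defaults (linear C = 1; rbf
  # C = 0.5, gamma = 0.02), not that the argmax lands on them
  coh <- make_additive_cohort(n_cases = 400, n_controls = 400, n_snps = 20,
                              or = 1.3, seed = 30)
  std <- standardize_features(coh$genotypes$values)
  sp_l <- search_spec(n_draws = 8, seed = 31)
  res_l <- mc_hyperparameter_search(std$train, coh$phenotype, "linear", sp_l)
  ref_l <- cv_score(std$train, coh$phenotype, svm_config("linear", C = 1),
                    seed = prsvm:::derive_seed(sp_l$seed, "mc_folds"))
  expect_gt(res_l$best_score, ref_l - 0.02)

  sp_r <- search_spec(n_draws = 8, seed = 32)
  res_r <- mc_hyperparameter_search(std$train, coh$phenotype, "rbf", sp_r)
  ref_r <- cv_score(std$train, coh$phenotype,
                    svm_config("rbf", C = 0.5, gamma = 0.02),
                    seed = prsvm:::derive_seed(sp_r$seed, "mc_folds"))
  expect_gt(res_r$best_score, ref_r - 0.02)
  # the gamma prior's scale keeps draws in the useful bandwidth regime
  expect_gt(res_r$best$gamma, 0.001)
  expect_lt(res_r$best$gamma, 0.2)
})

test_that("tuning reserves a holdout and reports its AUC", {
  coh <- make_additive_cohort(n_cases = 300, n_controls = 300, n_snps = 10,
                              or = 1.5, seed = 33)
  tuned <- tune_svm(coh$genotypes$values, coh$phenotype, "linear",
                    search_spec(n_draws = 3, seed = 34))
  expect_true(tuned$holdout_auc >= 0 && tuned$holdout_auc <= 1)
  expect_equal(nrow(tuned$trace), 3)
})
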