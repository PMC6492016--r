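test_that("sampled genotypes follow Hardy-Weinberg proportions and reject bad MAFs", {
  expect_error(sample_genotypes(100, c(0, 0.3)), "0, 1")
  expect_error(sample_genotypes(100, c(0.3, 1)), "0, 1")

  g <- sample_genotypes(100000, c(0.5, 0.2), seed = 101)
  # symmetry at MAF 0.5: column mean 1 within 3 SE
  se_mean <- sqrt(2 * 0.5 * 0.5 / 100000)
  expect_lt(abs(mean(g$values[, 1]) - 1), 3 * se_mean)
  # HWE class frequencies at MAF 0.2: (0.64, 0.32, 0.04) within 3 SE
  freq <- tabulate(g$values[, 2] + 1L, 3L) / 100000
  expected <- c(0.64, 0.32, 0.04)
  se <- sqrt(expected * (1 - expected) / 100000)
  expect_true(all(abs(freq - expected) < 3 * se))
})

test_that("independently sampled SNPs are uncorrelated (permutation null bound)", {
  g <- sample_genotypes(10000, c(0.3, 0.3), seed = 202)
  r_obs <- cor(g$values[, 1], g$values[, 2])
  null_r <- vapply(1:500, function(i) {
    set.seed(5000 + i)
    cor(g$values[, 1], sample(g$values[, 2]))
  }, numeric(1))
  expect_lt(abs(r_obs), quantile(abs(null_r), 0.998))
})

test_that("HWE goodness of fit holds across seeds", {
  pvals <- unlist(lapply(1:5, function(s) {
    g <- sample_genotypes(5000, c(0.1, 0.25, 0.4), seed = s)
    apply(g$values, 2, function(col) {
      obs <- tabulate(col + 1L, 3L)
      f <- mean(col) / 2
      exp <- 5000 * c((1 - f)^2, 2 * f * (1 - f), f^2)
      pchisq(sum((obs - exp)^2 / exp), df = 1, lower.tail = FALSE)
    })
  }))
  expect_gt(min(pvals), 1e-6)
})

test_that("solve_intercept hits the target prevalence", {
  # no genetic effects: closed form
  expect_equal(solve_intercept(0.3, 0, prevalence = 0.1), qlogis(0.1))

  # two SNPs, OR = 4, MAF 0.2: independent 9-cell enumeration oracle
  b0 <- solve_intercept(c(0.2, 0.2), rep(log(4), 2), prevalence = 0.1)
  cells <- expand.grid(g1 = 0:2, g2 = 0:2)
  pr <- dbinom(cells$g1, 2, 0.2) * dbinom(cells$g2, 2, 0.2)
  pen <- sum(pr * plogis(b0 + log(4) * (cells$g1 + cells$g2)))
  expect_lt(abs(pen - 0.1), 1e-8)

  # one SNP, OR = 2, MAF 0.3: Monte-Carlo penetrance oracle at 1e6 draws
  b1 <- solve_intercept(0.3, log(2), prevalence = 0.1)
  set.seed(77)
  gmc <- rbinom(1e6, 2, 0.3)
  pen_mc <- mean(plogis(b1 + log(2) * gmc))
  expect_lt(abs(pen_mc - 0.1), 3 * sd(plogis(b1 + log(2) * gmc)) / 1000)

  # more than three causal loci takes the Monte-Carlo path and stays close
  b4 <- solve_intercept(rep(0.3, 4), rep(log(1.5), 4), prevalence = 0.1)
  set.seed(78)
  g4 <- matrix(rbinom(4e5, 2, 0.3), ncol = 4)
  expect_lt(abs(mean(plogis(b4 + g4 %*% rep(log(1.5), 4))) - 0.1), 0.003)
})

test_that("additive phenotype assignment matches the logistic model", {
  g <- sample_genotypes(50000, rep(0.3, 2), seed = 301)
  expect_error(assign_phenotype_additive(g, c(0.1), qlogis(0.1)), "length")

  # null model: case fraction near K
  y0 <- assign_phenotype_additive(g, c(0, 0), qlogis(0.1), seed = 302)
  expect_lt(abs(mean(y0) - 0.1), 3 * sqrt(0.1 * 0.9 / 50000))
  # null SNP shows no case/control frequency difference
  f_case <- mean(g$values[y0 == 1, 1]) / 2
  f_ctrl <- mean(g$values[y0 == 0, 1]) / 2
  se <- sqrt(0.3 * 0.7 / (2 * sum(y0 == 1)) + 0.3 * 0.7 / (2 * sum(y0 == 0)))
  expect_lt(abs(f_case - f_ctrl), 3 * se)

  # population logistic regression recovers beta = log 2 within 3 SE
  betas <- c(log(2), 0)
  b0 <- solve_intercept(rep(0.3, 2), betas, prevalence = 0.1)
  y <- assign_phenotype_additive(g, betas, b0, seed = 303)
  fit <- glm(y ~ g$values[, 1], family = binomial())
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est[1] - log(2)), 3 * est[2])
})

test_that("XOR phenotype has null marginals at the nulling MAF only", {
  maf0 <- xor_null_maf()
  expect_equal(1 - (1 - maf0)^2, 0.5)  # carrier probability 1/2

  g <- sample_genotypes(50000, rep(maf0, 2), seed = 401)
  expect_error(assign_phenotype_xor(g, c(2, 2), 1.5, -2), "distinct")
  expect_error(assign_phenotype_xor(g, c(1, 5), 1.5, -2), "range")

  b0 <- solve_intercept(rep(maf0, 2), c(0, 0),
                        list(list(1L, 2L, 1.5)), prevalence = 0.1)
  # theta = 0: case fraction is plogis(b0)
  y0 <- assign_phenotype_xor(g, c(1, 2), 0, b0, seed = 402)
  expect_lt(abs(mean(y0) - plogis(b0)), 3 * sqrt(plogis(b0) / 50000))

  y <- assign_phenotype_xor(g, c(1, 2), 1.5, b0, seed = 403)
  # marginal per-locus log OR within 3 SE of zero
  for (j in 1:2) {
    est <- summary(glm(y ~ g$values[, j],
                       family = binomial()))$coefficients[2, ]
    expect_lt(abs(est[1]), 3 * est[2])
  }
  # carrier x carrier table shows strong association among cases/controls
  xa <- g$values[, 1] >= 1
  xb <- g$values[, 2] >= 1
  tab <- table(xor(xa, xb), y)
  expect_lt(chisq.test(tab)$p.value, 1e-6)

  # off the nulling MAF the marginals are nonzero (documented behaviour)
  g2 <- sample_genotypes(50000, rep(0.2, 2), seed = 404)
  b02 <- solve_intercept(rep(0.2, 2), c(0, 0),
                         list(list(1L, 2L, 1.5)), prevalence = 0.1)
  y2 <- assign_phenotype_xor(g2, c(1, 2), 1.5, b02, seed = 405)
  est2 <- summary(glm(y2 ~ g2$values[, 1],
                      family = binomial()))$coefficients[2, ]
  expect_gt(abs(est2[1]), 3 * est2[2])
})

test_that("retrospective sampling fills quotas exactly and reproducibly", {
  spec <- cohort_spec(100, 100, 3, mafs = rep(0.3, 3),
                      causal_betas = c(log(2), 0, 0), seed = 7)
  coh <- sample_case_control(spec)
  expect_equal(sum(coh$phenotype == 1L), 100)
  expect_equal(sum(coh$phenotype == 0L), 100)
  expect_equal(n_snps(coh$genotypes), 3)

  coh2 <- sample_case_control(spec)
  expect_identical(coh$genotypes$values, coh2$genotypes$values)
  expect_identical(coh$phenotype, coh2$phenotype)

  # risk SNP enriched in cases at scale
  spec_big <- cohort_spec(2000, 2000, 2, mafs = rep(0.3, 2),
                          causal_betas = c(log(2), 0), seed = 8)
  big <- sample_case_control(spec_big)
  f1 <- allele_freq(genotype_matrix(
    big$genotypes$values[big$phenotype == 1, , drop = FALSE]))
  f0 <- allele_freq(genotype_matrix(
    big$genotypes$values[big$phenotype == 0, , drop = FALSE]))
  expect_gt(f1[1], f0[1])
  # null SNP difference within 3 SE
  se <- sqrt(0.3 * 0.7 / (2 * 2000) * 2)
  expect_lt(abs(f1[2] - f0[2]), 3 * se)
})

test_that("per-SNP effects are recovered without bias on population samples", {
  bias <- vapply(1:25, function(r) {
    g <- sample_genotypes(50000, 0.3, seed = 6000 + r)
    b0 <- solve_intercept(0.3, log(2), prevalence = 0.1)
    y <- assign_phenotype_additive(g, log(2), b0, seed = 7000 + r)
    coef(glm(y ~ g$values[, 1], family = binomial()))[2] - log(2)
  }, numeric(1))
  expect_lt(abs(mean(bias)), 0.02)
})

test_that("missingness injection is MCAR with the requested rate", {
  g <- sample_genotypes(1000, rep(0.3, 10), seed = 501)
  expect_identical(inject_missing(g, 0)$values, g$values)
  expect_true(all(is.na(inject_missing(g, 1, seed = 502)$values)))

  g_big <- sample_genotypes(10000, rep(0.3, 100), seed = 503)
  gm <- inject_missing(g_big, 0.01, seed = 504)
  frac <- mean(is.na(gm$values))
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / 1e6))
  # untouched where not masked
  keep <- !is.na(gm$values)
  expect_identical(gm$values[keep], g_big$values[keep])
})
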