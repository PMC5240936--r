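test_that("a perfect logit-scale association saturates the statistic", {
  bmi <- seq(22, 33, length.out = 40)
  meth <- plogis(2 * bmi - 55)  # logit stays inside the clipping range
  rec <- fitCpgAssociation(meth, bmi, spec = modelSpec("residualOutcome"))
  expect_equal(rec$beta, 2, tolerance = 1e-8)
  expect_gt(abs(rec$t), 1e6)   # numerically saturated
  expect_equal(rec$p, .Machine$double.xmin)
  expect_identical(rec$direction, "+")
})

test_that("null associations produce uniform p-values", {
  set.seed(31)
  p <- replicate(500, {
    bmi <- rnorm(200, 28, 5)
    meth <- plogis(rnorm(200))
    fitCpgAssociation(meth, bmi)$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("planted effects recover the correct direction", {
  set.seed(32)
  ok <- replicate(50, {
    bmi <- rnorm(1000, 28, 5)
    meth <- plogis(0.05 * bmi + rnorm(1000))
    fitCpgAssociation(meth, bmi)$direction == "+"
  })
  expect_gte(mean(ok), 0.99)
})

test_that("the two model orientations agree in direction on clean data", {
  bmi <- rnorm(200, 28, 5)
  meth <- plogis(0.1 * (bmi - 28) + 0.3)
  a <- fitCpgAssociation(meth, bmi, spec = modelSpec("methOutcome"))
  b <- fitCpgAssociation(meth, bmi, spec = modelSpec("residualOutcome"))
  expect_identical(a$direction, b$direction)
})

test_that("p-values match the t reference distribution exactly", {
  co <- firstCohort(tinyConfig(seed = 41L, n = 120L))
  rec <- runEwas(co, modelSpec())
  df <- rec$n - 4  # intercept + bmi + age + sex
  expect_equal(rec$p, 2 * (1 - pt(abs(rec$t), df)), tolerance = 1e-10)
  expect_identical(rec$direction, ifelse(rec$beta >= 0, "+", "-"))
})

test_that("surrogate variables recover planted latent factors", {
  set.seed(51)
  n <- 500; p <- 80
  f <- matrix(rnorm(n * 2), n, 2)
  load <- matrix(rnorm(2 * p, 0, 1), 2, p)
  meth <- t(f %*% load + matrix(rnorm(n * p, 0, 0.5), n, p))
  age <- rnorm(n, 65, 8)
  sv <- estimateSurrogateVariables(meth, cbind(age = age), k = 2)
  expect_equal(dim(sv), c(n, 2))
  cc <- stats::cancor(sv, f)$cor
  expect_true(all(cc > 0.9))
  # orthogonality to the covariate space and among factors
  X <- cbind(1, age)
  expect_lt(max(abs(crossprod(X, sv))) / n, 1e-8)
  expect_lt(abs(crossprod(sv[, 1], sv[, 2])), 1e-8)
})

test_that("surrogate-variable edge cases behave", {
  set.seed(52)
  meth <- matrix(rnorm(200), 10, 20)
  expect_identical(ncol(estimateSurrogateVariables(meth, NULL, 0)), 0L)
  cov <- rnorm(20)
  degenerate <- rbind(2 * cov, -cov, 0.5 * cov)  # pure covariate structure
  expect_warning(sv <- estimateSurrogateVariables(degenerate,
                                                  cbind(cov), k = 2),
                 "degenerate|recoverable")
  expect_lt(ncol(sv), 2L)
})

test_that("surrogate adjustment deflates lambda on confounded nulls", {
  lams <- t(vapply(1:20, function(r) {
    cfg <- simConfig(nCohorts = 1L, nSamplesPerCohort = 300L, nCpgs = 100L,
                     nSnps = 110L, nGenes = 10L, nGrsSnps = 5L,
                     fracCausalCpgs = 0, fracReactiveCpgs = 0,
                     confoundingSd = 0.8, cellBmiEffect = 2,
                     grsVarBmi = 0, seed = 500L + r)
    co <- firstCohort(cfg)
    z0 <- signedZFromP(runEwas(co, modelSpec())$p, "+")
    # 4 factors: two cell components plus batch structure
    z2 <- signedZFromP(runEwas(co, modelSpec(nSurrogateVariables = 4L))$p,
                       "+")
    c(genomicInflation(z0)$lambda, genomicInflation(z2)$lambda)
  }, numeric(2)))
  expect_lt(median(lams[, 2]), median(lams[, 1]))
})

test_that("the BMI range filter drops out-of-range samples inclusively", {
  co <- firstCohort(tinyConfig(seed = 61L, n = 100L))
  ph <- phenotypes(co)
  ph$bmi[1] <- 17; ph$bmi[2] <- 36; ph$bmi[3] <- 18; ph$bmi[4] <- 35
  co2 <- cohortDataset(ph, betaValues(co), cpgAnnotation(co), dosages(co),
                       snpAnnotation(co), exprValues(co), geneAnnotation(co))
  rec <- runEwas(co2, modelSpec(bmiRangeFilter = c(18, 35)))
  expect_true(all(rec$n == sum(ph$bmi >= 18 & ph$bmi <= 35)))
  expect_error(runEwas(co2, modelSpec(bmiRangeFilter = c(100, 110))),
               "retained n = 0")
})

test_that("repeated EWAS runs are identical and cluster SEs are sane", {
  co <- firstCohort(tinyConfig(seed = 71L, n = 150L))
  s <- modelSpec()
  expect_identical(runEwas(co, s), runEwas(co, s))
  cl <- modelSpec(clusterField = "family_id")
  a <- runEwas(co, s); b <- runEwas(co, cl)
  expect_equal(a$beta, b$beta, tolerance = 1e-10)  # point estimates agree
  expect_true(all(b$se > 0))
})

test_that("interaction tests report the product term correctly", {
  set.seed(81)
  n <- 1000
  # effect present only in males (sex = 0)
  ok <- replicate(40, {
    bmi <- rnorm(n, 28, 5); sex <- rbinom(n, 1, 0.5)
    meth <- plogis(0.05 * bmi * (sex == 0) + rnorm(n))
    testInteraction(meth, bmi, sex)$p < 0.05
  })
  expect_gt(mean(ok), 0.9)
  # coding invariance: flipping the modifier flips the sign only
  bmi <- rnorm(n, 28, 5); sex <- rbinom(n, 1, 0.5)
  meth <- plogis(0.03 * bmi * sex + rnorm(n))
  a <- testInteraction(meth, bmi, sex)
  b <- testInteraction(meth, bmi, 1 - sex)
  expect_equal(a$beta, -b$beta, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  expect_error(testInteraction(meth, bmi, rep(1, n)), "constant")
})
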