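test_that("Wald ratios obey their algebraic identities", {
  expect_equal(waldRatio(0.5, 0.1, 0.25, 0.1)$estimate, 0.5)
  z <- waldRatio(1.0, 0, 2.0, 0.2)
  expect_equal(z$estimate, 2.0)
  expect_equal(z$se, 0.2)
  a <- waldRatio(0.4, 0.05, 1.2, 0.3)
  b <- waldRatio(-0.4, 0.05, 1.2, 0.3)
  expect_equal(a$estimate, -b$estimate)
  expect_equal(a$se, b$se)
  expect_error(waldRatio(0, 0.1, 1, 0.1), "zero effect")
})

test_that("noise-free 2SLS recovers the exact coefficient", {
  g <- rep(0:2, each = 20)
  exposure <- g
  outcome <- 2 * exposure
  res <- twoStageLeastSquares(outcome, exposure, g)
  expect_equal(res$tsls_beta, 2, tolerance = 1e-12)
})

test_that("single-IV 2SLS equals the Wald ratio and F equals t^2", {
  set.seed(301)
  for (r in 1:50) {
    n <- 60
    g <- rbinom(n, 2, 0.3)
    cv <- cbind(age = rnorm(n, 60, 8))
    x <- 0.4 * g + 0.02 * cv[, 1] + rnorm(n)
    y <- 1.3 * x + rnorm(n)
    res <- twoStageLeastSquares(y, x, g, cv)
    # reduced-form oracle
    fx <- lm(x ~ g + cv); fy <- lm(y ~ g + cv)
    wr <- coef(fy)["g"] / coef(fx)["g"]
    expect_equal(res$tsls_beta, unname(wr), tolerance = 1e-8)
    t1 <- summary(fx)$coefficients["g", "t value"]
    expect_equal(res$stage1_F, t1^2, tolerance = 1e-8)
  }
})

test_that("causal estimates are invariant to instrument recoding", {
  set.seed(302)
  n <- 500
  g <- rbinom(n, 2, 0.4)
  x <- 0.5 * g + rnorm(n)
  y <- 0.8 * x + rnorm(n)
  a <- twoStageLeastSquares(y, x, g)
  b <- twoStageLeastSquares(y, x, 2 - g)
  expect_equal(a$tsls_beta, b$tsls_beta, tolerance = 1e-10)
  expect_equal(a$stage1_F, b$stage1_F, tolerance = 1e-8)
  expect_error(twoStageLeastSquares(y, x, rep(1, n)), "constant")
})

test_that("the cis scan recovers the planted meQTL and breaks ties", {
  hits <- vapply(1:20, function(r) {
    sim <- simulateMultiCohort(causalOneConfig(seed = 3000L + r, n = 1000L))
    tr <- cpgTruth(sim$truth)
    rec <- scanCisMeqtl(tr$cpg_id[1], sim$cohorts[[1]])
    rec$snp_id == tr$meqtl_snp[1]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # tie-break: a duplicated dosage column resolves to the nearer SNP
  sim <- simulateMultiCohort(causalOneConfig(seed = 333L, n = 400L))
  co <- sim$cohorts[[1]]
  tr <- cpgTruth(sim$truth)
  sa <- snpAnnotation(co); D <- dosages(co)
  iTop <- match(tr$meqtl_snp[1], sa$snp_id)
  jFar <- which(sa$chrom == sa$chrom[iTop])[2]
  D[jFar, ] <- D[iTop, ]                       # exact duplicate, further away
  sa$pos[jFar] <- sa$pos[iTop] + 3e5
  co2 <- cohortDataset(phenotypes(co), betaValues(co), cpgAnnotation(co),
                       D, sa, exprValues(co), geneAnnotation(co))
  rec <- scanCisMeqtl(tr$cpg_id[1], co2)
  near <- if (abs(sa$pos[iTop] - cpgAnnotation(co)$pos[1]) <
                abs(sa$pos[jFar] - cpgAnnotation(co)$pos[1]))
    sa$snp_id[iTop] else sa$snp_id[jFar]
  expect_identical(rec$snp_id, near)
  expect_message(out <- scanCisMeqtl(tr$cpg_id[1], co, windowBp = 0),
                 "no instrument")
  expect_null(out)
})

test_that("GRS construction is scale-invariant with a missing-SNP policy", {
  co <- firstCohort(tinyConfig(seed = 311L, n = 300L))
  sa <- snpAnnotation(co)
  grsSnps <- sa$snp_id[sa$gwas_weight != 0]
  expect_length(grsSnps, 97L)
  one <- buildGrs(co, setNames(1, grsSnps[1]))
  d <- dosages(co)[grsSnps[1], ]
  expect_equal(unname(one), unname((d - mean(d)) / sd(d)), tolerance = 1e-12)
  w <- setNames(sa$gwas_weight[sa$gwas_weight != 0], grsSnps)
  expect_equal(buildGrs(co, w), buildGrs(co, 2 * w), tolerance = 1e-12)
  wMissing <- c(w, setNames(rep(0.1, 10), paste0("absent", 1:10)))
  expect_warning(g2 <- buildGrs(co, wMissing), "renormalised")
  expect_error(buildGrs(co, setNames(rep(1, 30),
                                     paste0("absent", 1:30))), "> 20%")
})

test_that("a 1-SNP GRS and the single-SNP sensitivity path coincide", {
  sim <- simulateMultiCohort(tinyConfig(seed = 321L, n = 400L))
  co <- sim$cohorts[[1]]
  tr <- cpgTruth(sim$truth)
  cpgs <- tr$cpg_id[tr$role == "reactive"][1:2]
  snp <- snpAnnotation(co)$snp_id[which(snpAnnotation(co)$gwas_weight != 0)[1]]
  a <- reverseMr(cpgs, co, buildGrs(co, setNames(1, snp)))
  b <- singleSnpSensitivity(cpgs, co, snp)
  expect_equal(a$tsls_beta, b$tsls_beta, tolerance = 1e-8)
  expect_equal(a$p_causal, b$p_causal, tolerance = 1e-8)
  # monomorphic instrument is refused
  D <- dosages(co); D[snp, ] <- 1
  co2 <- cohortDataset(phenotypes(co), betaValues(co), cpgAnnotation(co),
                       D, snpAnnotation(co), exprValues(co),
                       geneAnnotation(co))
  expect_error(singleSnpSensitivity(cpgs, co2, snp), "monomorphic")
})

test_that("two-step MR guards instrument independence and severed chains", {
  cfgMed <- simConfig(nCohorts = 1L, nSamplesPerCohort = 800L, nCpgs = 1L,
                      nSnps = 8L, nGenes = 1L, nGrsSnps = 0L,
                      fracCausalCpgs = 1, fracReactiveCpgs = 0,
                      methToExprEffect = -0.5, exprToBmiEffect = 1.5,
                      seed = 331L)
  sim <- simulateMultiCohort(cfgMed)
  co <- sim$cohorts[[1]]
  tr <- cpgTruth(sim$truth)
  res <- twoStepMr(tr$meqtl_snp[1], tr$linked_gene[1], tr$eqtl_snp[1], co)
  expect_lt(res$step1$p, 0.05)
  expect_identical(res$step1$direction,
                   if (tr$true_meqtl_effect[1] * tr$true_meth_expr_effect[1]
                       >= 0) "+" else "-")
  expect_error(twoStepMr(tr$meqtl_snp[1], tr$linked_gene[1],
                         tr$meqtl_snp[1], co), "not independent")
  # severed chain: no methylation -> expression coupling
  cfg0 <- simConfig(nCohorts = 1L, nSamplesPerCohort = 800L, nCpgs = 1L,
                    nSnps = 8L, nGenes = 1L, nGrsSnps = 0L,
                    fracCausalCpgs = 1, fracReactiveCpgs = 0,
                    methToExprEffect = 0, seed = 332L)
  sim0 <- simulateMultiCohort(cfg0)
  tr0 <- cpgTruth(sim0$truth)
  res0 <- twoStepMr(tr0$meqtl_snp[1], tr0$linked_gene[1], tr0$eqtl_snp[1],
                    sim0$cohorts[[1]])
  expect_gt(res0$step1$p, 0.001)  # meQTL no longer predicts expression
})

test_that("conditioning on the meQTL attenuates genotype-driven signal only", {
  set.seed(341)
  meds <- replicate(100, {
    n <- 500
    g <- rbinom(n, 2, 0.3)
    bmi <- rnorm(n, 28, 5)                 # orthogonal to g
    # moderate meQTL: conditioning then barely moves the residual scale
    meth <- plogis(0.3 * g + 0.05 * (bmi - 28) + rnorm(n))
    co <- .attenuationCohort(meth, bmi, g)
    conditionalMeqtlAttenuation("cg1", co)$attenuation
  })
  expect_lt(abs(median(meds)), 0.05)
  # association running entirely through the genotype attenuates to ~1
  n <- 2000
  g <- rbinom(n, 2, 0.4)
  bmi <- 28 + 2 * g + rnorm(n, 0, 0.5)
  meth <- plogis(g + rnorm(n, 0, 0.1))
  co <- .attenuationCohort(meth, bmi, g)
  a <- conditionalMeqtlAttenuation("cg1", co)
  expect_gt(a$attenuation, 0.8)
})
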