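test_that("p-to-z conversion matches the normal quantile oracle", {
  expect_equal(signedZFromP(0.05, "+"), qnorm(0.975), tolerance = 1e-10)
  expect_equal(round(signedZFromP(0.05, "+"), 5), 1.95996)
  expect_identical(signedZFromP(1, "-"), 0)
  p <- c(0.3, 0.01, 1e-8)
  expect_equal(signedZFromP(p, "+"), -signedZFromP(p, "-"))
  expect_error(signedZFromP(0, "+"), "\\(0, 1\\]")
  expect_error(signedZFromP(1.5, "+"), "\\(0, 1\\]")
  expect_warning(z <- signedZFromP(1e-310, "+"), "clamped")
  expect_lte(z, 38)
})

test_that("Stouffer combination honours its algebraic identities", {
  one <- stoufferMeta(data.frame(p = 0.01, direction = "+", n = 500))
  expect_equal(one$z, qnorm(1 - 0.01 / 2), tolerance = 1e-10)
  expect_equal(one$p, 0.01, tolerance = 1e-10)
  # equal weights: (2 + 2)/sqrt(2)
  pz2 <- 2 * pnorm(-2)
  eq <- stoufferMeta(data.frame(p = c(pz2, pz2), direction = c("+", "+"),
                                n = c(400, 400)))
  expect_equal(eq$z, 4 / sqrt(2), tolerance = 1e-9)
  # exact cancellation
  ca <- stoufferMeta(data.frame(p = c(pz2, pz2), direction = c("+", "-"),
                                n = c(400, 400)))
  expect_equal(ca$z, 0, tolerance = 1e-12)
  expect_equal(ca$p, 1, tolerance = 1e-12)
  expect_false(ca$direction_consistent)
  # p = 2(1 - Phi(|z|)) invariant
  set.seed(1)
  rec <- data.frame(p = runif(4), direction = sample(c("+", "-"), 4, TRUE),
                    n = c(100, 200, 300, 400))
  m <- stoufferMeta(rec)
  expect_equal(m$p, 2 * (1 - pnorm(abs(m$z))), tolerance = 1e-10)
  # order invariance
  m2 <- stoufferMeta(rec[c(3, 1, 4, 2), ])
  expect_equal(m$z, m2$z, tolerance = 1e-12)
  expect_error(stoufferMeta(data.frame()), "no cohort")
})

test_that("k identical equal-n cohorts scale z by sqrt(k)", {
  z1 <- 1.7
  p1 <- 2 * pnorm(-z1)
  for (k in 1:5) {
    m <- stoufferMeta(data.frame(p = rep(p1, k), direction = rep("+", k),
                                 n = rep(250, k)))
    expect_equal(m$z, z1 * sqrt(k), tolerance = 1e-9)
  }
})

test_that("genomic inflation matches the chi-square median identity", {
  expect_equal(genomicInflation(rep(qnorm(0.75), 1000))$lambda, 1,
               tolerance = 1e-3)
  set.seed(2)
  expect_true(abs(genomicInflation(rnorm(1e5))$lambda - 1) < 0.02)
  expect_true(abs(genomicInflation(rnorm(1e5, 0, sqrt(2)))$lambda - 2)
              < 0.04)
  expect_error(genomicInflation(numeric(0)), "no test")
  expect_warning(genomicInflation(rnorm(50)), "unstable")
})

test_that("Bonferroni thresholds reproduce printed gates", {
  expect_equal(signif(bonferroniThreshold(0.05, 405000), 2), 1.2e-7)
  expect_equal(bonferroniThreshold(0.05, 135), 3.7037e-4, tolerance = 1e-4)
  expect_identical(bonferroniThreshold(0.05, 1), 0.05)
  expect_error(bonferroniThreshold(0.05, 0), "m must be")
  expect_error(bonferroniThreshold(1.2, 10), "alpha")
})

test_that("replication adjudication gates on threshold and direction", {
  disc <- data.frame(cpg_id = c("cg1", "cg2"), z = c(5, -5),
                     p = c(1e-7, 1e-7))
  # cg1 replicates (+, tiny p); cg2 has tiny p but the wrong direction
  repl <- list(
    A = data.frame(cpg_id = c("cg1", "cg2"), p = c(1e-6, 1e-5),
                   direction = c("+", "+"), n = c(800, 800)))
  res <- adjudicateReplication(disc, repl, alpha = 0.05)
  expect_equal(res$threshold, 0.025)
  expect_identical(res$replicated, "cg1")
  expect_false(res$table$replicated[res$table$cpg_id == "cg2"])
  # a CpG absent from one cohort is tested in the remaining cohorts
  repl2 <- c(repl, list(B = data.frame(cpg_id = "cg1", p = 0.5,
                                       direction = "+", n = 100)))
  res2 <- adjudicateReplication(disc, repl2)
  expect_true(is.na(res2$table$pass_B[res2$table$cpg_id == "cg2"]))
  expect_identical(res2$replicated, "cg1")
})

test_that("replication enriches for true effects in simulation", {
  cfg <- simConfig(nCohorts = 2L, nSamplesPerCohort = 1000L, nCpgs = 100L,
                   nSnps = 300L, nGenes = 50L, fracCausalCpgs = 0.25,
                   fracReactiveCpgs = 0.25, seed = 314L)
  sim <- simulateMultiCohort(cfg)
  tr <- cpgTruth(sim$truth)
  disc <- runEwas(sim$cohorts[[1]])
  # take every CpG forward with its discovery direction
  discHits <- data.frame(cpg_id = disc$cpg_id,
                         z = signedZFromP(disc$p, disc$direction),
                         p = disc$p)
  res <- adjudicateReplication(discHits, list(runEwas(sim$cohorts[[2]])))
  isTrue <- tr$role[match(discHits$cpg_id, tr$cpg_id)] != "null"
  rep_ <- discHits$cpg_id %in% res$replicated
  ft <- fisher.test(table(replicated = rep_, true = isTrue))
  expect_lt(ft$p.value, 0.01)
  expect_gt(mean(rep_[isTrue]), mean(rep_[!isTrue]))
})
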