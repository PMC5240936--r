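test_that("greedy pruning follows the significance order", {
  set.seed(101)
  n <- 400
  z <- rnorm(n)
  # pairwise correlations ~ (1,2): 0.9, (1,3)/(2,3): ~0.1
  m <- rbind(cpgA = z,
             cpgB = 0.9 * z + sqrt(1 - 0.81) * rnorm(n),
             cpgC = rnorm(n))
  expect_identical(pruneCorrelated(c("cpgA", "cpgB", "cpgC"), m, 0.7),
                   c("cpgA", "cpgC"))
  # vacuous bound keeps everything
  expect_identical(pruneCorrelated(c("cpgA", "cpgB", "cpgC"), m, 1.0),
                   c("cpgA", "cpgB", "cpgC"))
  # an exact duplicate is dropped
  m2 <- rbind(m, cpgD = m["cpgA", ])
  expect_identical(pruneCorrelated(c("cpgA", "cpgD", "cpgC"), m2, 0.99),
                   c("cpgA", "cpgC"))
  m3 <- rbind(m, flat = rep(0.3, n))
  expect_warning(kept <- pruneCorrelated(c("flat", "cpgA"), m3, 0.7),
                 "zero-variance")
  expect_identical(kept, "cpgA")
})

test_that("pruned panels are pairwise below the bound (exhaustive)", {
  co <- firstCohort(tinyConfig(seed = 103L, n = 250L))
  bv <- betaValues(co)
  kept <- pruneCorrelated(rownames(bv), bv, 0.7)
  cm <- cor(t(bv[kept, ]))
  expect_true(all(abs(cm[upper.tri(cm)]) < 0.7))
})

test_that("incremental R2 starts at baseline and is nondecreasing", {
  set.seed(111)
  n <- 300
  age <- rnorm(n, 65, 8); sex <- rbinom(n, 1, 0.5)
  meth <- matrix(runif(5 * n, 0.2, 0.8), 5, n,
                 dimnames = list(paste0("cg", 1:5), NULL))
  bmi <- 25 + 0.05 * age + 2 * meth[1, ] + rnorm(n, 0, 2)
  cv <- cbind(age = age, sex = sex)
  cur <- incrementalR2(bmi, cv, paste0("cg", 1:5), meth)
  base <- summary(lm(bmi ~ age + sex))$r.squared
  expect_equal(cur$r2[cur$k == 0], base, tolerance = 1e-10)
  expect_true(all(diff(cur$r2) >= -1e-12))
  # a perfectly determined outcome saturates at k = 1
  bmi2 <- 20 + 3 * meth[1, ]
  cur2 <- incrementalR2(bmi2, cv, "cg1", meth)
  expect_equal(cur2$r2[cur2$k == 1], 1, tolerance = 1e-10)
})

test_that("ten ~2%-variance CpGs land near 20% adjusted R2 at n=2000", {
  set.seed(112)
  n <- 2000
  meth <- matrix(rnorm(10 * n), 10, n,
                 dimnames = list(paste0("cg", 1:10), NULL))
  age <- rnorm(n, 65, 8); sex <- rbinom(n, 1, 0.5)
  # each CpG independently explains ~2% of BMI variance (total 20%)
  noise <- rnorm(n, 0, sqrt(0.8))
  bmi <- 28 + colSums(sqrt(0.02) * meth) + noise
  cur <- incrementalR2(bmi, cbind(age = age, sex = sex),
                       paste0("cg", 1:10), meth)
  expect_gt(cur$adj_r2[cur$k == 10], 0.15)
  expect_lt(cur$adj_r2[cur$k == 10], 0.25)
})

test_that("composite scores standardise exactly and behave linearly", {
  m <- matrix(c(0.2, 0.8), 1, 2, dimnames = list("cg1", c("s1", "s2")))
  sc <- compositeScore(m, c(cg1 = 1))
  expect_equal(sc$standardized, c(-sqrt(0.5), sqrt(0.5)), tolerance = 1e-10)
  co <- firstCohort(tinyConfig(seed = 121L, n = 200L))
  bv <- betaValues(co)
  w <- setNames(rnorm(10), rownames(bv)[1:10])
  a <- compositeScore(bv, w)
  expect_lt(abs(mean(a$standardized)), 1e-8)
  expect_lt(abs(sd(a$standardized) - 1), 1e-8)
  # negating weights negates the standardized score
  b <- compositeScore(bv, -w)
  expect_equal(b$standardized, -a$standardized, tolerance = 1e-10)
  # a constant shift of one CpG leaves standardized scores unchanged
  bv2 <- bv; bv2[names(w)[1], ] <- bv2[names(w)[1], ] / 2 + 0.1
  w2 <- w; w2[1] <- w2[1] * 2
  d <- compositeScore(bv2, w2)
  expect_equal(d$standardized, a$standardized, tolerance = 1e-8)
  expect_error(compositeScore(bv, setNames(0, rownames(bv)[1])),
               "all weights")
})

test_that("missing beta values flag the sample and omit the term", {
  m <- matrix(c(0.2, 0.4, 0.6, NA, 0.5, 0.1), 2, 3,
              dimnames = list(c("cg1", "cg2"), c("s1", "s2", "s3")))
  sc <- compositeScore(m, c(cg1 = 1, cg2 = 1))
  expect_identical(attr(sc, "flagged"), "s2")
  expect_equal(sc$raw[2], 0.6)  # NA term omitted
})

test_that("decile summaries partition samples and track a perfect score", {
  set.seed(131)
  bmi <- runif(1000, 20, 40)
  d <- decileSummary(bmi, bmi)
  expect_equal(sum(d$n), 1000)
  expect_true(all(abs(d$n - 100) <= 1))
  expect_true(all(diff(d$median_bmi) > 0))
  expect_equal(d$obesity_prevalence[1], 0)
  expect_equal(d$obesity_prevalence[10], 1)
  # boundary: one sample per decile
  d10 <- decileSummary(1:10, seq(20, 38, 2))
  expect_true(all(d10$n == 1))
  expect_error(decileSummary(1:5, rep(25, 5)), "fewer bins")
  # null score: prevalences near the overall rate
  sc <- rnorm(1000)
  dn <- decileSummary(sc, bmi)
  overall <- mean(bmi >= 30)
  expect_true(all(abs(dn$obesity_prevalence - overall) <
                    4 * sqrt(overall * (1 - overall) / 100)))
})

test_that("per-SD models recover a planted linear slope", {
  set.seed(141)
  n <- 2000
  age <- rnorm(n, 65, 8); sex <- rbinom(n, 1, 0.5)
  bmi <- rnorm(n, 28, 5)
  score <- (bmi - mean(bmi)) / sd(bmi) + rnorm(n, 0, 0.05)
  res <- perSdModels(score, bmi, age, sex)
  expect_equal(res$linear$beta, sd(bmi), tolerance = 0.05)
  expect_gt(res$obesity$or, 1)
  expect_gt(res$overweight$or, 1)
  expect_error(perSdModels(rep(1, n), bmi, age, sex), "zero variance")
})

test_that("null-score odds-ratio CIs cover 1 at the nominal rate", {
  set.seed(142)
  covers <- replicate(200, {
    n <- 400
    bmi <- rnorm(n, 28, 5)
    res <- perSdModels(rnorm(n), bmi, rnorm(n, 65, 8), rbinom(n, 1, 0.5))
    res$obesity$ci95[1] <= 1 && res$obesity$ci95[2] >= 1
  })
  expect_gte(mean(covers), 0.90)
  expect_lte(mean(covers), 0.99)
})
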