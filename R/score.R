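#' Greedy correlation pruning of a ranked CpG list
#'
#' Scans CpGs in the supplied order (most significant first) and retains
#' a CpG only when its absolute Pearson correlation with every
#' already-retained CpG is below `rThreshold` — keeping the more
#' significant member of each correlated group. Zero-variance CpGs are
#' excluded with a warning.
#'
#' @param cpgIds character vector ordered by increasing p-value
#' @param meth CpG x sample beta matrix or a [CohortDataset-class]
#' @param rThreshold absolute correlation bound (default 0.7)
#' @return retained CpG IDs in scan order
#' @export
pruneCorrelated <- function(cpgIds, meth, rThreshold = 0.7) {
  if (is(meth, "CohortDataset")) meth <- betaValues(meth)
  if (ncol(meth) < 3L) stop("need >= 3 samples to estimate correlations")
  M <- t(meth[cpgIds, , drop = FALSE])   # samples x CpGs, scan order
  sds <- apply(M, 2, sd)
  if (any(sds == 0)) {
    warning("zero-variance CpGs excluded: ",
            paste(cpgIds[sds == 0], collapse = ", "))
    cpgIds <- cpgIds[sds > 0]
    M <- M[, sds > 0, drop = FALSE]
  }
  kept <- integer(0)
  for (j in seq_along(cpgIds)) {
    if (!length(kept) ||
        all(abs(cor(M[, j], M[, kept, drop = FALSE])) < rThreshold))
      kept <- c(kept, j)
  }
  cpgIds[kept]
}

#' Incremental variance in BMI explained by ranked CpGs
#'
#' Fits `BMI ~ age + sex` and then adds the first `k` CpGs of a pruned,
#' significance-ordered panel for `k = 0 .. length(panel)`, reporting R^2
#' (nondecreasing by construction) and adjusted R^2 at each step.
#'
#' @param bmi numeric outcome vector
#' @param covariates data.frame/matrix with the baseline covariates
#'   (age, sex)
#' @param cpgIds ordered CpG panel
#' @param meth CpG x sample beta matrix or [CohortDataset-class]
#' @return data.frame with `k`, `r2`, `adj_r2`
#' @export
incrementalR2 <- function(bmi, covariates, cpgIds, meth) {
  if (is(meth, "CohortDataset")) meth <- betaValues(meth)
  cv <- as.matrix(covariates)
  n <- length(bmi)
  if (length(cpgIds) > n - ncol(cv) - 2L)
    stop("too many CpGs for the available degrees of freedom")
  tss <- sum((bmi - mean(bmi))^2)
  out <- data.frame(k = 0:length(cpgIds), r2 = NA_real_, adj_r2 = NA_real_)
  for (k in 0:length(cpgIds)) {
    X <- cbind(1, cv,
               if (k > 0) t(meth[cpgIds[seq_len(k)], , drop = FALSE]))
    qx <- qr(X)
    rss <- sum(qr.resid(qx, bmi)^2)
    r2 <- 1 - rss / tss
    p <- qx$rank - 1L
    out$r2[out$k == k] <- r2
    out$adj_r2[out$k == k] <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  }
  out
}

#' Additive weighted composite methylation score
#'
#' For each sample, sums beta-value x weight over the scored CpGs (the
#' weights carry the direction of effect) and standardises the raw sums
#' to mean 0, SD 1 (sample SD, n - 1). A missing beta value drops that
#' term for that sample and flags the sample.
#'
#' @param meth CpG x sample beta matrix or a [CohortDataset-class]
#' @param weights named numeric vector of per-CpG effect-size weights
#' @return data.frame (`sample_id`, `raw`, `standardized`) with
#'   attributes `weights` and `flagged` (sample IDs with omitted terms)
#' @export
compositeScore <- function(meth, weights) {
  if (is(meth, "CohortDataset")) meth <- betaValues(meth)
  if (all(weights == 0)) stop("all weights are zero")
  miss <- setdiff(names(weights), rownames(meth))
  if (length(miss))
    stop("weights name CpGs absent from the matrix: ",
         paste(miss, collapse = ", "))
  B <- meth[names(weights), , drop = FALSE]
  W <- B * weights
  flagged <- colnames(B)[colSums(is.na(W)) > 0]
  raw <- colSums(W, na.rm = TRUE)
  s <- sd(raw)
  if (s == 0) stop("composite score has zero variance")
  res <- data.frame(sample_id = colnames(B), raw = raw,
                    standardized = (raw - mean(raw)) / s,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "weights") <- weights
  attr(res, "flagged") <- flagged
  res
}

#' Decile summary of BMI against a composite score
#'
#' Bins samples into `nDeciles` near-equal groups by score rank (ties
#' broken by stable sample order) and reports per-bin counts, median BMI
#' and obesity prevalence (fraction with BMI >= the obesity cutoff).
#'
#' @param score numeric vector, or the data.frame from [compositeScore()]
#' @param bmi numeric vector aligned to the score
#' @param config a [ScoreConfig-class]
#' @return data.frame: `decile`, `n`, `median_bmi`, `obesity_prevalence`
#' @export
decileSummary <- function(score, bmi, config = scoreConfig()) {
  if (is.data.frame(score)) score <- score$standardized
  n <- length(score)
  d <- config@nDeciles
  if (n < d) stop("n (", n, ") < number of deciles (", d,
                  "); use fewer bins")
  ord <- order(score)                      # stable for ties
  sizes <- diff(floor(seq(0, n, length.out = d + 1)))
  bin <- integer(n)
  bin[ord] <- rep(seq_len(d), times = sizes)
  out <- data.frame(decile = seq_len(d), n = as.integer(sizes),
                    median_bmi = NA_real_, obesity_prevalence = NA_real_)
  for (k in seq_len(d)) {
    b <- bmi[bin == k]
    out$median_bmi[k] <- median(b)
    out$obesity_prevalence[k] <- mean(b >= config@obesityCutoff)
  }
  out
}

.waldCi <- function(est, se, level = 0.95) {
  q <- qnorm(1 - (1 - level) / 2)
  c(est - q * se, est + q * se)
}

#' Linear and logistic per-SD models of BMI on the composite score
#'
#' Age- and sex-adjusted models per SD of the composite methylation
#' measure: a linear model of BMI, and logistic models of obesity
#' (BMI >= 30) and overweight (BMI 25-29.9) each against the reference
#' category (BMI < 25), reporting odds ratios with Wald 95% CIs. Perfect
#' separation is flagged and the CI reported as unbounded.
#'
#' @param score numeric vector or [compositeScore()] data.frame
#' @param bmi,age,sex aligned phenotype vectors
#' @param config a [ScoreConfig-class]
#' @return list: `linear` (beta, se, p), `obesity` and `overweight`
#'   (or, ci95, p, separation flag)
#' @export
perSdModels <- function(score, bmi, age, sex, config = scoreConfig()) {
  if (is.data.frame(score)) score <- score$standardized
  if (sd(score) == 0) stop("score has zero variance")
  scoreSd <- (score - mean(score)) / sd(score)
  lf <- lm(bmi ~ scoreSd + age + sex)
  ls <- summary(lf)$coefficients["scoreSd", ]
  linear <- list(beta = unname(ls[1]), se = unname(ls[2]),
                 p = unname(ls[4]))
  logisticLeg <- function(inCategory, inReference) {
    use <- inCategory | inReference
    y <- as.integer(inCategory[use])
    if (!any(y) || all(y))
      stop("a BMI category is empty; logistic contrast undefined")
    fit <- suppressWarnings(glm(y ~ scoreSd[use] + age[use] + sex[use],
                                family = binomial()))
    co <- summary(fit)$coefficients[2, ]
    sep <- !fit$converged || abs(co[1]) > 15
    ci <- if (sep) c(0, Inf) else exp(.waldCi(co[1], co[2]))
    list(or = unname(exp(co[1])), ci95 = unname(ci), p = unname(co[4]),
         separation = sep)
  }
  ref <- bmi < config@referenceUpper
  list(linear = linear,
       obesity = logisticLeg(bmi >= config@obesityCutoff, ref),
       overweight = logisticLeg(bmi >= config@overweightRange[1] &
                                  bmi <= config@overweightRange[2], ref))
}
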