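# Dense OLS machinery shared by the EWAS, expression and MR modules.
# X must contain the intercept column explicitly.
.checkFullRank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("perfect collinearity among model columns: ",
         paste(bad, collapse = ", "))
  }
  qx
}

# Fit one design against a matrix of outcomes; returns per-outcome
# statistics for the coefficient in column `coefIdx` of X.
.olsMany <- function(X, Y, coefIdx) {
  qx <- .checkFullRank(X)
  n <- nrow(X); p <- ncol(X); df <- n - p
  B <- qr.coef(qx, Y)
  E <- qr.resid(qx, Y)
  sigma2 <- colSums(E^2) / df
  XtXi <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * XtXi[coefIdx, coefIdx])
  beta <- B[coefIdx, ]
  t <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  pv <- ifelse(is.finite(t), 2 * pt(-abs(t), df), .Machine$double.xmin)
  pv <- pmax(pv, .Machine$double.xmin)
  data.frame(beta = beta, se = se, t = t, p = pv, n = n,
             direction = ifelse(beta >= 0, "+", "-"),
             stringsAsFactors = FALSE)
}

# CR1 cluster-robust (sandwich) covariance; df = clusters - 1.
.olsCluster <- function(X, y, cluster, coefIdx) {
  qx <- .checkFullRank(X)
  n <- nrow(X); p <- ncol(X)
  b <- qr.coef(qx, y)
  e <- qr.resid(qx, y)
  XtXi <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  gs <- split(seq_len(n), cluster)
  G <- length(gs)
  meat <- matrix(0, p, p)
  for (ix in gs) {
    xe <- colSums(X[ix, , drop = FALSE] * e[ix])
    meat <- meat + tcrossprod(xe)
  }
  adj <- G / (G - 1) * (n - 1) / (n - p)
  V <- adj * XtXi %*% meat %*% XtXi
  se <- sqrt(V[coefIdx, coefIdx])
  t <- if (se > 0) b[coefIdx] / se else sign(b[coefIdx]) * Inf
  pv <- if (is.finite(t)) 2 * pt(-abs(t), G - 1) else .Machine$double.xmin
  data.frame(beta = b[coefIdx], se = se, t = t,
             p = max(pv, .Machine$double.xmin), n = n,
             direction = if (b[coefIdx] >= 0) "+" else "-",
             stringsAsFactors = FALSE)
}

.covarMatrix <- function(ph, covariates) {
  if (!length(covariates)) return(NULL)
  as.matrix(ph[, covariates, drop = FALSE])
}

#' Estimate surrogate variables from a methylation matrix
#'
#' Returns the top-`k` principal axes (sample scores) of the
#' covariate-residualised, feature-standardised methylation matrix — a
#' principal-component surrogate for differential cell proportions and
#' technical effects. Scores are mutually orthogonal and orthogonal to
#' the covariate column space by construction.
#'
#' @param meth CpG x sample matrix (beta or M values) or a
#'   [CohortDataset-class] (M-values of its beta assay are used)
#' @param covariates sample-level covariate matrix/data.frame or `NULL`
#' @param k number of surrogate variables requested
#' @return samples x k matrix (0 columns when `k = 0`); fewer columns
#'   with a warning when the residual matrix is rank-deficient
#' @export
estimateSurrogateVariables <- function(meth, covariates = NULL, k) {
  if (is(meth, "CohortDataset")) meth <- betaToM(betaValues(meth))
  Y <- t(meth)
  n <- nrow(Y)
  if (k <= 0) return(matrix(0, n, 0))
  X <- cbind(intercept = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  if (k >= n - ncol(X))
    stop("k must be < n_samples - covariate count")
  R <- qr.resid(qr(X), Y)
  sds <- apply(R, 2, sd)
  keep <- sds > 1e-12
  if (!any(keep)) {
    warning("residual methylation matrix is degenerate; 0 factors returned")
    return(matrix(0, n, 0))
  }
  Rs <- scale(R[, keep, drop = FALSE])
  sv <- svd(Rs, nu = min(k, n), nv = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-8)
  kEff <- min(k, rank)
  if (kEff < k)
    warning(sprintf("only %d surrogate variables recoverable (asked %d)",
                    kEff, k))
  sv$u[, seq_len(kEff), drop = FALSE]
}

.prepareOutcome <- function(methVec, style) {
  switch(style,
         methOutcome = inverseNormalTransform(methVec),
         residualOutcome = betaToM(methVec))
}

#' Association of one CpG with BMI
#'
#' Ordinary-least-squares fit in the orientation of `spec`: the
#' (transformed) methylation value is the dependent variable and BMI the
#' independent variable of interest, adjusted for covariates. With
#' `cluster` supplied, standard errors are CR1 cluster-robust over that
#' grouping (the stand-in for a family random effect) and the t reference
#' has `clusters - 1` degrees of freedom. Samples with any missing model
#' variable are dropped (complete-case).
#'
#' @param meth numeric vector of beta values for one CpG
#' @param bmi numeric vector, kg/m^2
#' @param covariates matrix/data.frame of adjustment covariates or `NULL`
#' @param spec a [ModelSpec-class]; only `style` is consulted here
#' @param cluster optional grouping vector for cluster-robust SEs
#' @param cpgId label recorded in the output
#' @return one-row data.frame: `cpg_id`, `beta`, `se`, `t`, `p`, `n`,
#'   `direction`
#' @export
fitCpgAssociation <- function(meth, bmi, covariates = NULL,
                              spec = modelSpec(), cluster = NULL,
                              cpgId = "cpg") {
  cv <- if (!is.null(covariates)) as.matrix(covariates)
  cc <- complete.cases(meth, bmi, if (!is.null(cv)) cv)
  meth <- meth[cc]; bmi <- bmi[cc]
  if (!is.null(cv)) cv <- cv[cc, , drop = FALSE]
  y <- .prepareOutcome(meth, spec@style)
  X <- cbind(intercept = rep(1, length(y)), bmi = bmi, cv)
  if (length(y) <= ncol(X) + 1L)
    stop("too few samples (n = ", length(y), ") for ", ncol(X),
         " model terms")
  rec <- if (is.null(cluster)) .olsMany(X, cbind(y), coefIdx = 2L)
         else .olsCluster(X, y, cluster[cc], coefIdx = 2L)
  cbind(cpg_id = cpgId, rec, stringsAsFactors = FALSE)
}

#' Run a per-cohort EWAS of BMI
#'
#' Fits every CpG of a cohort against BMI under a [ModelSpec-class]:
#' optional inclusive BMI-range restriction, covariate adjustment,
#' surrogate-variable estimation on the restricted samples, and either
#' the inverse-normal-transformed-outcome or batch-residual orientation.
#' CpGs without missing values are fit in one vectorised pass.
#'
#' @param cohort a [CohortDataset-class]
#' @param spec a [ModelSpec-class]
#' @return data.frame with one row per CpG: `cpg_id`, `beta`, `se`, `t`,
#'   `p`, `n`, `direction`
#' @examples
#' sim <- simulateMultiCohort(simConfig(nCohorts = 1L,
#'   nSamplesPerCohort = 150L, nCpgs = 30L, nSnps = 130L, nGenes = 12L,
#'   seed = 11L))
#' head(runEwas(sim$cohorts[[1]], modelSpec()))
#' @export
runEwas <- function(cohort, spec = modelSpec()) {
  ph <- phenotypes(cohort)
  if (is.null(ph$bmi) || !is.numeric(ph$bmi))
    stop("phenotype table lacks a numeric bmi column")
  keep <- rep(TRUE, nrow(ph))
  if (length(spec@bmiRangeFilter))
    keep <- ph$bmi >= spec@bmiRangeFilter[1] &
      ph$bmi <= spec@bmiRangeFilter[2]
  if (!any(keep))
    stop("no samples retained after BMI range filter (retained n = 0)")
  ph <- ph[keep, , drop = FALSE]
  beta <- betaValues(cohort)[, keep, drop = FALSE]
  cv <- .covarMatrix(ph, spec@covariates)

  if (spec@style == "methOutcome") {
    Y <- apply(beta, 1L, inverseNormalTransform)   # samples x CpGs
  } else {
    M <- t(betaToM(beta))
    bt <- ph$batch %||% rep(1L, nrow(ph))
    Xb <- if (length(unique(bt)) > 1L) stats::model.matrix(~ factor(bt))
          else matrix(1, nrow(ph), 1L)
    Y <- qr.resid(qr(Xb), M)
  }
  colnames(Y) <- rownames(beta)

  sv <- if (spec@nSurrogateVariables > 0)
    estimateSurrogateVariables(betaToM(beta), cv,
                               spec@nSurrogateVariables) else NULL
  if (!is.null(sv) && ncol(sv) > 0) colnames(sv) <- paste0("sv", seq_len(ncol(sv)))
  X <- cbind(intercept = rep(1, nrow(ph)), bmi = ph$bmi, cv, sv)

  cl <- if (length(spec@clusterField)) ph[[spec@clusterField]]
  hasNA <- apply(Y, 2L, anyNA) | anyNA(X)
  out <- vector("list", ncol(Y))
  if (any(!hasNA) && is.null(cl)) {
    recs <- .olsMany(X, Y[, !hasNA, drop = FALSE], coefIdx = 2L)
    out[!hasNA] <- split(cbind(cpg_id = colnames(Y)[!hasNA], recs,
                               stringsAsFactors = FALSE),
                         seq_len(sum(!hasNA)))
  }
  slow <- if (is.null(cl)) which(hasNA) else seq_len(ncol(Y))
  for (j in slow) {
    cc <- complete.cases(Y[, j], X)
    rec <- if (is.null(cl)) .olsMany(X[cc, , drop = FALSE],
                                     cbind(Y[cc, j]), 2L)
           else .olsCluster(X[cc, , drop = FALSE], Y[cc, j], cl[cc], 2L)
    out[[j]] <- cbind(cpg_id = colnames(Y)[j], rec,
                      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Test a BMI-by-modifier interaction for one CpG
#'
#' Adds a `bmi x modifier` product term to the main-effects model (with
#' inverse-normal-transformed methylation as the outcome) and reports the
#' product-term statistics.
#'
#' @param meth beta-value vector for one CpG
#' @param bmi numeric vector
#' @param modifier numeric/binary vector (sex coding or age); must vary
#' @param covariates optional covariate matrix/data.frame
#' @return list with `beta`, `se`, `t`, `p` for the interaction term
#' @export
testInteraction <- function(meth, bmi, modifier, covariates = NULL) {
  if (length(unique(modifier[!is.na(modifier)])) < 2L)
    stop("modifier is constant; interaction not identified")
  cv <- if (!is.null(covariates)) as.matrix(covariates)
  cc <- complete.cases(meth, bmi, modifier, if (!is.null(cv)) cv)
  y <- inverseNormalTransform(meth[cc])
  X <- cbind(intercept = 1, bmi = bmi[cc], modifier = modifier[cc],
             if (!is.null(cv)) cv[cc, , drop = FALSE],
             bmi_x_mod = bmi[cc] * modifier[cc])
  rec <- .olsMany(X, cbind(y), coefIdx = ncol(X))
  list(beta = rec$beta, se = rec$se, t = rec$t, p = rec$p)
}
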