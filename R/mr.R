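# Instrument strength below which an MR result is flagged (never
# dropped): the conventional weak-instrument rule of thumb.
.WEAK_F <- 10

#' Scan the cis window for the top meQTL of one CpG
#'
#' Regresses logit-scale methylation on each SNP dosage within
#' `windowBp` of the CpG (inclusive bounds, same chromosome), adjusted
#' for covariates, and returns the lowest-p SNP. Ties break towards the
#' smaller distance, then the lexicographically smaller SNP ID.
#'
#' @param cpgId CpG identifier
#' @param cohort a [CohortDataset-class]
#' @param windowBp half-width of the cis window (default 500 kb)
#' @param covariates matrix/data.frame or `NULL` (age and sex from the
#'   phenotype table when `NULL`)
#' @return one-row data.frame (`snp_id`, `target_id`, `beta`, `se`, `p`,
#'   `cis`, `distance_bp`), or `NULL` with a message when no SNP lies in
#'   the window
#' @export
scanCisMeqtl <- function(cpgId, cohort, windowBp = 5e5, covariates = NULL) {
  ca <- cpgAnnotation(cohort)
  i <- match(cpgId, ca$cpg_id)
  if (is.na(i)) stop("unknown CpG: ", cpgId)
  sa <- snpAnnotation(cohort)
  dist <- abs(sa$pos - ca$pos[i])
  inWin <- sa$chrom == ca$chrom[i] & dist <= windowBp
  if (!any(inWin)) {
    message("no SNP within ", windowBp, " bp of ", cpgId,
            "; no instrument available")
    return(NULL)
  }
  ph <- phenotypes(cohort)
  cv <- if (is.null(covariates)) cbind(age = ph$age, sex = ph$sex)
        else as.matrix(covariates)
  y <- betaToM(betaValues(cohort)[cpgId, ])
  D <- dosages(cohort)[inWin, , drop = FALSE]
  ids <- sa$snp_id[inWin]; dd <- dist[inWin]
  recs <- lapply(seq_len(nrow(D)), function(k) {
    if (sd(D[k, ]) == 0)
      return(data.frame(beta = 0, se = Inf, p = 1))
    X <- cbind(intercept = 1, dosage = D[k, ], cv)
    .olsMany(X, cbind(y), coefIdx = 2L)[, c("beta", "se", "p")]
  })
  recs <- do.call(rbind, recs)
  best <- order(recs$p, dd, ids)[1]
  data.frame(snp_id = ids[best], target_id = cpgId,
             beta = recs$beta[best], se = recs$se[best], p = recs$p[best],
             cis = TRUE, distance_bp = dd[best], stringsAsFactors = FALSE)
}

#' Wald ratio causal estimate from two reduced-form fits
#'
#' `estimate = beta_gy / beta_gx`; the first-order delta-method SE is
#' `|estimate| * sqrt(se_gy^2/beta_gy^2 + se_gx^2/beta_gx^2)`, and the
#' NO-Measurement-Error (NOME) variant `se_gy / |beta_gx|` drops the
#' stage-1 uncertainty. Both are reported.
#'
#' @param betaGx,seGx instrument-exposure coefficient and SE
#' @param betaGy,seGy instrument-outcome coefficient and SE
#' @return list: `estimate`, `se` (full delta), `seNome`
#' @export
waldRatio <- function(betaGx, seGx, betaGy, seGy) {
  if (betaGx == 0) stop("instrument has zero effect on the exposure")
  est <- betaGy / betaGx
  seNome <- seGy / abs(betaGx)
  se <- if (betaGy == 0) seNome
        else abs(est) * sqrt(seGy^2 / betaGy^2 + seGx^2 / betaGx^2)
  list(estimate = est, se = se, seNome = seNome)
}

#' Two-stage least squares instrumental-variable estimate
#'
#' Stage 1 regresses the exposure on the instrument(s) plus covariates;
#' stage 2 regresses the outcome on the fitted exposure plus covariates.
#' The variance uses the standard 2SLS correction: stage-2 residuals are
#' recomputed with the observed exposure. The joint F of the instrument
#' terms in stage 1 is reported; F < 10 flags the result as
#' weak-instrument (never suppressed). For a single instrument the 2SLS
#' coefficient equals the Wald ratio of the two reduced forms.
#'
#' @param outcome,exposure aligned numeric vectors
#' @param iv instrument vector or matrix (one column per instrument)
#' @param covariates matrix/data.frame or `NULL`
#' @param exposureId,outcomeId,ivDescription labels for the result row
#' @return one-row data.frame: `exposure_id`, `outcome_id`, `iv`,
#'   `stage1_F`, `tsls_beta`, `tsls_se`, `ci_low`, `ci_high`,
#'   `p_causal`, `weak_instrument`, `n`
#' @export
twoStageLeastSquares <- function(outcome, exposure, iv, covariates = NULL,
                                 exposureId = "exposure",
                                 outcomeId = "outcome",
                                 ivDescription = "iv") {
  Z <- as.matrix(iv)
  cv <- if (!is.null(covariates)) as.matrix(covariates)
  cc <- complete.cases(outcome, exposure, Z, if (!is.null(cv)) cv)
  y <- outcome[cc]; x <- exposure[cc]
  Z <- Z[cc, , drop = FALSE]
  if (!is.null(cv)) cv <- cv[cc, , drop = FALSE]
  n <- length(y); kIv <- ncol(Z)
  if (any(apply(Z, 2, sd) == 0))
    stop("instrument is constant; undefined-instrument")
  colnames(Z) <- paste0("iv", seq_len(kIv))
  X1 <- cbind(intercept = rep(1, n), Z, cv)
  q1 <- .checkFullRank(X1)
  rss1 <- sum(qr.resid(q1, x)^2)
  X0 <- cbind(intercept = rep(1, n), cv)
  rss0 <- sum(qr.resid(qr(X0), x)^2)
  df1 <- n - ncol(X1)
  stage1F <- ((rss0 - rss1) / kIv) / (rss1 / df1)
  xhat <- x - qr.resid(q1, x)

  Xh <- cbind(intercept = rep(1, n), exposure = xhat, cv)
  qh <- .checkFullRank(Xh)
  b <- qr.coef(qh, y)
  Xa <- cbind(intercept = rep(1, n), exposure = x, cv)
  e <- y - drop(Xa %*% b)
  p <- ncol(Xh); df <- n - p
  sigma2 <- sum(e^2) / df
  XtXi <- chol2inv(qr.R(qh))[order(qh$pivot), order(qh$pivot), drop = FALSE]
  se <- sqrt(sigma2 * XtXi[2, 2])
  tstat <- b[2] / se
  ci <- b[2] + c(-1, 1) * qt(0.975, df) * se
  data.frame(exposure_id = exposureId, outcome_id = outcomeId,
             iv = ivDescription, stage1_F = stage1F,
             tsls_beta = unname(b[2]), tsls_se = se,
             ci_low = ci[1], ci_high = ci[2],
             p_causal = 2 * pt(-abs(tstat), df),
             weak_instrument = stage1F < .WEAK_F, n = n,
             stringsAsFactors = FALSE)
}

.mrCovariates <- function(cohort) {
  ph <- phenotypes(cohort)
  cbind(age = ph$age, sex = ph$sex)
}

#' Forward Mendelian randomization: methylation -> BMI
#'
#' For each CpG, instruments its standardized logit-scale methylation
#' (SD units) with the top cis-meQTL (scanned with [scanCisMeqtl()]
#' unless records are supplied) and estimates the causal effect on BMI
#' by 2SLS, adjusted for age and sex. Reports Bonferroni (over tested
#' CpGs) and nominal p < 0.05 flags; CpGs without any instrument are
#' skipped and recorded.
#'
#' @param cpgIds CpGs to test (e.g. the replicated set)
#' @param cohort a [CohortDataset-class]
#' @param meqtlRecords optional data.frame of pre-computed instruments
#'   (`target_id`, `snp_id`); scanned per CpG when `NULL`
#' @param windowBp cis-window half-width for the scan
#' @param alpha nominal significance level
#' @return data.frame of MR results (one row per instrumented CpG) with
#'   `wald_ratio`, `nominal_significant`, `bonferroni_significant`; the
#'   `skipped` attribute lists uninstrumented CpGs
#' @export
forwardMr <- function(cpgIds, cohort, meqtlRecords = NULL,
                      windowBp = 5e5, alpha = 0.05) {
  ph <- phenotypes(cohort)
  cv <- .mrCovariates(cohort)
  B <- betaValues(cohort); D <- dosages(cohort)
  rows <- list(); skipped <- character(0)
  for (cg in cpgIds) {
    snp <- if (!is.null(meqtlRecords)) {
      j <- match(cg, meqtlRecords$target_id)
      if (is.na(j)) NA_character_ else meqtlRecords$snp_id[j]
    } else {
      rec <- scanCisMeqtl(cg, cohort, windowBp = windowBp)
      if (is.null(rec)) NA_character_ else rec$snp_id
    }
    if (is.na(snp)) { skipped <- c(skipped, cg); next }
    expo <- .scale1(betaToM(B[cg, ]))
    res <- twoStageLeastSquares(ph$bmi, expo, D[snp, ], cv,
                                exposureId = cg, outcomeId = "bmi",
                                ivDescription = snp)
    res$wald_ratio <- res$tsls_beta   # single-IV identity
    rows[[cg]] <- res
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    thr <- bonferroniThreshold(alpha, nrow(out))
    out$nominal_significant <- out$p_causal < alpha
    out$bonferroni_significant <- out$p_causal < thr
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}

#' Build a weighted genetic risk score instrument
#'
#' `score_i = sum_s weight_s * dosage_si`, standardized to sample SD 1.
#' More than 20% missing weight SNPs is an error; up to 20% triggers
#' renormalisation by the available absolute-weight sum with a warning.
#'
#' @param cohort a [CohortDataset-class] (or SNP x sample dosage matrix)
#' @param weights data.frame (`snp_id`, `weight`) or named numeric
#'   vector; defaults to the nonzero `gwas_weight` rows of the cohort's
#'   SNP annotation
#' @return named numeric vector of standardized per-sample scores
#' @export
buildGrs <- function(cohort, weights = NULL) {
  D <- if (is(cohort, "CohortDataset")) dosages(cohort) else cohort
  if (is.null(weights)) {
    sa <- snpAnnotation(cohort)
    weights <- setNames(sa$gwas_weight[sa$gwas_weight != 0],
                        sa$snp_id[sa$gwas_weight != 0])
    if (!length(weights)) stop("cohort annotation carries no GRS weights")
  }
  if (is.data.frame(weights))
    weights <- setNames(weights$weight, weights$snp_id)
  present <- names(weights) %in% rownames(D)
  if (mean(!present) > 0.2)
    stop(sprintf("%.0f%% of GRS SNPs missing from the genotypes (> 20%%)",
                 100 * mean(!present)))
  if (any(!present)) {
    warning(sum(!present), " GRS SNPs missing; score renormalised by the ",
            "available absolute-weight sum")
    w <- weights[present]
    weights <- w * sum(abs(weights)) / sum(abs(w))
  }
  raw <- drop(crossprod(D[names(weights), , drop = FALSE], weights))
  s <- sd(raw)
  if (s == 0) stop("GRS has zero variance")
  setNames((raw - mean(raw)) / s, colnames(D))
}

#' Reverse Mendelian randomization: BMI -> methylation
#'
#' 2SLS with BMI as the exposure, instrumented by a genetic risk score
#' (or any single-column instrument), and each CpG's standardized
#' logit-scale methylation as the outcome, adjusted for age and sex.
#'
#' @param cpgIds CpGs treated as outcomes
#' @param cohort a [CohortDataset-class]
#' @param grs per-sample instrument vector (e.g. from [buildGrs()])
#' @param alpha nominal significance level
#' @param ivDescription label for the instrument column
#' @return data.frame of MR results with `nominal_significant`
#' @export
reverseMr <- function(cpgIds, cohort, grs, alpha = 0.05,
                      ivDescription = "grs") {
  ph <- phenotypes(cohort)
  cv <- .mrCovariates(cohort)
  B <- betaValues(cohort)
  rows <- lapply(cpgIds, function(cg) {
    y <- .scale1(betaToM(B[cg, ]))
    twoStageLeastSquares(y, ph$bmi, grs, cv, exposureId = "bmi",
                         outcomeId = cg, ivDescription = ivDescription)
  })
  out <- do.call(rbind, rows)
  out$nominal_significant <- out$p_causal < alpha
  rownames(out) <- NULL
  out
}

#' Single-SNP sensitivity reverse MR
#'
#' [reverseMr()] with one SNP's dosage as the BMI instrument (the
#' FTO-style sensitivity analysis): less prone to pleiotropy, less
#' powerful, so weak-instrument flags are expected more often.
#'
#' @param cpgIds CpGs treated as outcomes
#' @param cohort a [CohortDataset-class]
#' @param snpId the instrument SNP
#' @param alpha nominal significance level
#' @return data.frame of MR results
#' @export
singleSnpSensitivity <- function(cpgIds, cohort, snpId, alpha = 0.05) {
  d <- dosages(cohort)[snpId, ]
  if (sd(d) == 0) stop("instrument SNP ", snpId,
                       " is monomorphic; undefined-instrument")
  reverseMr(cpgIds, cohort, d, alpha = alpha, ivDescription = snpId)
}

#' Two-step Mendelian randomization through gene expression
#'
#' Step 1 tests whether the meQTL instrument for the exposure CpG is
#' associated with the mediator gene's expression (direction and p).
#' Step 2 estimates the mediator's causal effect on BMI by 2SLS using an
#' eQTL instrument required to be approximately independent of the meQTL
#' (dosage r^2 below `ldIndependenceR2`).
#'
#' @param meqtlSnp,eqtlSnp instrument SNP IDs
#' @param geneId the mediator gene
#' @param cohort a [CohortDataset-class]
#' @param ldIndependenceR2 maximum allowed dosage r^2 between the two
#'   instruments
#' @return list: `step1` (snp, gene, beta, se, p, direction),
#'   `step2` (2SLS result row), `iv_r2`
#' @export
twoStepMr <- function(meqtlSnp, geneId, eqtlSnp, cohort,
                      ldIndependenceR2 = 0.2) {
  D <- dosages(cohort)
  r2 <- cor(D[meqtlSnp, ], D[eqtlSnp, ])^2
  if (is.na(r2)) r2 <- 0
  if (r2 >= ldIndependenceR2)
    stop(sprintf("instruments %s and %s are not independent (r^2 = %.3f)",
                 meqtlSnp, eqtlSnp, r2))
  ph <- phenotypes(cohort)
  cv <- .mrCovariates(cohort)
  E <- exprValues(cohort)
  if (!geneId %in% rownames(E)) stop("no expression for gene ", geneId)
  X <- cbind(intercept = 1, dosage = D[meqtlSnp, ], cv)
  s1 <- .olsMany(X, cbind(E[geneId, ]), coefIdx = 2L)
  expo <- .scale1(E[geneId, ])
  s2 <- twoStageLeastSquares(ph$bmi, expo, D[eqtlSnp, ], cv,
                             exposureId = geneId, outcomeId = "bmi",
                             ivDescription = eqtlSnp)
  list(step1 = data.frame(snp_id = meqtlSnp, gene_id = geneId,
                          beta = s1$beta, se = s1$se, p = s1$p,
                          direction = s1$direction,
                          stringsAsFactors = FALSE),
       step2 = s2, iv_r2 = r2)
}

#' Attenuation of the EWAS statistic conditional on the top cis-meQTL
#'
#' Refits the CpG-BMI association with the top meQTL dosage added as a
#' covariate and reports `(|t_before| - |t_after|) / |t_before|`
#' (negative values — strengthening — are reported as-is). Minimal
#' attenuation indicates the association is not driven by local genetic
#' variation.
#'
#' @param cpgId the CpG
#' @param cohort a [CohortDataset-class]
#' @param qtl one-row data.frame from [scanCisMeqtl()] (scanned when
#'   `NULL`)
#' @param spec a [ModelSpec-class] for the base model orientation
#' @return list: `t_before`, `t_after`, `attenuation`, `snp_id`
#'   (`attenuation` is `NA` with a flag when the genotype is constant)
#' @export
conditionalMeqtlAttenuation <- function(cpgId, cohort, qtl = NULL,
                                        spec = modelSpec()) {
  if (is.null(qtl)) qtl <- scanCisMeqtl(cpgId, cohort)
  if (is.null(qtl)) stop("no meQTL instrument for ", cpgId)
  ph <- phenotypes(cohort)
  cv <- .mrCovariates(cohort)
  meth <- betaValues(cohort)[cpgId, ]
  g <- dosages(cohort)[qtl$snp_id, ]
  before <- fitCpgAssociation(meth, ph$bmi, cv, spec, cpgId = cpgId)
  if (sd(g) == 0)
    return(list(t_before = before$t, t_after = NA_real_,
                attenuation = NA_real_, snp_id = qtl$snp_id,
                degenerate = TRUE))
  after <- fitCpgAssociation(meth, ph$bmi, cbind(cv, meqtl = g), spec,
                             cpgId = cpgId)
  list(t_before = before$t, t_after = after$t,
       attenuation = (abs(before$t) - abs(after$t)) / abs(before$t),
       snp_id = qtl$snp_id, degenerate = FALSE)
}
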