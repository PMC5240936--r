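#' Association of one CpG's methylation with its linked gene's expression
#'
#' OLS with expression as the dependent variable and methylation as the
#' independent variable of interest, adjusted for the supplied
#' covariates (typically age, sex and batch). The reported R^2 is the
#' partial R^2 of the methylation term, `t^2 / (t^2 + df)`.
#'
#' @param meth beta-value vector for the CpG
#' @param expr expression vector for the linked gene
#' @param covariates matrix/data.frame or `NULL`
#' @return one-row data.frame: `beta`, `se`, `t`, `p`, `r2`, `n`,
#'   `direction`
#' @export
fitCpgExpression <- function(meth, expr, covariates = NULL) {
  cv <- if (!is.null(covariates)) as.matrix(covariates)
  cc <- complete.cases(meth, expr, if (!is.null(cv)) cv)
  X <- cbind(intercept = 1, meth = meth[cc],
             if (!is.null(cv)) cv[cc, , drop = FALSE])
  rec <- .olsMany(X, cbind(expr[cc]), coefIdx = 2L)
  df <- rec$n - ncol(X)
  rec$r2 <- if (is.finite(rec$t)) rec$t^2 / (rec$t^2 + df) else 1
  rec[, c("beta", "se", "t", "p", "r2", "n", "direction")]
}

#' Run methylation-expression and expression-BMI models for a CpG panel
#'
#' For every CpG in `cpgIds` with a linked gene in the cohort's gene
#' annotation, fits the CpG-expression model and (once per unique gene)
#' the expression-BMI model, both adjusted for age, sex and batch. CpGs
#' without a gene link are skipped and counted.
#'
#' @param cohort a [CohortDataset-class]
#' @param cpgIds CpGs to test (typically the replicated set)
#' @return list: `cpgExpr` (per pair: `cpg_id`, `gene_id`, stats),
#'   `exprBmi` (per unique gene), `skipped` (unlinked CpG IDs)
#' @export
runExpressionAnalysis <- function(cohort, cpgIds) {
  ph <- phenotypes(cohort)
  bt <- ph$batch %||% rep(1L, nrow(ph))
  cv <- cbind(age = ph$age, sex = ph$sex,
              if (length(unique(bt)) > 1L)
                stats::model.matrix(~ factor(bt))[, -1, drop = FALSE])
  ga <- geneAnnotation(cohort)
  link <- ga$gene_id[match(cpgIds, ga$linked_cpg)]
  skipped <- cpgIds[is.na(link)]
  pairs <- data.frame(cpg_id = cpgIds[!is.na(link)],
                      gene_id = link[!is.na(link)],
                      stringsAsFactors = FALSE)
  B <- betaValues(cohort); E <- exprValues(cohort)
  cpgExpr <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    cbind(pairs[i, ], fitCpgExpression(B[pairs$cpg_id[i], ],
                                       E[pairs$gene_id[i], ], cv),
          stringsAsFactors = FALSE)))
  genes <- unique(pairs$gene_id)
  exprBmi <- do.call(rbind, lapply(genes, function(g) {
    X <- cbind(intercept = 1, expr = E[g, ], cv)
    rec <- .olsMany(X, cbind(ph$bmi), coefIdx = 2L)
    rec$r2 <- if (is.finite(rec$t)) rec$t^2 / (rec$t^2 + (rec$n - ncol(X)))
              else 1
    cbind(gene_id = g,
          rec[, c("beta", "se", "t", "p", "r2", "n", "direction")],
          stringsAsFactors = FALSE)
  }))
  rownames(cpgExpr) <- rownames(exprBmi) <- NULL
  list(cpgExpr = cpgExpr, exprBmi = exprBmi, skipped = skipped)
}

#' Three-way significance gate over CpG-BMI, CpG-expression and
#' expression-BMI legs
#'
#' A CpG-gene pair is three-way significant when (1) the CpG is in the
#' replicated CpG-BMI set, (2) its CpG-expression p-value passes
#' Bonferroni over the tested pairs, and (3) its gene's expression-BMI
#' p-value passes Bonferroni over the unique genes tested. Thresholds
#' are recomputed from the supplied counts, never hard-coded. Direction
#' triangles are reported but no sign-consistency is forced.
#'
#' @param replicatedCpgs character vector (the CpG-BMI leg)
#' @param cpgBmiRecords data.frame keyed by `cpg_id` with `p`,
#'   `direction` (discovery/meta statistics for the display columns)
#' @param cpgExprRecords data.frame from [runExpressionAnalysis()]
#' @param exprBmiRecords data.frame from [runExpressionAnalysis()]
#' @param alpha family-wise error rate for each expression leg
#' @return data.frame mirroring a three-way association table: per pair,
#'   directions, R^2 and p per leg plus `three_way_significant`
#' @export
threeWayGate <- function(replicatedCpgs, cpgBmiRecords, cpgExprRecords,
                         exprBmiRecords, alpha = 0.05) {
  orphans <- setdiff(cpgExprRecords$gene_id, exprBmiRecords$gene_id)
  if (length(orphans))
    stop("genes missing from expression-BMI records: ",
         paste(orphans, collapse = ", "))
  thrPair <- bonferroniThreshold(alpha, nrow(cpgExprRecords))
  thrGene <- bonferroniThreshold(alpha, length(unique(exprBmiRecords$gene_id)))
  bi <- match(cpgExprRecords$cpg_id, cpgBmiRecords$cpg_id)
  if (anyNA(bi))
    stop("CpGs missing from CpG-BMI records: ",
         paste(cpgExprRecords$cpg_id[is.na(bi)], collapse = ", "))
  bmiDir <- if ("direction" %in% names(cpgBmiRecords))
    cpgBmiRecords$direction else ifelse(cpgBmiRecords$z >= 0, "+", "-")
  gi <- match(cpgExprRecords$gene_id, exprBmiRecords$gene_id)
  out <- data.frame(
    cpg_id = cpgExprRecords$cpg_id, gene_id = cpgExprRecords$gene_id,
    cpg_bmi_dir = bmiDir[bi],
    cpg_bmi_p = cpgBmiRecords$p[bi],
    cpg_expr_dir = cpgExprRecords$direction,
    cpg_expr_r2 = cpgExprRecords$r2, cpg_expr_p = cpgExprRecords$p,
    expr_bmi_dir = exprBmiRecords$direction[gi],
    expr_bmi_r2 = exprBmiRecords$r2, expr_bmi_p = exprBmiRecords$p,
    stringsAsFactors = FALSE)
  out$three_way_significant <-
    out$cpg_id %in% replicatedCpgs &
    out$cpg_expr_p < thrPair &
    out$expr_bmi_p < thrGene
  attr(out, "thresholds") <- c(pair = thrPair, gene = thrGene)
  out
}
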