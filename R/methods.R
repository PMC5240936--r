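#' @describeIn CohortDataset-class phenotype table
#' @export
setMethod("phenotypes", "CohortDataset", function(x) x@phenotypes)

#' @describeIn CohortDataset-class CpG x sample beta-value matrix
#' @export
setMethod("betaValues", "CohortDataset",
          function(x) SummarizedExperiment::assay(x@methylation))

#' @describeIn CohortDataset-class SNP x sample dosage matrix
#' @export
setMethod("dosages", "CohortDataset",
          function(x) SummarizedExperiment::assay(x@genotypes))

#' @describeIn CohortDataset-class gene x sample expression matrix
#' @export
setMethod("exprValues", "CohortDataset",
          function(x) SummarizedExperiment::assay(x@expression))

#' @describeIn CohortDataset-class cohort label
#' @export
setMethod("cohortId", "CohortDataset", function(x) x@cohortId)

annDf <- function(se) as.data.frame(SummarizedExperiment::rowData(se))

#' @describeIn CohortDataset-class CpG annotation (chrom, pos, gene)
#' @export
setMethod("cpgAnnotation", "CohortDataset", function(x) annDf(x@methylation))

#' @describeIn CohortDataset-class SNP annotation (chrom, pos, maf, weight)
#' @export
setMethod("snpAnnotation", "CohortDataset", function(x) annDf(x@genotypes))

#' @describeIn CohortDataset-class gene annotation (links to CpG and eQTL)
#' @export
setMethod("geneAnnotation", "CohortDataset", function(x) annDf(x@expression))

setMethod("show", "CohortDataset", function(object) {
  cat("CohortDataset '", object@cohortId, "': ",
      nrow(object@phenotypes), " samples\n", sep = "")
  cat("  methylation: ", nrow(object@methylation), " CpGs | genotypes: ",
      nrow(object@genotypes), " SNPs | expression: ",
      nrow(object@expression), " genes\n", sep = "")
  cat("  BMI ", sprintf("%.1f +/- %.1f kg/m^2", mean(object@phenotypes$bmi),
                        sd(object@phenotypes$bmi)), "\n", sep = "")
})

#' @describeIn GroundTruth-class per-CpG roles and true effects
#' @export
setMethod("cpgTruth", "GroundTruth", function(x) x@cpg)

#' @describeIn GroundTruth-class per-SNP true BMI effects
#' @export
setMethod("snpTruth", "GroundTruth", function(x) x@snp)

setMethod("show", "GroundTruth", function(object) {
  tab <- table(object@cpg$role)
  cat("GroundTruth:", nrow(object@cpg), "CpGs (",
      paste(names(tab), as.integer(tab), collapse = ", "), ");",
      sum(object@snp$is_grs), "GRS SNPs\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nCohorts, "cohort(s), n =",
      paste(object@nSamplesPerCohort, collapse = "/"), "\n")
  cat("  features:", object@nCpgs, "CpGs,", object@nSnps, "SNPs (",
      object@nGrsSnps, "GRS ),", object@nGenes, "genes\n")
  cat(sprintf("  causal %.0f%% @ %.2g kg/m^2/SD; reactive %.0f%% @ %.2g SD/kg/m^2; seed %d\n",
              100 * object@fracCausalCpgs, object@causalEffectBmiPerSdMeth,
              100 * object@fracReactiveCpgs, object@reactiveEffectMethPerBmi,
              object@seed))
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@style, "| covariates:",
      paste(object@covariates, collapse = "+"),
      "| SVs:", object@nSurrogateVariables, "\n")
  if (length(object@bmiRangeFilter))
    cat("  BMI filter: [", paste(object@bmiRangeFilter, collapse = ", "),
        "] kg/m^2\n")
  if (length(object@clusterField))
    cat("  cluster-robust over:", object@clusterField, "\n")
})
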