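#' Build a simulation configuration
#'
#' All arguments have defaults describing the package's reference
#' synthetic world (see the methods vignette for the calibration): five
#' cohorts of 2000 samples (two discovery, three replication in
#' [runPipeline()]), 200 CpGs of which 5% are causal for BMI and 8%
#' reactive to it, cis-meQTL/eQTL instruments of fixed magnitude and
#' random sign, two latent cell factors plus two technical batches, and a
#' 97-SNP polygenic score contributing ~0.8 (kg/m^2)^2 of BMI variance.
#'
#' @param nCohorts,nSamplesPerCohort,nCpgs,nSnps,nGenes,nGrsSnps counts;
#'   `nSamplesPerCohort` is recycled to `nCohorts`
#' @param mafRange minor-allele-frequency range in (0, 0.5]
#' @param fracCausalCpgs,fracReactiveCpgs proportions of CpGs causal for /
#'   reactive to BMI
#' @param causalEffectBmiPerSdMeth kg/m^2 per SD methylation (magnitude)
#' @param reactiveEffectMethPerBmi SD methylation per kg/m^2 (magnitude)
#' @param meqtlEffectSd,eqtlEffectSd QTL effect magnitude per allele
#' @param methToExprEffect expression SD per methylation SD (signed)
#' @param exprToBmiEffect kg/m^2 per expression SD for causal-linked genes
#' @param nCellComponents,nBatches,confoundingSd,cellBmiEffect confounding
#' @param noiseSdBmi,noiseSdMeth,noiseSdExpr residual scales
#' @param ageRange,fracFemale,fracSmokers demographics
#' @param grsVarBmi BMI variance contributed by the GRS SNPs
#' @param seed integer seed
#' @return a validated [SimConfig-class] object
#' @examples
#' cfg <- simConfig(nCohorts = 1L, nSamplesPerCohort = 100L, nCpgs = 20L,
#'                  nSnps = 120L, nGenes = 10L, seed = 7L)
#' @export
simConfig <- function(nCohorts = 5L, nSamplesPerCohort = 2000L,
                      nCpgs = 200L, nSnps = 300L, nGenes = 60L,
                      nGrsSnps = 97L, mafRange = c(0.05, 0.5),
                      fracCausalCpgs = 0.05, fracReactiveCpgs = 0.08,
                      causalEffectBmiPerSdMeth = 1.0,
                      reactiveEffectMethPerBmi = 0.03,
                      meqtlEffectSd = 0.5, eqtlEffectSd = 0.5,
                      methToExprEffect = -0.3, exprToBmiEffect = 0,
                      nCellComponents = 2L, nBatches = 2L,
                      confoundingSd = 0.4, cellBmiEffect = 0.5,
                      noiseSdBmi = 4.0, noiseSdMeth = 1.0,
                      noiseSdExpr = 1.0, ageRange = c(50, 85),
                      fracFemale = 0.5, fracSmokers = 0.1,
                      grsVarBmi = 0.8, seed = 1L) {
  n <- rep_len(as.integer(nSamplesPerCohort), as.integer(nCohorts))
  new("SimConfig", nCohorts = as.integer(nCohorts), nSamplesPerCohort = n,
      nCpgs = as.integer(nCpgs), nSnps = as.integer(nSnps),
      nGenes = as.integer(nGenes), nGrsSnps = as.integer(nGrsSnps),
      mafRange = as.numeric(mafRange),
      fracCausalCpgs = fracCausalCpgs, fracReactiveCpgs = fracReactiveCpgs,
      causalEffectBmiPerSdMeth = causalEffectBmiPerSdMeth,
      reactiveEffectMethPerBmi = reactiveEffectMethPerBmi,
      meqtlEffectSd = meqtlEffectSd, eqtlEffectSd = eqtlEffectSd,
      methToExprEffect = methToExprEffect, exprToBmiEffect = exprToBmiEffect,
      nCellComponents = as.integer(nCellComponents),
      nBatches = as.integer(nBatches), confoundingSd = confoundingSd,
      cellBmiEffect = cellBmiEffect, noiseSdBmi = noiseSdBmi,
      noiseSdMeth = noiseSdMeth, noiseSdExpr = noiseSdExpr,
      ageRange = as.numeric(ageRange), fracFemale = fracFemale,
      fracSmokers = fracSmokers, grsVarBmi = grsVarBmi,
      seed = as.integer(seed))
}

#' Build a per-cohort EWAS model specification
#'
#' @param style `"methOutcome"` (inverse-normal-transformed methylation as
#'   outcome) or `"residualOutcome"` (batch-adjusted logit residual)
#' @param covariates subset of `c("age","sex","smoking")`
#' @param nSurrogateVariables surrogate variables to estimate and adjust for
#' @param bmiRangeFilter `NULL` or inclusive `c(low, high)` in kg/m^2
#' @param interactionTerm `NULL`, `"sex"` or `"age"`
#' @param clusterField `NULL` or a phenotype column for cluster-robust SEs
#' @return a validated [ModelSpec-class]
#' @export
modelSpec <- function(style = c("methOutcome", "residualOutcome"),
                      covariates = c("age", "sex"),
                      nSurrogateVariables = 0L, bmiRangeFilter = NULL,
                      interactionTerm = NULL, clusterField = NULL) {
  style <- match.arg(style)
  bad <- setdiff(covariates, c("age", "sex", "smoking"))
  if (length(bad))
    stop("unsupported covariates: ", paste(bad, collapse = ", "))
  new("ModelSpec", style = style, covariates = as.character(covariates),
      nSurrogateVariables = as.integer(nSurrogateVariables),
      bmiRangeFilter = as.numeric(bmiRangeFilter %||% numeric(0)),
      interactionTerm = as.character(interactionTerm %||% character(0)),
      clusterField = as.character(clusterField %||% character(0)))
}

#' Build a composite-score configuration
#'
#' Defaults follow the standard epidemiological BMI categories: obesity at
#' BMI >= 30 kg/m^2, overweight 25-29.9 kg/m^2, reference below 25, and a
#' correlation-pruning bound of |r| < 0.7.
#'
#' @param rThreshold absolute correlation bound for pruning
#' @param obesityCutoff,overweightRange,referenceUpper BMI category bounds
#' @param nDeciles number of score bins
#' @return a validated [ScoreConfig-class]
#' @export
scoreConfig <- function(rThreshold = 0.7, obesityCutoff = 30,
                        overweightRange = c(25, 29.9), referenceUpper = 25,
                        nDeciles = 10L) {
  new("ScoreConfig", rThreshold = rThreshold, obesityCutoff = obesityCutoff,
      overweightRange = as.numeric(overweightRange),
      referenceUpper = referenceUpper, nDeciles = as.integer(nDeciles))
}

#' Assemble a cohort dataset from matrices
#'
#' @param phenotypes data.frame with `sample_id`, `age`, `sex`, `smoking`,
#'   `bmi` and optionally `batch`, `family_id`
#' @param beta CpG x sample matrix of beta values in [0,1]
#' @param cpgAnnotation data.frame (`cpg_id`, `chrom`, `pos`, `gene`)
#'   aligned to `rownames(beta)`
#' @param dosage SNP x sample matrix with entries in [0,2]
#' @param snpAnnotation data.frame (`snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `maf`, `gwas_weight`)
#' @param expr gene x sample matrix
#' @param geneAnnotation data.frame (`gene_id`, `chrom`, `pos`,
#'   `linked_cpg`, `eqtl_snp`)
#' @param cohortId character label
#' @return a validated [CohortDataset-class]
#' @export
cohortDataset <- function(phenotypes, beta, cpgAnnotation, dosage,
                          snpAnnotation, expr, geneAnnotation,
                          cohortId = "cohort1") {
  ids <- as.character(phenotypes$sample_id)
  mkSE <- function(m, ann, key) {
    rownames(m) <- as.character(ann[[key]])
    colnames(m) <- ids
    SummarizedExperiment::SummarizedExperiment(
      assays = list(m), rowData = S4Vectors::DataFrame(ann))
  }
  names(phenotypes) <- tolower(names(phenotypes))
  new("CohortDataset", phenotypes = phenotypes,
      methylation = mkSE(beta, cpgAnnotation, "cpg_id"),
      genotypes = mkSE(dosage, snpAnnotation, "snp_id"),
      expression = mkSE(expr, geneAnnotation, "gene_id"),
      cohortId = cohortId)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
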