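#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats approx coef complete.cases cor glm lm lm.fit median
#'   pchisq pf plogis pnorm pt qchisq qlogis qnorm qt quantile rbinom rnorm
#'   runif sd setNames var binomial ks.test fisher.test
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Simulation configuration for multi-cohort methylation/BMI datasets
#'
#' Container for every parameter of the synthetic multi-cohort generator.
#' The defaults of [simConfig()] describe a desk-scale world mirroring the
#' statistical structure of a blood-based BMI EWAS in older adults: several
#' cohorts of ~2000 participants, a few hundred CpGs of which a small
#' fraction causally raise or lower BMI and another fraction react to BMI,
#' cis-meQTLs and eQTLs as usable instruments, latent cell-composition and
#' batch confounding, and a polygenic SNP set (a stand-in for the 97-SNP
#' GIANT score) influencing BMI.
#'
#' @slot nCohorts number of cohorts generated under one shared law
#' @slot nSamplesPerCohort integer vector (recycled to `nCohorts`)
#' @slot nCpgs,nSnps,nGenes,nGrsSnps feature counts; `nGrsSnps` of the
#'   `nSnps` SNPs carry true BMI effects and GWAS weights
#' @slot mafRange minor-allele-frequency range, within (0, 0.5]
#' @slot fracCausalCpgs,fracReactiveCpgs proportions of CpGs that are
#'   causal for, respectively reactive to, BMI (sum <= 1)
#' @slot causalEffectBmiPerSdMeth kg/m^2 change in BMI per SD of causal-CpG
#'   methylation (logit scale); sign randomised per CpG
#' @slot reactiveEffectMethPerBmi SD of methylation per kg/m^2 BMI for
#'   reactive CpGs; sign randomised per CpG
#' @slot meqtlEffectSd,eqtlEffectSd absolute cis-QTL effect per effect
#'   allele (logit units for methylation, expression SD for genes); sign
#'   randomised per feature
#' @slot methToExprEffect expression SD per SD of linked-CpG methylation
#'   (negative by default: methylation mostly represses expression)
#' @slot exprToBmiEffect kg/m^2 per expression SD for causal-CpG-linked
#'   genes; nonzero values close the mediation chain meth -> expr -> BMI
#' @slot nCellComponents,nBatches latent cell factors and technical batches
#' @slot confoundingSd scale of cell-factor loadings and batch offsets on
#'   the methylation logit (and, attenuated, on expression)
#' @slot cellBmiEffect kg/m^2 per SD of the first cell factor, giving the
#'   confounder a path into BMI so surrogate variables have work to do
#' @slot noiseSdBmi,noiseSdMeth,noiseSdExpr residual scales (kg/m^2, logit
#'   units, expression units)
#' @slot ageRange,fracFemale,fracSmokers demographics
#' @slot grsVarBmi total BMI variance contributed by the GRS SNPs
#'   ((kg/m^2)^2); weights are rescaled to meet it exactly in expectation
#' @slot seed integer seed; the full multi-cohort draw is a pure function
#'   of the configuration including this seed
#' @seealso [simConfig()], [simulateMultiCohort()]
#' @export
setClass("SimConfig", representation(
  nCohorts = "integer", nSamplesPerCohort = "integer",
  nCpgs = "integer", nSnps = "integer", nGenes = "integer",
  nGrsSnps = "integer", mafRange = "numeric",
  fracCausalCpgs = "numeric", fracReactiveCpgs = "numeric",
  causalEffectBmiPerSdMeth = "numeric", reactiveEffectMethPerBmi = "numeric",
  meqtlEffectSd = "numeric", eqtlEffectSd = "numeric",
  methToExprEffect = "numeric", exprToBmiEffect = "numeric",
  nCellComponents = "integer", nBatches = "integer",
  confoundingSd = "numeric", cellBmiEffect = "numeric",
  noiseSdBmi = "numeric", noiseSdMeth = "numeric", noiseSdExpr = "numeric",
  ageRange = "numeric", fracFemale = "numeric", fracSmokers = "numeric",
  grsVarBmi = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  prop <- c(fracCausalCpgs = object@fracCausalCpgs,
            fracReactiveCpgs = object@fracReactiveCpgs,
            fracFemale = object@fracFemale,
            fracSmokers = object@fracSmokers)
  bad <- prop < 0 | prop > 1
  if (any(bad))
    msg <- c(msg, paste0("proportions outside [0,1]: ",
                         paste(names(prop)[bad], collapse = ", ")))
  if (object@fracCausalCpgs + object@fracReactiveCpgs > 1)
    msg <- c(msg, "fracCausalCpgs + fracReactiveCpgs must be <= 1")
  if (any(object@nSamplesPerCohort < 2L))
    msg <- c(msg, "sample counts must be >= 2")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must lie within (0, 0.5] with low <= high")
  if (object@nCohorts < 1L) msg <- c(msg, "nCohorts must be >= 1")
  if (length(object@nSamplesPerCohort) != object@nCohorts)
    msg <- c(msg, "nSamplesPerCohort must have one entry per cohort")
  nNonNull <- round(object@nCpgs * object@fracCausalCpgs) +
    round(object@nCpgs * object@fracReactiveCpgs)
  if (object@nSnps < 2L * nNonNull + object@nGrsSnps)
    msg <- c(msg, sprintf(
      "nSnps (%d) too small: need >= 2 x non-null CpGs (%d) + nGrsSnps (%d)",
      object@nSnps, nNonNull, object@nGrsSnps))
  if (object@nGenes < nNonNull)
    msg <- c(msg, "nGenes must be >= number of causal + reactive CpGs")
  if (length(msg)) msg else TRUE
})

#' One cohort's aligned phenotype and molecular data
#'
#' Bundles a phenotype table with methylation, genotype and expression
#' assays, each stored as a [SummarizedExperiment::SummarizedExperiment]
#' whose `rowData` carries the feature annotation (chromosome, position,
#' gene links, MAF, GWAS weights). Validity enforces that the four
#' components share one identical, ordered, duplicate-free sample-ID set,
#' that beta values lie in [0,1] and dosages in [0,2].
#'
#' @slot phenotypes data.frame with columns `sample_id`, `age`, `sex`
#'   (1 = female), `smoking`, `bmi`, `batch`, optionally `family_id`
#' @slot methylation SummarizedExperiment, assay `beta` (CpG x sample)
#' @slot genotypes SummarizedExperiment, assay `dosage` (SNP x sample)
#' @slot expression SummarizedExperiment, assay `expr` (gene x sample)
#' @slot cohortId character scalar label
#' @seealso [phenotypes()], [betaValues()], [dosages()], [exprValues()]
#' @export
setClass("CohortDataset", representation(
  phenotypes = "data.frame",
  methylation = "SummarizedExperiment",
  genotypes = "SummarizedExperiment",
  expression = "SummarizedExperiment",
  cohortId = "character"))

setValidity("CohortDataset", function(object) {
  msg <- character(0)
  ph <- object@phenotypes
  need <- c("sample_id", "age", "sex", "smoking", "bmi")
  miss <- setdiff(need, colnames(ph))
  if (length(miss))
    return(paste("phenotypes missing columns:", paste(miss, collapse = ", ")))
  ids <- as.character(ph$sample_id)
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated sample IDs")
  if (anyNA(ids)) msg <- c(msg, "missing sample_id")
  for (nm in c("methylation", "genotypes", "expression")) {
    se <- slot(object, nm)
    if (!identical(colnames(se), ids))
      msg <- c(msg, paste0(nm, " sample IDs do not match phenotype order"))
  }
  bv <- SummarizedExperiment::assay(object@methylation)
  if (length(bv) && (min(bv, na.rm = TRUE) < 0 || max(bv, na.rm = TRUE) > 1))
    msg <- c(msg, "methylation beta values outside [0,1]")
  dv <- SummarizedExperiment::assay(object@genotypes)
  if (length(dv) && (min(dv, na.rm = TRUE) < 0 || max(dv, na.rm = TRUE) > 2))
    msg <- c(msg, "dosages outside [0,2]")
  if (any(ph$bmi <= 0, na.rm = TRUE)) msg <- c(msg, "bmi must be > 0")
  if (any(ph$age <= 0, na.rm = TRUE)) msg <- c(msg, "age must be > 0")
  if (length(object@cohortId) != 1L) msg <- c(msg, "cohortId must be scalar")
  if (length(msg)) msg else TRUE
})

#' Ground-truth manifest emitted by the simulator
#'
#' Records the causal role of every CpG (`causal`, `reactive` or `null`),
#' the true effect sizes, the assigned cis-meQTL SNP and linked gene, and
#' the true BMI effect of every GRS SNP. Null CpGs have all true effects
#' equal to zero. This is the oracle against which parameter-recovery
#' tests of the downstream analyses are scored.
#'
#' @slot cpg data.frame keyed by `cpg_id` with `role`, `true_causal_effect`
#'   (kg/m^2 per SD methylation), `true_reactive_effect` (SD methylation
#'   per kg/m^2), `meqtl_snp`, `true_meqtl_effect` (logit per allele),
#'   `linked_gene`, `true_meth_expr_effect`, `eqtl_snp`,
#'   `true_eqtl_effect`, `true_expr_bmi_effect`
#' @slot snp data.frame keyed by `snp_id` with `true_bmi_effect` (kg/m^2
#'   per allele; nonzero only for GRS SNPs) and `is_grs`
#' @export
setClass("GroundTruth", representation(cpg = "data.frame",
                                       snp = "data.frame"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  cg <- object@cpg
  if (!all(cg$role %in% c("causal", "reactive", "null")))
    msg <- c(msg, "roles must be causal/reactive/null")
  nul <- cg$role == "null"
  if (any(cg$true_causal_effect[nul] != 0) ||
      any(cg$true_reactive_effect[nul] != 0) ||
      any(cg$true_meqtl_effect[nul] != 0))
    msg <- c(msg, "null CpGs must have all true effects = 0")
  if (length(msg)) msg else TRUE
})

#' Per-cohort EWAS model specification
#'
#' Describes how each CpG is regressed against BMI. `methOutcome` mirrors
#' a mixed-cohort primary model: inverse-normal-transformed methylation as
#' the dependent variable, BMI the independent variable of interest.
#' `residualOutcome` mirrors the alternative convention of carrying
#' forward a batch-adjusted logit-scale residual as the outcome. Both
#' orientations report the BMI term, so directions are comparable.
#'
#' @slot style `"methOutcome"` or `"residualOutcome"`
#' @slot covariates subset of `c("age","sex","smoking")`
#' @slot nSurrogateVariables number of surrogate variables to estimate
#'   from the methylation matrix and include as covariates
#' @slot bmiRangeFilter numeric(0) or inclusive `c(low, high)` in kg/m^2
#' @slot interactionTerm character(0), `"sex"` or `"age"`
#' @slot clusterField character(0) or a phenotype column (e.g.
#'   `family_id`) over which sandwich cluster-robust SEs are computed
#' @seealso [modelSpec()], [runEwas()]
#' @export
setClass("ModelSpec", representation(
  style = "character", covariates = "character",
  nSurrogateVariables = "integer", bmiRangeFilter = "numeric",
  interactionTerm = "character", clusterField = "character"))

setValidity("ModelSpec", function(object) {
  msg <- character(0)
  if (!object@style %in% c("methOutcome", "residualOutcome"))
    msg <- c(msg, "style must be 'methOutcome' or 'residualOutcome'")
  if (object@nSurrogateVariables < 0L)
    msg <- c(msg, "nSurrogateVariables must be >= 0")
  if (length(object@bmiRangeFilter) &&
      (length(object@bmiRangeFilter) != 2L ||
       object@bmiRangeFilter[1] >= object@bmiRangeFilter[2]))
    msg <- c(msg, "bmiRangeFilter must be c(low, high) with low < high")
  if (length(object@interactionTerm) &&
      !object@interactionTerm %in% c("sex", "age"))
    msg <- c(msg, "interactionTerm must be 'sex' or 'age'")
  if (length(msg)) msg else TRUE
})

#' Composite methylation score configuration
#'
#' @slot rThreshold absolute Pearson correlation bound for greedy pruning
#' @slot obesityCutoff BMI at or above which a sample counts as obese
#' @slot overweightRange inclusive BMI range counted as overweight
#' @slot referenceUpper BMI strictly below this is the reference category
#' @slot nDeciles number of score bins for the decile summary
#' @seealso [scoreConfig()], [compositeScore()]
#' @export
setClass("ScoreConfig", representation(
  rThreshold = "numeric", obesityCutoff = "numeric",
  overweightRange = "numeric", referenceUpper = "numeric",
  nDeciles = "integer"))

setValidity("ScoreConfig", function(object) {
  if (object@rThreshold <= 0 || object@rThreshold > 1)
    return("rThreshold must be in (0, 1]")
  if (object@nDeciles < 1L) return("nDeciles must be >= 1")
  TRUE
})
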