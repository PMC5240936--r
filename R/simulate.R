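# Fixed demographic coefficients of the BMI model (kg/m^2); centred at the
# reference adult (age 67, male, non-smoker) with intercept 28 so cohort
# means and SDs land near the 26-28 +/- 4-5 kg/m^2 typical of older-adult
# cohorts. Not config slots: they are part of the stated world.
.BMI_INTERCEPT <- 28
.BMI_AGE_EFFECT <- -0.04
.BMI_SEX_EFFECT <- -0.5
.BMI_SMOKE_EFFECT <- -1.0
.BMI_AGE_CENTER <- 67

.scale1 <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  (x - mean(x)) / s
}

# Shared generative law: everything that is fixed across cohorts
# (annotation, roles, true effect sizes, loadings, MAFs, GRS weights).
.drawLaw <- function(config) {
  nCpgs <- config@nCpgs
  nCausal <- round(nCpgs * config@fracCausalCpgs)
  nReactive <- round(nCpgs * config@fracReactiveCpgs)
  cpgIds <- sprintf("cg%05d", seq_len(nCpgs))
  roles <- rep("null", nCpgs)
  nonNull <- sample(nCpgs, nCausal + nReactive)
  roles[nonNull[seq_len(nCausal)]] <- "causal"
  if (nReactive > 0)
    roles[nonNull[nCausal + seq_len(nReactive)]] <- "reactive"
  cpgPos <- seq_len(nCpgs) * 1e6
  mu <- runif(nCpgs, qlogis(0.2), qlogis(0.8))

  causalEff <- ifelse(roles == "causal",
                      sample(c(-1, 1), nCpgs, TRUE) *
                        config@causalEffectBmiPerSdMeth, 0)
  reactiveEff <- ifelse(roles == "reactive",
                        sample(c(-1, 1), nCpgs, TRUE) *
                          config@reactiveEffectMethPerBmi, 0)

  isNonNull <- roles != "null"
  nNon <- sum(isNonNull)
  # one cis-meQTL within 100 kb of each non-null CpG, one eQTL 200 kb out
  # for its linked gene, decoys filling the +/-500 kb windows, GRS SNPs on
  # a separate chromosome
  nDecoy <- config@nSnps - 2L * nNon - config@nGrsSnps
  snpIds <- sprintf("snp%05d", seq_len(config@nSnps))
  meqtlIdx <- seq_len(nNon)
  eqtlIdx <- nNon + seq_len(nNon)
  decoyIdx <- if (nDecoy > 0) 2L * nNon + seq_len(nDecoy) else integer(0)
  grsIdx <- config@nSnps - config@nGrsSnps + seq_len(config@nGrsSnps)

  snpChrom <- rep("chr1", config@nSnps)
  snpChrom[grsIdx] <- "chr2"
  snpPos <- numeric(config@nSnps)
  snpPos[meqtlIdx] <- cpgPos[isNonNull] + 5e4
  snpPos[eqtlIdx] <- cpgPos[isNonNull] + 2e5
  if (nDecoy > 0) {
    host <- sample(nCpgs, nDecoy, replace = TRUE)
    snpPos[decoyIdx] <- pmax(1, cpgPos[host] +
                               round(runif(nDecoy, -5e5, 5e5)))
  }
  snpPos[grsIdx] <- seq_len(config@nGrsSnps) * 1e6
  maf <- runif(config@nSnps, config@mafRange[1], config@mafRange[2])

  meqtlSnp <- rep(NA_character_, nCpgs)
  meqtlSnp[isNonNull] <- snpIds[meqtlIdx]
  meqtlEff <- numeric(nCpgs)
  meqtlEff[isNonNull] <- sample(c(-1, 1), nNon, TRUE) * config@meqtlEffectSd

  # genes: the first nNon genes are linked one-to-one to the non-null CpGs
  # (same locus); the rest are unlinked background genes; null CpGs are
  # intergenic (no gene annotation)
  geneIds <- sprintf("gene%04d", seq_len(config@nGenes))
  linkedGene <- rep(NA_character_, nCpgs)
  linkedGene[isNonNull] <- geneIds[seq_len(nNon)]
  geneChrom <- rep("chr3", config@nGenes)
  genePos <- seq_len(config@nGenes) * 1e6
  geneChrom[seq_len(nNon)] <- "chr1"
  genePos[seq_len(nNon)] <- cpgPos[isNonNull]
  geneLinkedCpg <- rep(NA_character_, config@nGenes)
  geneLinkedCpg[seq_len(nNon)] <- cpgIds[isNonNull]
  geneEqtlSnp <- rep(NA_character_, config@nGenes)
  geneEqtlSnp[seq_len(nNon)] <- snpIds[eqtlIdx]
  eqtlEff <- numeric(config@nGenes)
  eqtlEff[seq_len(nNon)] <- sample(c(-1, 1), nNon, TRUE) * config@eqtlEffectSd
  methExprEff <- numeric(config@nGenes)
  methExprEff[seq_len(nNon)] <- config@methToExprEffect
  exprBmiEff <- numeric(config@nGenes)
  exprBmiEff[seq_len(nNon)][roles[isNonNull] == "causal"] <-
    config@exprToBmiEffect

  # GRS weights rescaled so the expected score variance hits grsVarBmi
  gw <- numeric(config@nSnps)
  if (config@nGrsSnps > 0) {
    raw <- rnorm(config@nGrsSnps)
    v <- sum(2 * maf[grsIdx] * (1 - maf[grsIdx]) * raw^2)
    gw[grsIdx] <- if (v > 0) raw * sqrt(config@grsVarBmi / v) else 0
  }

  # latent cell factors load on a random 30% of CpGs
  k <- config@nCellComponents
  cellLoad <- matrix(0, nrow = k, ncol = nCpgs)
  if (k > 0) {
    hit <- matrix(runif(k * nCpgs) < 0.3, nrow = k)
    cellLoad[hit] <- rnorm(sum(hit), 0, config@confoundingSd)
  }

  list(
    cpg = data.frame(cpg_id = cpgIds, chrom = "chr1", pos = cpgPos,
                     gene = linkedGene, role = roles, mu = mu,
                     causalEff = causalEff, reactiveEff = reactiveEff,
                     meqtlSnp = meqtlSnp, meqtlEff = meqtlEff,
                     stringsAsFactors = FALSE),
    snp = data.frame(snp_id = snpIds, chrom = snpChrom, pos = snpPos,
                     effect_allele = "B", maf = maf, gwas_weight = gw,
                     is_grs = seq_len(config@nSnps) %in% grsIdx,
                     stringsAsFactors = FALSE),
    gene = data.frame(gene_id = geneIds, chrom = geneChrom, pos = genePos,
                      linked_cpg = geneLinkedCpg, eqtl_snp = geneEqtlSnp,
                      eqtlEff = eqtlEff, methExprEff = methExprEff,
                      exprBmiEff = exprBmiEff, stringsAsFactors = FALSE),
    cellLoad = cellLoad)
}

.simulateCohort <- function(config, law, n, cohortLabel) {
  nCpgs <- config@nCpgs
  ids <- paste0(cohortLabel, "_S", sprintf("%04d", seq_len(n)))
  age <- round(runif(n, config@ageRange[1], config@ageRange[2]))
  sex <- as.integer(runif(n) < config@fracFemale)
  smoking <- as.integer(runif(n) < config@fracSmokers)
  batch <- sample(config@nBatches, n, replace = TRUE)

  dosage <- matrix(rbinom(config@nSnps * n, 2L, rep(law$snp$maf, times = n)),
                   nrow = config@nSnps, ncol = n)

  k <- config@nCellComponents
  cellF <- matrix(rnorm(n * max(k, 1L)), nrow = n)[, seq_len(k), drop = FALSE]
  batchEffMeth <- matrix(rnorm(config@nBatches * nCpgs, 0,
                               config@confoundingSd),
                         nrow = config@nBatches)
  batchEffExpr <- matrix(rnorm(config@nBatches * config@nGenes, 0,
                               config@confoundingSd / 2),
                         nrow = config@nBatches)

  confMeth <- batchEffMeth[batch, , drop = FALSE]
  if (k > 0) confMeth <- confMeth + cellF %*% law$cellLoad

  snpRow <- function(id) dosage[match(id, law$snp$snp_id), ]

  # pass 1: causal + null CpG methylation (logit scale)
  mlogit <- matrix(NA_real_, nrow = n, ncol = nCpgs)
  noise <- matrix(rnorm(n * nCpgs, 0, config@noiseSdMeth), nrow = n)
  pre <- law$cpg$role != "reactive"
  for (j in which(pre)) {
    g <- if (is.na(law$cpg$meqtlSnp[j])) 0 else
      law$cpg$meqtlEff[j] * snpRow(law$cpg$meqtlSnp[j])
    mlogit[, j] <- law$cpg$mu[j] + g + confMeth[, j] + noise[, j]
  }

  # expression of causal-linked genes (may feed BMI when exprToBmiEffect
  # is nonzero, closing the meth -> expr -> BMI mediation chain)
  expr <- matrix(NA_real_, nrow = n, ncol = config@nGenes)
  exprNoise <- matrix(rnorm(n * config@nGenes, 0, config@noiseSdExpr),
                      nrow = n)
  geneCpgIdx <- match(law$gene$linked_cpg, law$cpg$cpg_id)
  geneStage1 <- !is.na(geneCpgIdx) &
    law$cpg$role[ifelse(is.na(geneCpgIdx), 1L, geneCpgIdx)] == "causal"
  simGene <- function(j) {
    e <- batchEffExpr[batch, j] + exprNoise[, j]
    if (!is.na(law$gene$eqtl_snp[j]))
      e <- e + law$gene$eqtlEff[j] * snpRow(law$gene$eqtl_snp[j])
    if (!is.na(geneCpgIdx[j]))
      e <- e + law$gene$methExprEff[j] * .scale1(mlogit[, geneCpgIdx[j]])
    e
  }
  for (j in which(geneStage1)) expr[, j] <- simGene(j)

  # BMI: demographics + polygenic score + causal methylation (+ mediated
  # expression) + first-cell-factor confounding + noise
  bmi <- .BMI_INTERCEPT + .BMI_AGE_EFFECT * (age - .BMI_AGE_CENTER) +
    .BMI_SEX_EFFECT * sex + .BMI_SMOKE_EFFECT * smoking +
    drop(crossprod(dosage, law$snp$gwas_weight))
  for (j in which(law$cpg$role == "causal"))
    bmi <- bmi + law$cpg$causalEff[j] * .scale1(mlogit[, j])
  for (j in which(geneStage1 & law$gene$exprBmiEff != 0))
    bmi <- bmi + law$gene$exprBmiEff[j] * .scale1(expr[, j])
  if (k > 0) bmi <- bmi + config@cellBmiEffect * cellF[, 1]
  bmi <- bmi + rnorm(n, 0, config@noiseSdBmi)

  # pass 2: reactive CpGs respond to realised BMI
  for (j in which(law$cpg$role == "reactive")) {
    g <- if (is.na(law$cpg$meqtlSnp[j])) 0 else
      law$cpg$meqtlEff[j] * snpRow(law$cpg$meqtlSnp[j])
    mlogit[, j] <- law$cpg$mu[j] + g +
      law$cpg$reactiveEff[j] * (bmi - .BMI_INTERCEPT) +
      confMeth[, j] + noise[, j]
  }
  for (j in which(!geneStage1)) expr[, j] <- simGene(j)

  ph <- data.frame(sample_id = ids, age = age, sex = sex,
                   smoking = smoking, bmi = bmi, batch = batch,
                   family_id = ids, stringsAsFactors = FALSE)
  cohortDataset(
    phenotypes = ph,
    beta = t(plogis(mlogit)),
    cpgAnnotation = law$cpg[, c("cpg_id", "chrom", "pos", "gene")],
    dosage = dosage,
    snpAnnotation = law$snp[, c("snp_id", "chrom", "pos", "effect_allele",
                                "maf", "gwas_weight")],
    expr = t(expr),
    geneAnnotation = law$gene[, c("gene_id", "chrom", "pos", "linked_cpg",
                                  "eqtl_snp")],
    cohortId = cohortLabel)
}

#' Simulate multi-cohort methylation/genotype/expression/BMI datasets
#'
#' Draws one shared generative law (feature annotation, causal roles, true
#' effect sizes, confounder loadings, MAFs, GRS weights) and then
#' independent per-cohort realisations of it. Generation order follows
#' the causal schema: genotypes, then causal and null CpG methylation
#' (meQTL + confounders + noise on the logit scale), then expression of
#' causal-linked genes, then BMI (demographics + weighted GRS + causal
#' methylation in SD units + optional mediated expression + confounding +
#' noise), then reactive CpG methylation responding to realised BMI, then
#' the remaining expression. Fully reproducible from `config@seed`.
#'
#' @param config a [SimConfig-class] from [simConfig()]
#' @return list with `cohorts` (list of [CohortDataset-class]) and
#'   `truth` (a [GroundTruth-class] manifest)
#' @examples
#' sim <- simulateMultiCohort(simConfig(nCohorts = 1L,
#'   nSamplesPerCohort = 80L, nCpgs = 20L, nSnps = 120L, nGenes = 10L,
#'   seed = 3L))
#' table(cpgTruth(sim$truth)$role)
#' @export
simulateMultiCohort <- function(config) {
  validObject(config)
  minN <- 3L + 2L  # age, sex, smoking covariates + 2
  if (any(config@nSamplesPerCohort < minN))
    stop("refusing to simulate: each cohort needs n >= ", minN,
         " (number of covariates + 2)")
  set.seed(config@seed)
  law <- .drawLaw(config)
  cohorts <- vector("list", config@nCohorts)
  for (i in seq_len(config@nCohorts))
    cohorts[[i]] <- .simulateCohort(config, law,
                                    config@nSamplesPerCohort[i],
                                    paste0("cohort", i))
  names(cohorts) <- vapply(cohorts, cohortId, character(1))

  cpgT <- data.frame(
    cpg_id = law$cpg$cpg_id, role = law$cpg$role,
    true_causal_effect = law$cpg$causalEff,
    true_reactive_effect = law$cpg$reactiveEff,
    meqtl_snp = law$cpg$meqtlSnp, true_meqtl_effect = law$cpg$meqtlEff,
    linked_gene = law$cpg$gene, stringsAsFactors = FALSE)
  gi <- match(cpgT$linked_gene, law$gene$gene_id)
  cpgT$true_meth_expr_effect <- ifelse(is.na(gi), 0, law$gene$methExprEff[gi])
  cpgT$eqtl_snp <- ifelse(is.na(gi), NA_character_, law$gene$eqtl_snp[gi])
  cpgT$true_eqtl_effect <- ifelse(is.na(gi), 0, law$gene$eqtlEff[gi])
  cpgT$true_expr_bmi_effect <- ifelse(is.na(gi), 0, law$gene$exprBmiEff[gi])
  snpT <- data.frame(snp_id = law$snp$snp_id,
                     true_bmi_effect = law$snp$gwas_weight,
                     is_grs = law$snp$is_grs, stringsAsFactors = FALSE)
  list(cohorts = cohorts,
       truth = new("GroundTruth", cpg = cpgT, snp = snpT))
}
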