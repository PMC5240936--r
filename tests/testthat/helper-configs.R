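# Small configurations reused across tests. These are stated worlds, not
# tuning knobs: effect sizes follow the package defaults or the explicit
# scenario a test describes.

# a compact but fully featured world (causal + reactive + nulls)
tinyConfig <- function(seed = 1L, n = 300L, ...) {
  simConfig(nCohorts = 1L, nSamplesPerCohort = n, nCpgs = 40L,
            nSnps = 130L, nGenes = 12L, nGrsSnps = 97L, seed = seed, ...)
}

# the global null: every effect and confounder scale zero, so CpG tests
# are mutually independent and exactly calibrated
nullConfig <- function(seed, n = 500L, nCpgs = 2000L) {
  simConfig(nCohorts = 1L, nSamplesPerCohort = n, nCpgs = nCpgs,
            nSnps = 10L, nGenes = 1L, nGrsSnps = 5L,
            fracCausalCpgs = 0, fracReactiveCpgs = 0,
            causalEffectBmiPerSdMeth = 0, reactiveEffectMethPerBmi = 0,
            meqtlEffectSd = 0, eqtlEffectSd = 0, methToExprEffect = 0,
            confoundingSd = 0, cellBmiEffect = 0, grsVarBmi = 0,
            seed = seed)
}

# one strongly instrumented causal CpG (forward-MR recovery world)
causalOneConfig <- function(seed, n = 2000L, effect = 2.0) {
  simConfig(nCohorts = 1L, nSamplesPerCohort = n, nCpgs = 1L,
            nSnps = 8L, nGenes = 1L, nGrsSnps = 0L,
            fracCausalCpgs = 1, fracReactiveCpgs = 0,
            causalEffectBmiPerSdMeth = effect, seed = seed)
}

firstCohort <- function(config) simulateMultiCohort(config)$cohorts[[1]]

# hand-built one-CpG cohort with its meQTL placed in cis, for attenuation
# and other single-locus scenarios
.attenuationCohort <- function(meth, bmi, g) {
  n <- length(bmi)
  ph <- data.frame(sample_id = sprintf("s%04d", seq_len(n)),
                   age = round(runif(n, 50, 85)),
                   sex = rbinom(n, 1, 0.5), smoking = rbinom(n, 1, 0.1),
                   bmi = bmi, batch = 1L, stringsAsFactors = FALSE)
  cohortDataset(
    ph,
    beta = matrix(meth, 1, n, dimnames = list("cg1", ph$sample_id)),
    cpgAnnotation = data.frame(cpg_id = "cg1", chrom = "chr1", pos = 1e6,
                               gene = NA_character_),
    dosage = matrix(g, 1, n, dimnames = list("snp1", ph$sample_id)),
    snpAnnotation = data.frame(snp_id = "snp1", chrom = "chr1",
                               pos = 1e6 + 5e4, effect_allele = "B",
                               maf = 0.3, gwas_weight = 0),
    expr = matrix(rnorm(n), 1, n, dimnames = list("gene1", ph$sample_id)),
    geneAnnotation = data.frame(gene_id = "gene1", chrom = "chr3",
                                pos = 1e6, linked_cpg = NA_character_,
                                eqtl_snp = NA_character_),
    cohortId = "handmade")
}
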