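.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analytical chain on simulated (or supplied) cohorts
#'
#' Executes simulate-or-load, per-cohort discovery EWAS, sample-size-
#' weighted meta-analysis with Bonferroni gating and genomic inflation,
#' external replication adjudication, composite-score analyses in the
#' first replication cohort, methylation-expression-BMI three-way
#' gating, forward / reverse / two-step Mendelian randomization, and
#' conditional-on-meQTL sensitivity models. All thresholds are derived
#' from `alpha` and the test counts at run time. With `outDir` set,
#' every stage's table is written as TSV together with a run manifest.
#'
#' @param config a [SimConfig-class]; ignored when `cohorts` is given
#' @param cohorts optional list of [CohortDataset-class] to analyse
#' @param truth optional [GroundTruth-class] carried into the bundle
#' @param nDiscovery how many leading cohorts form the discovery set
#' @param spec discovery/replication [ModelSpec-class]
#' @param scoreCfg a [ScoreConfig-class]
#' @param alpha family-wise error rate used throughout
#' @param windowBp cis-meQTL scan window half-width
#' @param ldIndependenceR2 instrument-independence bound for two-step MR
#' @param outDir optional output directory
#' @return named list bundle: `discoveryEwas`, `discoveryMeta`,
#'   `inflation`, `hits`, `replication`, `replicated`, `score`,
#'   `expression`, `threeWay`, `forwardMr`, `grs`, `reverseMr`,
#'   `twoStep`, `attenuation`, `truth`, `manifest`
#' @export
runPipeline <- function(config = simConfig(), cohorts = NULL, truth = NULL,
                        nDiscovery = 2L,
                        spec = modelSpec(nSurrogateVariables = 3L),
                        scoreCfg = scoreConfig(), alpha = 0.05,
                        windowBp = 5e5, ldIndependenceR2 = 0.2,
                        outDir = NULL) {
  if (is.null(cohorts)) {
    sim <- .stage("simulate", simulateMultiCohort(config))
    cohorts <- sim$cohorts
    truth <- sim$truth
  }
  if (nDiscovery < 1L || nDiscovery > length(cohorts))
    stop("nDiscovery must be between 1 and the number of cohorts")
  disc <- cohorts[seq_len(nDiscovery)]
  repl <- cohorts[-seq_len(nDiscovery)]

  discEwas <- .stage("discovery-ewas", lapply(disc, runEwas, spec = spec))
  nCpgs <- nrow(discEwas[[1]])
  discMeta <- .stage("discovery-meta",
                     metaEwas(discEwas, alpha = alpha, mTests = nCpgs))
  inflation <- genomicInflation(discMeta$z)
  hits <- discMeta[discMeta$significant, , drop = FALSE]
  bundle <- list(discoveryEwas = discEwas, discoveryMeta = discMeta,
                 inflation = inflation, hits = hits, truth = truth)

  if (!length(repl)) {
    message("no replication cohorts configured; pipeline stops after ",
            "discovery (", nrow(hits), " hits at alpha/", nCpgs, ")")
    bundle$manifest <- .manifest(config, alpha)
    if (!is.null(outDir)) .writeBundle(bundle, outDir)
    return(bundle)
  }
  if (!nrow(hits)) {
    message("no discovery hits at the Bonferroni gate; pipeline stops")
    bundle$manifest <- .manifest(config, alpha)
    if (!is.null(outDir)) .writeBundle(bundle, outDir)
    return(bundle)
  }

  replEwas <- .stage("replication-ewas", lapply(repl, runEwas, spec = spec))
  replication <- .stage("replication",
                        adjudicateReplication(hits, replEwas, alpha))
  replicated <- replication$replicated
  bundle$replication <- replication
  bundle$replicated <- replicated

  # composite-score analyses in the first replication cohort, with the
  # first discovery cohort's effect sizes as weights
  scoreCohort <- repl[[1]]
  ranked <- hits$cpg_id[order(hits$p)]
  ranked <- ranked[ranked %in% replicated]
  bundle$score <- .stage("score", {
    panel <- pruneCorrelated(ranked, scoreCohort,
                             rThreshold = scoreCfg@rThreshold)
    w <- discEwas[[1]]$beta[match(panel, discEwas[[1]]$cpg_id)]
    names(w) <- panel
    ph <- phenotypes(scoreCohort)
    sc <- compositeScore(scoreCohort, w)
    maxK <- min(length(panel), nrow(ph) - 4L)
    list(panel = panel, weights = w, score = sc,
         deciles = decileSummary(sc, ph$bmi, scoreCfg),
         perSd = perSdModels(sc, ph$bmi, ph$age, ph$sex, scoreCfg),
         r2Curve = incrementalR2(ph$bmi,
                                 cbind(age = ph$age, sex = ph$sex),
                                 panel[seq_len(maxK)], scoreCohort))
  })

  exprCohort <- disc[[1]]
  bundle$expression <- .stage("expression",
                              runExpressionAnalysis(exprCohort, replicated))
  bundle$threeWay <- .stage("three-way", threeWayGate(
    replicated, discMeta, bundle$expression$cpgExpr,
    bundle$expression$exprBmi, alpha = alpha))

  bundle$forwardMr <- .stage("forward-mr",
                             forwardMr(replicated, exprCohort,
                                       windowBp = windowBp, alpha = alpha))
  bundle$grs <- .stage("grs", buildGrs(exprCohort))
  bundle$reverseMr <- .stage("reverse-mr",
                             reverseMr(replicated, exprCohort, bundle$grs,
                                       alpha = alpha))

  # two-step MR for forward-nominal CpGs whose linked gene has an
  # independent eQTL instrument
  bundle$twoStep <- .stage("two-step-mr", {
    fm <- bundle$forwardMr
    cand <- fm$exposure_id[fm$nominal_significant]
    ga <- geneAnnotation(exprCohort)
    out <- list()
    for (cg in cand) {
      gi <- match(cg, ga$linked_cpg)
      if (is.na(gi) || is.na(ga$eqtl_snp[gi])) next
      meqtlSnp <- fm$iv[fm$exposure_id == cg]
      res <- tryCatch(
        twoStepMr(meqtlSnp, ga$gene_id[gi], ga$eqtl_snp[gi], exprCohort,
                  ldIndependenceR2 = ldIndependenceR2),
        error = function(e) conditionMessage(e))
      out[[cg]] <- res
    }
    out
  })

  bundle$attenuation <- .stage("conditional-meqtl", {
    rows <- lapply(replicated, function(cg) {
      a <- tryCatch(conditionalMeqtlAttenuation(cg, exprCohort,
                                                spec = spec),
                    error = function(e) NULL)
      if (is.null(a)) return(NULL)
      data.frame(cpg_id = cg, t_before = a$t_before, t_after = a$t_after,
                 attenuation = a$attenuation, snp_id = a$snp_id,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  bundle$manifest <- .manifest(config, alpha)
  if (!is.null(outDir)) .writeBundle(bundle, outDir)
  bundle
}

.manifest <- function(config, alpha) {
  cfgFile <- tempfile()
  dput(lapply(slotNames(config), function(s) slot(config, s)), cfgFile)
  h <- unname(tools::md5sum(cfgFile))
  unlink(cfgFile)
  data.frame(key = c("package_version", "config_md5", "seed", "alpha"),
             value = c(as.character(packageVersion("methylMR")), h,
                       config@seed, alpha), stringsAsFactors = FALSE)
}

.writeBundle <- function(bundle, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) if (!is.null(d)) .writeTsv(d, file.path(outDir, f))
  for (i in seq_along(bundle$discoveryEwas))
    w(bundle$discoveryEwas[[i]], sprintf("ewas_discovery_%d.tsv", i))
  w(bundle$discoveryMeta, "meta_discovery.tsv")
  w(qqData(bundle$discoveryMeta$p), "qq_discovery.tsv")
  w(bundle$hits, "hits.tsv")
  w(bundle$replication$table, "replication.tsv")
  if (!is.null(bundle$score)) {
    w(bundle$score$score, "composite_score.tsv")
    w(bundle$score$deciles, "score_deciles.tsv")
    w(bundle$score$r2Curve, "score_r2_curve.tsv")
  }
  w(bundle$expression$cpgExpr, "cpg_expression.tsv")
  w(bundle$expression$exprBmi, "expression_bmi.tsv")
  w(bundle$threeWay, "three_way.tsv")
  w(bundle$forwardMr, "mr_forward.tsv")
  w(bundle$reverseMr, "mr_reverse.tsv")
  w(bundle$attenuation, "meqtl_attenuation.tsv")
  w(bundle$manifest, "manifest.tsv")
  invisible(outDir)
}
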