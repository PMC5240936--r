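# Float-safety constants for p <-> z conversion (documented design
# choice): two-sided p-values below .P_FLOOR are clamped before the
# quantile transform and |z| is capped at .Z_CAP.
.P_FLOOR <- 1e-300
.Z_CAP <- 38

#' Signed Z statistic from a two-sided p-value and direction
#'
#' `z = sign(direction) * qnorm(1 - p/2)`, the METAL-style conversion
#' used when per-cohort effect sizes are not on a common scale and only
#' (p, direction, n) is propagated to meta-analysis.
#'
#' @param p two-sided p-value(s) in (0, 1]
#' @param direction `"+"`/`"-"` (or +1/-1) per p-value
#' @return signed standard-normal statistic(s)
#' @examples
#' signedZFromP(0.05, "+")   # 1.95996
#' @export
signedZFromP <- function(p, direction) {
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  if (any(p < .P_FLOOR, na.rm = TRUE)) {
    warning("p-values below ", .P_FLOOR, " clamped before z conversion")
    p <- pmax(p, .P_FLOOR)
  }
  s <- if (is.character(direction)) ifelse(direction == "+", 1, -1)
       else sign(direction)
  z <- s * qnorm(1 - p / 2)
  pmin(pmax(z, -.Z_CAP), .Z_CAP)
}

#' Sample-size-weighted (Stouffer) meta-analysis of one feature
#'
#' Combines per-cohort two-sided p-values and directions with weights
#' `sqrt(n_i)`: `z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))`. Effect sizes
#' never enter, so cohorts with non-comparable regression scales can be
#' combined. Directional consistency is the requirement that every
#' cohort's sign agrees.
#'
#' @param records data.frame with columns `p`, `direction`, `n` (one row
#'   per cohort or per cohort stratum)
#' @return one-row data.frame: `z`, `p`, `directions` (e.g. `"++-"`),
#'   `direction_consistent`, `n_total`
#' @examples
#' stoufferMeta(data.frame(p = c(0.01, 0.03), direction = c("+", "+"),
#'                         n = c(500, 500)))
#' @export
stoufferMeta <- function(records) {
  if (!nrow(records)) stop("no cohort records supplied")
  if (any(records$n <= 0)) stop("all n must be > 0")
  z <- signedZFromP(records$p, records$direction)
  zc <- sum(sqrt(records$n) * z) / sqrt(sum(records$n))
  dirs <- ifelse(z >= 0, "+", "-")
  data.frame(z = zc, p = 2 * pnorm(-abs(zc)),
             directions = paste(dirs, collapse = ""),
             direction_consistent = length(unique(dirs)) == 1L,
             n_total = sum(records$n), stringsAsFactors = FALSE)
}

#' Meta-analyse per-cohort EWAS results across a CpG panel
#'
#' Applies [stoufferMeta()] per CpG over a list of per-cohort EWAS record
#' tables (as returned by [runEwas()]); cohorts missing a CpG are skipped
#' for that CpG. Significance is gated at `alpha / mTests` (Bonferroni;
#' `mTests` defaults to the number of CpGs meta-analysed).
#'
#' @param ewasList list of data.frames with `cpg_id`, `p`, `direction`, `n`
#' @param alpha family-wise error rate
#' @param mTests number of tests for the Bonferroni gate
#' @return data.frame: `cpg_id`, `z`, `p`, `directions`,
#'   `direction_consistent`, `n_total`, `significant`
#' @export
metaEwas <- function(ewasList, alpha = 0.05, mTests = NULL) {
  if (!length(ewasList)) stop("no cohort EWAS tables supplied")
  cpgs <- unique(unlist(lapply(ewasList, `[[`, "cpg_id")))
  sameOrder <- all(vapply(ewasList, function(d)
    identical(d$cpg_id, cpgs), logical(1)))
  if (sameOrder) {
    # vectorised path: every cohort reports the same CpG panel
    Z <- vapply(ewasList, function(d) signedZFromP(d$p, d$direction),
                numeric(length(cpgs)))
    Z <- matrix(Z, nrow = length(cpgs))
    nTot <- vapply(ewasList, function(d) d$n, numeric(length(cpgs)))
    nTot <- matrix(nTot, nrow = length(cpgs))
    zc <- rowSums(sqrt(nTot) * Z) / sqrt(rowSums(nTot))
    dirs <- apply(Z >= 0, 1L, function(s)
      paste(ifelse(s, "+", "-"), collapse = ""))
    res <- data.frame(cpg_id = cpgs, z = zc, p = 2 * pnorm(-abs(zc)),
                      directions = dirs,
                      direction_consistent = apply(Z >= 0, 1L, function(s)
                        length(unique(s)) == 1L),
                      n_total = rowSums(nTot), stringsAsFactors = FALSE)
  } else {
    rows <- lapply(cpgs, function(cg) {
      rec <- do.call(rbind, lapply(ewasList, function(d)
        d[d$cpg_id == cg, c("p", "direction", "n")]))
      cbind(cpg_id = cg, stoufferMeta(rec), stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
  }
  thr <- bonferroniThreshold(alpha, mTests %||% nrow(res))
  res$significant <- res$p < thr
  rownames(res) <- NULL
  res
}

#' Genomic inflation factor
#'
#' `lambda = median(z^2) / qchisq(0.5, 1)` — the ratio of the observed
#' median test chi-square to the null chi-square(1) median (0.4549364).
#' Values near 1 indicate calibrated tests; inflation suggests residual
#' confounding or true polygenicity.
#'
#' @param z vector of test statistics on the standard-normal scale
#' @return list with `lambda` and `nTests`
#' @export
genomicInflation <- function(z) {
  z <- z[!is.na(z)]
  if (!length(z)) stop("no test statistics supplied")
  if (length(z) < 100L)
    warning("genomic inflation estimated from < 100 tests is unstable")
  list(lambda = median(z^2) / qchisq(0.5, 1), nTests = length(z))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0, 1)
#' @param m number of tests (>= 1)
#' @return `alpha / m`
#' @examples
#' bonferroniThreshold(0.05, 405000)  # 1.2e-7
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Adjudicate external replication of discovery hits
#'
#' The replication gate is `alpha / n_discovery_hits` (Bonferroni over
#' the CpGs taken forward). A CpG replicates when the meta-analysis of
#' the replication cohorts reaches that threshold with the same direction
#' as discovery. Per-cohort pass flags (same threshold and direction
#' requirement within each cohort) are reported alongside; cohorts
#' missing a CpG are excluded from that CpG's test but the CpG stays in
#' the meta-analysis over available cohorts.
#'
#' @param discoveryHits data.frame of discovery [metaEwas()] records
#'   (typically the significant subset) with `cpg_id` and `z` or
#'   `directions`
#' @param replicationList list of per-cohort EWAS tables
#' @param alpha family-wise error rate
#' @return list: `replicated` (character vector of CpG IDs), `threshold`,
#'   and `table` (per CpG: replication meta z/p/direction, discovery
#'   direction, per-cohort pass flags)
#' @export
adjudicateReplication <- function(discoveryHits, replicationList,
                                  alpha = 0.05) {
  if (!nrow(discoveryHits)) stop("discovery hit set is empty")
  thr <- bonferroniThreshold(alpha, nrow(discoveryHits))
  discDir <- if ("z" %in% names(discoveryHits))
    ifelse(discoveryHits$z >= 0, "+", "-")
  else substr(discoveryHits$directions, 1L, 1L)
  rows <- lapply(seq_len(nrow(discoveryHits)), function(i) {
    cg <- discoveryHits$cpg_id[i]
    rec <- do.call(rbind, lapply(replicationList, function(d)
      d[d$cpg_id == cg, c("p", "direction", "n")]))
    passes <- vapply(replicationList, function(d) {
      r <- d[d$cpg_id == cg, ]
      if (!nrow(r)) NA else r$p < thr && r$direction == discDir[i]
    }, logical(1))
    names(passes) <- paste0("pass_", names(replicationList) %||%
                              seq_along(replicationList))
    if (is.null(rec) || !nrow(rec)) {
      base <- data.frame(cpg_id = cg, z = NA_real_, p = NA_real_,
                         direction = NA_character_,
                         discovery_direction = discDir[i],
                         replicated = FALSE, stringsAsFactors = FALSE)
    } else {
      m <- stoufferMeta(rec)
      base <- data.frame(cpg_id = cg, z = m$z, p = m$p,
                         direction = if (m$z >= 0) "+" else "-",
                         discovery_direction = discDir[i],
                         replicated = m$p < thr &&
                           (m$z >= 0) == (discDir[i] == "+"),
                         stringsAsFactors = FALSE)
    }
    cbind(base, as.data.frame(as.list(passes)))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(replicated = tab$cpg_id[tab$replicated], threshold = thr,
       table = tab)
}

#' QQ-plot coordinates for a p-value set
#'
#' Expected versus observed -log10 p under the uniform null, ready for
#' plotting or writing as TSV.
#'
#' @param p vector of p-values
#' @return data.frame with `expected` and `observed`, sorted
#' @export
qqData <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(p))
}
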