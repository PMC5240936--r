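.writeTsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write phenotype tables
#'
#' Tab-separated, one header row. Reading validates the invariants:
#' `sample_id` present and duplicate-free, `bmi` and `age` positive.
#'
#' @param phenotypes data.frame as in [CohortDataset-class]
#' @param path file path
#' @return `readPhenotypes()` returns the validated data.frame
#' @export
writePhenotypes <- function(phenotypes, path) .writeTsv(phenotypes, path)

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d)) stop("phenotype file lacks sample_id")
  d$sample_id <- as.character(d$sample_id)
  if (anyNA(d$sample_id)) stop("missing sample_id values")
  if (anyDuplicated(d$sample_id)) stop("duplicated sample_id values")
  for (col in c("bmi", "age"))
    if (col %in% names(d) && any(d[[col]] <= 0, na.rm = TRUE))
      stop(col, " must be > 0 (row ",
           which(d[[col]] <= 0)[1], ")")
  d
}

#' Read and write feature-by-sample matrices as TSV
#'
#' First column holds the feature ID, remaining columns one sample each.
#' Reading validates numeric cells (and an optional value range),
#' reporting the offending row/column on failure.
#'
#' @param m numeric matrix with feature rownames and sample colnames
#' @param path file path
#' @param idCol header name of the feature-ID column
#' @param range optional `c(low, high)` validity range for values
#' @return `readMatrixTsv()` returns the numeric matrix
#' @export
writeMatrixTsv <- function(m, path, idCol = "feature_id") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- idCol
  .writeTsv(d, path)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(path, idCol = NULL, range = NULL) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("matrix file needs an ID column plus samples")
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    num <- suppressWarnings(array(as.numeric(m), dim(m)))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    bad <- bad[1, , drop = TRUE]
    stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                 bad[1], colnames(m)[bad[2]], basename(path)))
  }
  if (!is.null(range)) {
    out <- which(m < range[1] | m > range[2], arr.ind = TRUE)
    if (nrow(out))
      stop(sprintf(
        "value %g outside [%g, %g] at feature '%s', sample '%s' in %s",
        m[out[1, 1], out[1, 2]], range[1], range[2], ids[out[1, 1]],
        colnames(m)[out[1, 2]], basename(path)))
  }
  rownames(m) <- ids
  m
}

#' Write one cohort as a directory of TSV files
#'
#' Emits `phenotypes.tsv`, `methylation.tsv` + `cpg_annotation.tsv`,
#' `genotypes.tsv` + `snp_annotation.tsv`, `expression.tsv` +
#' `gene_annotation.tsv`. [readCohort()] reverses this, aligning the
#' components by intersecting sample IDs (intersection size reported;
#' empty intersection is an error).
#'
#' @param cohort a [CohortDataset-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(phenotypes(cohort), file.path(dir, "phenotypes.tsv"))
  writeMatrixTsv(betaValues(cohort), file.path(dir, "methylation.tsv"),
                 "cpg_id")
  .writeTsv(cpgAnnotation(cohort), file.path(dir, "cpg_annotation.tsv"))
  writeMatrixTsv(dosages(cohort), file.path(dir, "genotypes.tsv"),
                 "snp_id")
  .writeTsv(snpAnnotation(cohort), file.path(dir, "snp_annotation.tsv"))
  writeMatrixTsv(exprValues(cohort), file.path(dir, "expression.tsv"),
                 "gene_id")
  .writeTsv(geneAnnotation(cohort), file.path(dir, "gene_annotation.tsv"))
  invisible(dir)
}

#' @rdname writeCohort
#' @param cohortId label for the reassembled dataset
#' @export
readCohort <- function(dir, cohortId = basename(dir)) {
  ph <- readPhenotypes(file.path(dir, "phenotypes.tsv"))
  beta <- readMatrixTsv(file.path(dir, "methylation.tsv"), range = c(0, 1))
  dose <- readMatrixTsv(file.path(dir, "genotypes.tsv"), range = c(0, 2))
  expr <- readMatrixTsv(file.path(dir, "expression.tsv"))
  ids <- Reduce(intersect, list(ph$sample_id, colnames(beta),
                                colnames(dose), colnames(expr)))
  if (!length(ids)) stop("no samples shared across the cohort components")
  message("aligned ", length(ids), " shared samples in ", dir)
  ph <- ph[match(ids, ph$sample_id), , drop = FALSE]
  cohortDataset(
    phenotypes = ph, beta = beta[, ids, drop = FALSE],
    cpgAnnotation = read.delim(file.path(dir, "cpg_annotation.tsv"),
                               stringsAsFactors = FALSE),
    dosage = dose[, ids, drop = FALSE],
    snpAnnotation = read.delim(file.path(dir, "snp_annotation.tsv"),
                               stringsAsFactors = FALSE),
    expr = expr[, ids, drop = FALSE],
    geneAnnotation = read.delim(file.path(dir, "gene_annotation.tsv"),
                                stringsAsFactors = FALSE),
    cohortId = cohortId)
}

#' Write genotypes as a minimal VCFv4.2
#'
#' One row per SNP with GT as the only FORMAT field and one sample
#' column per individual; dosages are rounded to {0,1,2} and encoded
#' 0/0, 0/1, 1/1 (REF A, ALT G). [readVcfDosages()] parses any VCF with
#' GT calls back to a dosage matrix (count of ALT alleles) using
#' Bioconductor's VariantAnnotation.
#'
#' @param cohort a [CohortDataset-class] (its genotype assay is written)
#' @param path output `.vcf` path
#' @return invisibly, `path`
#' @export
writeVcfDosages <- function(cohort, path) {
  D <- round(dosages(cohort))
  sa <- snpAnnotation(cohort)
  gt <- matrix(c("0/0", "0/1", "1/1")[D + 1L], nrow = nrow(D))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(D)),
                     collapse = "\t")), con)
  body <- cbind(sub("^chr", "", sa$chrom), format(sa$pos, scientific = FALSE,
                                                  trim = TRUE),
                sa$snp_id, "A", "G", ".", ".", ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname writeVcfDosages
#' @return `readVcfDosages()` returns a list with `dosage` (SNP x sample
#'   matrix) and `annotation` (snp_id, chrom, pos)
#' @export
readVcfDosages <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  count1 <- function(s) {
    a <- strsplit(s, "[/|]")
    vapply(a, function(x) sum(x == "1"), numeric(1))
  }
  dose <- matrix(count1(as.vector(gt)), nrow = nrow(gt),
                 dimnames = dimnames(gt))
  rr <- SummarizedExperiment::rowRanges(vcf)
  list(dosage = dose,
       annotation = data.frame(
         snp_id = names(rr),
         chrom = as.character(GenomeInfoDb::seqnames(rr)),
         pos = BiocGenerics::start(rr), stringsAsFactors = FALSE))
}

#' Write and read the ground-truth manifest as TSV
#'
#' Two files: `<prefix>_cpg.tsv` and `<prefix>_snp.tsv`.
#'
#' @param truth a [GroundTruth-class]
#' @param prefix path prefix
#' @return `readGroundTruth()` returns a [GroundTruth-class]
#' @export
writeGroundTruth <- function(truth, prefix) {
  .writeTsv(cpgTruth(truth), paste0(prefix, "_cpg.tsv"))
  .writeTsv(snpTruth(truth), paste0(prefix, "_snp.tsv"))
  invisible(prefix)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(prefix) {
  new("GroundTruth",
      cpg = read.delim(paste0(prefix, "_cpg.tsv"),
                       stringsAsFactors = FALSE),
      snp = read.delim(paste0(prefix, "_snp.tsv"),
                       stringsAsFactors = FALSE))
}
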