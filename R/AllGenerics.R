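#' @rdname CohortDataset-class
#' @param x a `CohortDataset`
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname CohortDataset-class
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname CohortDataset-class
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname CohortDataset-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname CohortDataset-class
#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))

#' @rdname CohortDataset-class
#' @export
setGeneric("cpgAnnotation", function(x) standardGeneric("cpgAnnotation"))

#' @rdname CohortDataset-class
#' @export
setGeneric("snpAnnotation", function(x) standardGeneric("snpAnnotation"))

#' @rdname CohortDataset-class
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))

#' @rdname GroundTruth-class
#' @param x a `GroundTruth`
#' @export
setGeneric("cpgTruth", function(x) standardGeneric("cpgTruth"))

#' @rdname GroundTruth-class
#' @export
setGeneric("snpTruth", function(x) standardGeneric("snpTruth"))
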