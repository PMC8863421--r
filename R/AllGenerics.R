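#' Extract the M-value matrix
#' @param x an [MValueSet-class]
#' @return numeric matrix, CpGs x samples.
#' @export
setGeneric("mValues", function(x) standardGeneric("mValues"))

#' Correction stage of an M-value container
#' @param x an [MValueSet-class]
#' @return `"raw"`, `"technical"` or `"biological"`.
#' @export
setGeneric("correctionStage", function(x) standardGeneric("correctionStage"))

#' CpG position table (0-based starts)
#' @param x an [MValueSet-class]
#' @return data.frame with `cpg_id`, `chrom`, `start`, `end`.
#' @export
setGeneric("cpgPositions", function(x) standardGeneric("cpgPositions"))

#' Relationship matrices of a set
#' @param x a [RelationshipMatrixSet-class]
#' @param which optional component labels to extract.
#' @return named list of matrices.
#' @export
setGeneric("relMatrices", function(x, which = NULL) standardGeneric("relMatrices"))

#' Batch assignments of a relationship-matrix set
#' @param x a [RelationshipMatrixSet-class]
#' @return data.frame of per-sample batch variables.
#' @export
setGeneric("batchInfo", function(x) standardGeneric("batchInfo"))

#' Planted causal sites of a simulation
#' @param x a [SimTruth-class]
#' @param phenotype optional phenotype name filter.
#' @return data.frame with `phenotype`, `cpg_id`, `slope`.
#' @export
setGeneric("causalSites", function(x, phenotype = NULL) standardGeneric("causalSites"))

#' @rdname mValues
setMethod("mValues", "MValueSet", function(x)
  SummarizedExperiment::assay(x, "M"))

#' @rdname correctionStage
setMethod("correctionStage", "MValueSet", function(x) x@stage)

#' @rdname cpgPositions
setMethod("cpgPositions", "MValueSet", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(cpg_id = names(rr),
             chrom = as.character(GenomicRanges::seqnames(rr)),
             start = GenomicRanges::start(rr) - 1L,
             end = GenomicRanges::end(rr),
             stringsAsFactors = FALSE)
})

#' @rdname relMatrices
setMethod("relMatrices", "RelationshipMatrixSet", function(x, which = NULL) {
  if (is.null(which)) return(x@matrices)
  bad <- setdiff(which, names(x@matrices))
  if (length(bad)) stop("unknown component(s): ", paste(bad, collapse = ", "))
  x@matrices[which]
})

#' @rdname batchInfo
setMethod("batchInfo", "RelationshipMatrixSet", function(x) x@batch)

#' @rdname causalSites
setMethod("causalSites", "SimTruth", function(x, phenotype = NULL) {
  if (is.null(phenotype)) return(x@causal)
  x@causal[x@causal$phenotype %in% phenotype, , drop = FALSE]
})

setMethod("show", "MValueSet", function(object) {
  cat("MValueSet:", nrow(object), "CpGs x", ncol(object), "samples",
      sprintf("[stage: %s]\n", object@stage))
  callNextMethod()
})

setMethod("show", "RelationshipMatrixSet", function(object) {
  n <- nrow(object@matrices[["K"]])
  cat("RelationshipMatrixSet:", n, "samples; components",
      paste(names(object@matrices), collapse = "/"), "\n")
  cat(" batch variables:", paste(names(object@batch), collapse = ", "), "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@causal), "planted causal CpG effects over",
      length(unique(object@causal$phenotype)), "phenotype(s)\n")
  if (any(object@cellSeason != 0))
    cat(" seasonal cell-composition amplitudes:",
        paste(sprintf("%s=%.2f", names(object@cellSeason), object@cellSeason),
              collapse = ", "), "\n")
})

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign:", object@nIndividuals, "individuals,",
      object@nCpgs, "CpGs,", object@nCausal, "causal sites/phenotype\n")
  vf <- object@varFractions
  cat(" variance fractions:",
      paste(sprintf("%s=%.2f", names(vf), vf), collapse = " "),
      sprintf("resid=%.2f\n", 1 - sum(vf)))
  cat(" prevalences:",
      paste(sprintf("%s=%.3f", names(object@prevalences), object@prevalences),
            collapse = " "), "| seed:", object@seed, "\n")
})
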