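#' @import methods
NULL

#' Design of a simulated family-structured methylome cohort
#'
#' A `CohortDesign` captures every knob of the synthetic cohort generator:
#' cohort and methylome size, the mix of family types, planted CpG-phenotype
#' effects, the variance decomposition of each CpG into familial
#' (G/K/F/C/S), batch (plate, blood-draw date), cell-composition and residual
#' components, and the prevalence of each binary phenotype (drawn by a
#' liability-threshold model).
#'
#' Variance fractions are proportions of per-CpG variance and must sum to at
#' most 1; the remainder is independent residual noise. The `G` component
#' defaults to 0 with its share folded into `K` (common-genetic and kinship
#' covariance collapse to one matrix unless distinct fractions are supplied).
#'
#' @slot nIndividuals integer, number of samples.
#' @slot nCpgs integer, number of CpG probes.
#' @slot familyMix named numeric, sampling weights over family types
#'   `couples` (two founders), `trios` (founders + 1 child) and `sibships`
#'   (founders + 2-3 children).
#' @slot nCausal integer, causal CpGs per phenotype.
#' @slot effectSize numeric, liability slope per causal CpG (per M-value unit).
#' @slot varFractions named numeric over
#'   `G, K, F, C, S, plate, date, cell`, each in `[0, 1]`.
#' @slot prevalences named numeric in (0, 1), one per binary phenotype.
#' @slot liabilityFamilial numeric, share of phenotype liability variance
#'   with kinship covariance.
#' @slot cellSeasonAmplitude numeric, amplitude (in SD units) of the seasonal
#'   birth-date modulation of lymphocyte/granulocyte composition.
#' @slot seed integer, global seed feeding per-stage RNG streams.
#'
#' @export
setClass("CohortDesign", representation(
  nIndividuals = "integer",
  nCpgs = "integer",
  familyMix = "numeric",
  nCausal = "integer",
  effectSize = "numeric",
  varFractions = "numeric",
  prevalences = "numeric",
  liabilityFamilial = "numeric",
  cellSeasonAmplitude = "numeric",
  seed = "integer"
))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (object@nIndividuals < 2L) msg <- c(msg, "nIndividuals must be >= 2")
  if (object@nCpgs < 1L) msg <- c(msg, "nCpgs must be >= 1")
  if (object@nCausal > object@nCpgs)
    msg <- c(msg, "nCausal exceeds nCpgs")
  vf <- object@varFractions
  need <- c("G", "K", "F", "C", "S", "plate", "date", "cell")
  if (!all(need %in% names(vf)))
    msg <- c(msg, paste("varFractions must name:", paste(need, collapse = ", ")))
  else {
    if (any(vf < 0 | vf > 1)) msg <- c(msg, "variance fractions must lie in [0, 1]")
    if (sum(vf) > 1 + 1e-12)
      msg <- c(msg, "variance fractions sum to more than 1 (invalid design)")
  }
  if (any(object@prevalences <= 0 | object@prevalences >= 1))
    msg <- c(msg, "prevalences must lie strictly in (0, 1)")
  mix <- object@familyMix
  if (!all(c("couples", "trios", "sibships") %in% names(mix)) ||
      any(mix < 0) || sum(mix) <= 0)
    msg <- c(msg, "familyMix must be non-negative weights over couples/trios/sibships")
  if (length(msg)) msg else TRUE
})

#' Construct a cohort design
#'
#' @param nIndividuals number of samples to simulate.
#' @param nCpgs number of CpG probes.
#' @param familyMix named weights over family types.
#' @param nCausal causal CpGs per phenotype.
#' @param effectSize planted liability slope per causal CpG.
#' @param varFractions named per-CpG variance shares (see [CohortDesign-class]).
#' @param prevalences named binary-phenotype prevalences; defaults are the
#'   cohort rates the pipeline is designed around (3.5% preterm birth,
#'   13% MDD).
#' @param liabilityFamilial kinship-structured share of liability variance.
#' @param cellSeasonAmplitude seasonal cell-composition amplitude (SD units);
#'   0 disables the birth-date/cell-count coupling.
#' @param seed global integer seed.
#' @return A validated [CohortDesign-class] object.
#' @examples
#' cohortDesign(nIndividuals = 100, nCpgs = 50)
#' @export
cohortDesign <- function(nIndividuals = 500L,
                         nCpgs = 2000L,
                         familyMix = c(couples = 0.3, trios = 0.4, sibships = 0.3),
                         nCausal = 5L,
                         effectSize = 0.3,
                         varFractions = c(G = 0, K = 0.15, F = 0.05, C = 0.02,
                                          S = 0.03, plate = 0.10, date = 0.05,
                                          cell = 0),
                         prevalences = c(preterm = 0.035, mdd = 0.13),
                         liabilityFamilial = 0.2,
                         cellSeasonAmplitude = 0,
                         seed = 1L) {
  new("CohortDesign",
      nIndividuals = as.integer(nIndividuals),
      nCpgs = as.integer(nCpgs),
      familyMix = familyMix,
      nCausal = as.integer(nCausal),
      effectSize = effectSize,
      varFractions = varFractions,
      prevalences = prevalences,
      liabilityFamilial = liabilityFamilial,
      cellSeasonAmplitude = cellSeasonAmplitude,
      seed = as.integer(seed))
}

#' Set of sample-by-sample relationship matrices plus batch assignments
#'
#' Holds the five covariance structures used by the familial correction and
#' the simulator: `G` (common genetic), `K` (kinship/additive relationship),
#' `F` (nuclear family), `C` (couple) and `S` (sibling), together with the
#' per-sample batch frame (plate, plate position, blood-draw date,
#' measurement set, family id).
#'
#' @slot matrices named list of five symmetric PSD matrices with unit
#'   diagonal.
#' @slot batch data.frame of per-sample batch assignments.
#' @export
setClass("RelationshipMatrixSet", representation(
  matrices = "list",
  batch = "data.frame"
))

setValidity("RelationshipMatrixSet", function(object) {
  msg <- character()
  need <- c("G", "K", "F", "C", "S")
  if (!all(need %in% names(object@matrices)))
    return(paste("matrices must be named", paste(need, collapse = ", ")))
  for (nm in need) {
    A <- object@matrices[[nm]]
    if (!is.matrix(A) || nrow(A) != ncol(A))
      msg <- c(msg, paste(nm, "is not square"))
    else {
      if (!isSymmetric(unname(A), tol = 1e-8))
        msg <- c(msg, paste(nm, "is not symmetric"))
      if (max(abs(diag(A) - 1)) > 1e-8)
        msg <- c(msg, paste(nm, "diagonal entries must equal 1"))
      off <- A[upper.tri(A)]
      if (length(off) && (min(off) < -1e-8 || max(off) > 1 + 1e-8))
        msg <- c(msg, paste(nm, "off-diagonal entries must lie in [0, 1]"))
      if (!isPSD(A)) msg <- c(msg, paste(nm, "is not positive semidefinite"))
    }
  }
  n <- nrow(object@matrices[["K"]])
  if (nrow(object@batch) != n)
    msg <- c(msg, "batch frame rows must match matrix dimension")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated cohort
#'
#' Records what the generator planted so recovery can be tested: causal CpG
#' ids and slopes per phenotype, and the per-cell-type seasonal shift tied to
#' birth date.
#'
#' @slot causal data.frame with columns `phenotype`, `cpg_id`, `slope`.
#' @slot cellSeason named numeric, per-cell-column seasonal amplitude.
#' @export
setClass("SimTruth", representation(
  causal = "data.frame",
  cellSeason = "numeric"
))

#' CpG-by-sample M-value container
#'
#' Extends `RangedSummarizedExperiment` with a correction-stage flag. The
#' single assay `M` holds log2(methylated/unmethylated) intensity ratios;
#' `rowRanges` carries CpG coordinates (0-based starts internally, BED
#' convention on disk).
#'
#' @slot stage character, one of `raw`, `technical`, `biological`.
#' @export
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
setClass("MValueSet",
         contains = "RangedSummarizedExperiment",
         representation(stage = "character"))

setValidity("MValueSet", function(object) {
  msg <- character()
  if (!"M" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'M' is required")
  else if (any(!is.finite(SummarizedExperiment::assay(object, "M"))))
    msg <- c(msg, "M-values must all be finite")
  if (!object@stage %in% c("raw", "technical", "biological"))
    msg <- c(msg, "stage must be raw/technical/biological")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate CpG ids")
  if (length(msg)) msg else TRUE
})

#' Construct an MValueSet
#'
#' @param M numeric matrix, CpGs in rows (rownames = CpG ids), samples in
#'   columns (colnames = sample ids).
#' @param positions data.frame with columns `cpg_id`, `chrom`, `start`
#'   (0-based) and optionally `end`; rows matched to `rownames(M)`.
#' @param stage correction stage flag.
#' @param colData optional per-sample `DataFrame`.
#' @return An [MValueSet-class].
#' @export
MValueSet <- function(M, positions, stage = "raw", colData = NULL) {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)))
  if (anyDuplicated(positions$cpg_id))
    stop("duplicate cpg_id in positions table")
  idx <- match(rownames(M), positions$cpg_id)
  if (anyNA(idx)) stop("positions table is missing some CpG ids present in M")
  positions <- positions[idx, , drop = FALSE]
  end <- if ("end" %in% names(positions)) positions$end else positions$start + 1L
  rr <- GenomicRanges::GRanges(
    seqnames = positions$chrom,
    ranges = IRanges::IRanges(start = positions$start + 1L, end = end),
    cpg_id = positions$cpg_id)
  names(rr) <- positions$cpg_id
  if (is.null(colData)) colData <- S4Vectors::DataFrame(row.names = colnames(M))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(M = M), rowRanges = rr, colData = colData)
  new("MValueSet", se, stage = stage)
}
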