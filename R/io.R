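#' Readers and writers for the pipeline's plain-text interchange formats
#'
#' All tables travel as TSV (gzip transparently supported by the readers),
#' CpG coordinates as BED (0-based half-open, matching the package's
#' internal convention), gene sets as GMT. Readers validate schemas and
#' report offending line numbers; every writer/reader pair round-trips to
#' the identical canonical file.
#'
#' @name stressmwasIO
NULL

#' @describeIn stressmwasIO Write a CpG-by-sample M-value matrix (first
#'   column `cpg_id`, one column per sample).
#' @param mset an [MValueSet-class] or matrix with dimnames.
#' @param path output file.
#' @export
writeMValueTSV <- function(mset, path) {
  M <- if (is(mset, "MValueSet")) mValues(mset) else mset
  dt <- data.table::data.table(cpg_id = rownames(M))
  dt <- cbind(dt, data.table::as.data.table(M))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @describeIn stressmwasIO Read an M-value matrix written by
#'   [writeMValueTSV()]; errors name the line of any duplicate CpG id.
#' @export
readMValueTSV <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != "cpg_id")
    stop("malformed header in ", path, ": first column must be 'cpg_id'")
  dup <- which(duplicated(dt$cpg_id))
  if (length(dup))
    stop("duplicate cpg_id '", dt$cpg_id[dup[1]], "' at line ", dup[1] + 1L,
         " of ", path)
  M <- as.matrix(dt[, -1])
  rownames(M) <- dt$cpg_id
  M
}

#' @describeIn stressmwasIO Write CpG positions as 4-column BED
#'   (chrom, 0-based start, end, cpg_id; no header).
#' @param positions data.frame `cpg_id`, `chrom`, `start`, `end`.
#' @export
writeBed <- function(positions, path) {
  data.table::fwrite(positions[, c("chrom", "start", "end", "cpg_id")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @describeIn stressmwasIO Read a 4-column BED of CpG positions.
#' @param one_based set `TRUE` if the file's starts are 1-based; they are
#'   converted to the internal 0-based convention.
#' @export
readBed <- function(path, one_based = FALSE) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "cpg_id"))
  bad <- which(dt$end <= dt$start)
  if (length(bad))
    stop("coordinate violation (end <= start) at line ", bad[1], " of ", path)
  dup <- which(duplicated(dt$cpg_id))
  if (length(dup))
    stop("duplicate cpg_id '", dt$cpg_id[dup[1]], "' at line ", dup[1],
         " of ", path)
  out <- as.data.frame(dt[, c("cpg_id", "chrom", "start", "end")])
  if (one_based) out$start <- out$start - 1L
  out
}

#' @describeIn stressmwasIO Write a sample/phenotype table.
#' @param samples data.frame with a `sample_id` column.
#' @export
writeSampleTSV <- function(samples, path) {
  data.table::fwrite(samples, path, sep = "\t")
  invisible(path)
}

#' @describeIn stressmwasIO Read a sample/phenotype table; `sample_id`
#'   must be present and unique.
#' @export
readSampleTSV <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!"sample_id" %in% names(dt))
    stop("malformed header in ", path, ": 'sample_id' column required")
  dup <- which(duplicated(dt$sample_id))
  if (length(dup))
    stop("duplicate sample_id '", dt$sample_id[dup[1]], "' at line ",
         dup[1] + 1L, " of ", path)
  as.data.frame(dt)
}

#' @describeIn stressmwasIO Write a labelled square relationship matrix.
#' @param A square numeric matrix with dimnames.
#' @export
writeRelMatrixTSV <- function(A, path) {
  dt <- data.table::data.table(sample_id = rownames(A))
  dt <- cbind(dt, data.table::as.data.table(A))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @describeIn stressmwasIO Read a labelled square relationship matrix.
#' @export
readRelMatrixTSV <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  A <- as.matrix(dt[, -1])
  rownames(A) <- dt$sample_id
  if (nrow(A) != ncol(A) || !identical(rownames(A), colnames(A)))
    stop(path, " is not a labelled square matrix")
  A
}

#' @describeIn stressmwasIO Read a GMT gene-set file (name, description,
#'   then >= 1 gene per line); malformed lines are reported by number.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf < 3L & nzchar(lines))
  if (length(bad))
    stop("malformed GMT line ", bad[1], " in ", path,
         ": name, description and at least one gene required")
  fgsea::gmtPathways(path)
}

#' @describeIn stressmwasIO Write an association summary-statistics table.
#' @param table association table (`cpg_id`, `chrom`, `pos`, `effect`,
#'   `se`, `stat`, `p`, `n`, `engine`).
#' @export
writeSummaryTSV <- function(table, path) {
  need <- c("cpg_id", "chrom", "pos", "effect", "se", "stat", "p", "n",
            "engine")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("summary table missing column(s): ",
                         paste(miss, collapse = ", "))
  data.table::fwrite(table[, need], path, sep = "\t")
  invisible(path)
}

#' @describeIn stressmwasIO Read an association summary-statistics table.
#' @export
readSummaryTSV <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("cpg_id", "effect", "se", "p")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("malformed header in ", path, ": missing ",
                         paste(miss, collapse = ", "))
  dt
}

#' @describeIn stressmwasIO Read a FAM-like pedigree table (`family_id`,
#'   `sample_id`, `father_id`, `mother_id`, `sex`; 0/NA = founder).
#' @export
readPedigreeTSV <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("family_id", "sample_id", "father_id", "mother_id")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("malformed header in ", path, ": missing ",
                         paste(miss, collapse = ", "))
  dup <- which(duplicated(dt$sample_id))
  if (length(dup))
    stop("duplicate sample_id '", dt$sample_id[dup[1]], "' at line ",
         dup[1] + 1L, " of ", path)
  dt
}

#' Expected additive-relationship matrix from a pedigree
#'
#' Standard tabular (recursive) computation: founders are unrelated,
#' `A[i, j] = 0.5 * (A[j, father(i)] + A[j, mother(i)])` with parents
#' processed before offspring.
#'
#' @param ped data.frame from [readPedigreeTSV()].
#' @return symmetric matrix with unit diagonal (no inbreeding).
#' @export
kinshipFromPedigree <- function(ped) {
  ids <- ped$sample_id
  n <- length(ids)
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  # order so parents precede children
  depth <- rep(0L, n)
  repeat {
    d2 <- pmax(ifelse(is.na(fa), 0L, depth[fa] + 1L),
               ifelse(is.na(mo), 0L, depth[mo] + 1L))
    if (all(d2 == depth)) break
    depth <- d2
  }
  ord <- order(depth)
  A <- diag(n)
  for (i in ord) {
    for (j in seq_len(n)) {
      if (j == i) next
      aij <- 0.5 * ((if (is.na(fa[i])) 0 else A[j, fa[i]]) +
                      (if (is.na(mo[i])) 0 else A[j, mo[i]]))
      A[i, j] <- A[j, i] <- aij
    }
  }
  dimnames(A) <- list(ids, ids)
  A
}

#' Read and validate a run configuration
#'
#' YAML with fields `seed`, `out_dir`, optional `design` overrides
#' (`nIndividuals`, `nCpgs`, ...), `thresholds` (`alpha`,
#' `score_thresholds`) and `engines` (`mwas1`, `mwas2` logicals). Referenced
#' input paths must exist at validation.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$engines <- modifyList(list(mwas1 = TRUE, mwas2 = TRUE),
                            cfg$engines %||% list())
  thr <- modifyList(list(alpha = 0.05, score_thresholds = 10^-(7:1)),
                    cfg$thresholds %||% list())
  if (thr$alpha <= 0 || thr$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (any(thr$score_thresholds <= 0 | thr$score_thresholds > 1))
    stop("score thresholds must lie in (0, 1]")
  cfg$thresholds <- thr
  for (p in unlist(cfg$inputs %||% list()))
    if (!file.exists(p)) stop("configured input path does not exist: ", p)
  cfg
}

#' Run the end-to-end pipeline on a simulated cohort
#'
#' Orchestrates the full analysis in method order: cohort simulation,
#' technical correction, both association engines on a chosen phenotype,
#' inflation diagnostics and Miami export, and a discovery/target profile
#' score (Set 1 discovery, Set 2 scoring of the same phenotype). All
#' outputs are written to `out_dir` as TSV plus a JSON manifest with the
#' seed and an md5 checksum per file; re-running with the same seed
#' reproduces identical checksums.
#'
#' @param design a [CohortDesign-class] (its seed drives every stage).
#' @param out_dir output directory (created).
#' @param phenotype which simulated phenotype to analyse.
#' @param n_pcs methylome PCs for both engines.
#' @param run_mwas2 logical; the multi-component engine can be switched off
#'   for quick runs.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(design, out_dir, phenotype = "brs", n_pcs = 10L,
                        run_mwas2 = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  coh <- simulateCohort(design)
  if (!phenotype %in% names(coh$samples))
    stop("validation error: phenotype '", phenotype,
         "' is not produced by this design")
  cd <- as.data.frame(SummarizedExperiment::colData(coh$mset))
  tech <- correctTechnical(
    coh$mset,
    fixed = cd[, c("plate_position", "set", "clinic", "year", "weekday")])

  files <- list()
  wr <- function(name, writer, obj) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    files[[name]] <<- unname(tools::md5sum(p))
  }
  wr("samples.tsv", writeSampleTSV, coh$samples)
  wr("mvalues_corrected.tsv", writeMValueTSV, tech)
  wr("cpg_positions.bed", writeBed, cpgPositions(coh$mset))
  for (nm in names(relMatrices(coh$rel)))
    wr(paste0("relmatrix_", nm, ".tsv"), writeRelMatrixTSV,
       relMatrices(coh$rel)[[nm]])

  phen <- coh$samples[[phenotype]]
  t1 <- runMwas1(tech, phen, n_pcs = n_pcs)
  wr(paste0("mwas1_", phenotype, ".tsv"), writeSummaryTSV, t1)
  lam <- list(mwas1 = genomicInflation(t1$p)$lambda)
  if (run_mwas2) {
    t2 <- runMwas2(tech, phen, n_pcs = n_pcs)
    wr(paste0("mwas2_", phenotype, ".tsv"), writeSummaryTSV, t2)
    lam$mwas2 <- genomicInflation(t2$p)$lambda
    thr <- bonferroniThreshold(0.05, nrow(t1))
    wr("miami.tsv", function(obj, p) data.table::fwrite(obj, p, sep = "\t"),
       miamiExport(t1, t2, thr))
  }

  ## profile score: discovery in Set 1, scoring in Set 2
  set1 <- coh$samples$set == "Set1"
  disc <- runMwas1(tech[, set1], phen[set1], n_pcs = min(n_pcs, 5L))
  sweep <- tryCatch(
    thresholdSweep(disc, tech[, !set1], phen[!set1],
                   discovery_samples = coh$samples$sample_id[set1]),
    error = function(e) NULL)
  if (!is.null(sweep))
    wr(paste0("score_sweep_", phenotype, ".tsv"),
       function(obj, p) data.table::fwrite(obj, p, sep = "\t"), sweep)

  manifest <- list(package_version = as.character(utils::packageVersion("stressmwas")),
                   seed = design@seed, phenotype = phenotype,
                   lambda = lam, files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
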