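#' Bonferroni family-wise threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroniThreshold(0.05, 713522)   # methylome-wide line, ~7.01e-8
#' bonferroniThreshold(0.05, 8)        # eight phenotypes, 6.25e-3
#' @export
bonferroniThreshold <- function(alpha = 0.05, n_tests) {
  if (any(n_tests < 1)) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Genomic inflation factor
#'
#' `lambda` = median of the observed chi-squared statistics
#' (`qchisq(1 - p, df = 1)`) divided by the null median of the chi-squared
#' distribution with 1 df (~0.4549); ~1 for a well-calibrated test.
#'
#' @param p_values vector of P-values in (0, 1].
#' @return list: `lambda`, `n`.
#' @export
genomicInflation <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no valid P-values")
  if (any(p <= 0 | p > 1)) stop("P-values must lie in (0, 1]")
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  list(lambda = median(chi) / qchisq(0.5, df = 1), n = length(p))
}

#' QQ-plot coordinates with a 95% confidence band
#'
#' Observed order statistics of -log10(P) against uniform expectations
#' `(i - 0.5) / n`, with the pointwise beta-distribution 95% band of the
#' i-th order statistic.
#'
#' @param p_values vector of P-values.
#' @return data.frame: `expected`, `observed`, `lower`, `upper` (-log10
#'   scale), ordered so both axes are monotone.
#' @export
qqPoints <- function(p_values) {
  p <- sort(p_values[!is.na(p_values)])
  n <- length(p)
  if (!n) stop("no valid P-values")
  i <- seq_len(n)
  data.frame(expected = -log10((i - 0.5) / n),
             observed = -log10(p),
             lower = -log10(qbeta(0.975, i, n - i + 1)),
             upper = -log10(qbeta(0.025, i, n - i + 1)))[n:1, ]
}

#' Plot-ready Miami table for the two engines
#'
#' One row per probe in the union of the two tables, in genome order, with
#' the first engine's P-values on the log10 scale (negative, plotted
#' downwards) and the second's on the -log10 scale; probes missing from one
#' engine keep their row with an `NA` cell. The significance line sits at
#' `+/- log10(threshold)`.
#'
#' @param table_mwas1,table_mwas2 association tables (`cpg_id`, `chrom`,
#'   `pos`, `p`).
#' @param threshold significance threshold for the reference lines.
#' @return data.frame: `cpg_id`, `chrom`, `pos`, `log10p_mwas1` (<= 0),
#'   `neglog10p_mwas2` (>= 0), `sig_line_mwas1`, `sig_line_mwas2`.
#' @export
miamiExport <- function(table_mwas1, table_mwas2,
                        threshold = bonferroniThreshold(0.05, 713522)) {
  univ <- unique(rbind(table_mwas1[, c("cpg_id", "chrom", "pos")],
                       table_mwas2[, c("cpg_id", "chrom", "pos")]))
  chrnum <- suppressWarnings(as.integer(sub("^chr", "", univ$chrom)))
  univ <- univ[order(chrnum, univ$pos), ]
  out <- data.frame(
    univ,
    log10p_mwas1 = log10(table_mwas1$p[match(univ$cpg_id, table_mwas1$cpg_id)]),
    neglog10p_mwas2 = -log10(table_mwas2$p[match(univ$cpg_id,
                                                 table_mwas2$cpg_id)]),
    row.names = NULL)
  out$sig_line_mwas1 <- log10(threshold)
  out$sig_line_mwas2 <- -log10(threshold)
  out
}

#' Annotate significant CpG sites to genes
#'
#' @param table association table with `cpg_id` and `p`.
#' @param annotation data.frame `cpg_id`, `gene` (empty/NA = unannotated).
#' @param threshold significance threshold.
#' @return list: `genes` (unique annotated gene symbols), `unannotated`
#'   (significant CpGs without a gene), `sig_cpgs`.
#' @export
annotateSignificant <- function(table, annotation,
                                threshold = bonferroniThreshold(0.05, 713522)) {
  sig <- table$cpg_id[!is.na(table$p) & table$p < threshold]
  g <- annotation$gene[match(sig, annotation$cpg_id)]
  g[!is.na(g) & g == ""] <- NA
  list(genes = unique(g[!is.na(g)]),
       unannotated = sig[is.na(g)],
       sig_cpgs = sig)
}

#' Overlap of two annotated gene lists
#' @param genes1,genes2 character vectors.
#' @return character vector of shared genes.
#' @export
geneOverlap <- function(genes1, genes2) intersect(genes1, genes2)

# Upper tail P(X >= x) of Wallenius' noncentral hypergeometric
# distribution: m1 "white" items with odds `omega`, m2 others, n drawn.
# Exact integral representation with the substitution t = u^D, evaluated
# in log scale for stability; omega = 1 reduces to the central
# hypergeometric and is dispatched to phyper exactly.
pWalleniusTail <- function(x, m1, m2, n, omega) {
  if (omega == 1) return(phyper(x - 1, m1, m2, n, lower.tail = FALSE))
  support <- max(0, n - m2):min(n, m1)
  if (x > max(support)) return(0)
  if (x <= min(support)) return(1)
  logpmf <- function(k) {
    D <- omega * (m1 - k) + (m2 - (n - k))
    if (D <= 0) return(-Inf)
    # integral of D * (1-u^omega)^k (1-u)^(n-k) u^(D-1) du on (0,1)
    logf <- function(u) k * log1p(-u^omega) + (n - k) * log1p(-u) +
      (D - 1) * log(u)
    grid <- seq(1e-9, 1 - 1e-9, length.out = 512)
    M <- max(logf(grid))
    int <- integrate(function(u) exp(logf(u) - M), 0, 1,
                     rel.tol = 1e-10, subdivisions = 1000L)$value
    lchoose(m1, k) + lchoose(m2, n - k) + log(D) + M + log(int)
  }
  lp <- vapply(support, logpmf, 1.0)
  lp <- lp - max(lp)
  dens <- exp(lp)
  sum(dens[support >= x]) / sum(dens)   # normalized over the support
}

#' Gene-set over-representation with probe-number bias correction
#'
#' Maps significant and universe CpGs to genes, then tests each gene set
#' for over-representation of significant genes with Wallenius' noncentral
#' hypergeometric distribution, the odds weight of a set being the ratio
#' of mean probes-per-gene inside versus outside the set. Genes carrying
#' more probes are more likely to be hit by chance; the weight absorbs
#' that bias, and with equal probe counts the test reduces exactly to the
#' ordinary hypergeometric tail. Unadjusted and Benjamini-Hochberg
#' adjusted P-values are both reported.
#'
#' @param sig_cpgs character vector of significant CpG ids.
#' @param all_cpgs character vector of all analysed CpG ids.
#' @param annotation data.frame `cpg_id`, `gene`.
#' @param gene_sets named list of gene-id vectors (see [readGMT()]).
#' @return data.frame: `set`, `n_genes`, `n_sig`, `odds`, `p`, `fdr`.
#' @export
genesetEnrichment <- function(sig_cpgs, all_cpgs, annotation, gene_sets) {
  ann <- annotation[!is.na(annotation$gene) & annotation$gene != "", ]
  ann <- ann[ann$cpg_id %in% all_cpgs, ]
  probe_counts <- table(ann$gene)
  universe <- names(probe_counts)
  sig_genes <- unique(ann$gene[ann$cpg_id %in% sig_cpgs])
  n_draw <- length(sig_genes)
  res <- lapply(names(gene_sets), function(nm) {
    inset <- intersect(gene_sets[[nm]], universe)
    m1 <- length(inset)
    if (m1 == 0)
      return(data.frame(set = nm, n_genes = 0L, n_sig = 0L, odds = NA_real_,
                        p = NA_real_))
    m2 <- length(universe) - m1
    x <- length(intersect(sig_genes, inset))
    w_in <- mean(probe_counts[inset])
    w_out <- if (m2 > 0) mean(probe_counts[setdiff(universe, inset)]) else w_in
    omega <- w_in / w_out
    p <- if (n_draw == 0) 1 else pWalleniusTail(x, m1, m2, n_draw, omega)
    data.frame(set = nm, n_genes = m1, n_sig = x, odds = omega, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}
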