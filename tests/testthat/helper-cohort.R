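# Shared fixtures: small simulated cohorts and design shortcuts.

smallDesign <- function(n = 120, p = 80, seed = 11, ...) {
  cohortDesign(nIndividuals = n, nCpgs = p, nCausal = 2, seed = seed, ...)
}

# Pure-noise design: no familial, batch or cell structure.
noiseFractions <- c(G = 0, K = 0, F = 0, C = 0, S = 0,
                    plate = 0, date = 0, cell = 0)

techCovariates <- function(mset) {
  cd <- as.data.frame(SummarizedExperiment::colData(mset))
  cd[, c("plate_position", "set", "clinic", "year", "weekday")]
}

# Sibling index pairs from a pedigree's batch frame.
sibPairs <- function(rel) {
  b <- batchInfo(rel)
  out <- NULL
  for (f in unique(b$family_id)) {
    k <- which(b$family_id == f & b$role == "child")
    if (length(k) >= 2) out <- rbind(out, t(combn(k, 2)))
  }
  out
}
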