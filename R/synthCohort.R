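#' Simulate a family-structured pedigree and its relationship matrices
#'
#' Generates independent nuclear families (two founders plus 0-3 offspring,
#' mixed according to `familyMix`) until the cohort is filled, then builds
#' the five sample-by-sample covariance structures used throughout the
#' pipeline: `K` the expected additive relationship (parent-offspring and
#' full-sibling pairs 0.5, spouses 0), `F` nuclear-family blocks, `C` couple
#' blocks, `S` sibling blocks and `G` (defaulting to `K`: common-genetic and
#' kinship components collapse in simulation unless configured apart).
#' Batch assignments (plate, plate position, blood-draw date, clinic,
#' appointment year/weekday, measurement set) are drawn alongside; whole
#' families are assigned to the same measurement set so the two sets share
#' no relatives.
#'
#' @param design a [CohortDesign-class].
#' @return A [RelationshipMatrixSet-class].
#' @examples
#' rel <- simulatePedigree(cohortDesign(nIndividuals = 60, nCpgs = 10))
#' relMatrices(rel, "K")[[1]][1:4, 1:4]
#' @export
simulatePedigree <- function(design) {
  validObject(design)
  n <- design@nIndividuals
  mix <- design@familyMix
  sizes <- c(couples = 2L, trios = 3L, sibships = NA_integer_, singletons = 1L)
  if (min(sizes[names(mix)][mix > 0], 2L, na.rm = TRUE) > n)
    stop("invalid design: smallest family size exceeds nIndividuals")

  withStageSeed(design@seed, "pedigree", {
    fam_id <- integer(n); role <- character(n)
    i <- 0L; f <- 0L
    types <- names(mix)
    while (i < n) {
      f <- f + 1L
      ty <- sample(types, 1L, prob = mix)
      size <- switch(ty,
                     couples = 2L,
                     trios = 3L,
                     sibships = 2L + sample(2:3, 1L),
                     singletons = 1L)
      if (i + size > n) { ty <- "singletons"; size <- 1L }
      idx <- i + seq_len(size)
      fam_id[idx] <- f
      role[idx] <- if (ty == "singletons") "founder1" else
        c("founder1", "founder2", rep("child", size - 2L))
      i <- i + size
    }

    K <- diag(n); F <- diag(n); C <- diag(n); S <- diag(n)
    for (fid in unique(fam_id)) {
      m <- which(fam_id == fid)
      if (length(m) < 2L) next
      F[m, m] <- 1
      f1 <- m[role[m] == "founder1"]; f2 <- m[role[m] == "founder2"]
      kids <- m[role[m] == "child"]
      C[f1, f2] <- C[f2, f1] <- 1
      for (k in kids) {
        K[k, f1] <- K[f1, k] <- 0.5
        K[k, f2] <- K[f2, k] <- 0.5
      }
      if (length(kids) > 1L) {
        K[kids, kids] <- 0.5; S[kids, kids] <- 1
        diag(K)[kids] <- 1; diag(S)[kids] <- 1
      }
    }
    diag(K) <- 1; diag(F) <- 1; diag(C) <- 1; diag(S) <- 1

    ids <- sprintf("S%05d", seq_len(n))
    dimnames(K) <- dimnames(F) <- dimnames(C) <- dimnames(S) <- list(ids, ids)

    n_plates <- max(2L, ceiling(n / 96))
    plate <- sample(rep(seq_len(n_plates), length.out = n))
    position <- stats::ave(seq_len(n), plate, FUN = seq_along)
    draw_date <- sample(seq_len(max(10L, round(n / 12))), n, replace = TRUE)
    # balance whole families across the two measurement sets
    fams <- unique(fam_id)
    fam_set <- integer(length(fams)); csize <- c(0L, 0L)
    for (j in seq_along(fams)) {
      s <- which.min(csize)
      fam_set[j] <- s
      csize[s] <- csize[s] + sum(fam_id == fams[j])
    }
    batch <- data.frame(
      sample_id = ids,
      family_id = fam_id,
      role = role,
      plate = plate,
      plate_position = position,
      draw_date = draw_date,
      clinic = sample(1:5, n, replace = TRUE),
      year = sample(2006:2011, n, replace = TRUE),
      weekday = sample(1:5, n, replace = TRUE),
      set = paste0("Set", fam_set[match(fam_id, fams)]),
      stringsAsFactors = FALSE)

    new("RelationshipMatrixSet",
        matrices = list(G = K, K = K, F = F, C = C, S = S),
        batch = batch)
  })
}

# Baseline blood cell-type proportion means (whole-blood reference ranges).
.CELL_PROPS <- c(CD8T = 0.08, CD4T = 0.15, NK = 0.05, Bcell = 0.07,
                 Mono = 0.07, Gran = 0.58)

#' Simulate the methylome of a designed cohort
#'
#' Each CpG's M-values are built as baseline level + familial component
#' draws (covariance `sqrt(f_c) * chol(A_c)` per component `c` in G/K/F/C/S)
#' + plate and blood-draw-date random intercepts + an optional
#' cell-composition component + independent residual noise, with the
#' variance fractions of `design`. Sample-level covariates that the
#' methylome depends on (sex, age, smoking, birth day-of-year, blood cell
#' proportions and haematological counts) are drawn here and stored in the
#' returned object's `colData`; when `cellSeasonAmplitude > 0` the
#' lymphoid/granulocyte balance is modulated by a cosine of birth date, and
#' when the `cell` variance fraction is positive that composition feeds the
#' methylome, creating the seasonal confounding structure the association
#' engines are evaluated against.
#'
#' Causal CpGs (`nCausal` per phenotype, slopes `+/- effectSize`) are
#' reserved and recorded in the returned [SimTruth-class]; the phenotypes
#' themselves are drawn by [simulatePhenotypes()].
#'
#' @param design a [CohortDesign-class].
#' @param rel the [RelationshipMatrixSet-class] from [simulatePedigree()].
#' @return list with elements `mset` (an [MValueSet-class]) and `truth`
#'   (a [SimTruth-class]).
#' @export
simulateMethylome <- function(design, rel) {
  validObject(design); validObject(rel)
  n <- design@nIndividuals
  p <- design@nCpgs
  if (nrow(batchInfo(rel)) != n)
    stop("relationship matrices do not conform to design nIndividuals")
  vf <- design@varFractions
  if (sum(vf) > 1 + 1e-12) stop("invalid design: variance fractions sum over 1")
  f_res <- 1 - sum(vf)

  withStageSeed(design@seed, "methylome", {
    batch <- batchInfo(rel)
    ids <- batch$sample_id

    ## sample covariates
    sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.59, 0.41))
    age <- round(pmin(pmax(rnorm(n, 50, 14), 18), 95), 1)
    smoking_status <- sample(c("never", "ever"), n, replace = TRUE,
                             prob = c(0.55, 0.45))
    pack_years <- ifelse(smoking_status == "ever",
                         round(rgamma(n, 2, 0.15), 1), 0)
    birth_day <- sample(1:365, n, replace = TRUE)

    ## cell composition, optionally modulated by birth season
    season <- -cos(2 * pi * (birth_day + 10) / 365)   # -1 winter .. +1 summer
    amp <- design@cellSeasonAmplitude
    props <- matrix(rep(.CELL_PROPS, each = n), n, 6,
                    dimnames = list(ids, names(.CELL_PROPS)))
    noise_sd <- .CELL_PROPS * 0.15
    for (j in seq_len(6)) props[, j] <- props[, j] + rnorm(n, 0, noise_sd[j])
    lymphoid <- c("CD8T", "CD4T", "NK", "Bcell")
    if (amp != 0) {
      # summer-born: higher lymphocyte share, lower granulocyte share
      for (cc in lymphoid)
        props[, cc] <- props[, cc] + amp * noise_sd[cc] * season
      props[, "Gran"] <- props[, "Gran"] - amp * noise_sd["Gran"] * season
    }
    props <- pmax(props, 0.005)
    props <- props / rowSums(props)
    ## what the analyst sees: reference-based deconvolution estimates carry
    ## error and do not sum exactly to one
    props_est <- pmax(props + matrix(rnorm(n * 6, 0, 0.02), n, 6), 0.001)

    ## haematological counts (10^9 cells/L scale) derived from proportions
    ## haematology analysers are precise, so count noise is small; the
    ## shared total-count factor is recoverable from the joint count set
    wbc <- rnorm(n, 6.8, 1.0)
    counts <- cbind(
      basophil = pmax(rnorm(n, 0.05, 0.02), 0.001),
      eosinophil = pmax(rnorm(n, 0.2, 0.08), 0.001),
      lymphocyte = pmax(rowSums(props[, lymphoid]) * wbc + rnorm(n, 0, 0.08), 0.05),
      monocyte = pmax(props[, "Mono"] * wbc + rnorm(n, 0, 0.04), 0.01),
      neutrophil = pmax(props[, "Gran"] * wbc + rnorm(n, 0, 0.12), 0.1))
    rownames(counts) <- ids

    ## methylome: n x p accumulated, transposed at the end
    M <- matrix(0, n, p)
    for (comp in c("G", "K", "F", "C", "S")) {
      f <- vf[[comp]]
      if (f <= 0) next
      L <- psdFactor(relMatrices(rel, comp)[[1]])
      M <- M + sqrt(f) * (L %*% matrix(rnorm(n * p), n, p))
    }
    if (vf[["plate"]] > 0) {
      u <- matrix(rnorm(max(batch$plate) * p), ncol = p)
      M <- M + sqrt(vf[["plate"]]) * u[batch$plate, , drop = FALSE]
    }
    if (vf[["date"]] > 0) {
      u <- matrix(rnorm(max(batch$draw_date) * p), ncol = p)
      M <- M + sqrt(vf[["date"]]) * u[batch$draw_date, , drop = FALSE]
    }
    if (vf[["cell"]] > 0) {
      Cs <- scale(props)
      W <- matrix(rnorm(6 * p), 6, p) / sqrt(6)
      M <- M + sqrt(vf[["cell"]]) * (Cs %*% W)
    }
    if (f_res > 0) M <- M + sqrt(f_res) * matrix(rnorm(n * p), n, p)

    ## baseline per-CpG levels: bimodal, as M-values are in practice
    mu <- sample(c(-2.5, 2.5), p, replace = TRUE) + rnorm(p, 0, 0.5)
    M <- t(M) + mu   # now p x n
    cpg_ids <- sprintf("cg%07d", seq_len(p))
    rownames(M) <- cpg_ids; colnames(M) <- ids

    ## genomic coordinates: spread over 22 autosomes, sorted within chrom
    chrom <- sort(sample(1:22, p, replace = TRUE,
                         prob = 23 - (1:22)))
    pos <- unlist(lapply(split(seq_len(p), chrom), function(ii)
      cumsum(sample(500:5000, length(ii), replace = TRUE)) + 10000L),
      use.names = FALSE)
    positions <- data.frame(cpg_id = cpg_ids, chrom = paste0("chr", chrom),
                            start = as.integer(pos),
                            end = as.integer(pos) + 1L,
                            stringsAsFactors = FALSE)

    ## plant causal sites per phenotype (disjoint across phenotypes)
    phen_names <- c(names(design@prevalences), "brs")
    causal <- data.frame(phenotype = character(), cpg_id = character(),
                         slope = numeric(), stringsAsFactors = FALSE)
    if (design@nCausal > 0) {
      pool <- sample(cpg_ids)
      need <- design@nCausal * length(phen_names)
      if (need > p) stop("invalid design: nCausal x phenotypes exceeds nCpgs")
      picked <- matrix(pool[seq_len(need)], ncol = length(phen_names))
      causal <- do.call(rbind, lapply(seq_along(phen_names), function(k)
        data.frame(phenotype = phen_names[k], cpg_id = picked[, k],
                   slope = design@effectSize *
                     sample(c(-1, 1), design@nCausal, replace = TRUE),
                   stringsAsFactors = FALSE)))
    }

    cd <- S4Vectors::DataFrame(
      batch[, setdiff(names(batch), "sample_id")],
      sex = sex, age = age, smoking_status = smoking_status,
      pack_years = pack_years, birth_day = birth_day,
      props_est, counts, row.names = ids)

    truth <- new("SimTruth", causal = causal,
                 cellSeason = c(lymphocyte = amp, neutrophil = -amp))
    list(mset = MValueSet(M, positions, stage = "raw", colData = cd),
         truth = truth)
  })
}

#' Draw phenotypes for a simulated cohort
#'
#' Binary phenotypes are drawn by a liability-threshold model: liability =
#' sum over planted causal CpGs of slope x (centred M-value) + a
#' kinship-structured familial term + independent residual, with the
#' residual variance set so the liability is standard normal; cases are
#' samples whose liability exceeds `qnorm(1 - prevalence)`. The continuous
#' phenotype (`brs`) is built the same way and standardized. Seasonal
#' phenotypes (`birth_datescore`, `birth_month`) derive from the birth
#' day-of-year drawn with the methylome.
#'
#' @param design a [CohortDesign-class].
#' @param mset the simulated [MValueSet-class].
#' @param truth the matching [SimTruth-class].
#' @param rel the [RelationshipMatrixSet-class] (for the familial liability
#'   term).
#' @return data.frame: one row per sample with covariates, cell columns and
#'   all phenotypes.
#' @export
simulatePhenotypes <- function(design, mset, truth, rel) {
  validObject(design)
  if (any(design@prevalences <= 0 | design@prevalences >= 1))
    stop("prevalence outside (0, 1)")
  M <- mValues(mset)
  n <- ncol(M)
  cd <- as.data.frame(SummarizedExperiment::colData(mset))
  missing_causal <- setdiff(causalSites(truth)$cpg_id, rownames(M))
  if (length(missing_causal))
    stop("causal CpGs absent from the simulated matrix: ",
         paste(head(missing_causal), collapse = ", "))

  withStageSeed(design@seed, "phenotypes", {
    LK <- psdFactor(relMatrices(rel, "K")[[1]])
    famvar <- design@liabilityFamilial

    liab <- function(phen) {
      cs <- causalSites(truth, phen)
      g <- if (nrow(cs)) {
        Mc <- M[cs$cpg_id, , drop = FALSE]
        drop(crossprod(Mc - rowMeans(Mc), cs$slope))
      } else rep(0, n)
      vres <- 1 - famvar - sum(cs$slope^2)
      if (vres < 0)
        stop("planted effects and familial share imply liability variance > 1; ",
             "reduce effectSize, nCausal or liabilityFamilial")
      g + sqrt(famvar) * drop(LK %*% rnorm(n)) + rnorm(n, 0, sqrt(vres))
    }

    out <- data.frame(sample_id = colnames(M), cd, stringsAsFactors = FALSE)
    for (phen in names(design@prevalences)) {
      thr <- qnorm(1 - design@prevalences[[phen]])
      out[[phen]] <- as.integer(liab(phen) > thr)
    }
    y <- liab("brs")
    out$brs <- as.numeric(zscore(y))
    out$birth_datescore <- birthDateScore(out$birth_day)
    month <- findInterval(out$birth_day, cumsum(c(0, 31, 28, 31, 30, 31, 30,
                                                  31, 31, 30, 31, 30)) + 1)
    out$birth_month <- as.integer(month %in% 4:10)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete cohort in one call
#'
#' Convenience wrapper running [simulatePedigree()], [simulateMethylome()]
#' and [simulatePhenotypes()] off one design.
#'
#' @param design a [CohortDesign-class].
#' @return list with `design`, `rel`, `mset`, `truth`, `samples`.
#' @examples
#' coh <- simulateCohort(cohortDesign(nIndividuals = 60, nCpgs = 40, seed = 7))
#' dim(mValues(coh$mset))
#' @export
simulateCohort <- function(design) {
  rel <- simulatePedigree(design)
  sim <- simulateMethylome(design, rel)
  samples <- simulatePhenotypes(design, sim$mset, sim$truth, rel)
  list(design = design, rel = rel, mset = sim$mset, truth = sim$truth,
       samples = samples)
}
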