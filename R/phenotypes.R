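#' Early-life phenotype constructors
#'
#' These functions build the eight early-life environment phenotypes from
#' raw records. All binary constructors code exposure = 1, use strict
#' inequalities at thresholds (equality = unexposed) and return `NA` --
#' never 0 -- when the defining field is missing.
#'
#' @name earlyLifePhenotypes
NULL

#' @describeIn earlyLifePhenotypes 1 if recorded gestation < 37 weeks.
#' @param gestation_weeks numeric vector of gestation lengths in weeks.
#' @export
pretermFlag <- function(gestation_weeks) {
  ifelse(is.na(gestation_weeks), NA_integer_,
         as.integer(gestation_weeks < 37))
}

#' @describeIn earlyLifePhenotypes 1 if birth weight is below the sex- and
#'   gestation-adjusted centile threshold from `centile_table` (columns
#'   `sex`, `gestation_weeks`, `threshold`, in grams). Records whose
#'   (sex, gestation) cell is absent from the table get `NA` with a warning.
#' @param birth_weight numeric, grams.
#' @param sex character vector matching the table's `sex` coding.
#' @param centile_table data.frame of per-cell weight thresholds.
#' @export
lowBirthWeightFlag <- function(birth_weight, gestation_weeks, sex,
                               centile_table) {
  stopifnot(all(c("sex", "gestation_weeks", "threshold") %in%
                  names(centile_table)))
  key <- paste(sex, gestation_weeks)
  thr <- centile_table$threshold[match(
    key, paste(centile_table$sex, centile_table$gestation_weeks))]
  miss_cell <- !is.na(birth_weight) & !is.na(gestation_weeks) &
    !is.na(sex) & is.na(thr)
  if (any(miss_cell))
    warning(sum(miss_cell),
            " record(s) fall in (sex, gestation) cells absent from the",
            " centile table; flagged as missing")
  ifelse(is.na(birth_weight) | is.na(thr), NA_integer_,
         as.integer(birth_weight < thr))
}

#' @describeIn earlyLifePhenotypes 1 for births April through October
#'   inclusive.
#' @param birth_month integer 1-12.
#' @export
birthMonthFlag <- function(birth_month) {
  if (any(!is.na(birth_month) & (birth_month < 1 | birth_month > 12)))
    stop("birth_month outside 1..12")
  ifelse(is.na(birth_month), NA_integer_, as.integer(birth_month %in% 4:10))
}

#' Seasonal birth-date score
#'
#' Maps day-of-year to a cosine score,
#' `y = -cos(2 * pi * (date + 10) / 365)`, ranging from -1 at the winter
#' solstice (21 December, day 355) to +1 at the summer solstice (21 June,
#' day 172). Use `date = 59.5` for births on 29 February.
#'
#' @param date day of birth within the year (1 January = 1); values in
#'   `[1, 365]`, halves allowed for the leap day.
#' @return numeric score in `[-1, 1]`; `NA` passes through.
#' @examples
#' birthDateScore(355)   # winter solstice: -1
#' birthDateScore(172)   # summer solstice: ~ +1
#' @export
birthDateScore <- function(date) {
  bad <- !is.na(date) & (date < 1 | date > 365)
  if (any(bad)) stop("date outside [1, 365]: ",
                     paste(head(date[bad]), collapse = ", "))
  -cos(2 * pi * (date + 10) / 365)
}

#' Day-of-year for a calendar birth date, leap day mapped to 59.5
#'
#' @param month integer 1-12.
#' @param day integer day of month.
#' @return numeric day-of-year in `[1, 365]` with 29 February = 59.5.
#' @export
dayOfYear <- function(month, day) {
  cum <- cumsum(c(0, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30))
  out <- cum[month] + day
  out[!is.na(month) & !is.na(day) & month == 2 & day == 29] <- 59.5
  out
}

#' @describeIn earlyLifePhenotypes 1 if the youngest available parent was
#'   under 21 at the individual's birth; for lone-parent records supply only
#'   the co-resident parent's age. `NA` when both ages are missing.
#' @param mother_age,father_age parental ages at birth, years.
#' @export
youngParentFlag <- function(mother_age, father_age) {
  m <- pmin(mother_age, father_age, na.rm = TRUE)
  suppressWarnings(m[is.na(mother_age) & is.na(father_age)] <- NA)
  ifelse(is.na(m), NA_integer_, as.integer(m < 21))
}

#' @describeIn earlyLifePhenotypes 1 if exactly one parent lived in the
#'   individual's region at birth; `NA` (excluded) if neither did.
#' @param child_region,mother_region,father_region region codes at the time
#'   of birth.
#' @export
loneParentFlag <- function(child_region, mother_region, father_region) {
  with_m <- !is.na(mother_region) & !is.na(child_region) &
    mother_region == child_region
  with_f <- !is.na(father_region) & !is.na(child_region) &
    father_region == child_region
  n_with <- with_m + with_f
  out <- ifelse(n_with == 1L, 1L, ifelse(n_with == 2L, 0L, NA_integer_))
  out[is.na(child_region) |
        (is.na(mother_region) & is.na(father_region))] <- NA_integer_
  out
}

#' @describeIn earlyLifePhenotypes 1 if the birth region is one of the four
#'   cities classed as urban (Edinburgh, Glasgow, Aberdeen, Dundee by
#'   default); unknown regions give `NA`.
#' @param region birth region.
#' @param cities character vector defining the urban set.
#' @param known_regions optional vector of valid region codes; regions
#'   outside it give `NA`.
#' @export
urbanFlag <- function(region,
                      cities = c("Edinburgh", "Glasgow", "Aberdeen", "Dundee"),
                      known_regions = NULL) {
  out <- ifelse(is.na(region), NA_integer_, as.integer(region %in% cities))
  if (!is.null(known_regions))
    out[!is.na(region) & !region %in% known_regions] <- NA_integer_
  out
}

#' @describeIn earlyLifePhenotypes population density (persons / km^2)
#'   looked up by (region, year) from `density_table` (columns `region`,
#'   `year`, `density`).
#' @param year birth year.
#' @param density_table data.frame keyed by (region, year).
#' @export
populationDensity <- function(region, year, density_table) {
  stopifnot(all(c("region", "year", "density") %in% names(density_table)))
  density_table$density[match(paste(region, year),
                              paste(density_table$region, density_table$year))]
}

#' Resilience-scale score from six Likert items
#'
#' Individuals answering fewer than `min_items` of the six items are
#' dropped; remaining missing cells are imputed by iterative random-forest
#' regression (each incomplete item regressed on the other five, cycled to
#' convergence, 500 trees per forest); the score is the first unrotated
#' principal component of the completed item matrix, oriented so that
#' higher scores mean a higher mean item response. Reverse-keyed items must
#' be pre-oriented by the caller (or listed in `reverse_items`).
#'
#' @param likert matrix/data.frame, individuals x 6 items, integer 1-5 with
#'   `NA` allowed; rownames are sample ids.
#' @param min_items minimum answered items to retain an individual.
#' @param reverse_items optional column indices to reflect (6 - x) before
#'   scoring.
#' @param standardize if `TRUE`, rescale scores to SD 1; by default raw PC1
#'   scores are returned.
#' @param n_trees trees per forest in the imputation.
#' @param seed RNG seed for the imputation.
#' @return data.frame `sample_id`, `brs` for retained individuals.
#' @export
brsScore <- function(likert, min_items = 5L, reverse_items = NULL,
                     standardize = FALSE, n_trees = 500L, seed = 1L) {
  X <- as.matrix(likert)
  stopifnot(ncol(X) == 6L)
  if (is.null(rownames(X))) rownames(X) <- seq_len(nrow(X))
  if (!is.null(reverse_items)) X[, reverse_items] <- 6 - X[, reverse_items]
  keep <- rowSums(!is.na(X)) >= min_items
  X <- X[keep, , drop = FALSE]
  if (!nrow(X)) stop("no individuals with >= ", min_items, " responses")
  if (anyNA(X)) X <- imputeIterative(X, n_trees = n_trees, seed = seed)
  if (any(apply(X, 2, sd) == 0))
    stop("degenerate input: at least one item has zero variance")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  score <- pc$x[, 1]
  if (cor(score, rowMeans(X)) < 0) score <- -score   # orientation rule
  if (standardize) score <- score / sd(score)
  data.frame(sample_id = rownames(X), brs = as.numeric(score),
             stringsAsFactors = FALSE)
}

# Iterative random-forest imputation of an all-numeric matrix: initialize
# missing cells at column means, then cycle over incomplete columns fitting
# a forest of the observed rows on the other columns until the change in
# imputed values stalls (missForest-style stopping).
imputeIterative <- function(X, n_trees = 500L, max_iter = 10L, seed = 1L) {
  miss <- is.na(X)
  Ximp <- X
  for (j in seq_len(ncol(X)))
    Ximp[miss[, j], j] <- mean(X[, j], na.rm = TRUE)
  prev_diff <- Inf
  for (it in seq_len(max_iter)) {
    old <- Ximp
    for (j in which(colSums(miss) > 0)) {
      obs <- !miss[, j]
      fit <- ranger::ranger(
        y = Ximp[obs, j], x = as.data.frame(Ximp[obs, -j, drop = FALSE]),
        num.trees = n_trees, seed = seed + it * 131L + j)
      Ximp[!obs, j] <- predict(
        fit, data = as.data.frame(Ximp[!obs, -j, drop = FALSE]))$predictions
    }
    dnew <- sum((Ximp[miss] - old[miss])^2) / max(sum(Ximp[miss]^2), 1e-12)
    if (dnew >= prev_diff || dnew < 1e-8) break
    prev_diff <- dnew
  }
  Ximp
}

#' Centre and scale a phenotype to mean 0, SD 1
#'
#' Standardizes over non-missing entries with the sample-SD convention;
#' errors on constant input.
#'
#' @param x numeric vector, `NA` allowed.
#' @return numeric vector of the same length.
#' @examples
#' standardizePhenotype(c(1, 2, 3))
#' @export
standardizePhenotype <- function(x) zscore(x)
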