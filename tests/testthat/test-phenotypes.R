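test_that("preterm flag uses a strict 37-week threshold and keeps NA", {
  expect_identical(pretermFlag(c(36, 37, 28, NA)), c(1L, 0L, 1L, NA))
})

test_that("low birth weight flags below the per-cell centile threshold", {
  tab <- expand.grid(sex = c("F", "M"), gestation_weeks = 36:40)
  tab$threshold <- 2500 + 100 * (tab$gestation_weeks - 38) +
    ifelse(tab$sex == "M", 100, 0)
  expect_identical(
    lowBirthWeightFlag(c(2300, 2500, 2600), c(38, 38, 38), c("F", "F", "F"),
                       tab),
    c(1L, 0L, 0L))                       # equality -> unexposed
  expect_warning(
    out <- lowBirthWeightFlag(3000, 45, "F", tab), "absent")
  expect_true(is.na(out))

  # a 3rd-centile threshold table flags ~3% of a simulated population
  set.seed(1)
  g <- sample(36:40, 5000, replace = TRUE)
  s <- sample(c("F", "M"), 5000, replace = TRUE)
  mu <- 3300 + 120 * (g - 38) + ifelse(s == "M", 120, 0)
  w <- rnorm(5000, mu, 450)
  tab3 <- expand.grid(sex = c("F", "M"), gestation_weeks = 36:40)
  tab3$threshold <- qnorm(0.03, 3300 + 120 * (tab3$gestation_weeks - 38) +
                            ifelse(tab3$sex == "M", 120, 0), 450)
  frac <- mean(lowBirthWeightFlag(w, g, s, tab3))
  expect_gt(frac, 0.02); expect_lt(frac, 0.04)
})

test_that("birth month window is April-October inclusive", {
  expect_identical(birthMonthFlag(c(4, 10, 3, 11, NA)), c(1L, 1L, 0L, 0L, NA))
  expect_error(birthMonthFlag(13), "1..12")
})

test_that("birth-date score hits the solstice endpoints", {
  expect_equal(birthDateScore(355), -1)                    # 21 December
  expect_equal(round(birthDateScore(172), 2), 1)           # 21 June
  expect_equal(birthDateScore(81.25), 0, tolerance = 1e-12)
  expect_equal(dayOfYear(2, 29), 59.5)                     # leap day
  expect_equal(dayOfYear(12, 21), 355)
  expect_equal(dayOfYear(6, 21), 172)
  expect_error(birthDateScore(400), "\\[1, 365\\]")
  # symmetry around the score's summer peak (date + 10 = 365/2)
  expect_equal(birthDateScore(172.5 - 30), birthDateScore(172.5 + 30),
               tolerance = 1e-12)
})

test_that("young-parent flag is strict at 21 and honours the lone-parent rule", {
  expect_identical(youngParentFlag(c(20, 21, NA, NA), c(30, 21, 19, NA)),
                   c(1L, 0L, 1L, NA))
})

test_that("lone-parent flag counts co-resident parents by region", {
  expect_identical(
    loneParentFlag(child_region = c("A", "A", "A", "A"),
                   mother_region = c("A", "A", "B", NA),
                   father_region = c("B", "A", "B", NA)),
    c(1L, 0L, NA, NA))                  # neither parent present -> excluded
})

test_that("urbanicity and population density follow their lookups", {
  expect_identical(urbanFlag(c("Glasgow", "Highland", NA)), c(1L, 0L, NA))
  expect_identical(urbanFlag("Atlantis", known_regions = c("Glasgow")),
                   NA_integer_)
  dens <- data.frame(region = c("A", "A"), year = c(1970, 1980),
                     density = c(100, 120))
  expect_equal(populationDensity(c("A", "A", "B"), c(1970, 1980, 1970), dens),
               c(100, 120, NA))
})

test_that("resilience score drops sparse responders and matches rank-1 structure", {
  set.seed(5)
  base <- sample(1:5, 60, replace = TRUE)
  lik <- matrix(pmin(pmax(base + sample(-1:1, 360, TRUE), 1), 5), 60, 6)
  rownames(lik) <- sprintf("P%02d", 1:60)
  lik[1, 1:3] <- NA                      # 3 answered -> dropped
  out <- brsScore(lik, n_trees = 50)
  expect_false("P01" %in% out$sample_id)
  expect_equal(nrow(out), 59)
  # orientation: higher score = higher mean response
  expect_gt(cor(out$brs, rowMeans(lik[out$sample_id, ], na.rm = TRUE)), 0.8)

  # perfectly correlated items: PC1 is an affine map of the item mean
  lik2 <- matrix(rep(base, 6), 60, 6)
  lik2 <- lik2 + 0.001 * matrix(rnorm(360), 60, 6)  # break exact ties
  rownames(lik2) <- sprintf("Q%02d", 1:60)
  out2 <- brsScore(lik2, n_trees = 50)
  expect_gt(abs(cor(out2$brs, rowMeans(lik2))), 0.999)

  expect_error(brsScore(matrix(3, 10, 6)), "zero variance")
})

test_that("sparse missingness is imputed without dropping anyone", {
  set.seed(6)
  lik <- matrix(sample(1:5, 900 * 6, replace = TRUE), 900, 6)
  rownames(lik) <- sprintf("R%03d", 1:900)
  idx <- cbind(sample(900, 20), sample(6, 20, replace = TRUE))
  lik[idx] <- NA
  out <- brsScore(lik, n_trees = 50)
  expect_equal(nrow(out), 900)
  expect_false(anyNA(out$brs))
})

test_that("standardization is exact, idempotent, and rejects constants", {
  expect_equal(standardizePhenotype(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardizePhenotype(rnorm(50))
  expect_equal(standardizePhenotype(z), z, tolerance = 1e-12)
  expect_error(standardizePhenotype(rep(2, 10)), "zero variance")
  x <- c(1, NA, 3, 5)
  z2 <- standardizePhenotype(x)
  expect_true(is.na(z2[2]))
  expect_equal(mean(z2, na.rm = TRUE), 0)
  expect_equal(sd(z2, na.rm = TRUE), 1)
})
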