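test_that("SOFA arithmetic maps latent levels to bounded subscores and totals", {
  expect_equal(computeSofa(rep(10, 6))$total, 24L)
  expect_equal(computeSofa(rep(3.5, 6))$total, 24L)
  expect_equal(computeSofa(rep(0, 6))$total, 0L)
  ## the degeneracy the score is criticized for: different profiles, same sum
  a <- computeSofa(c(4, 0, 0, 0, 0, 0))
  b <- computeSofa(c(1, 1, 1, 1, 0, 0))
  expect_equal(a$total, 4L)
  expect_equal(b$total, 4L)
  expect_false(identical(a$subscores, b$subscores))
  expect_error(computeSofa(rep(1, 5)), "six organ systems")
  expect_error(computeSofa(c(-1, rep(0, 5))), "nonnegative")
})

test_that("generated cohorts satisfy the structural invariants", {
  co <- smallCohort(seed = 3)
  cd <- SummarizedExperiment::colData(co)
  sub <- as.matrix(as.data.frame(cd[, sofaSubscoreNames()]))
  expect_true(all(cd$sofa_total == rowSums(sub)))
  expect_true(all(sub >= 0 & sub <= 4))
  expect_true(all(cd$day >= 1))
  expect_false(anyDuplicated(paste(cd$patient_id, cd$day)) > 0)
  ## no state vector after a patient's exit day
  expect_true(all(cd$day <= cd$exit_day))
  ## trajectories are contiguous from day 1
  for (p in unique(cd$patient_id)) {
    d <- sort(cd$day[cd$patient_id == p])
    expect_equal(d, seq_along(d))
  }
})

test_that("generation is reproducible and degenerate configs error", {
  expect_identical(
    SummarizedExperiment::assay(smallCohort(seed = 9), "features"),
    SummarizedExperiment::assay(smallCohort(seed = 9), "features"))
  expect_error(generateCohort(cohortConfig(nTdm = 0, nControl = 0)),
               "zero patients")
  expect_error(generateCohort(cohortConfig(nContinuous = 0, nDiscrete = 0,
                                           nPathogen = 0, nInformative = 0)),
               "zero features")
  expect_error(cohortConfig(missingRate = 1), "missingRate")
  expect_error(cohortConfig(recoveryRateTdm = 0.1, recoveryRateControl = 0.2),
               "recoveryRateTdm")
})

test_that("disabling exits yields exactly maxDays state vectors per patient", {
  co <- generateCohort(cohortConfig(
    nTdm = 8, nControl = 8, nContinuous = 4, nDiscrete = 2, nPathogen = 0,
    nInformative = 3, maxDays = 5, deathHazardScale = 0,
    dischargeSofaThreshold = -1, seed = 2))
  cd <- SummarizedExperiment::colData(co)
  expect_equal(unname(table(cd$patient_id)), rep(5L, 16L),
               ignore_attr = TRUE)
  expect_true(all(cd$exit_status == "in_study"))
})

test_that("study-scale config produces a state-vector count of the reported order", {
  co <- generateCohort(cohortConfig())  # 123 + 125 patients, 10 days
  n <- ncol(co)
  expect_gt(n, 2376 / 2)
  expect_lt(n, 2376 * 2)
  cd <- SummarizedExperiment::colData(co)
  expect_equal(length(unique(cd$patient_id)), 248L)
})

test_that("null-effect arms are exchangeable on day 1", {
  ## day-1 arm feature-mean differences within 2 SEs. The nominal coverage of
  ## a 2-SE band is ~95.4%; with 15 features x 20 seeds and within-cohort
  ## feature correlation, a 3-sigma lower bound on the pooled coverage is
  ## ~0.90 — a systematic arm difference would push it far below that.
  inside <- vapply(1:20, function(s) {
    co <- generateCohort(cohortConfig(
      nTdm = 100, nControl = 100, nContinuous = 10, nDiscrete = 3,
      nPathogen = 2, nInformative = 6, maxDays = 1,
      recoveryRateControl = 0.2, recoveryRateTdm = 0.2,
      deathHazardScale = 0, dischargeSofaThreshold = -1, seed = s))
    x <- stateMatrix(co)
    arm <- SummarizedExperiment::colData(co)$arm
    ok <- vapply(seq_len(ncol(x)), function(j) {
      a <- x[arm == "TDM", j]; b <- x[arm == "control", j]
      se <- sqrt(var(a) / length(a) + var(b) / length(b))
      se == 0 || abs(mean(a) - mean(b)) <= 2 * se
    }, logical(1))
    mean(ok)
  }, numeric(1))
  expect_gte(mean(inside), 0.90)
})

test_that("a larger TDM rate advantage lowers TDM latent dysfunction post-onset", {
  meanTdmLatent <- function(delta) {
    mean(vapply(1:10, function(s) {
      co <- generateCohort(cohortConfig(
        nTdm = 30, nControl = 30, nContinuous = 4, nDiscrete = 0,
        nPathogen = 0, nInformative = 2, maxDays = 6,
        recoveryRateControl = 0.15, recoveryRateTdm = 0.15 + delta,
        effectOnsetDay = 2, deathHazardScale = 0,
        dischargeSofaThreshold = -1, seed = s))
      cd <- SummarizedExperiment::colData(co)
      lat <- S4Vectors::metadata(co)$latent
      sel <- cd$arm == "TDM" & cd$day == 5
      mean(colSums(lat[, sel, drop = FALSE]))
    }, numeric(1)))
  }
  m <- vapply(c(0, 0.15, 0.3), meanTdmLatent, numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("missingness injection blanks only feature cells at the right rate", {
  co <- smallCohort(seed = 5)
  expect_identical(injectMissingness(co, 0), co)
  h1 <- injectMissingness(co, 0.05, seed = 11)
  h2 <- injectMissingness(co, 0.05, seed = 11)
  expect_identical(SummarizedExperiment::assay(h1, "features"),
                   SummarizedExperiment::assay(h2, "features"))
  m <- SummarizedExperiment::assay(h1, "features")
  expect_gt(length(m), 2000)  # enough cells for the binomial band
  frac <- mean(is.na(m))
  expect_gte(frac, 0.04); expect_lte(frac, 0.06)
  ## SOFA and identifiers untouched
  expect_false(anyNA(SummarizedExperiment::colData(h1)$sofa_total))
  expect_error(injectMissingness(co, 1), "missing_rate")
})

test_that("cohort CSV round trips are exact in both layouts", {
  co <- smallCohort(seed = 7, nTdm = 3, nControl = 3, maxDays = 4,
                    missingRate = 0.1)
  for (fmt in c("wide", "long")) {
    path <- tempfile(fileext = ".csv")
    writeCohort(co, path, fmt)
    back <- readCohort(path)
    expect_identical(SummarizedExperiment::assay(co, "features"),
                     SummarizedExperiment::assay(back, "features"))
    expect_identical(
      as.data.frame(SummarizedExperiment::colData(co)),
      as.data.frame(SummarizedExperiment::colData(back)))
    expect_identical(featureKinds(co), featureKinds(back))
    ## config survives through the sidecar
    expect_equal(S4Vectors::metadata(back)$config@seed,
                 S4Vectors::metadata(co)$config@seed)
  }
  ## long and wide describe the same cohort
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  writeCohort(co, p1, "wide"); writeCohort(co, p2, "long")
  expect_identical(SummarizedExperiment::assay(readCohort(p1), "features"),
                   SummarizedExperiment::assay(readCohort(p2), "features"))
  expect_error(suppressWarnings(
    writeCohort(co, file.path(tempdir(), "no/such/dir/x.csv"))))
})

test_that("a state vector with all features missing survives a round trip", {
  co <- smallCohort(seed = 8, nTdm = 2, nControl = 2, maxDays = 3)
  m <- SummarizedExperiment::assay(co, "features")
  m[, 1] <- NA_real_
  SummarizedExperiment::assay(co, "features") <- m
  path <- tempfile(fileext = ".csv")
  writeCohort(co, path, "wide")
  back <- readCohort(path)
  expect_equal(ncol(back), ncol(co))
  expect_true(all(is.na(SummarizedExperiment::assay(back, "features")[, 1])))
})
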