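test_that("patient splits partition by patient with configured sizes", {
  ids <- sprintf("P%03d", 1:248)
  s <- splitPatients(ids, holdout_n = 10, train_fraction = 0.8, seed = 5)
  expect_equal(length(s$holdout), 10)
  expect_equal(length(s$train), round(0.8 * 238))
  expect_equal(length(s$test), 238 - round(0.8 * 238))
  ## every patient in exactly one partition
  expect_setequal(c(s$holdout, s$train, s$test), ids)
  expect_equal(length(intersect(s$train, s$test)), 0)
  expect_identical(s, splitPatients(ids, 10, 0.8, seed = 5))
  expect_error(splitPatients(sprintf("P%d", 1:12), holdout_n = 10),
               "too few")
})

test_that("grouped CV folds never split a patient's days", {
  pr <- plantedRegression(seed = 2, nPatients = 20, daysPer = 4)
  fold <- sofaspace:::groupedFolds(pr$groups, 5, seed = 3)
  perPatient <- tapply(fold, pr$groups, function(f) length(unique(f)))
  expect_true(all(perPatient == 1))
  expect_equal(sort(unique(fold)), 1:5)
})

test_that("fitness is negative MAE with its degenerate closed forms", {
  pr <- plantedRegression(seed = 3)
  ## constant target: MAE 0 for any subset, any estimator fold split
  expect_equal(subsetFitness("f01", pr$x, rep(5, nrow(pr$x)), pr$groups,
                             "linear"), 0)
  ## target an exact linear function of the subset: fitness ~ 0
  yExact <- as.numeric(pr$x[, pr$informative] %*% rep(2, 5))
  expect_lt(abs(subsetFitness(pr$informative, pr$x, yExact, pr$groups,
                              "linear")), 1e-6)
  expect_error(subsetFitness("nope", pr$x, pr$y, pr$groups), "unknown feature")
  expect_error(subsetFitness(character(), pr$x, pr$y, pr$groups), "nonempty")
})

test_that("informative subsets outscore pure-noise subsets", {
  wins <- vapply(1:20, function(s) {
    pr <- plantedRegression(seed = s, nPatients = 30, daysPer = 4)
    good <- subsetFitness(pr$informative, pr$x, pr$y, pr$groups, "linear",
                          seed = s)
    bad <- subsetFitness(pr$noise[1:5], pr$x, pr$y, pr$groups, "linear",
                         seed = s)
    good > bad
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("GA search respects cardinality, elitism and degenerate limits", {
  pr <- plantedRegression(seed = 4, nPatients = 30, daysPer = 3,
                          nNoise = 10)
  cfg <- gaConfig(populationSize = 16, generations = 8, repetitions = 1,
                  estimator = "linear", seed = 6)
  g <- gaSearch(pr$x, pr$y, pr$groups, k = 5, cfg)
  expect_equal(length(g$best), 5)
  expect_equal(anyDuplicated(g$best), 0)
  expect_false(is.unsorted(g$trace))  # monotone best-so-far
  ## k = all features: the only individual is the full set
  gAll <- gaSearch(pr$x, pr$y, pr$groups, k = ncol(pr$x), cfg)
  expect_setequal(gAll$best, colnames(pr$x))
  ## zero generations: best of the random initial population
  g0 <- gaSearch(pr$x, pr$y, pr$groups, k = 3,
                 gaConfig(populationSize = 10, generations = 0,
                          estimator = "linear", seed = 2))
  expect_equal(length(g0$best), 3)
  expect_equal(length(g0$trace), 0)
  expect_error(gaSearch(pr$x, pr$y, pr$groups, k = 99, cfg), "exceeds")
  ## fixed seed: bit-reproducible
  expect_identical(g, gaSearch(pr$x, pr$y, pr$groups, k = 5, cfg))
})

test_that("k sweep returns one repeated-k-fold score per cardinality", {
  pr <- plantedRegression(seed = 5, nPatients = 30, daysPer = 3,
                          nInformative = 3, nNoise = 5)
  cfg <- gaConfig(populationSize = 12, generations = 4, estimator = "linear",
                  seed = 3)
  sw <- sweepK(pr$x, pr$y, pr$groups, cfg, k_range = 2:5,
               n_splits = 5, n_repeats = 2)
  expect_equal(sw$k, 2:5)
  expect_equal(nrow(sw), 4)
  expect_true(all(is.finite(sw$score_mean)))
  ## fold accounting: n_splits x n_repeats scores behind each mean
  rs <- repeatedKfoldScore(pr$informative, pr$x, pr$y, pr$groups, "linear",
                           n_splits = 5, n_repeats = 2)
  expect_equal(length(rs$scores), 10)
  expect_equal(rs$mean, mean(rs$scores))
})

test_that("frequency analysis thresholds, falls back, and unionizes", {
  pr <- plantedRegression(seed = 6, nPatients = 20, daysPer = 3,
                          nInformative = 2, nNoise = 4)
  cfg <- gaConfig(populationSize = 10, generations = 3, estimator = "linear",
                  frequencyThreshold = 0.10, seed = 4)
  ## 13 picks out of 100 -> 0.13 > 0.10 -> in pool; unpicked -> excluded
  reps <- c(replicate(13, c("f01", "f02"), simplify = FALSE),
            replicate(87, c("f02", "f03"), simplify = FALSE))
  rep1 <- frequencyAnalysis(reps, colnames(pr$x), pr$x, pr$y, pr$groups, cfg)
  expect_equal(unname(rep1@frequencies["f01"]), 0.13)
  expect_equal(unname(rep1@frequencies["f04"]), 0)
  expect_true(all(c("f01", "f02", "f03") %in% rep1@details$pool))
  expect_false("f04" %in% rep1@details$pool)
  ## single repetition: frequencies are 0 or 1
  repOne <- frequencyAnalysis(list(c("f01", "f03")), colnames(pr$x),
                              pr$x, pr$y, pr$groups, cfg)
  expect_true(all(repOne@frequencies %in% c(0, 1)))
  ## empty pool: loud top-k fallback
  cfgHigh <- gaConfig(populationSize = 10, generations = 3,
                      estimator = "linear", frequencyThreshold = 0.99,
                      seed = 4)
  expect_warning(
    repFb <- frequencyAnalysis(list(c("f01", "f02"), c("f03", "f04")),
                               colnames(pr$x), pr$x, pr$y, pr$groups,
                               cfgHigh),
    "empty candidate pool")
  expect_true(repFb@details$fallback)
  expect_error(frequencyAnalysis(list(), colnames(pr$x), pr$x, pr$y,
                                 pr$groups, cfg), "at least one")
})

test_that("generating features are picked far more often than noise features", {
  ## reduced repetitions of the GA on the synthetic cohort: features tied to
  ## the latent organ states should dominate the pick frequencies
  ## k is kept below the informative count: the informative features are
  ## correlated mixes of the same latent organ states, so at larger k the
  ## redundant slots are filled arbitrarily and the contrast washes out
  nRep <- 20L
  co <- smallCohort(seed = 31, nTdm = 30, nControl = 30, maxDays = 6,
                    nContinuous = 12, nDiscrete = 0, nPathogen = 0,
                    nInformative = 5, deathHazardScale = 0,
                    dischargeSofaThreshold = -1)
  cd <- SummarizedExperiment::colData(co)
  x <- stateMatrix(co)
  picks <- unlist(lapply(seq_len(nRep), function(r) {
    pats <- unique(cd$patient_id)
    tr <- sofaspace:::withSeed(500L + r, sample(pats, 48))
    rows <- cd$patient_id %in% tr
    gaSearch(x[rows, ], cd$sofa_total[rows], cd$patient_id[rows], k = 3,
             gaConfig(populationSize = 20, generations = 8,
                      estimator = "linear", seed = r))$best
  }))
  informative <- rownames(co)[SummarizedExperiment::rowData(co)$informative]
  noise <- setdiff(rownames(co), informative)
  freq <- table(factor(picks, levels = rownames(co))) / nRep
  expect_gte(mean(freq[informative]), 3 * mean(freq[noise]))
})

test_that("scenarios wire estimators and feature groups correctly", {
  co <- smallCohort(seed = 21, nTdm = 12, nControl = 12, maxDays = 5)
  cfg <- gaConfig(populationSize = 10, generations = 2, repetitions = 2,
                  forestTrees = 30, seed = 8)
  r2 <- runScenario(co, 2, cfg, k = 3, holdout_n = 3)
  expect_s4_class(r2, "SelectionReport")
  expect_equal(r2@details$estimator, "linear")
  expect_equal(length(r2@holdout), 3)
  expect_true(all(r2@chosen %in% rownames(co)))
  ## scenario 4 runs one GA per feature group: chosen unions the groups
  r4 <- runScenario(co, 4, cfg, k = 2, holdout_n = 3)
  kinds <- featureKinds(co)
  perGroup <- table(kinds[r4@chosen])
  expect_true(all(perGroup <= 2))
  expect_equal(length(r4@details$repetition_subsets), 3)  # three sub-runs
  ## degenerate group: skipped and logged
  noPath <- smallCohort(seed = 22, nTdm = 10, nControl = 10, maxDays = 5,
                        nPathogen = 0)
  r3 <- runScenario(noPath, 3, cfg, k = 2, holdout_n = 3)
  expect_true(any(grepl("pathogen", r3@details$log)))
  expect_error(runScenario(co, 9, cfg), "unknown scenario")
  ## end-to-end reproducibility under a fixed seed
  expect_identical(r2@chosen, runScenario(co, 2, cfg, k = 3, holdout_n = 3)@chosen)
})
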