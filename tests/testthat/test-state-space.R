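## hand-constructed reference with known mean/covariance for closed forms
refWith <- function(mu, sigma) {
  new("ReferenceState", members = rbind(mu, mu + 1), mu = mu, sigma = sigma,
      sigmaInv = solve(sigma), lambda = 0, normConst = 1,
      referenceSofa = 1)
}

test_that("Mahalanobis distance matches its closed forms", {
  ref <- refWith(c(1, 2), diag(2))
  expect_equal(unname(mahalanobisDist(c(1, 2), ref)), 0)
  ## identity covariance reduces to Euclidean: offset (3,4) -> 5
  expect_equal(unname(mahalanobisDist(c(4, 6), ref)), 5)
  ## diagonal covariance diag(2, 0.5), offset (1,1): sqrt(1/2 + 2)
  ref2 <- refWith(c(0, 0), diag(c(2, 0.5)))
  expect_equal(unname(mahalanobisDist(c(1, 1), ref2)), sqrt(2.5))
  expect_error(mahalanobisDist(c(1, 2, 3), ref), "dimension mismatch")
})

test_that("pairwise Mahalanobis distance is a metric", {
  ref <- refWith(c(0, 0, 0), diag(3))
  expect_equal(pairwiseMahalanobis(c(1, 2, 3), c(1, 2, 3), ref), 0)
  expect_equal(pairwiseMahalanobis(c(0, 0, 0), c(3, 0, 4), ref), 5)
  set.seed(31)
  S <- crossprod(matrix(rnorm(9), 3))
  refR <- refWith(rep(0, 3), S + diag(0.5, 3))
  for (i in 1:25) {
    x <- rnorm(3); y <- rnorm(3); z <- rnorm(3)
    dxy <- pairwiseMahalanobis(x, y, refR)
    dyz <- pairwiseMahalanobis(y, z, refR)
    dxz <- pairwiseMahalanobis(x, z, refR)
    expect_equal(dxy, pairwiseMahalanobis(y, x, refR))
    expect_lte(dxz, dxy + dyz + 1e-12)
  }
})

test_that("reference construction enforces membership and regularization contracts", {
  set.seed(7)
  x <- matrix(rnorm(60), 20, 3)
  sofa <- c(rep(1, 10), rep(5, 10))
  ref <- buildReference(x, sofa, reference_sofa = 1)
  expect_equal(nrow(ref@members), 10)
  ## no SOFA = 0 states: building on 0 errors, motivating the SOFA = 1 choice
  expect_error(buildReference(x, sofa, reference_sofa = 0), "at least 2")
  ## identical members: normalization constant undefined
  xx <- rbind(x[1, ], x[1, ], x)
  expect_error(buildReference(xx, c(1, 1, rep(5, 20)), 1), "not distinct")
  ## singular covariance (fewer members than dimensions) is handled by the
  ## ridge: all distances finite
  wide <- matrix(rnorm(5 * 12), 5, 12)
  refS <- buildReference(wide, rep(1, 5), 1)
  expect_true(all(is.finite(mahalanobisDist(matrix(rnorm(24), 2, 12), refS))))
  expect_gt(refS@normConst, 0)
})

test_that("daily trajectory aggregates distances exactly", {
  ref <- refWith(c(0, 0), diag(2))
  x <- rbind(c(2, 0), c(0, 4), c(1, 0))
  arm <- c("TDM", "TDM", "control")
  day <- c(1, 1, 2)
  tm <- dailyTrajectory(x, arm, day, ref, normalize = FALSE)
  t11 <- tm[tm$arm == "TDM" & tm$day == 1, ]
  expect_equal(t11$n_patients, 2)
  expect_equal(t11$cum_sum, 6)   # distances 2 and 4
  expect_equal(t11$mean_dist, 3)
  ## empty arm-day rows are emitted with explicit NA, not dropped
  c1 <- tm[tm$arm == "control" & tm$day == 1, ]
  expect_equal(c1$n_patients, 0)
  expect_true(is.na(c1$cum_sum))
  ## single patient-day: cum sum = mean = the distance
  one <- dailyTrajectory(rbind(c(2, 0)), "TDM", 1L, ref, normalize = FALSE)
  expect_equal(one$cum_sum, one$mean_dist)
})

test_that("normalization makes the reference self-distance exactly 1", {
  for (s in 1:3) {
    co <- smallCohort(seed = s)
    enc <- encodeStates(co)
    cd <- SummarizedExperiment::colData(co)
    ref <- buildReference(enc$matrix, cd$sofa_total, 1)
    ## recompute the mean pairwise distance with the exported pairwise op
    mem <- ref@members
    pairs <- utils::combn(nrow(mem), 2)
    d <- vapply(seq_len(ncol(pairs)), function(i) {
      pairwiseMahalanobis(mem[pairs[1, i], ], mem[pairs[2, i], ], ref)
    }, numeric(1))
    expect_equal(mean(d) / ref@normConst, 1, tolerance = 1e-9)
  }
  ## c = 1 makes normalization the identity
  ref1 <- refWith(c(0, 0), diag(2))
  m <- dailyTrajectory(rbind(c(1, 1)), "TDM", 1L, ref1)
  expect_equal(m$mean_norm, m$mean_dist)
})

test_that("normalized metrics are invariant to a global feature rescaling", {
  set.seed(21)
  n <- 40
  x <- matrix(rnorm(n * 3), n, 3)
  sofa <- rep(c(1, 6), each = n / 2)
  arm <- rep(c("TDM", "control"), n / 2)
  day <- rep(1:2, each = n / 2)
  m1 <- dailyTrajectory(x, arm, day,
                        buildReference(x, sofa, 1, regularization = 0))
  m2 <- dailyTrajectory(2 * x, arm, day,
                        buildReference(2 * x, sofa, 1, regularization = 0))
  expect_equal(m1$mean_norm, m2$mean_norm, tolerance = 1e-8)
  expect_equal(m1$cum_sum_norm, m2$cum_sum_norm, tolerance = 1e-8)
})

test_that("noiseless recovering trajectories have non-increasing distance", {
  co <- generateCohort(cohortConfig(
    nTdm = 10, nControl = 10, nContinuous = 6, nDiscrete = 0, nPathogen = 0,
    nInformative = 6, maxDays = 8, obsNoiseSd = 0,
    recoveryRateControl = 0.4, recoveryRateTdm = 0.5,
    deathHazardScale = 0, dischargeSofaThreshold = 1, seed = 17))
  enc <- encodeStates(co)
  cd <- SummarizedExperiment::colData(co)
  ref <- buildReference(enc$matrix, cd$sofa_total, 1)
  d <- mahalanobisDist(enc$matrix, ref)
  for (p in unique(cd$patient_id)) {
    sel <- cd$patient_id == p
    traj <- d[sel][order(cd$day[sel])]
    ## monotone up to the exit day (the final step lands inside the
    ## reference zone and may tick past its center)
    if (length(traj) > 2) {
      expect_true(all(diff(traj[-length(traj)]) <= 1e-8))
    }
  }
})

test_that("day-1 similarity matches hand-enumerated pair means", {
  ## three collinear points at 0, 1, 2: means 1.5, 1.0, 1.5
  x <- matrix(c(0, 1, 2), ncol = 1)
  sim <- day1Similarity(x, c("TDM", "control", "TDM"), n_perm = 50, seed = 1)
  expect_equal(sim$per_patient$mean_dist, c(1.5, 1.0, 1.5))
  ## two identical patients: both means zero
  sim2 <- day1Similarity(rbind(c(1, 2), c(1, 2)), c("TDM", "control"),
                         n_perm = 10, seed = 1)
  expect_equal(sim2$per_patient$mean_dist, c(0, 0))
  expect_error(day1Similarity(rbind(c(1, 2)), "TDM"), "at least 2")
})

test_that("2-D embeddings preserve what they should", {
  set.seed(9)
  x <- matrix(rnorm(40), 20, 2)
  e <- embed2d(x, "pca")
  ## PCA of 2-D data is a rotation: pairwise distances preserved
  expect_equal(as.numeric(dist(as.matrix(e))), as.numeric(dist(x)),
               tolerance = 1e-9)
  expect_equal(attr(e, "var_explained"), 1, tolerance = 1e-12)
  ## rank-2 data in higher dimension: two components explain everything
  z <- cbind(x, x[, 1] + x[, 2], 2 * x[, 1] - x[, 2])
  expect_equal(attr(embed2d(z, "pca"), "var_explained"), 1, tolerance = 1e-9)
  ## duplicated dataset gives duplicated embedding rows
  e2 <- embed2d(rbind(x, x), "pca")
  expect_equal(as.matrix(e2)[1:20, ], as.matrix(e2)[21:40, ],
               tolerance = 1e-9)
  ## deterministic sign convention
  expect_identical(embed2d(x, "pca"), embed2d(x, "pca"))
  expect_error(embed2d(x[1:2, , drop = FALSE], "pca"), "at least 3")
})

test_that("t-SNE embedding is seeded and separates well-separated clusters", {
  set.seed(10)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 12), 30, 2))
  e1 <- embed2d(x, "tsne", seed = 4, perplexity = 10)
  e2 <- embed2d(x, "tsne", seed = 4, perplexity = 10)
  expect_identical(e1, e2)
  ## cluster structure survives the embedding
  within <- mean(dist(e1[1:30, ])) + mean(dist(e1[31:60, ]))
  between <- mean(as.matrix(dist(as.matrix(e1)))[1:30, 31:60])
  expect_gt(between, within / 2)
})
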