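## Mahalanobis-distance "multidimensional SOFA" trajectory analysis against
## the SOFA = 1 reference distribution.

#' Build the SOFA = 1 reference-state distribution
#'
#' Members are all encoded + scaled state vectors (any arm, any day) whose
#' total SOFA equals `reference_sofa`; the default of 1 reflects that SOFA = 0
#' states are vanishingly rare in severe sepsis cohorts, making SOFA = 1 the
#' practical "healthy town". The covariance inverse is computed after adding
#' `regularization * I` (default `1e-6 * trace(sigma)/dim`, needed because
#' reference membership is typically much smaller than the feature count),
#' and the normalization constant `c` is the mean Mahalanobis distance over
#' all unordered member pairs under that same regularized inverse.
#'
#' @param x numeric matrix of encoded + scaled state vectors (rows).
#' @param sofa_total integer vector of total SOFA scores, one per row.
#' @param reference_sofa membership filter (default 1).
#' @param regularization ridge added to the covariance diagonal; `NULL` means
#'   `1e-6 * trace(sigma)/ncol`.
#' @return A [ReferenceState-class].
#' @export
buildReference <- function(x, sofa_total, reference_sofa = 1,
                           regularization = NULL) {
  stopifnot(nrow(x) == length(sofa_total))
  members <- x[sofa_total == reference_sofa, , drop = FALSE]
  if (nrow(members) < 2L) {
    stop("need at least 2 states with SOFA total == ", reference_sofa,
         " to form a reference distribution (found ", nrow(members), ")")
  }
  if (nrow(unique(as.data.frame(members))) < 2L) {
    stop("reference members are not distinct; ",
         "the pairwise normalization constant would be zero")
  }
  mu <- colMeans(members)
  sigma <- stats::cov(members)
  if (any(!is.finite(sigma))) stop("non-finite reference covariance")
  if (is.null(regularization)) {
    regularization <- 1e-6 * sum(diag(sigma)) / ncol(members)
  }
  reg <- sigma + diag(regularization, ncol(sigma))
  ch <- tryCatch(chol(reg), error = function(e) {
    stop("regularized covariance is not positive definite; ",
         "increase `regularization` (", conditionMessage(e), ")")
  })
  sigmaInv <- chol2inv(ch)
  sigmaInv <- (sigmaInv + t(sigmaInv)) / 2
  ref <- new("ReferenceState",
             members = members, mu = mu, sigma = sigma, sigmaInv = sigmaInv,
             lambda = regularization, normConst = 1,
             referenceSofa = reference_sofa)
  ref@normConst <- meanPairwiseDistance(ref)
  validObject(ref)
  ref
}

## Cholesky factor U of the regularized inverse: D(a,b) = ||U (a-b)||.
whiteningFactor <- function(reference) chol(reference@sigmaInv)

## mean Mahalanobis distance over all unordered member pairs
meanPairwiseDistance <- function(reference) {
  U <- whiteningFactor(reference)
  z <- reference@members %*% t(U)
  mean(stats::dist(z))
}

#' Mahalanobis distance from state vectors to the reference distribution
#'
#' `D(A, R) = sqrt((A - mu) SigmaInv (A - mu)^T)` with the reference's
#' regularized inverse covariance; reduces to the Euclidean distance when the
#' covariance is the identity.
#'
#' @param x numeric vector (one state) or matrix (states as rows) with the
#'   reference's dimensionality.
#' @param reference a [ReferenceState-class].
#' @return numeric vector of nonnegative distances.
#' @export
mahalanobisDist <- function(x, reference) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(reference@mu)) {
    stop("dimension mismatch: state has ", ncol(x), " features, reference ",
         length(reference@mu))
  }
  U <- whiteningFactor(reference)
  z <- sweep(x, 2L, reference@mu) %*% t(U)
  sqrt(rowSums(z^2))
}

#' Pairwise Mahalanobis distance between two state vectors
#'
#' Uses the reference's regularized inverse covariance, so the metric is the
#' same one the trajectory numerator uses — the normalization constant is
#' unit-consistent by construction. Symmetric, and zero iff `x == y`.
#'
#' @param x,y numeric state vectors of the reference's dimensionality.
#' @param reference a [ReferenceState-class].
#' @return nonnegative scalar.
#' @export
pairwiseMahalanobis <- function(x, y, reference) {
  if (length(x) != length(reference@mu) || length(y) != length(x)) {
    stop("dimension mismatch between states and reference")
  }
  d <- x - y
  sqrt(max(0, as.numeric(d %*% reference@sigmaInv %*% d)))
}

#' Per-arm daily Mahalanobis trajectory aggregates
#'
#' For each arm and day `t`: the patients present `P(t)`, the cumulative sum
#' of their distances to the reference `CumSum(t)`, the per-patient mean
#' `CumSum(t)/P(t)`, and (after [normalizeTrajectory()]) the same quantities
#' divided by the reference normalization constant. Days on which an arm has
#' no patients are emitted with explicit `NA`s rather than dropped. The
#' normalized per-patient mean is the headline recovery curve: the sum alone
#' conflates recovery with attrition as arm sizes shrink over time.
#'
#' @param x numeric matrix of encoded + scaled state vectors (rows).
#' @param arm,day arm label and day index per row.
#' @param reference a [ReferenceState-class].
#' @param normalize add normalized columns (default TRUE).
#' @return data.frame with columns `arm`, `day`, `n_patients`, `cum_sum`,
#'   `mean_dist` and, if normalized, `cum_sum_norm`, `mean_norm`; the
#'   per-state distances are attached as attribute `"distances"`.
#' @export
dailyTrajectory <- function(x, arm, day, reference, normalize = TRUE) {
  stopifnot(nrow(x) == length(arm), length(arm) == length(day))
  d <- mahalanobisDist(x, reference)
  arms <- sort(unique(arm))
  days <- seq_len(max(day))
  grid <- expand.grid(arm = arms, day = days, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- arm == grid$arm[i] & day == grid$day[i]
    n <- sum(sel)
    data.frame(arm = grid$arm[i], day = grid$day[i], n_patients = n,
               cum_sum = if (n) sum(d[sel]) else NA_real_,
               mean_dist = if (n) mean(d[sel]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$arm, out$day), ]
  rownames(out) <- NULL
  if (normalize) out <- normalizeTrajectory(out, reference)
  attr(out, "distances") <- data.frame(arm = arm, day = day, distance = d)
  out
}

#' Normalize trajectory metrics by the reference pairwise distance
#'
#' Divides every distance statistic by the reference normalization constant
#' `c`, so the reported curves read "how far from the reference, if the
#' distance between SOFA = 1 patients is 1". The reference members' own mean
#' pairwise normalized distance is exactly 1.
#'
#' @param metrics data.frame from [dailyTrajectory()].
#' @param reference a [ReferenceState-class] with `normConst > 0`.
#' @return `metrics` with `cum_sum_norm` and `mean_norm` columns.
#' @export
normalizeTrajectory <- function(metrics, reference) {
  if (!isTRUE(reference@normConst > 0)) {
    stop("reference normalization constant must be > 0")
  }
  metrics$cum_sum_norm <- metrics$cum_sum / reference@normConst
  metrics$mean_norm <- metrics$mean_dist / reference@normConst
  metrics
}

#' Day-1 pairwise-distance similarity of the two arms
#'
#' For every patient, the mean Euclidean distance from their day-1 state to
#' all other patients' day-1 states (the states are expected to be encoded
#' and scaled already). The arm difference in the mean of these per-patient
#' means is assessed by a seeded label-permutation test — under a fair
#' randomization the arms should be exchangeable on day 1.
#'
#' @param x numeric matrix of day-1 state vectors, one row per patient.
#' @param arm arm label per row.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer RNG seed.
#' @return list with `per_patient` (data.frame `arm`, `mean_dist`),
#'   `arm_means`, `observed` (absolute arm difference) and `p_value`.
#' @export
day1Similarity <- function(x, arm, n_perm = 1000L, seed = 1L) {
  if (nrow(x) < 2L) stop("need at least 2 patients")
  dm <- as.matrix(stats::dist(x))
  perPatient <- rowSums(dm) / (nrow(dm) - 1L)
  armStat <- function(lab) {
    abs(mean(perPatient[lab == lab[1]]) - mean(perPatient[lab != lab[1]]))
  }
  observed <- armStat(arm)
  perm <- withSeed(seed, {
    vapply(seq_len(n_perm), function(i) armStat(sample(arm)), numeric(1))
  })
  pval <- (1 + sum(perm >= observed)) / (n_perm + 1)
  list(
    per_patient = data.frame(arm = arm, mean_dist = unname(perPatient)),
    arm_means = tapply(perPatient, arm, mean),
    observed = observed,
    p_value = pval
  )
}

#' Embed state vectors in two dimensions for inspection
#'
#' `"pca"` gives a deterministic linear embedding (signs fixed so each
#' component's largest-magnitude loading is positive); `"tsne"` runs a seeded
#' exact t-SNE (see [tsneEmbed()]).
#'
#' @param x numeric matrix of state vectors (>= 3 rows).
#' @param method `"pca"` or `"tsne"`.
#' @param seed RNG seed for the t-SNE path.
#' @param perplexity t-SNE perplexity.
#' @return data.frame with columns `dim1`, `dim2`; for PCA the fraction of
#'   variance explained is attached as attribute `"var_explained"`.
#' @export
embed2d <- function(x, method = c("pca", "tsne"), seed = 1L, perplexity = 30) {
  method <- match.arg(method)
  if (nrow(x) < 3L) stop("need at least 3 states to embed")
  if (method == "pca") {
    keep <- apply(x, 2L, function(v) var(v) > 0)
    p <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(p$rotation))
    rot <- p$rotation[, seq_len(k), drop = FALSE]
    flip <- vapply(seq_len(k), function(j) {
      sign(rot[which.max(abs(rot[, j])), j])
    }, numeric(1))
    coords <- sweep(p$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
    if (k < 2L) coords <- cbind(coords, 0)
    out <- data.frame(dim1 = coords[, 1], dim2 = coords[, 2])
    attr(out, "var_explained") <- sum(p$sdev[seq_len(k)]^2) / sum(p$sdev^2)
    out
  } else {
    coords <- tsneEmbed(x, seed = seed, perplexity = perplexity)
    data.frame(dim1 = coords[, 1], dim2 = coords[, 2])
  }
}

#' End-to-end trajectory analysis of a cohort
#'
#' Encodes and scales the cohort's state vectors ([encodeStates()]), builds
#' the SOFA = 1 reference ([buildReference()]) from the analysis patients,
#' and returns the per-arm daily normalized trajectory ([dailyTrajectory()]).
#'
#' @param cohort a [SepsisCohort-class].
#' @param reference_sofa membership filter for the reference (default 1).
#' @param regularization covariance ridge; `NULL` = automatic.
#' @param smoothing target-encoder smoothing weight.
#' @param exclude_patients patient ids excluded from encoder fitting and
#'   reference membership (e.g. a holdout set); their trajectories are still
#'   reported.
#' @return list with `metrics`, `reference`, `encoder`.
#' @export
trajectoryAnalysis <- function(cohort, reference_sofa = 1,
                               regularization = NULL, smoothing = 1,
                               exclude_patients = character()) {
  cd <- colData(cohort)
  analysisPatients <- setdiff(unique(cd$patient_id), exclude_patients)
  enc <- encodeStates(cohort, train_patients = analysisPatients,
                      smoothing = smoothing)
  inAnalysis <- cd$patient_id %in% analysisPatients
  ref <- buildReference(enc$matrix[inAnalysis, , drop = FALSE],
                        cd$sofa_total[inAnalysis],
                        reference_sofa = reference_sofa,
                        regularization = regularization)
  metrics <- dailyTrajectory(enc$matrix, cd$arm, cd$day, ref)
  list(metrics = metrics, reference = ref, encoder = enc$encoder)
}
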