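## Genetic-algorithm wrapper feature selection for SOFA prediction:
## patient-grouped CV fitness (negative MAE), fixed-cardinality subset GA,
## k-sweep, repetition frequency analysis and the thresholded-union run.

## deterministic seed derivation that stays inside 32-bit integer range
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(offset) * 1013) %% 2147483647)
}

#' Patient-level holdout / train / test split
#'
#' Splits are always by patient — all of a patient's days travel together —
#' mirroring the protocol: a small holdout set is removed entirely from
#' feature selection, and the remainder is split 4:1 into train and test.
#'
#' @param patient_ids character vector of unique patient ids.
#' @param holdout_n patients left out completely (default 10).
#' @param train_fraction fraction of the remainder used for training
#'   (default 0.8).
#' @param seed integer RNG seed.
#' @return list with `holdout`, `train`, `test` character vectors.
#' @export
splitPatients <- function(patient_ids, holdout_n = 10L, train_fraction = 0.8,
                          seed = 1L) {
  patient_ids <- unique(patient_ids)
  if (length(patient_ids) < holdout_n + 5L) {
    stop("too few patients: need at least ", holdout_n + 5L)
  }
  withSeed(seed, {
    ids <- sample(patient_ids)
    holdout <- ids[seq_len(holdout_n)]
    rest <- ids[-seq_len(holdout_n)]
    nTrain <- round(train_fraction * length(rest))
    list(holdout = sort(holdout),
         train = sort(rest[seq_len(nTrain)]),
         test = sort(rest[-seq_len(nTrain)]))
  })
}

## fold id per row such that no patient straddles folds
groupedFolds <- function(groups, k, seed = 1L) {
  pats <- unique(groups)
  if (length(pats) < k) stop("fewer patients than folds")
  withSeed(seed, {
    fold <- stats::setNames(rep_len(seq_len(k), length(pats)), sample(pats))
  })
  unname(fold[as.character(groups)])
}

fitPredictMae <- function(xTr, yTr, xVa, yVa, estimator, forest_trees, seed) {
  if (estimator == "linear") {
    fit <- stats::lm.fit(cbind(1, as.matrix(xTr)), yTr)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- as.numeric(cbind(1, as.matrix(xVa)) %*% beta)
  } else {
    fit <- ranger::ranger(
      x = as.data.frame(xTr), y = yTr, num.trees = forest_trees,
      num.threads = 1L, seed = seed)
    pred <- stats::predict(fit, data = as.data.frame(xVa),
                           num.threads = 1L)$predictions
  }
  mean(abs(pred - yVa))
}

#' Cross-validated fitness of a feature subset
#'
#' Mean over patient-grouped CV folds of the negative mean absolute error of
#' the estimator predicting the SOFA total on the validation fold. Folds are
#' grouped by patient so within-patient autocorrelation cannot leak.
#'
#' @param subset character vector of feature names (nonempty).
#' @param x feature matrix/data.frame, rows = state vectors.
#' @param y numeric target (SOFA totals).
#' @param groups patient id per row.
#' @param estimator `"forest"` or `"linear"`.
#' @param cv_folds number of folds (default 5).
#' @param seed RNG seed (fold assignment, forest).
#' @param forest_trees trees per forest fit.
#' @return scalar fitness (negative MAE; 0 is perfect).
#' @export
subsetFitness <- function(subset, x, y, groups, estimator = "forest",
                          cv_folds = 5L, seed = 1L, forest_trees = 100L) {
  if (!length(subset)) stop("subset must be nonempty")
  unknown <- setdiff(subset, colnames(x))
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  }
  fold <- groupedFolds(groups, cv_folds, seed)
  xs <- x[, subset, drop = FALSE]
  maes <- vapply(seq_len(cv_folds), function(f) {
    tr <- fold != f
    fitPredictMae(xs[tr, , drop = FALSE], y[tr],
                  xs[!tr, , drop = FALSE], y[!tr],
                  estimator, forest_trees, deriveSeed(seed, f))
  }, numeric(1))
  -mean(maes)
}

#' Repeated k-fold score of a feature subset
#'
#' Scores the subset with patient-grouped repeated k-fold CV
#' (10 splits x 3 repeats by default) and returns the mean and standard
#' deviation of the fold scores (negative MAE).
#'
#' @inheritParams subsetFitness
#' @param n_splits,n_repeats repeated k-fold settings (default 10 x 3).
#' @return list with `mean`, `sd`, `scores` (all fold scores).
#' @export
repeatedKfoldScore <- function(subset, x, y, groups, estimator = "forest",
                               n_splits = 10L, n_repeats = 3L, seed = 1L,
                               forest_trees = 100L) {
  xs <- x[, subset, drop = FALSE]
  scores <- unlist(lapply(seq_len(n_repeats), function(r) {
    fold <- groupedFolds(groups, n_splits, deriveSeed(seed, r))
    vapply(seq_len(n_splits), function(f) {
      tr <- fold != f
      -fitPredictMae(xs[tr, , drop = FALSE], y[tr],
                     xs[!tr, , drop = FALSE], y[!tr],
                     estimator, forest_trees, deriveSeed(seed, r * 100 + f))
    }, numeric(1))
  }))
  list(mean = mean(scores), sd = sd(scores), scores = scores)
}

#' Genetic-algorithm search for the best fixed-size feature subset
#'
#' Evolves a population of `k`-feature subsets: tournament parent selection,
#' set-preserving uniform crossover (a child is `k` distinct features
#' sampled from the parents' union), swap mutation (one in-subset feature
#' exchanged for one out-of-subset feature) and elitism. Every individual
#' has exactly `k` distinct features at every generation, and the returned
#' best-so-far trace is monotone non-decreasing. Fitness evaluations are
#' memoized per subset.
#'
#' @param x,y,groups as in [subsetFitness()].
#' @param k subset cardinality.
#' @param config a [GAConfig-class].
#' @param seed RNG seed (default: `config@seed`).
#' @return list with `best` (feature names), `fitness`, `trace`
#'   (best-so-far per generation) and `evaluations`.
#' @export
gaSearch <- function(x, y, groups, k, config = gaConfig(), seed = config@seed) {
  features <- colnames(x)
  p <- length(features)
  if (k > p) stop("k = ", k, " exceeds the number of features (", p, ")")
  if (k < 1L) stop("k must be >= 1")
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  fitnessOf <- function(idx) {
    key <- paste(sort(idx), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    evals <<- evals + 1L
    val <- subsetFitness(features[idx], x, y, groups,
                         estimator = config@estimator,
                         cv_folds = config@cvFolds,
                         seed = deriveSeed(seed, 7L),
                         forest_trees = config@forestTrees)
    cache[[key]] <- val
    val
  }
  withSeed(deriveSeed(seed, 11L), {
    pop <- lapply(seq_len(config@populationSize), function(i) {
      sort(sample.int(p, k))
    })
    fit <- vapply(pop, fitnessOf, numeric(1))
    bestIdx <- pop[[which.max(fit)]]
    bestFit <- max(fit)
    trace <- numeric(config@generations)
    gen <- 0L
    while (gen < config@generations) {
      gen <- gen + 1L
      tournament <- function() {
        cand <- sample.int(config@populationSize, config@tournamentSize)
        pop[[cand[which.max(fit[cand])]]]
      }
      newPop <- vector("list", config@populationSize)
      ord <- order(fit, decreasing = TRUE)
      nE <- min(config@elitism, config@populationSize)
      for (e in seq_len(nE)) newPop[[e]] <- pop[[ord[e]]]
      for (i in seq(nE + 1L, length.out = config@populationSize - nE)) {
        u <- union(tournament(), tournament())
        child <- if (length(u) > k) sort(sample(u, k)) else sort(u)
        if (runif(1) < config@mutationRate) {
          out <- setdiff(seq_len(p), child)
          if (length(out)) {
            child <- sort(c(child[-sample.int(k, 1L)], sample(out, 1L)))
          }
        }
        newPop[[i]] <- child
      }
      pop <- newPop
      fit <- vapply(pop, fitnessOf, numeric(1))
      if (max(fit) > bestFit) {
        bestFit <- max(fit)
        bestIdx <- pop[[which.max(fit)]]
      }
      trace[gen] <- bestFit
    }
    list(best = features[bestIdx], fitness = bestFit, trace = trace,
         evaluations = evals)
  })
}

#' Sweep the subset cardinality and score each best subset
#'
#' For each `k` in `k_range`, runs [gaSearch()] and scores its best subset
#' with patient-grouped repeated k-fold CV; the resulting curve supports
#' choosing the optimum number of features (the value-of-added-information
#' analysis).
#'
#' @inheritParams gaSearch
#' @param k_range integer vector of cardinalities.
#' @param n_splits,n_repeats repeated k-fold settings.
#' @return data.frame `k`, `score_mean`, `score_sd`, `fitness`; the best
#'   subsets are attached as attribute `"subsets"`.
#' @export
sweepK <- function(x, y, groups, config = gaConfig(),
                   k_range = seq_len(ncol(x)), n_splits = 10L,
                   n_repeats = 3L, seed = config@seed) {
  res <- lapply(k_range, function(k) {
    g <- gaSearch(x, y, groups, k, config, seed = deriveSeed(seed, k))
    s <- repeatedKfoldScore(g$best, x, y, groups,
                            estimator = config@estimator,
                            n_splits = n_splits, n_repeats = n_repeats,
                            seed = deriveSeed(seed, 1000L + k),
                            forest_trees = config@forestTrees)
    list(row = data.frame(k = k, score_mean = s$mean, score_sd = s$sd,
                          fitness = g$fitness),
         subset = g$best)
  })
  out <- do.call(rbind, lapply(res, `[[`, "row"))
  rownames(out) <- NULL
  attr(out, "subsets") <- lapply(res, `[[`, "subset")
  out
}

#' Pick-frequency analysis across GA repetitions, with final union run
#'
#' Per-feature pick frequency = picks / repetitions. Features picked more
#' often than `threshold` (protocol: 10%) form the candidate pool, over
#' which one final [gaSearch()] is run to capture multivariate correlations;
#' its best subset is the chosen feature set. An empty pool falls back,
#' loudly, to the top-k features by frequency.
#'
#' @param repetition_subsets list of character vectors (one per repetition).
#' @param universe all candidate feature names.
#' @param x,y,groups data for the final union run.
#' @param config a [GAConfig-class] (`frequencyThreshold` is used).
#' @param k_final cardinality of the final run (default: the repetition
#'   cardinality, capped at the pool size).
#' @param seed RNG seed.
#' @return A [SelectionReport-class].
#' @export
frequencyAnalysis <- function(repetition_subsets, universe, x, y, groups,
                              config = gaConfig(), k_final = NULL,
                              seed = config@seed) {
  if (!length(repetition_subsets)) stop("need at least one repetition")
  picks <- table(factor(unlist(repetition_subsets), levels = universe))
  freq <- as.numeric(picks) / length(repetition_subsets)
  names(freq) <- universe
  pool <- universe[freq > config@frequencyThreshold]
  fallback <- FALSE
  if (is.null(k_final)) k_final <- length(repetition_subsets[[1]])
  if (!length(pool)) {
    fallback <- TRUE
    warning("empty candidate pool at threshold ", config@frequencyThreshold,
            "; falling back to the top-", k_final, " features by frequency")
    pool <- names(sort(freq, decreasing = TRUE))[seq_len(min(k_final, length(universe)))]
  }
  kUse <- min(k_final, length(pool))
  final <- gaSearch(x[, pool, drop = FALSE], y, groups, kUse, config,
                    seed = deriveSeed(seed, 4242L))
  new("SelectionReport",
      frequencies = freq, chosen = final$best,
      kCurve = data.frame(k = integer(), score_mean = numeric(),
                          score_sd = numeric()),
      scenario = NA_integer_, holdout = character(),
      details = list(pool = pool, fallback = fallback,
                     final_fitness = final$fitness,
                     repetitions = length(repetition_subsets)))
}

## run the repetition protocol on one feature group
runGroupSelection <- function(x, y, groups, config, k, seed) {
  pats <- unique(groups)
  reps <- lapply(seq_len(config@repetitions), function(r) {
    rs <- deriveSeed(seed, 100000L + r)
    ## re-draw the train portion per repetition (4:1 within the analysis set)
    trainPats <- withSeed(rs, sample(pats, round(0.8 * length(pats))))
    rows <- groups %in% trainPats
    gaSearch(x[rows, , drop = FALSE], y[rows], groups[rows],
             k = min(k, ncol(x)), config, seed = rs)$best
  })
  reps
}

#' Run one of the four feature-selection scenarios on a cohort
#'
#' Scenario 1: all features, raw values, random-forest estimator.
#' Scenario 2: all features, target-encoded + scaled, linear estimator.
#' Scenarios 3 and 4 repeat 1 and 2 but run three independent GA wrappers on
#' the continuous, discrete and pathogen feature groups and concatenate the
#' chosen subsets (which by construction cannot capture cross-group
#' interactions). Encoders are fitted on the selection patients only. A
#' degenerate (empty) group is skipped and logged.
#'
#' @param cohort a [SepsisCohort-class].
#' @param scenario integer 1-4.
#' @param config a [GAConfig-class]; `estimator` is overridden to match the
#'   scenario.
#' @param k subset cardinality per GA run (per group for scenarios 3-4).
#' @param holdout_n,train_fraction patient split parameters.
#' @param smoothing target-encoder smoothing (scenarios 2 and 4).
#' @return A [SelectionReport-class].
#' @export
runScenario <- function(cohort, scenario, config = gaConfig(), k = 5L,
                        holdout_n = 10L, train_fraction = 0.8,
                        smoothing = 1) {
  if (!scenario %in% 1:4) stop("unknown scenario id: ", scenario)
  config@estimator <- if (scenario %in% c(1L, 3L)) "forest" else "linear"
  cd <- colData(cohort)
  split <- splitPatients(unique(cd$patient_id), holdout_n, train_fraction,
                         seed = config@seed)
  selRows <- cd$patient_id %in% split$train
  kinds <- featureKinds(cohort)
  wide <- as.data.frame(stateMatrix(cohort), check.names = FALSE)
  if (scenario %in% c(2L, 4L)) {
    enc <- fitEncoder(wide[selRows, , drop = FALSE],
                      target = cd$sofa_total[selRows],
                      discrete_cols = names(kinds)[kinds != "continuous"],
                      smoothing = smoothing)
    xAll <- encodeFeatures(wide, enc)
  } else {
    xAll <- as.matrix(wide)
  }
  x <- xAll[selRows, , drop = FALSE]
  y <- cd$sofa_total[selRows]
  groups <- cd$patient_id[selRows]

  groupsOf <- if (scenario %in% c(1L, 2L)) {
    list(all = colnames(x))
  } else {
    split(names(kinds),
          factor(kinds, levels = c("continuous", "discrete", "pathogen")))
  }
  log <- character()
  allReps <- list(); chosen <- character(); freq <- numeric(0)
  for (gname in names(groupsOf)) {
    feats <- intersect(groupsOf[[gname]], colnames(x))
    if (!length(feats)) {
      log <- c(log, paste0("group '", gname, "' is empty; skipped"))
      next
    }
    xs <- x[, feats, drop = FALSE]
    reps <- runGroupSelection(xs, y, groups, config,
                              k = min(k, ncol(xs)),
                              seed = deriveSeed(config@seed,
                                                match(gname, names(groupsOf))))
    rep_ <- frequencyAnalysis(reps, feats, xs, y, groups, config,
                              k_final = min(k, ncol(xs)),
                              seed = deriveSeed(config@seed, 999L))
    chosen <- c(chosen, rep_@chosen)
    freq <- c(freq, rep_@frequencies)
    allReps[[gname]] <- reps
  }
  new("SelectionReport",
      frequencies = freq, chosen = chosen,
      kCurve = data.frame(k = integer(), score_mean = numeric(),
                          score_sd = numeric()),
      scenario = as.integer(scenario), holdout = split$holdout,
      details = list(log = log, split = split, k = k,
                     estimator = config@estimator,
                     repetition_subsets = allReps))
}
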