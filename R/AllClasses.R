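#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames colData rowData
NULL

#' Configuration of the synthetic two-arm ICU cohort generator
#'
#' Parameters of the latent organ-dysfunction simulator. Defaults emulate the
#' structure of the TDM trial the analysis was designed for: 123 TDM and 125
#' control patients followed for up to 10 days, 199 observed features (150
#' continuous, 13 discrete, 36 pathogen presence flags) of which 28 carry
#' signal about the latent organ states.
#'
#' @slot nTdm,nControl number of patients per arm.
#' @slot nContinuous,nDiscrete,nPathogen feature counts by kind.
#' @slot nInformative number of continuous/discrete features causally tied to
#'   the latent organ states (the rest are pure noise).
#' @slot maxDays maximum follow-up, days.
#' @slot recoveryRateControl,recoveryRateTdm exponential decay rate of latent
#'   dysfunction, 1/day; `recoveryRateTdm >= recoveryRateControl` encodes a
#'   beneficial TDM effect, equality the null.
#' @slot effectOnsetDay first day on which the arms' rates may differ.
#' @slot obsNoiseSd Gaussian observation noise on continuous features.
#' @slot deathHazardScale scale of the per-day death hazard (1/day per unit of
#'   summed latent dysfunction); 0 disables death.
#' @slot dischargeSofaThreshold patients leave alive once their total SOFA is
#'   at or below this value; -1 disables discharge.
#' @slot missingRate fraction of feature cells blanked post hoc, in [0, 1).
#' @slot seed integer RNG seed.
#' @export
setClass("CohortConfig",
  representation(
    nTdm = "integer", nControl = "integer",
    nContinuous = "integer", nDiscrete = "integer", nPathogen = "integer",
    nInformative = "integer", maxDays = "integer",
    recoveryRateControl = "numeric", recoveryRateTdm = "numeric",
    effectOnsetDay = "integer", obsNoiseSd = "numeric",
    deathHazardScale = "numeric", dischargeSofaThreshold = "numeric",
    missingRate = "numeric", seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  counts <- c(
    nTdm = object@nTdm, nControl = object@nControl,
    nContinuous = object@nContinuous, nDiscrete = object@nDiscrete,
    nPathogen = object@nPathogen, nInformative = object@nInformative,
    maxDays = object@maxDays
  )
  if (any(counts < 0L)) {
    msg <- c(msg, "all counts must be >= 0")
  }
  if (object@nInformative > object@nContinuous + object@nDiscrete) {
    msg <- c(msg, "nInformative must not exceed nContinuous + nDiscrete")
  }
  if (object@recoveryRateControl < 0 || object@recoveryRateTdm < 0) {
    msg <- c(msg, "recovery rates must be nonnegative")
  }
  if (object@recoveryRateTdm < object@recoveryRateControl) {
    msg <- c(msg, "recoveryRateTdm must be >= recoveryRateControl (equality = null effect)")
  }
  if (object@missingRate < 0 || object@missingRate >= 1) {
    msg <- c(msg, "missingRate must lie in [0, 1)")
  }
  if (object@obsNoiseSd < 0) msg <- c(msg, "obsNoiseSd must be >= 0")
  if (object@deathHazardScale < 0) msg <- c(msg, "deathHazardScale must be >= 0")
  if (object@effectOnsetDay < 1L) msg <- c(msg, "effectOnsetDay must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn CohortConfig-class Constructor with study-scale defaults.
#' @param nTdm,nControl,nContinuous,nDiscrete,nPathogen,nInformative,maxDays,recoveryRateControl,recoveryRateTdm,effectOnsetDay,obsNoiseSd,deathHazardScale,dischargeSofaThreshold,missingRate,seed see slots.
#' @return A validated `CohortConfig`.
#' @export
cohortConfig <- function(nTdm = 123L, nControl = 125L,
                         nContinuous = 150L, nDiscrete = 13L, nPathogen = 36L,
                         nInformative = 28L, maxDays = 10L,
                         recoveryRateControl = 0.15, recoveryRateTdm = 0.25,
                         effectOnsetDay = 2L, obsNoiseSd = 0.3,
                         deathHazardScale = 0.004,
                         dischargeSofaThreshold = 1,
                         missingRate = 0, seed = 1L) {
  new("CohortConfig",
    nTdm = as.integer(nTdm), nControl = as.integer(nControl),
    nContinuous = as.integer(nContinuous), nDiscrete = as.integer(nDiscrete),
    nPathogen = as.integer(nPathogen), nInformative = as.integer(nInformative),
    maxDays = as.integer(maxDays),
    recoveryRateControl = recoveryRateControl, recoveryRateTdm = recoveryRateTdm,
    effectOnsetDay = as.integer(effectOnsetDay), obsNoiseSd = obsNoiseSd,
    deathHazardScale = deathHazardScale,
    dischargeSofaThreshold = dischargeSofaThreshold,
    missingRate = missingRate, seed = as.integer(seed)
  )
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nTdm, "TDM /", object@nControl, "control patients,",
      object@nContinuous + object@nDiscrete + object@nPathogen, "features (",
      object@nInformative, "informative ), up to", object@maxDays, "days\n")
  cat("  recovery rates: control", object@recoveryRateControl,
      "| TDM", object@recoveryRateTdm, "(onset day", object@effectOnsetDay, ")\n")
  invisible(NULL)
})

#' Two-arm longitudinal patient-state container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one column
#' per patient-day state vector. The `"features"` assay stores observed
#' features (rows) by state vector (columns); `colData` carries patient id,
#' arm, day index (day 1 = first day post-randomization), the six SOFA organ
#' subscores, the total SOFA score and exit status; `rowData` carries the
#' feature kind (`continuous`, `discrete`, `pathogen`).
#'
#' @export
setClass("SepsisCohort", contains = "SummarizedExperiment")

setValidity("SepsisCohort", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("patient_id", "arm", "day", sofaSubscoreNames(),
            "sofa_total", "exit_status")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  }
  if (!"features" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'features' is required")
  }
  sub <- as.matrix(as.data.frame(cd[, sofaSubscoreNames()]))
  if (any(sub < 0L | sub > 4L)) msg <- c(msg, "SOFA subscores must lie in 0..4")
  if (any(cd$sofa_total != rowSums(sub))) {
    msg <- c(msg, "sofa_total must equal the sum of the six subscores")
  }
  if (any(cd$day < 1L)) msg <- c(msg, "day index must be >= 1")
  if (anyDuplicated(paste(cd$patient_id, cd$day))) {
    msg <- c(msg, "at most one state vector per (patient_id, day)")
  }
  if (!all(cd$arm %in% c("TDM", "control"))) {
    msg <- c(msg, "arm must be 'TDM' or 'control'")
  }
  if (!all(cd$exit_status %in% c("in_study", "left_alive", "left_dead"))) {
    msg <- c(msg, "exit_status must be in_study/left_alive/left_dead")
  }
  if (length(msg)) msg else TRUE
})

#' Names of the six SOFA organ-system subscore columns
#'
#' Respiratory, cardiovascular, hepatic, coagulation, renal and neurological
#' systems, each scored 0-4.
#' @return Character vector of length 6.
#' @export
sofaSubscoreNames <- function() {
  paste0("sofa_", c("respiratory", "cardiovascular", "hepatic",
                    "coagulation", "renal", "neurological"))
}

setMethod("show", "SepsisCohort", function(object) {
  cd <- colData(object)
  cat("SepsisCohort:", length(unique(cd$patient_id)), "patients,",
      ncol(object), "state vectors,", nrow(object), "features\n")
  cat("  arms:", sum(tapply(cd$arm, cd$patient_id, `[`, 1) == "TDM"), "TDM /",
      sum(tapply(cd$arm, cd$patient_id, `[`, 1) == "control"), "control;",
      "days 1..", max(cd$day), "\n", sep = " ")
  st <- table(tapply(cd$exit_status, cd$patient_id, `[`, 1))
  cat("  exits:", paste(names(st), as.integer(st), collapse = ", ", sep = "="), "\n")
  invisible(NULL)
})

#' SOFA = 1 reference-state distribution
#'
#' Holds the reference member matrix (encoded + scaled state vectors whose
#' total SOFA equals the reference score), their mean and covariance, the
#' regularized inverse covariance used in every Mahalanobis form, and the
#' normalization constant `c` = mean pairwise Mahalanobis distance among the
#' members (so that, after normalization, the distance between reference
#' patients is 1 by construction).
#'
#' @slot members numeric matrix, one reference state vector per row.
#' @slot mu reference mean vector.
#' @slot sigma reference covariance matrix.
#' @slot sigmaInv inverse of `sigma + lambda * I` (symmetric positive definite).
#' @slot lambda ridge regularization added to the covariance diagonal.
#' @slot normConst mean pairwise Mahalanobis distance among members.
#' @slot referenceSofa the SOFA total used as the membership filter.
#' @export
setClass("ReferenceState",
  representation(
    members = "matrix", mu = "numeric", sigma = "matrix",
    sigmaInv = "matrix", lambda = "numeric", normConst = "numeric",
    referenceSofa = "numeric"
  )
)

setValidity("ReferenceState", function(object) {
  msg <- character()
  d <- length(object@mu)
  if (!all(dim(object@sigma) == d) || !all(dim(object@sigmaInv) == d)) {
    msg <- c(msg, "sigma/sigmaInv dimensions must match mu")
  }
  if (max(abs(object@sigmaInv - t(object@sigmaInv))) > 1e-8) {
    msg <- c(msg, "regularized inverse must be symmetric")
  }
  if (object@normConst <= 0) msg <- c(msg, "normalization constant must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceState", function(object) {
  cat("ReferenceState (SOFA =", object@referenceSofa, "):",
      nrow(object@members), "members,", length(object@mu), "dimensions\n")
  cat("  lambda =", format(object@lambda), "; normalization constant c =",
      format(object@normConst), "\n")
  invisible(NULL)
})

#' Fitted leakage-safe encoder/scaler state
#'
#' Smoothed target-mean ("CatBoost-style") encodings for discrete features and
#' standard-scaling parameters for every feature, both fitted on training rows
#' only. Transforming any row — training or unseen — uses exclusively the
#' statistics stored here.
#'
#' @slot encodings named list: per discrete feature, a named numeric vector of
#'   category -> encoded value.
#' @slot prior global training-target mean (fallback for unseen categories).
#' @slot smoothing prior-count smoothing weight.
#' @slot center,scale per-feature standard-scaling parameters (training mean
#'   and standard deviation; zero-spread features get scale 1).
#' @slot columns feature columns in fitted order.
#' @slot discreteColumns subset of `columns` that were target-encoded.
#' @slot trainIds identifiers of the rows the encoder was fitted on.
#' @export
setClass("EncoderState",
  representation(
    encodings = "list", prior = "numeric", smoothing = "numeric",
    center = "numeric", scale = "numeric",
    columns = "character", discreteColumns = "character",
    trainIds = "character"
  )
)

setMethod("show", "EncoderState", function(object) {
  cat("EncoderState:", length(object@columns), "features (",
      length(object@discreteColumns), "target-encoded ), fitted on",
      length(object@trainIds), "rows; smoothing =", object@smoothing, "\n")
  invisible(NULL)
})

#' Genetic-algorithm wrapper configuration
#'
#' Defaults follow the published protocol: populations of 160 individuals
#' evolved for 100 generations with 5-fold grouped cross-validated negative
#' mean absolute error as fitness, 100 outer repetitions and a 10% pick
#' frequency threshold for the final union run. `estimator` picks the fitness
#' model: `"forest"` (information-based random forest on raw features) or
#' `"linear"` (distance-based linear model on encoded + scaled features).
#'
#' @slot populationSize,generations,cvFolds,repetitions integers.
#' @slot frequencyThreshold pick-frequency cutoff in (0, 1).
#' @slot estimator `"forest"` or `"linear"`.
#' @slot tournamentSize parent-selection tournament size.
#' @slot mutationRate per-individual probability of a swap mutation.
#' @slot elitism number of best individuals copied unchanged per generation.
#' @slot forestTrees trees per random forest fit.
#' @slot seed integer RNG seed.
#' @export
setClass("GAConfig",
  representation(
    populationSize = "integer", generations = "integer", cvFolds = "integer",
    repetitions = "integer", frequencyThreshold = "numeric",
    estimator = "character", tournamentSize = "integer",
    mutationRate = "numeric", elitism = "integer", forestTrees = "integer",
    seed = "integer"
  )
)

setValidity("GAConfig", function(object) {
  msg <- character()
  if (object@populationSize < 2L) msg <- c(msg, "populationSize must be >= 2")
  if (object@frequencyThreshold <= 0 || object@frequencyThreshold >= 1) {
    msg <- c(msg, "frequencyThreshold must lie in (0, 1)")
  }
  if (!object@estimator %in% c("forest", "linear")) {
    msg <- c(msg, "estimator must be 'forest' or 'linear'")
  }
  if (object@cvFolds < 2L) msg <- c(msg, "cvFolds must be >= 2")
  if (object@mutationRate < 0 || object@mutationRate > 1) {
    msg <- c(msg, "mutationRate must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GAConfig-class Constructor with protocol-scale defaults.
#' @param populationSize,generations,cvFolds,repetitions,frequencyThreshold,estimator,tournamentSize,mutationRate,elitism,forestTrees,seed see slots.
#' @export
gaConfig <- function(populationSize = 160L, generations = 100L, cvFolds = 5L,
                     repetitions = 100L, frequencyThreshold = 0.10,
                     estimator = c("forest", "linear"), tournamentSize = 3L,
                     mutationRate = 0.1, elitism = 1L, forestTrees = 100L,
                     seed = 1L) {
  new("GAConfig",
    populationSize = as.integer(populationSize),
    generations = as.integer(generations), cvFolds = as.integer(cvFolds),
    repetitions = as.integer(repetitions),
    frequencyThreshold = frequencyThreshold,
    estimator = match.arg(estimator), tournamentSize = as.integer(tournamentSize),
    mutationRate = mutationRate, elitism = as.integer(elitism),
    forestTrees = as.integer(forestTrees), seed = as.integer(seed)
  )
}

setMethod("show", "GAConfig", function(object) {
  cat("GAConfig:", object@populationSize, "individuals x",
      object@generations, "generations,", object@repetitions,
      "repetitions; estimator =", object@estimator,
      "; cv =", object@cvFolds, "\n")
  invisible(NULL)
})

#' Feature-selection report
#'
#' Output of the repeated GA wrapper: per-feature pick frequencies across
#' repetitions, the per-k cross-validation score curve, and the final chosen
#' feature set from the thresholded-union GA run.
#'
#' @slot frequencies named numeric in [0, 1], one entry per feature.
#' @slot chosen final selected feature names.
#' @slot kCurve data.frame with columns `k`, `score_mean`, `score_sd`.
#' @slot scenario scenario id 1-4.
#' @slot holdout patient ids excluded from selection.
#' @slot details list of run metadata (seeds, pool, fallbacks triggered).
#' @export
setClass("SelectionReport",
  representation(
    frequencies = "numeric", chosen = "character", kCurve = "data.frame",
    scenario = "integer", holdout = "character", details = "list"
  )
)

setValidity("SelectionReport", function(object) {
  msg <- character()
  if (length(object@frequencies) &&
      (min(object@frequencies) < 0 || max(object@frequencies) > 1)) {
    msg <- c(msg, "frequencies must lie in [0, 1]")
  }
  if (!all(object@chosen %in% names(object@frequencies))) {
    msg <- c(msg, "chosen set must be a subset of the feature universe")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionReport", function(object) {
  cat("SelectionReport (scenario", object@scenario, "):",
      length(object@chosen), "features chosen of",
      length(object@frequencies), ";", length(object@holdout),
      "holdout patients\n")
  top <- sort(object@frequencies, decreasing = TRUE)
  top <- head(top, 5L)
  cat("  top pick frequencies:",
      paste(names(top), format(top, digits = 2), collapse = ", "), "\n")
  invisible(NULL)
})
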