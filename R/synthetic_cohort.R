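#' @importFrom stats rnorm rgamma rbinom runif median sd var complete.cases
NULL

## Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Map latent organ-dysfunction levels to SOFA subscores and total
#'
#' Each of the six organ systems (respiratory, cardiovascular, hepatic,
#' coagulation, renal, neurological) is scored 0-4 by binning its nonnegative
#' latent dysfunction level at fixed thresholds; the total SOFA score is the
#' sum of the six subscores and ranges 0-24. The binning makes the score's
#' degeneracy explicit: very different organ profiles can share a total.
#'
#' @param latent numeric vector of six nonnegative latent levels, or a
#'   6-row matrix (one column per state).
#' @param thresholds increasing cut points defining subscores 0..4.
#' @return list with `subscores` (integer, 6 x n) and `total` (integer n).
#' @examples
#' computeSofa(rep(4, 6))$total  # 24
#' computeSofa(rep(0, 6))$total  # 0
#' @export
computeSofa <- function(latent, thresholds = c(0.5, 1.5, 2.5, 3.5)) {
  if (is.null(dim(latent))) latent <- matrix(latent, ncol = 1L)
  if (nrow(latent) != 6L) {
    stop("latent organ state must have exactly six organ systems, got ",
         nrow(latent))
  }
  if (any(latent < 0)) stop("latent dysfunction levels must be nonnegative")
  sub <- vapply(seq_len(ncol(latent)), function(j) {
    vapply(latent[, j], function(v) sum(v >= thresholds), integer(1))
  }, integer(6))
  sub <- matrix(as.integer(sub), nrow = 6L,
                dimnames = list(sofaSubscoreNames(), colnames(latent)))
  list(subscores = sub, total = as.integer(colSums(sub)))
}

## Structural (seed-fixed) parameters shared by all patients of a cohort.
cohortStructure <- function(config) {
  nc <- config@nContinuous; nd <- config@nDiscrete; np <- config@nPathogen
  niC <- min(config@nInformative, nc)
  niD <- config@nInformative - niC
  contNames <- if (nc) sprintf("cont_%03d", seq_len(nc)) else character()
  discNames <- if (nd) sprintf("disc_%02d", seq_len(nd)) else character()
  pathNames <- if (np) sprintf("path_%02d", seq_len(np)) else character()
  ## informative loadings: each informative feature mixes 1-3 organ systems
  loading <- function(n, signed) {
    W <- matrix(0, nrow = n, ncol = 6L)
    for (i in seq_len(n)) {
      organs <- sample.int(6L, sample(1:3, 1L))
      W[i, organs] <- runif(length(organs), 0.5, 1.5)
      if (signed) W[i, organs] <- W[i, organs] * sample(c(-1, 1), 1L)
    }
    W
  }
  list(
    contNames = contNames, discNames = discNames, pathNames = pathNames,
    niC = niC, niD = niD,
    contW = loading(niC, signed = TRUE),
    discW = loading(niD, signed = FALSE),
    pathPrev = if (np) runif(np, 0.02, 0.30) else numeric()
  )
}

#' Generate a synthetic two-arm ICU cohort
#'
#' Simulates, reproducibly from `config@seed`, one latent organ-dysfunction
#' trajectory per patient: initial levels are drawn identically in both arms
#' (arms exchangeable on day 1), then decay exponentially — at the control
#' rate on days up to `effectOnsetDay` and at the arm's own rate afterwards.
#' Observed continuous features are linear mixes of the latent levels plus
#' Gaussian noise for informative features and pure noise otherwise; discrete
#' features are threshold bins; pathogen flags are baseline Bernoulli draws
#' with arm-shared prevalences, constant over the stay. Patients leave alive
#' once their total SOFA falls to `dischargeSofaThreshold` or below, die with
#' a per-day hazard increasing in total latent dysfunction, and are otherwise
#' censored in study at `maxDays`.
#'
#' @param config a [CohortConfig-class] object.
#' @return A [SepsisCohort-class]; the latent trajectories are kept in
#'   `metadata(x)$latent` for ground-truth checks.
#' @export
generateCohort <- function(config) {
  validObject(config)
  nPat <- config@nTdm + config@nControl
  nFeat <- config@nContinuous + config@nDiscrete + config@nPathogen
  if (nPat == 0L) stop("degenerate config: zero patients")
  if (nFeat == 0L) stop("degenerate config: zero features")

  out <- withSeed(config@seed, {
    st <- cohortStructure(config)
    ids <- c(sprintf("T%03d", seq_len(config@nTdm)),
             sprintf("C%03d", seq_len(config@nControl)))
    armOf <- c(rep("TDM", config@nTdm), rep("control", config@nControl))
    featNames <- c(st$contNames, st$discNames, st$pathNames)

    featCols <- list(); latCols <- list(); meta <- list()
    for (p in seq_len(nPat)) {
      rate <- if (armOf[p] == "TDM") config@recoveryRateTdm else config@recoveryRateControl
      L <- rgamma(6L, shape = 6, rate = 3)
      pathFlags <- if (config@nPathogen) {
        as.numeric(rbinom(config@nPathogen, 1L, st$pathPrev))
      } else numeric()
      status <- "in_study"; lastDay <- 0L
      for (t in seq_len(config@maxDays)) {
        if (t > 1L) {
          r <- if (t > config@effectOnsetDay) rate else config@recoveryRateControl
          L <- L * exp(-r)
        }
        sofa <- computeSofa(L)
        x <- numeric(0)
        if (config@nContinuous) {
          xc <- rnorm(config@nContinuous)
          if (st$niC) {
            xc[seq_len(st$niC)] <- as.numeric(st$contW %*% L) +
              rnorm(st$niC, sd = config@obsNoiseSd)
          }
          x <- c(x, xc)
        }
        if (config@nDiscrete) {
          xd <- as.numeric(rbinom(config@nDiscrete, 3L, 0.4))
          if (st$niD) {
            q <- as.numeric(st$discW %*% L) / 1.5 +
              rnorm(st$niD, sd = config@obsNoiseSd)
            xd[seq_len(st$niD)] <- vapply(
              q, function(v) sum(v >= c(0.5, 1.5, 2.5, 3.5)), numeric(1))
          }
          x <- c(x, xd)
        }
        x <- c(x, pathFlags)
        key <- paste0(ids[p], "_d", t)
        featCols[[key]] <- x
        latCols[[key]] <- L
        meta[[key]] <- data.frame(
          patient_id = ids[p], arm = armOf[p], day = t,
          t(sofa$subscores[, 1]), sofa_total = sofa$total,
          stringsAsFactors = FALSE)
        lastDay <- t
        if (sofa$total <= config@dischargeSofaThreshold) {
          status <- "left_alive"; break
        }
        hazard <- 1 - exp(-config@deathHazardScale * sum(L))
        if (hazard > 0 && runif(1) < hazard) {
          status <- "left_dead"; break
        }
      }
      for (t in seq_len(lastDay)) {
        key <- paste0(ids[p], "_d", t)
        meta[[key]]$exit_status <- status
        meta[[key]]$exit_day <- lastDay
      }
    }

    assayMat <- do.call(cbind, featCols)
    rownames(assayMat) <- featNames
    latent <- do.call(cbind, latCols)
    rownames(latent) <- c("respiratory", "cardiovascular", "hepatic",
                          "coagulation", "renal", "neurological")
    cd <- do.call(rbind, meta)
    rownames(cd) <- names(meta)
    kinds <- c(rep("continuous", config@nContinuous),
               rep("discrete", config@nDiscrete),
               rep("pathogen", config@nPathogen))
    informative <- c(seq_len(config@nContinuous) <= st$niC,
                     seq_len(config@nDiscrete) <= st$niD,
                     rep(FALSE, config@nPathogen))
    se <- SummarizedExperiment(
      assays = list(features = assayMat),
      colData = S4Vectors::DataFrame(cd),
      rowData = S4Vectors::DataFrame(kind = kinds, informative = informative,
                                     row.names = featNames)
    )
    out <- methods::new("SepsisCohort", se)
    metadata(out)$config <- config
    metadata(out)$latent <- latent
    out
  })
  if (config@missingRate > 0) {
    out <- injectMissingness(out, config@missingRate,
                             seed = deriveSeed(config@seed, 777L))
  }
  out
}

#' State vectors as a samples-by-features matrix
#' @param cohort a [SepsisCohort-class].
#' @return numeric matrix, one row per patient-day.
#' @export
stateMatrix <- function(cohort) t(assay(cohort, "features"))

#' Per-patient exit summary
#' @param cohort a [SepsisCohort-class].
#' @return data.frame with one row per patient: `patient_id`, `arm`,
#'   `exit_status`, `exit_day`.
#' @export
cohortExits <- function(cohort) {
  cd <- as.data.frame(colData(cohort))
  out <- cd[!duplicated(cd$patient_id),
            c("patient_id", "arm", "exit_status", "exit_day")]
  rownames(out) <- NULL
  out
}

#' Feature kinds of a cohort
#' @param cohort a [SepsisCohort-class].
#' @return named character vector (`continuous`/`discrete`/`pathogen`).
#' @export
featureKinds <- function(cohort) {
  k <- rowData(cohort)$kind
  names(k) <- rownames(cohort)
  k
}

#' Blank feature cells at random to emulate missing clinical data
#'
#' Each feature cell is independently set to `NA` with probability
#' `missing_rate`; SOFA scores, identifiers and exit information are never
#' blanked. Reproducible given `seed`.
#'
#' @param cohort a [SepsisCohort-class].
#' @param missing_rate probability in [0, 1) of blanking a cell.
#' @param seed integer RNG seed.
#' @return The cohort with `NA` holes in its `features` assay.
#' @export
injectMissingness <- function(cohort, missing_rate, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (missing_rate == 0) return(cohort)
  m <- assay(cohort, "features")
  withSeed(seed, {
    holes <- matrix(runif(length(m)) < missing_rate, nrow = nrow(m))
    m[holes] <- NA_real_
  })
  SummarizedExperiment::assay(cohort, "features") <- m
  cohort
}

## full-precision numeric formatting so CSV round-trips are exact
fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

configToList <- function(config) {
  sl <- methods::slotNames(config)
  out <- lapply(sl, function(s) methods::slot(config, s))
  names(out) <- sl
  out
}

listToConfig <- function(lst) do.call(cohortConfig, lst)

#' Write a cohort to CSV (long or wide patient-card format)
#'
#' Long format has columns `patient_id, arm, day, feature, value` with SOFA
#' subscores, totals and exit information carried as reserved feature rows;
#' wide format has one row per patient-day. Values are written at full
#' precision so a write-read round trip is exact; missing cells are empty
#' strings. A JSON sidecar (`<path>.json`) records the feature schema and,
#' when available, the generating [CohortConfig-class].
#'
#' @param cohort a [SepsisCohort-class] with at least one state vector.
#' @param path output CSV path.
#' @param format `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (ncol(cohort) == 0L) stop("cohort has no state vectors")
  cd <- as.data.frame(colData(cohort))
  m <- assay(cohort, "features")
  if (format == "wide") {
    df <- data.frame(
      patient_id = cd$patient_id, arm = cd$arm, day = cd$day,
      exit_status = cd$exit_status, exit_day = cd$exit_day,
      as.data.frame(cd[, c(sofaSubscoreNames(), "sofa_total")]),
      stringsAsFactors = FALSE, check.names = FALSE)
    fm <- as.data.frame(apply(t(m), 2L, fmtNum), stringsAsFactors = FALSE,
                        check.names = FALSE)
    if (nrow(df) == 1L) fm <- as.data.frame(t(fm), check.names = FALSE)
    colnames(fm) <- rownames(m)
    df <- cbind(df, fm)
  } else {
    n <- ncol(m)
    featBlock <- data.frame(
      patient_id = rep(cd$patient_id, each = nrow(m)),
      arm = rep(cd$arm, each = nrow(m)),
      day = rep(cd$day, each = nrow(m)),
      feature = rep(rownames(m), times = n),
      value = fmtNum(as.numeric(m)),
      stringsAsFactors = FALSE)
    metaNames <- c(sofaSubscoreNames(), "sofa_total", "exit_status", "exit_day")
    metaBlock <- do.call(rbind, lapply(metaNames, function(nm) {
      data.frame(patient_id = cd$patient_id, arm = cd$arm, day = cd$day,
                 feature = nm,
                 value = as.character(cd[[nm]]),
                 stringsAsFactors = FALSE)
    }))
    df <- rbind(featBlock, metaBlock)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  sidecar <- list(
    format = format,
    features = rownames(m),
    kind = as.character(rowData(cohort)$kind),
    informative = as.logical(rowData(cohort)$informative)
  )
  if (!is.null(metadata(cohort)$config)) {
    sidecar$config <- configToList(metadata(cohort)$config)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort written by [writeCohort()]
#' @param path CSV path (the `<path>.json` sidecar must sit next to it).
#' @return A [SepsisCohort-class].
#' @export
readCohort <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  feats <- sidecar$features
  if (identical(sidecar$format, "wide")) {
    m <- t(vapply(feats, function(f) {
      suppressWarnings(as.numeric(ifelse(df[[f]] == "", NA, df[[f]])))
    }, numeric(nrow(df))))
    if (nrow(df) == 1L) m <- matrix(m, ncol = 1L)
    rownames(m) <- feats
    cd <- data.frame(
      patient_id = df$patient_id, arm = df$arm, day = as.integer(df$day),
      exit_status = df$exit_status, exit_day = as.integer(df$exit_day),
      stringsAsFactors = FALSE)
    for (nm in sofaSubscoreNames()) cd[[nm]] <- as.integer(df[[nm]])
    cd$sofa_total <- as.integer(df$sofa_total)
  } else {
    keys <- unique(df[, c("patient_id", "arm", "day")])
    keys$day <- as.integer(keys$day)
    id <- paste0(df$patient_id, "_d", df$day)
    uid <- paste0(keys$patient_id, "_d", keys$day)
    m <- matrix(NA_real_, nrow = length(feats), ncol = length(uid),
                dimnames = list(feats, uid))
    isFeat <- df$feature %in% feats
    m[cbind(match(df$feature[isFeat], feats), match(id[isFeat], uid))] <-
      suppressWarnings(as.numeric(ifelse(df$value[isFeat] == "", NA,
                                         df$value[isFeat])))
    pull <- function(nm, cast) {
      rows <- df$feature == nm
      out <- rep(NA_character_, length(uid))
      out[match(id[rows], uid)] <- df$value[rows]
      cast(out)
    }
    cd <- keys
    for (nm in sofaSubscoreNames()) cd[[nm]] <- pull(nm, as.integer)
    cd$sofa_total <- pull("sofa_total", as.integer)
    cd$exit_status <- pull("exit_status", as.character)
    cd$exit_day <- pull("exit_day", as.integer)
  }
  cd <- cd[, c("patient_id", "arm", "day", sofaSubscoreNames(), "sofa_total",
               "exit_status", "exit_day")]
  colnames(m) <- paste0(cd$patient_id, "_d", cd$day)
  rownames(cd) <- colnames(m)
  se <- SummarizedExperiment(
    assays = list(features = m),
    colData = S4Vectors::DataFrame(cd),
    rowData = S4Vectors::DataFrame(kind = sidecar$kind,
                                   informative = sidecar$informative,
                                   row.names = feats))
  out <- methods::new("SepsisCohort", se)
  if (!is.null(sidecar$config)) {
    metadata(out)$config <- listToConfig(sidecar$config)
  }
  out
}
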