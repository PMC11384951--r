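## End-to-end orchestration: generate -> prep -> encode -> select ->
## trajectory -> stats, with derived per-stage seeds, structured logging and
## a hashed report bundle.

#' Assemble a full pipeline run configuration
#'
#' Bundles the cohort generator settings, preparation thresholds, encoder
#' smoothing, GA configuration and scenario, state-space and statistics
#' settings under one master seed. Every stage seed is derived
#' deterministically from the master seed, so a configuration identifies a
#' run bit-for-bit.
#'
#' @param cohort a [CohortConfig-class].
#' @param ga a [GAConfig-class].
#' @param scenario feature-selection scenario 1-4.
#' @param k GA subset cardinality.
#' @param holdout_n patients held out of feature selection.
#' @param max_missing_drop,max_missing_impute,uniqueness_threshold data
#'   preparation thresholds.
#' @param smoothing target-encoder smoothing weight.
#' @param reference_sofa,regularization state-space settings.
#' @param day_cutoff exclusive exit-day cutoff for the last-SOFA ANOVA.
#' @param master_seed integer master seed.
#' @return A `runConfig` list.
#' @export
runConfig <- function(cohort = cohortConfig(), ga = gaConfig(),
                      scenario = 1L, k = 5L, holdout_n = 10L,
                      max_missing_drop = 0.5, max_missing_impute = 0.05,
                      uniqueness_threshold = 11, smoothing = 1,
                      reference_sofa = 1, regularization = NULL,
                      day_cutoff = 11, master_seed = 1L) {
  structure(list(
    cohort = cohort, ga = ga, scenario = as.integer(scenario),
    k = as.integer(k), holdout_n = as.integer(holdout_n),
    max_missing_drop = max_missing_drop,
    max_missing_impute = max_missing_impute,
    uniqueness_threshold = uniqueness_threshold, smoothing = smoothing,
    reference_sofa = reference_sofa, regularization = regularization,
    day_cutoff = day_cutoff, master_seed = as.integer(master_seed)
  ), class = "runConfig")
}

#' @export
print.runConfig <- function(x, ...) {
  cat("runConfig: scenario", x$scenario, ", k =", x$k,
      ", master seed", x$master_seed, "\n")
  show(x$cohort); show(x$ga)
  invisible(x)
}

#' Write / read a run configuration as YAML
#' @param config a `runConfig`.
#' @param path YAML file path.
#' @return `readRunConfig` returns the reconstructed `runConfig`;
#'   `writeRunConfig` returns `path` invisibly. The round trip is lossless.
#' @export
writeRunConfig <- function(config, path) {
  lst <- unclass(config)
  lst$cohort <- configToList(config$cohort)
  lst$ga <- lapply(stats::setNames(methods::slotNames(config$ga),
                                   methods::slotNames(config$ga)),
                   function(s) methods::slot(config$ga, s))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$cohort <- listToConfig(lst$cohort)
  lst$ga <- do.call(gaConfig, lst$ga)
  do.call(runConfig, c(lst[setdiff(names(lst), "master_seed")],
                       list(master_seed = lst$master_seed)))
}

stageSeeds <- function(master) {
  stages <- c("generate", "prep", "encode", "select", "trajectory", "stats")
  stats::setNames(vapply(seq_along(stages), function(i) {
    deriveSeed(master, i * 101L)
  }, integer(1)), stages)
}

#' Execute the full analysis pipeline
#'
#' Runs generate, prepare, select, trajectory and statistics stages in
#' order, reproducibly from the master seed, and (optionally) writes the
#' report bundle via [emitReport()]. The trajectory stage restricts the
#' state space to the features chosen by the selection stage and excludes
#' the holdout patients from encoder fitting and reference membership.
#'
#' @param config a [runConfig()].
#' @param outdir output directory for the report bundle; `NULL` skips
#'   emission.
#' @param verbose print per-stage progress.
#' @return list with `cohort`, `prep`, `selection`, `trajectory`, `stats`,
#'   `config`, `seeds` and, when emitted, `manifest`.
#' @export
runPipeline <- function(config, outdir = NULL, verbose = FALSE) {
  seeds <- stageSeeds(config$master_seed)
  note <- function(...) if (verbose) message("[sofaspace] ", ...)

  note("generate: synthetic cohort")
  cohortCfg <- config$cohort
  cohortCfg@seed <- seeds[["generate"]]
  cohort <- generateCohort(cohortCfg)

  note("prep: drop / impute / schema")
  prep <- prepareCohort(cohort,
                        max_missing_drop = config$max_missing_drop,
                        max_missing_impute = config$max_missing_impute,
                        uniqueness_threshold = config$uniqueness_threshold)

  note("select: GA scenario ", config$scenario)
  ga <- config$ga
  ga@seed <- seeds[["select"]]
  selection <- runScenario(prep$cohort, config$scenario, ga, k = config$k,
                           holdout_n = config$holdout_n,
                           smoothing = config$smoothing)

  note("trajectory: Mahalanobis state-space analysis")
  chosen <- selection@chosen
  sub <- if (length(chosen)) prep$cohort[chosen, ] else prep$cohort
  traj <- trajectoryAnalysis(sub,
                             reference_sofa = config$reference_sofa,
                             regularization = config$regularization,
                             smoothing = config$smoothing,
                             exclude_patients = selection@holdout)

  note("stats: exits, last SOFA, ANOVA, similarity")
  exits <- exitCurves(cohort)
  lastSofa <- lastSofaByDay(cohort, day_cutoff = config$day_cutoff)
  records <- attr(lastSofa, "records")
  anova <- if (length(unique(records$group)) >= 2L &&
                 length(unique(records$day)) >= 2L) {
    anovaGroupTime(records)
  } else NULL
  cd <- colData(sub)
  enc <- encodeStates(sub, smoothing = config$smoothing)
  day1 <- cd$day == 1L
  sim <- day1Similarity(enc$matrix[day1, , drop = FALSE], cd$arm[day1],
                        seed = seeds[["stats"]])
  exitComparison <- compareExitDistributions(exits)

  results <- list(
    cohort = cohort, prep = prep, selection = selection, trajectory = traj,
    stats = list(exits = exits, last_sofa = lastSofa, anova = anova,
                 day1_similarity = sim, exit_comparison = exitComparison),
    config = config, seeds = seeds)
  if (!is.null(outdir)) {
    results$manifest <- emitReport(results, outdir)
  }
  results
}

#' Compare the arms' exit-day distributions
#'
#' KS statistic and Hellinger distance between the per-patient exit-day
#' samples of the two arms, separately for alive and dead leavers, with
#' integer-day bins spanning the union support.
#'
#' @param exits output of [exitCurves()].
#' @return data.frame `status`, `ks`, `hellinger`, `n_tdm`, `n_control`
#'   (NA where a status has an empty sample in either arm).
#' @export
compareExitDistributions <- function(exits) {
  do.call(rbind, lapply(c("alive", "dead"), function(st) {
    a <- exits$exit_days[["TDM"]][[st]]
    b <- exits$exit_days[["control"]][[st]]
    if (!length(a) || !length(b)) {
      return(data.frame(status = st, ks = NA_real_, hellinger = NA_real_,
                        n_tdm = length(a), n_control = length(b)))
    }
    breaks <- seq(min(c(a, b)) - 0.5, max(c(a, b)) + 0.5, by = 1)
    data.frame(status = st,
               ks = ksStatistic(a, b),
               hellinger = hellingerDistance(binDensity(a, breaks),
                                             binDensity(b, breaks)),
               n_tdm = length(a), n_control = length(b))
  }))
}

writeTable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

savePlot <- function(p, path, width = 7, height = 5) {
  grDevices::png(path, width = width * 96, height = height * 96,
                 res = 96, type = "cairo")
  print(p)
  grDevices::dev.off()
  path
}

#' Write the report bundle for a pipeline run
#'
#' Emits the trajectory table, selection frequencies, exit tables,
#' statistics summaries (CSV/JSON) and the standard figures (normalized
#' trajectory curves, pick-frequency bars, exit curves), plus a manifest
#' listing every artifact with its MD5 hash.
#'
#' @param results list returned by [runPipeline()].
#' @param outdir output directory (created if needed).
#' @return data.frame manifest (`file`, `md5`), invisibly written as
#'   `manifest.csv`.
#' @export
emitReport <- function(results, outdir) {
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- character()
  add <- function(p) files <<- c(files, p)

  metrics <- results$trajectory$metrics
  add(writeTable(metrics, file.path(outdir, "trajectory.csv")))

  sel <- results$selection
  selDf <- data.frame(feature = names(sel@frequencies),
                      frequency = unname(sel@frequencies),
                      chosen = names(sel@frequencies) %in% sel@chosen)
  add(writeTable(selDf, file.path(outdir, "selection.csv")))

  add(writeTable(results$stats$exits$table, file.path(outdir, "exit_curves.csv")))
  add(writeTable(results$stats$last_sofa, file.path(outdir, "last_sofa.csv")))
  add(writeTable(results$stats$exit_comparison,
                 file.path(outdir, "exit_comparison.csv")))
  if (!is.null(results$stats$anova)) {
    add(writeTable(results$stats$anova, file.path(outdir, "anova.csv")))
  }

  summaryJson <- list(
    master_seed = results$config$master_seed,
    stage_seeds = as.list(results$seeds),
    scenario = sel@scenario,
    chosen_features = sel@chosen,
    holdout_patients = sel@holdout,
    reference = list(
      sofa = results$trajectory$reference@referenceSofa,
      members = nrow(results$trajectory$reference@members),
      lambda = results$trajectory$reference@lambda,
      norm_const = results$trajectory$reference@normConst),
    day1_similarity_p = results$stats$day1_similarity$p_value)
  jsonPath <- file.path(outdir, "summary.json")
  jsonlite::write_json(summaryJson, jsonPath, auto_unbox = TRUE, digits = NA)
  add(jsonPath)

  cfgPath <- file.path(outdir, "config.yaml")
  writeRunConfig(results$config, cfgPath)
  add(cfgPath)

  pm <- metrics[!is.na(metrics$mean_norm), ]
  add(savePlot(
    ggplot2::ggplot(pm, ggplot2::aes(x = day, y = mean_norm, colour = arm)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "day after randomization",
                    y = "normalized mean Mahalanobis distance",
                    title = "Distance to the SOFA = 1 reference state") +
      ggplot2::theme_minimal(),
    file.path(outdir, "trajectory.png")))

  topSel <- selDf[order(-selDf$frequency), ]
  topSel <- head(topSel, 40L)
  topSel$feature <- factor(topSel$feature, levels = rev(topSel$feature))
  add(savePlot(
    ggplot2::ggplot(topSel,
                    ggplot2::aes(x = feature, y = frequency, fill = chosen)) +
      ggplot2::geom_col() + ggplot2::coord_flip() +
      ggplot2::labs(y = "GA pick frequency", x = NULL,
                    title = "Feature pick frequency across GA repetitions") +
      ggplot2::theme_minimal(),
    file.path(outdir, "selection.png")))

  et <- results$stats$exits$table
  etLong <- rbind(
    data.frame(arm = et$arm, day = et$day, count = et$cum_alive,
               status = "left alive"),
    data.frame(arm = et$arm, day = et$day, count = et$cum_dead,
               status = "left dead"))
  add(savePlot(
    ggplot2::ggplot(etLong,
                    ggplot2::aes(x = day, y = count, colour = arm)) +
      ggplot2::geom_step() +
      ggplot2::facet_wrap(~status) +
      ggplot2::labs(x = "day", y = "cumulative patients",
                    title = "Study exits by arm") +
      ggplot2::theme_minimal(),
    file.path(outdir, "exits.png")))

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  writeTable(manifest, file.path(outdir, "manifest.csv"))
  manifest
}
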