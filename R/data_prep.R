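## Data preparation: raw heterogeneous per-day records -> one clean state
## vector per patient-day, split into continuous/discrete/pathogen groups.

#' Collapse repeated same-day measurements to one value per patient-day-feature
#'
#' Features on the averaging list (vitals, labs, dosing rates in the source
#' protocol) are represented by the arithmetic mean of all same-day entries;
#' all other features keep their last entry of the day. Single entries pass
#' through unchanged.
#'
#' @param records data.frame with columns `patient_id`, `day`, `feature`,
#'   `value` (one row per raw entry; multiple rows per key allowed).
#' @param mean_features character vector of feature names aggregated by mean.
#' @return data.frame with one row per (patient_id, day, feature).
#' @export
aggregateDaily <- function(records, mean_features = character()) {
  stopifnot(all(c("patient_id", "day", "feature", "value") %in% names(records)))
  key <- paste(records$patient_id, records$day, records$feature, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(i) {
    r <- records[i, , drop = FALSE]
    f <- r$feature[1]
    if (f %in% mean_features) {
      v <- suppressWarnings(as.numeric(r$value))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1]
        stop(sprintf(
          "non-numeric entry '%s' for mean-aggregated feature '%s' (patient %s, day %s)",
          r$value[bad], f, r$patient_id[bad], r$day[bad]))
      }
      r$value <- NULL
      out <- r[1, , drop = FALSE]
      out$value <- mean(v)
      out
    } else {
      r[nrow(r), , drop = FALSE]
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$day, out$feature),
             c("patient_id", "day", "feature", "value")]
  rownames(out) <- NULL
  out
}

#' Convert mixed-unit measurements to each feature's canonical unit
#'
#' When the same feature is reported in several units (e.g. g and mg), all
#' values are rescaled to the canonical unit by the multiplier in `unit_map`
#' and the unit tags are dropped.
#'
#' @param records data.frame with a numeric `value` column and a `unit`
#'   column of unit tags (`NA`/empty = already canonical).
#' @param unit_map data.frame with columns `unit` and `factor`: multiply a
#'   value in `unit` by `factor` to express it in the canonical unit.
#'   Canonical tags map with factor 1.
#' @return `records` with rescaled `value` and no `unit` column.
#' @export
harmonizeUnits <- function(records, unit_map) {
  stopifnot(all(c("unit", "factor") %in% names(unit_map)))
  u <- records$unit
  active <- !is.na(u) & u != ""
  unknown <- setdiff(unique(u[active]), unit_map$unit)
  if (length(unknown)) {
    stop("unknown unit tag(s): ", paste(unknown, collapse = ", "))
  }
  fac <- unit_map$factor[match(u[active], unit_map$unit)]
  records$value[active] <- as.numeric(records$value[active]) * fac
  records$unit <- NULL
  records
}

#' Derive per-patient exit status from death markers in the records
#'
#' A patient is flagged dead iff any record value matches one of the supplied
#' death markers (the raw trial logs encoded death in many inconsistent
#' spellings, hence a configurable marker list); the patient's last observed
#' day is their exit day. If records exist after a matched death marker the
#' evidence conflicts: a warning is raised and dead wins.
#'
#' @param records data.frame with `patient_id`, `day`, `value`.
#' @param death_markers character vector of values implying death.
#' @return data.frame with one row per patient: `patient_id`, `exit_status`
#'   (`left_alive`/`left_dead`), `exit_day`.
#' @export
deriveExitFlags <- function(records, death_markers = character()) {
  out <- lapply(split(records, records$patient_id), function(r) {
    dead <- as.character(r$value) %in% death_markers
    status <- if (any(dead)) "left_dead" else "left_alive"
    lastDay <- max(r$day)
    if (any(dead) && max(r$day[dead]) < lastDay) {
      warning(sprintf(
        "patient %s has records after a death marker (day %d < %d); flagging dead",
        r$patient_id[1], max(r$day[dead]), lastDay))
    }
    data.frame(patient_id = r$patient_id[1], exit_status = status,
               exit_day = lastDay, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Drop zero-variance and mostly-missing columns
#'
#' @param table wide data.frame (one row per patient-day).
#' @param max_missing_fraction columns whose missing fraction exceeds this
#'   are dropped (default 0.5).
#' @param protect column names never dropped (identifiers etc.).
#' @return list with `table` (reduced) and `log` (data.frame `column`,
#'   `reason` for every drop).
#' @export
dropUninformative <- function(table, max_missing_fraction = 0.5,
                              protect = c("patient_id", "arm", "day")) {
  log <- data.frame(column = character(), reason = character(),
                    stringsAsFactors = FALSE)
  for (cn in setdiff(names(table), protect)) {
    x <- table[[cn]]
    missFrac <- mean(is.na(x))
    if (missFrac > max_missing_fraction) {
      log <- rbind(log, data.frame(column = cn, reason = sprintf(
        "missing fraction %.3f > %.3f", missFrac, max_missing_fraction)))
    } else if (length(unique(x[!is.na(x)])) <= 1L) {
      log <- rbind(log, data.frame(column = cn, reason = "zero variance"))
    }
  }
  list(table = table[, setdiff(names(table), log$column), drop = FALSE],
       log = log)
}

statMode <- function(x) {
  tab <- table(x)
  cand <- names(tab)[tab == max(tab)]
  sort(cand)[1]  # lexicographically smallest on ties: deterministic, seed-free
}

#' Fill remaining missing values
#'
#' Numeric holes are replaced by the column median of the observed values,
#' categorical holes by the most frequent level (ties broken by taking the
#' lexicographically smallest level). Intended for columns whose missing
#' fraction is already small; columns exceeding `max_missing_fraction` should
#' have been dropped and raise an error here.
#'
#' @param table wide data.frame.
#' @param max_missing_fraction imputation eligibility threshold (default 0.05).
#' @return `table` with no missing values.
#' @export
imputeMissing <- function(table, max_missing_fraction = 0.05) {
  for (cn in names(table)) {
    x <- table[[cn]]
    if (!anyNA(x)) next
    if (all(is.na(x))) {
      stop("column '", cn, "' is entirely missing; it should have been dropped")
    }
    if (mean(is.na(x)) > max_missing_fraction) {
      stop(sprintf(
        "column '%s' has missing fraction %.3f > %.3f; drop it before imputing",
        cn, mean(is.na(x)), max_missing_fraction))
    }
    if (is.numeric(x)) {
      x[is.na(x)] <- median(x, na.rm = TRUE)
    } else {
      x[is.na(x)] <- statMode(x[!is.na(x)])
    }
    table[[cn]] <- x
  }
  table
}

#' Expand pathogen reports into per-code binary flags
#'
#' For every pathogen code in the vocabulary three binary columns are
#' produced per patient: presence, whether the pathogen was judged
#' sepsis-causing, and whether it is piperacillin resistant. Patients without
#' reports get all-zero flags.
#'
#' @param records data.frame with `patient_id`, `pathogen_type`,
#'   `can_cause_sepsis` (1 = probable), `pip_resistance` (3 = resistant,
#'   following the source coding 1:sensitive-2:intermediate-3:resistant).
#' @param vocabulary vector of valid pathogen codes.
#' @param patient_ids patients to emit rows for (default: those in `records`).
#' @return data.frame, one row per patient, columns
#'   `path_<code>_present/_sepsis/_resistant`.
#' @export
binarizePathogens <- function(records, vocabulary,
                              patient_ids = unique(records$patient_id)) {
  bad <- setdiff(unique(records$pathogen_type), vocabulary)
  if (length(bad)) {
    stop("pathogen code(s) outside vocabulary: ", paste(bad, collapse = ", "))
  }
  cols <- as.vector(t(outer(vocabulary, c("present", "sepsis", "resistant"),
                            function(v, s) sprintf("path_%s_%s", v, s))))
  out <- matrix(0L, nrow = length(patient_ids), ncol = length(cols),
                dimnames = list(patient_ids, cols))
  for (i in seq_len(nrow(records))) {
    p <- as.character(records$patient_id[i])
    if (!p %in% patient_ids) next
    code <- records$pathogen_type[i]
    out[p, sprintf("path_%s_present", code)] <- 1L
    if (isTRUE(records$can_cause_sepsis[i] == 1)) {
      out[p, sprintf("path_%s_sepsis", code)] <- 1L
    }
    if (isTRUE(records$pip_resistance[i] == 3)) {
      out[p, sprintf("path_%s_resistant", code)] <- 1L
    }
  }
  data.frame(patient_id = patient_ids, out, stringsAsFactors = FALSE,
             check.names = FALSE, row.names = NULL)
}

#' Classify features as continuous, discrete or pathogen
#'
#' A column is continuous when it has more than `uniqueness_threshold`
#' distinct observed values (the protocol's cut is 11), discrete otherwise;
#' pathogen-derived columns are always classed `pathogen` regardless of
#' their value count.
#'
#' @param table wide data.frame of feature columns.
#' @param uniqueness_threshold distinct-value cut (default 11).
#' @param pathogen_cols names of pathogen-derived columns.
#' @param exclude identifier columns to skip.
#' @return data.frame `feature`, `kind` — the feature schema.
#' @export
splitFeatureKinds <- function(table, uniqueness_threshold = 11,
                              pathogen_cols = character(),
                              exclude = c("patient_id", "arm", "day")) {
  feats <- setdiff(names(table), exclude)
  kind <- vapply(feats, function(cn) {
    if (cn %in% pathogen_cols) return("pathogen")
    x <- table[[cn]]
    n <- length(unique(x[!is.na(x)]))
    if (n > uniqueness_threshold) "continuous" else "discrete"
  }, character(1))
  data.frame(feature = feats, kind = unname(kind), stringsAsFactors = FALSE)
}

#' Clean a cohort: drop uninformative features, impute, derive the schema
#'
#' Applies the preparation pipeline to a [SepsisCohort-class] (possibly with
#' injected missingness): zero-variance and mostly-missing features are
#' dropped with a logged reason, remaining holes are median-imputed, and the
#' feature schema is re-derived from the observed values with pathogen
#' columns pinned by the cohort's feature kinds. On a fully observed cohort
#' this is the identity (up to feature ordering).
#'
#' @param cohort a [SepsisCohort-class].
#' @param max_missing_drop drop threshold on the missing fraction.
#' @param max_missing_impute imputation eligibility threshold.
#' @param uniqueness_threshold continuous/discrete cut on distinct values.
#' @return list with `cohort` (clean), `schema` (feature, kind) and
#'   `drop_log`.
#' @export
prepareCohort <- function(cohort, max_missing_drop = 0.5,
                          max_missing_impute = 0.05,
                          uniqueness_threshold = 11) {
  wide <- as.data.frame(stateMatrix(cohort), check.names = FALSE)
  dropped <- dropUninformative(wide, max_missing_drop, protect = character())
  clean <- imputeMissing(dropped$table, max_missing_impute)
  keep <- names(clean)
  pathCols <- rownames(cohort)[rowData(cohort)$kind == "pathogen"]
  schema <- splitFeatureKinds(clean, uniqueness_threshold,
                              pathogen_cols = intersect(pathCols, keep),
                              exclude = character())
  out <- cohort[keep, ]
  m <- t(as.matrix(clean))
  dimnames(m) <- dimnames(assay(out, "features"))
  assay(out, "features") <- m
  list(cohort = out, schema = schema, drop_log = dropped$log)
}
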