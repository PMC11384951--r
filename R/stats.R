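## Distribution-comparison and outcome statistics: two-sample KS statistic,
## Hellinger distance between binned densities, exit curves, last-recorded
## SOFA medians and the two-factor Type-2 ANOVA.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum over all observed values of the absolute difference between
#' the two right-continuous empirical CDFs; lies in [0, 1], is symmetric in
#' its arguments and invariant under any strictly monotone transform applied
#' to both samples.
#'
#' @param sample_a,sample_b nonempty numeric samples.
#' @return scalar in [0, 1].
#' @export
ksStatistic <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  pts <- sort(unique(c(sample_a, sample_b)))
  Fa <- vapply(pts, function(t) mean(sample_a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(sample_b <= t), numeric(1))
  max(abs(Fa - Fb))
}

#' Hellinger distance between two binned probability densities
#'
#' `D_H = sqrt(0.5 * sum((sqrt(f_i) - sqrt(g_i))^2))` for densities given as
#' probability masses on a shared bin grid. Bounded in [0, 1]: 0 for
#' identical densities, 1 for disjoint supports.
#'
#' @param density_f,density_g nonnegative vectors on the same grid, each
#'   summing to 1 (tolerance 1e-8).
#' @return scalar in [0, 1].
#' @export
hellingerDistance <- function(density_f, density_g) {
  if (length(density_f) != length(density_g)) {
    stop("densities must share the same bin grid")
  }
  if (any(density_f < 0) || any(density_g < 0)) stop("negative density")
  if (abs(sum(density_f) - 1) > 1e-8 || abs(sum(density_g) - 1) > 1e-8) {
    stop("each density must sum to 1 over its bins")
  }
  sqrt(0.5 * sum((sqrt(density_f) - sqrt(density_g))^2))
}

#' Bin a sample into a probability mass function on a shared grid
#' @param x numeric sample.
#' @param breaks bin edges covering all of `x`.
#' @return numeric vector of bin probabilities (sums to 1).
#' @export
binDensity <- function(x, breaks) {
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  h$counts / length(x)
}

#' Daily exit counts and cumulative exit curves per arm
#'
#' Counts, for each arm and day, the patients leaving the study alive and
#' dead, with cumulative curves, and returns the per-patient exit days by
#' status for feeding [ksStatistic()] and [hellingerDistance()]. Patients
#' still in study at the end of follow-up are censored (counted in neither
#' curve); a patient with no exit record and no maximum-day truncation is an
#' input error.
#'
#' @param cohort a [SepsisCohort-class].
#' @return list with `table` (arm, day, n_alive, n_dead, cum_alive,
#'   cum_dead), `exit_days` (split by arm and status) and `censored` counts.
#' @export
exitCurves <- function(cohort) {
  ex <- cohortExits(cohort)
  maxDay <- max(colData(cohort)$day)
  if (any(ex$exit_status == "in_study" & ex$exit_day < maxDay)) {
    stop("patient(s) recorded in_study before the maximum follow-up day: ",
         paste(ex$patient_id[ex$exit_status == "in_study" &
                               ex$exit_day < maxDay], collapse = ", "))
  }
  rows <- lapply(sort(unique(ex$arm)), function(a) {
    sub <- ex[ex$arm == a, ]
    data.frame(
      arm = a, day = seq_len(maxDay),
      n_alive = vapply(seq_len(maxDay), function(t) {
        sum(sub$exit_status == "left_alive" & sub$exit_day == t)
      }, numeric(1)),
      n_dead = vapply(seq_len(maxDay), function(t) {
        sum(sub$exit_status == "left_dead" & sub$exit_day == t)
      }, numeric(1)))
  })
  tab <- do.call(rbind, rows)
  tab$cum_alive <- stats::ave(tab$n_alive, tab$arm, FUN = cumsum)
  tab$cum_dead <- stats::ave(tab$n_dead, tab$arm, FUN = cumsum)
  exitDays <- lapply(split(ex, ex$arm), function(sub) {
    list(alive = sub$exit_day[sub$exit_status == "left_alive"],
         dead = sub$exit_day[sub$exit_status == "left_dead"])
  })
  list(table = tab, exit_days = exitDays,
       censored = tapply(ex$exit_status == "in_study", ex$arm, sum))
}

#' Median last-recorded SOFA score by arm and exit day
#'
#' For patients leaving with the given status before `day_cutoff`, the median
#' of their last-recorded total SOFA score per arm and exit day; days without
#' leavers are reported as explicit `NA`.
#'
#' @param cohort a [SepsisCohort-class].
#' @param status exit status to summarize (default `"left_alive"`).
#' @param day_cutoff exclusive upper bound on exit days (default 11, i.e.
#'   days 1-10).
#' @return data.frame `arm`, `day`, `n`, `median_last_sofa`; the underlying
#'   per-patient records are attached as attribute `"records"`.
#' @export
lastSofaByDay <- function(cohort, status = "left_alive", day_cutoff = 11) {
  cd <- as.data.frame(colData(cohort))
  last <- cd[cd$day == cd$exit_day & cd$exit_status == status &
               cd$exit_day < day_cutoff, ]
  grid <- expand.grid(arm = sort(unique(cd$arm)),
                      day = seq_len(min(max(cd$day), day_cutoff - 1L)),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$n <- mapply(function(a, t) {
    sum(last$arm == a & last$exit_day == t)
  }, grid$arm, grid$day)
  grid$median_last_sofa <- mapply(function(a, t) {
    v <- last$sofa_total[last$arm == a & last$exit_day == t]
    if (length(v)) median(v) else NA_real_
  }, grid$arm, grid$day)
  grid <- grid[order(grid$arm, grid$day), ]
  rownames(grid) <- NULL
  attr(grid, "records") <- data.frame(
    group = last$arm, day = last$exit_day, last_sofa = last$sofa_total)
  grid
}

#' Two-factor ANOVA of last-recorded SOFA on group and time
#'
#' Fits the additive OLS model `last_sofa ~ group + time` and reports
#' per-factor sums of squares, F statistics and p-values. The default is the
#' marginal (Type-2) decomposition — each factor adjusted for the other, via
#' [car::Anova] — with the sequential (Type-1) decomposition available; the
#' two coincide on balanced orthogonal designs. Time enters as a continuous
#' covariate by default.
#'
#' @param records data.frame with columns `group`, `day`, `last_sofa`.
#' @param type `"2"` (marginal, default) or `"1"` (sequential).
#' @param time_as `"continuous"` (single df, default) or `"factor"`.
#' @return data.frame with rows `group` and `time`: `sum_sq`, `df`,
#'   `F`, `p_value`; the fitted `lm` is attached as attribute `"model"`.
#' @export
anovaGroupTime <- function(records, type = c("2", "1"),
                           time_as = c("continuous", "factor")) {
  type <- match.arg(type)
  time_as <- match.arg(time_as)
  stopifnot(all(c("group", "day", "last_sofa") %in% names(records)))
  if (length(unique(records$group)) < 2L) {
    stop("factor 'group' must have at least 2 levels")
  }
  if (length(unique(records$day)) < 2L) {
    stop("factor 'time' must have at least 2 levels")
  }
  df <- data.frame(
    group = factor(records$group),
    time = if (time_as == "factor") factor(records$day) else records$day,
    last_sofa = records$last_sofa)
  fit <- stats::lm(last_sofa ~ group + time, data = df)
  if (type == "2") {
    a <- car::Anova(fit, type = 2)
    tab <- data.frame(term = rownames(a), sum_sq = a[["Sum Sq"]],
                      df = a[["Df"]], F = a[["F value"]],
                      p_value = a[["Pr(>F)"]])
  } else {
    a <- stats::anova(fit)
    tab <- data.frame(term = rownames(a), sum_sq = a[["Sum Sq"]],
                      df = a[["Df"]], F = a[["F value"]],
                      p_value = a[["Pr(>F)"]])
  }
  tab <- tab[tab$term %in% c("group", "time"), ]
  rownames(tab) <- NULL
  attr(tab, "model") <- fit
  tab
}
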