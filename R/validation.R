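# Method-evaluation statistics: external-vs-internal strain regression
# (accuracy and precision), mean-of-means pooling, one-way ANOVA across
# individuals, and peak-vs-elevation correlations.

#' Regress external-marker strain on a reference strain series
#'
#' Ordinary least squares of external strain on the simultaneously measured
#' internal (implanted-marker) strain, frame by frame. The slope against
#' the ideal slope of 1 measures method accuracy; the RMSE of the residuals
#' measures precision, both on the % strain scale.
#'
#' @param external,internal numeric strain series (%), time-aligned, on
#'   identical frame grids.
#' @param intercept include a free intercept (default `TRUE`).
#' @param min_frames minimum shared finite frames (default 10).
#' @return list: `slope`, `intercept`, `rmse` (% strain), `accuracy`
#'   (= slope / 1), `n_frames`, `r_squared`.
#' @export
compare_strain_methods <- function(external, internal, intercept = TRUE,
                                   min_frames = 10L) {
  if (length(external) != length(internal))
    stop("external and internal series have mismatched frame counts")
  ok <- is.finite(external) & is.finite(internal)
  if (sum(ok) < min_frames)
    stop("fewer than ", min_frames, " shared finite frames")
  x <- internal[ok]; y <- external[ok]
  if (stats::sd(x) < 1e-12)
    stop("internal strain has zero variance; regression undefined")
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ x + 0)
  co <- stats::coef(fit)
  slope <- unname(co[["x"]])
  b0 <- if (intercept) unname(co[["(Intercept)"]]) else 0
  res <- stats::residuals(fit)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = b0,
       rmse = sqrt(mean(res^2)),
       accuracy = slope / 1,
       n_frames = sum(ok),
       r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_)
}

#' Pool per-individual values as a mean of means
#'
#' When individuals differ significantly, a grand mean of per-individual
#' means (each individual weighted equally) with its SEM across individuals
#' is the appropriate summary; when they do not, trials may be pooled
#' directly. Both summaries are returned.
#'
#' @param values numeric per-trial values.
#' @param groups individual/group labels, same length as `values`.
#' @return list of class `group_summary`: `groups` data frame (`group`,
#'   `mean`, `sem`, `n`), `grand_mean`, `grand_sem` (SEM across group
#'   means; `NA` with a single group), `n_groups`, and `pooled_mean`,
#'   `pooled_sem`, `n_total` for the homogeneous case.
#' @export
pool_mean_of_means <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  if (!length(values)) stop("no finite values to pool")
  gm <- tapply(values, groups, mean)
  gs <- tapply(values, groups, stats::sd)
  gn <- tapply(values, groups, length)
  tab <- data.frame(group = names(gm), mean = as.numeric(gm),
                    sem = as.numeric(gs) / sqrt(as.numeric(gn)),
                    n = as.numeric(gn))
  k <- nrow(tab)
  structure(list(
    groups = tab,
    grand_mean = mean(tab$mean),
    grand_sem = if (k > 1) stats::sd(tab$mean) / sqrt(k) else NA_real_,
    n_groups = k,
    pooled_mean = mean(values),
    pooled_sem = stats::sd(values) / sqrt(length(values)),
    n_total = length(values)
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("mean of means over", x$n_groups, "groups:",
      format(x$grand_mean, digits = 3), "+/-",
      format(x$grand_sem, digits = 3), "(SEM)\n")
  invisible(x)
}

#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA F test for differences among groups (e.g. among
#' individual fish), assuming equal variances.
#'
#' @param values numeric response values.
#' @param groups group labels.
#' @return list: `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2L) stop("one-way ANOVA needs >= 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 values")
  if (n - k < 1L) stop("degenerate error degrees of freedom")
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df_between = unname(ft$parameter[1]),
       df_within = unname(ft$parameter[2]))
}

#' Correlate peak excursions with peak neurocranial elevation
#'
#' Pearson correlation (two-sided test) of each per-trial peak excursion
#' variable against per-trial peak elevation, asking whether strikes with
#' more cranial elevation also show larger ventral expansion.
#'
#' @param elevation_peaks numeric per-trial peak elevation (degrees).
#' @param excursion_peaks data frame (or named list) of per-trial peak
#'   excursions, one column per variable (mm), rows aligned with
#'   `elevation_peaks`.
#' @return data frame: `variable`, `r`, `p`, `n`.
#' @export
correlate_peaks <- function(elevation_peaks, excursion_peaks) {
  excursion_peaks <- as.data.frame(excursion_peaks)
  stopifnot(nrow(excursion_peaks) == length(elevation_peaks))
  out <- data.frame(variable = names(excursion_peaks), r = NA_real_,
                    p = NA_real_, n = NA_integer_)
  for (i in seq_along(excursion_peaks)) {
    y <- excursion_peaks[[i]]
    ok <- is.finite(y) & is.finite(elevation_peaks)
    if (sum(ok) < 3L) stop("need >= 3 paired trials for correlation")
    if (stats::sd(y[ok]) < 1e-12 || stats::sd(elevation_peaks[ok]) < 1e-12)
      stop("zero variance in '", names(excursion_peaks)[i],
           "' or elevation; correlation undefined")
    ct <- stats::cor.test(elevation_peaks[ok], y[ok])
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
    out$n[i] <- sum(ok)
  }
  out
}

#' Pool per-trial method-comparison statistics
#'
#' @param comparisons list of per-trial results from
#'   [compare_strain_methods()].
#' @return list of class `validation_report`: `trials` data frame,
#'   `mean_accuracy`, `accuracy_sem`, `mean_rmse`, `rmse_sem`,
#'   `underestimation_pct` (= 100 * (1 - mean accuracy)), `n_trials`.
#' @export
pool_validation <- function(comparisons) {
  stopifnot(length(comparisons) >= 1)
  tab <- data.frame(
    trial = seq_along(comparisons),
    slope = vapply(comparisons, `[[`, numeric(1), "slope"),
    intercept = vapply(comparisons, `[[`, numeric(1), "intercept"),
    rmse = vapply(comparisons, `[[`, numeric(1), "rmse"),
    accuracy = vapply(comparisons, `[[`, numeric(1), "accuracy"),
    n_frames = vapply(comparisons, `[[`, numeric(1), "n_frames")
  )
  n <- nrow(tab)
  sem <- function(x) if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
  structure(list(
    trials = tab,
    mean_accuracy = mean(tab$accuracy), accuracy_sem = sem(tab$accuracy),
    mean_rmse = mean(tab$rmse), rmse_sem = sem(tab$rmse),
    underestimation_pct = 100 * (1 - mean(tab$accuracy)),
    n_trials = n
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("External-vs-internal strain validation over", x$n_trials, "trials\n")
  cat("  accuracy (slope):", format(x$mean_accuracy, digits = 3), "+/-",
      format(x$accuracy_sem, digits = 2), "(SEM)\n")
  cat("  precision (RMSE):", format(x$mean_rmse, digits = 3), "+/-",
      format(x$rmse_sem, digits = 2), "% strain\n")
  cat("  underestimation margin:",
      format(x$underestimation_pct, digits = 3), "%\n")
  invisible(x)
}
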