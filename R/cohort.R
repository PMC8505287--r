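#' Aggregate field-level results to one sample summary
#'
#' Averages the per-field immunoreactive Area% and uniformity index over the
#' usable fields of one sample, giving the sample's representative value of
#' each parameter. Fields whose uniformity index is undefined (fewer than 2
#' cells) are excluded from the uniformity mean and counted out of
#' `n_fields_used`; Area% is averaged over all fields carrying a value.
#'
#' @param field_results A data.frame with one row per field and (any of the)
#'   columns `area_percent`, `uniformity_index`; `NA` marks an unusable
#'   value.
#' @param sample_id Sample identifier.
#' @param group Group label.
#' @return Object of class `ihc_sample_summary`: `sample_id`, `group`,
#'   `area_percent`, `uniformity_index`, `n_fields`, `n_fields_used`,
#'   `excluded` (TRUE when no field was usable for any parameter).
#' @export
summarize_sample <- function(field_results, sample_id, group) {
  stopifnot(is.data.frame(field_results), nrow(field_results) >= 1)
  ap <- if ("area_percent" %in% names(field_results))
    field_results$area_percent else rep(NA_real_, nrow(field_results))
  ui <- if ("uniformity_index" %in% names(field_results))
    field_results$uniformity_index else rep(NA_real_, nrow(field_results))
  usable_ui <- sum(!is.na(ui))
  excluded <- usable_ui == 0 && all(is.na(ap))
  if (excluded)
    warning("sample ", sample_id, " has zero usable fields; excluded")
  structure(list(sample_id = sample_id, group = group,
                 area_percent = if (all(is.na(ap))) NA_real_
                                else mean(ap, na.rm = TRUE),
                 uniformity_index = if (usable_ui == 0) NA_real_
                                    else mean(ui, na.rm = TRUE),
                 n_fields = nrow(field_results),
                 n_fields_used = usable_ui,
                 excluded = excluded),
            class = "ihc_sample_summary")
}

#' Two-group comparison of a sample-level parameter
#'
#' Classical two-sample Student's t-test (pooled variance, the test named by
#' the study design) of one parameter between the two groups, two-sided,
#' with `n_A + n_B - 2` degrees of freedom. Welch's unequal-variance variant
#' is available behind a flag. Samples with a missing (excluded) value of
#' the parameter are dropped listwise with a warning.
#'
#' @param groupA,groupB Numeric vectors of per-sample values (each of length
#'   >= 2 after dropping missing values), or lists of
#'   `ihc_sample_summary` objects from which `parameter` is extracted.
#' @param parameter Parameter name used when summaries are supplied and for
#'   labelling (e.g. `"uniformity_index"`, `"area_percent"`).
#' @param alpha Significance limit (default 0.05).
#' @param welch Use Welch's unequal-variance t-test instead (default FALSE).
#' @return Object of class `ihc_cohort_result`: per-group `n`, `mean`, `sd`,
#'   `sem`, plus `t`, `df`, `p`, `significant`, `parameter`, `alpha`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_groups <- function(groupA, groupB, parameter = "value",
                           alpha = 0.05, welch = FALSE) {
  pull <- function(g) {
    if (is.numeric(g)) return(g)
    vapply(g, function(s) {
      stopifnot(inherits(s, "ihc_sample_summary"))
      as.numeric(s[[parameter]])
    }, numeric(1))
  }
  a <- pull(groupA); b <- pull(groupB)
  if (anyNA(a) || anyNA(b)) {
    warning("dropping samples with missing ", parameter)
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
  }
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 samples with a usable ", parameter)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    t_stat <- 0; df <- length(a) + length(b) - 2; p <- 1
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  }
  grp <- function(v) list(n = length(v), mean = mean(v), sd = stats::sd(v),
                          sem = stats::sd(v) / sqrt(length(v)))
  structure(list(parameter = parameter, groupA = grp(a), groupB = grp(b),
                 t = t_stat, df = df, p = p,
                 significant = p < alpha, alpha = alpha, welch = welch),
            class = "ihc_cohort_result")
}

#' @export
print.ihc_cohort_result <- function(x, ...) {
  cat(sprintf("%s: A %.4f +/- %.4f (n=%d) vs B %.4f +/- %.4f (n=%d)\n",
              x$parameter, x$groupA$mean, x$groupA$sd, x$groupA$n,
              x$groupB$mean, x$groupB$sd, x$groupB$n))
  cat(sprintf("  %s t = %.4f, df = %g, p = %.4g%s\n",
              if (x$welch) "Welch" else "Student", x$t, x$df, x$p,
              if (x$significant) " (*)" else ""))
  invisible(x)
}

#' Tidy one-row data.frame of a cohort comparison
#' @param x An `ihc_cohort_result`.
#' @param ... Unused.
#' @return data.frame with group means/SD/SEM, t, df, p.
#' @export
as.data.frame.ihc_cohort_result <- function(x, ...) {
  data.frame(parameter = x$parameter,
             n_A = x$groupA$n, mean_A = x$groupA$mean, sd_A = x$groupA$sd,
             sem_A = x$groupA$sem,
             n_B = x$groupB$n, mean_B = x$groupB$mean, sd_B = x$groupB$sd,
             sem_B = x$groupB$sem,
             t = x$t, df = x$df, p = x$p, significant = x$significant)
}
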