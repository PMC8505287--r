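#' Pipeline configuration
#'
#' Bundles and validates every tunable of the field-level and cohort-level
#' analysis; all defaults match the documented decisions of the individual
#' stages.
#'
#' @param mode `"points"` (coordinate tables) or `"images"` (rendered
#'   fields; stain separation and detection are applied first).
#' @param stains An [stain_system()].
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_value Threshold when `threshold_method = "fixed"`.
#' @param min_area,opening_radius Mask-cleaning parameters ([clean_mask()]).
#' @param min_overlap_fraction Nuclear/immunoreactivity co-localization
#'   fraction ([detect_positive_cells()]).
#' @param n_sim Monte-Carlo simulations per field envelope (default 100).
#' @param alpha Significance level for envelopes and t-tests (default 0.05).
#' @param min_run_fraction Contiguous-run fraction for the verdict
#'   ([classify_pattern()]).
#' @param correction K-estimator edge correction (`"none"` default).
#' @param white_balance Apply background white-balancing to images first.
#' @param seed Master seed.
#' @return A validated list of class `ihc_config`.
#' @export
ihc_config <- function(mode = c("points", "images"),
                       stains = stain_system(),
                       threshold_method = c("otsu", "fixed"),
                       threshold_value = NULL,
                       min_area = 0, opening_radius = 0,
                       min_overlap_fraction = 0.5,
                       n_sim = 100, alpha = 0.05, min_run_fraction = 0.2,
                       correction = c("none", "translation"),
                       white_balance = FALSE, seed = 1) {
  cfg <- list(mode = match.arg(mode), stains = stains,
              threshold_method = match.arg(threshold_method),
              threshold_value = threshold_value,
              min_area = min_area, opening_radius = opening_radius,
              min_overlap_fraction = min_overlap_fraction,
              n_sim = n_sim, alpha = alpha,
              min_run_fraction = min_run_fraction,
              correction = match.arg(correction),
              white_balance = white_balance, seed = seed)
  stopifnot(inherits(cfg$stains, "ihc_stains"),
            cfg$n_sim >= 2, cfg$alpha > 0, cfg$alpha < 1,
            cfg$min_run_fraction >= 0, cfg$min_run_fraction <= 1,
            cfg$min_overlap_fraction >= 0, cfg$min_overlap_fraction <= 1,
            cfg$min_area >= 0, cfg$opening_radius >= 0)
  if (cfg$threshold_method == "fixed" && is.null(cfg$threshold_value))
    stop("threshold_method = 'fixed' requires threshold_value")
  class(cfg) <- "ihc_config"
  cfg
}

# image (nrow x ncol x 3 intensity array) -> pattern + area%
.cells_from_image <- function(image, config) {
  if (config$white_balance) image <- white_balance(image)
  od <- to_optical_density(image)
  un <- unmix(od, config$stains)
  thr <- function(ch) {
    if (config$threshold_method == "fixed")
      threshold_channel(ch, "fixed", t = config$threshold_value)
    else threshold_channel(ch, "otsu")
  }
  immuno <- clean_mask(thr(un$D), config$min_area, config$opening_radius)
  nuclei <- clean_mask(thr(un$H), config$min_area, config$opening_radius)
  list(pattern = detect_positive_cells(nuclei, immuno,
                                       config$min_overlap_fraction),
       area_percent = area_percent(immuno))
}

#' Analyze one field end to end
#'
#' Runs the full per-field procedure: for image input, stain separation,
#' thresholding and positive-cell detection; then the uniformity index and
#' the K-function envelope analysis of the resulting point pattern.
#' Deterministic under `config$seed` (offset by `seed_offset` so each field
#' of a cohort gets its own stream).
#'
#' Fields with fewer than 2 cells get `NA` spatial statistics and
#' `verdict = "undefined"` rather than an error, so cohort runs skip them
#' gracefully.
#'
#' @param input An `ihc_pattern`, an `ihc_field` (synthetic render), or a
#'   path to a TIFF/PNG image.
#' @param config An [ihc_config()].
#' @param seed_offset Integer offset added to the config seed.
#' @return List of class `ihc_field_summary`: `n`, `area_percent`,
#'   `uniformity_index`, `verdict`, `k` (an `ihc_kresult` or NULL),
#'   `pattern`, `config_used`.
#' @export
analyze_field <- function(input, config = ihc_config(), seed_offset = 0) {
  stopifnot(inherits(config, "ihc_config"))
  ap <- NA_real_
  if (inherits(input, "ihc_pattern")) {
    pattern <- input
  } else {
    if (is.character(input)) input <- read_field(input)
    img <- if (inherits(input, "ihc_field")) input$image else input
    res <- .cells_from_image(img, config)
    pattern <- res$pattern
    ap <- res$area_percent
  }
  seed <- (config$seed + seed_offset) %% 2147483647
  if (pattern$n < 2) {
    ui <- NA_real_; verdict <- "undefined"; k <- NULL
  } else {
    ui <- uniformity_index(pattern)$index
    k <- k_analysis(pattern, n_sim = config$n_sim, alpha = config$alpha,
                    seed = seed, correction = config$correction)
    verdict <- classify_pattern(k, config$min_run_fraction)$verdict
  }
  structure(list(n = pattern$n, area_percent = ap, uniformity_index = ui,
                 verdict = verdict, k = k, pattern = pattern,
                 config_used = config),
            class = "ihc_field_summary")
}

#' @export
print.ihc_field_summary <- function(x, ...) {
  cat(sprintf("field: n = %d cells, Area%% = %s, uniformity = %s, verdict = %s\n",
              x$n,
              ifelse(is.na(x$area_percent), "-", sprintf("%.2f", x$area_percent)),
              ifelse(is.na(x$uniformity_index), "-",
                     sprintf("%.3f", x$uniformity_index)),
              x$verdict))
  invisible(x)
}

#' Analyze a whole two-arm cohort
#'
#' Applies [analyze_field()] to every field of a cohort of point patterns,
#' aggregates fields to samples with [summarize_sample()], and compares the
#' two groups per parameter with [compare_groups()]. Envelope analysis per
#' field is optional (`envelopes = FALSE` skips the K-function and verdicts,
#' which the group comparison of scalar parameters does not need).
#'
#' @param cohort An `ihc_cohort` from [generate_cohort()], or a list with
#'   `fields` (manifest with `group`, `sample_id`, `field_id`) and
#'   `patterns` as returned by [read_patterns_csv()].
#' @param config An [ihc_config()].
#' @param envelopes Run the per-field K envelope analysis (default FALSE).
#' @param parameters Parameters to compare across groups.
#' @return List of class `ihc_cohort_report`: `field_results` (per-field
#'   data.frame), `sample_summaries`, `comparisons` (one
#'   `ihc_cohort_result` per parameter), `table` (tidy data.frame).
#' @export
analyze_cohort <- function(cohort, config = ihc_config(),
                           envelopes = FALSE,
                           parameters = c("uniformity_index",
                                          "area_percent")) {
  stopifnot(inherits(config, "ihc_config"))
  man <- cohort$fields
  fr <- lapply(seq_along(cohort$patterns), function(i) {
    p <- cohort$patterns[[i]]
    ui <- if (p$n >= 2) uniformity_index(p)$index else NA_real_
    verdict <- NA_character_
    if (envelopes && p$n >= 2) {
      k <- k_analysis(p, n_sim = config$n_sim, alpha = config$alpha,
                      seed = (config$seed + i) %% 2147483647,
                      correction = config$correction)
      verdict <- classify_pattern(k, config$min_run_fraction)$verdict
    }
    data.frame(group = man$group[i], sample_id = man$sample_id[i],
               field_id = man$field_id[i], n = p$n,
               uniformity_index = ui,
               area_percent = if ("area_percent" %in% names(man))
                 man$area_percent[i] else NA_real_,
               verdict = verdict)
  })
  fr <- do.call(rbind, fr)
  groups <- unique(man$group)
  if (length(groups) != 2) stop("cohort must contain exactly 2 groups")
  summaries <- lapply(split(fr, fr$sample_id), function(d)
    summarize_sample(d, d$sample_id[1], d$group[1]))
  comparisons <- list()
  for (par in parameters) {
    vals <- vapply(summaries, function(s) as.numeric(s[[par]]), numeric(1))
    grp <- vapply(summaries, function(s) s$group, character(1))
    a <- vals[grp == groups[1]]; b <- vals[grp == groups[2]]
    if (all(is.na(a)) || all(is.na(b))) next
    comparisons[[par]] <- compare_groups(a, b, parameter = par,
                                         alpha = config$alpha)
  }
  tab <- do.call(rbind, lapply(comparisons, as.data.frame))
  structure(list(field_results = fr, sample_summaries = summaries,
                 comparisons = comparisons, table = tab,
                 groups = groups, config_used = config),
            class = "ihc_cohort_report")
}

#' @export
print.ihc_cohort_report <- function(x, ...) {
  cat(sprintf("cohort report: %d fields, groups %s vs %s\n",
              nrow(x$field_results), x$groups[1], x$groups[2]))
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

#' Simulate and analyze a cohort in one call
#'
#' Convenience wrapper: generates a two-arm cohort under the given pattern
#' specs, then runs the full cohort analysis.
#'
#' @inheritParams generate_cohort
#' @param config An [ihc_config()] (its seed drives the generation).
#' @param envelopes Forwarded to [analyze_cohort()].
#' @return An `ihc_cohort_report` with the generated cohort attached as
#'   `$cohort`.
#' @export
simulate_cohort <- function(specA, specB, n_samples = 15, n_fields = 10,
                            window = ihc_window(1000, 1000),
                            n_range = c(50, 400),
                            config = ihc_config(), envelopes = FALSE) {
  cohort <- generate_cohort(specA, specB, n_samples, n_fields, window,
                            n_range, seed = config$seed)
  rep <- analyze_cohort(cohort, config, envelopes)
  rep$cohort <- cohort
  rep
}

#' Write a field summary to JSON
#'
#' Embeds the resolved configuration and package version so the record is
#' sufficient for an exact re-run.
#'
#' @param summary An `ihc_field_summary`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_field_json <- function(summary, path) {
  stopifnot(inherits(summary, "ihc_field_summary"))
  cfg <- summary$config_used
  cfg$stains <- list(hematoxylin = cfg$stains$S_H, dab = cfg$stains$S_D)
  out <- list(n = summary$n, area_percent = summary$area_percent,
              uniformity_index = summary$uniformity_index,
              verdict = summary$verdict,
              config = unclass(cfg),
              version = as.character(utils::packageVersion("ihcspat")))
  if (!is.null(summary$k))
    out <- c(out, summary$k[c("d_grid", "K_obs", "K0_mean",
                              "env_lo", "env_hi", "L")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
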