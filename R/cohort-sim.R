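#' Derive a per-field RNG seed from the master seed
#'
#' One RNG stream per field, keyed by (master seed, group, sample, field),
#' so cohorts are reproducible under partial re-runs. The mix is a simple
#' multiplicative hash folded into the 31-bit positive-integer range.
#'
#' @param master Master integer seed.
#' @param group Group index (1-based).
#' @param sample Sample index (1-based).
#' @param field Field index (1-based).
#' @return A positive integer seed below 2^31.
#' @export
field_seed <- function(master, group, sample, field) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(master) %% m)
  for (v in c(group, sample, field))
    s <- (s * 69069 + as.numeric(v) * 2654435761) %% m
  as.integer(s %% (m - 1)) + 1L
}

#' Generate a two-arm synthetic cohort of point patterns
#'
#' Mirrors the study design the analysis targets: two patient groups (by
#' default 15 samples each, labelled ABC and GCB), ten equal-area fields per
#' sample, one point pattern per field. Per-field point counts are drawn
#' uniformly from `n_range`, then the pattern is generated under the arm's
#' regime spec. Deterministic under `seed`; each field uses its own derived
#' stream (see [field_seed()]).
#'
#' @param specA,specB [pattern_spec()]s for the two arms (the `n_points`
#'   slot is overridden per field by the draw from `n_range`).
#' @param n_samples Samples per group (default 15).
#' @param n_fields Fields per sample (default 10).
#' @param window Shared observation window.
#' @param n_range Integer range of per-field point counts, default
#'   `c(50, 400)`.
#' @param labels Group labels, default `c("ABC", "GCB")`.
#' @param seed Master seed.
#' @return An object of class `ihc_cohort`: a list with `fields` (a
#'   data.frame manifest: group, sample_id, field_id, n, seed) and
#'   `patterns` (list of `ihc_pattern` parallel to the manifest rows).
#' @export
generate_cohort <- function(specA, specB, n_samples = 15, n_fields = 10,
                            window = ihc_window(1000, 1000),
                            n_range = c(50, 400),
                            labels = c("ABC", "GCB"), seed = 1) {
  stopifnot(inherits(specA, "ihc_pattern_spec"),
            inherits(specB, "ihc_pattern_spec"),
            inherits(window, "ihc_window"))
  if (n_samples < 1 || n_fields < 1)
    stop("n_samples and n_fields must be >= 1")
  specs <- list(specA, specB)
  rows <- list(); patterns <- list(); k <- 0L
  for (g in 1:2) {
    for (s in seq_len(n_samples)) {
      for (f in seq_len(n_fields)) {
        k <- k + 1L
        fs <- field_seed(seed, g, s, f)
        set.seed(fs)
        n_pts <- sample(seq.int(n_range[1], n_range[2]), 1L)
        sp <- specs[[g]]
        sp$n_points <- n_pts
        patterns[[k]] <- generate_pattern(sp, window)
        rows[[k]] <- data.frame(group = labels[g],
                                sample_id = sprintf("%s_%02d", labels[g], s),
                                field_id = f, n = n_pts, seed = fs)
      }
    }
  }
  structure(list(fields = do.call(rbind, rows), patterns = patterns,
                 window = window, labels = labels, seed = seed),
            class = "ihc_cohort")
}

#' @export
print.ihc_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d fields (%s)\n", nrow(x$fields),
              paste(sprintf("%s: %d", x$labels,
                            table(x$fields$group)[x$labels]),
                    collapse = ", ")))
  invisible(x)
}

#' Write a cohort's point truth and manifest to disk
#'
#' Writes one CSV (`sample_id, field_id, x, y, label`) with every point of
#' every field, plus a JSON manifest of the design and the per-field seeds.
#'
#' @param cohort An `ihc_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ihc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pts <- do.call(rbind, lapply(seq_along(cohort$patterns), function(i) {
    p <- cohort$patterns[[i]]
    if (p$n == 0) return(NULL)
    data.frame(sample_id = cohort$fields$sample_id[i],
               field_id = cohort$fields$field_id[i],
               x = p$x, y = p$y, label = cohort$fields$group[i])
  }))
  csv <- file.path(dir, "points.csv")
  utils::write.csv(pts, csv, row.names = FALSE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(window = cohort$window[c("width", "height")],
                            seed = cohort$seed,
                            fields = cohort$fields),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(points = csv, manifest = manifest))
}

#' Read point patterns from a coordinate CSV
#'
#' Reads a table with columns `sample_id, field_id, x, y` (and optionally
#' `label`) and splits it into one `ihc_pattern` per (sample, field).
#'
#' @param path CSV path.
#' @param window An [ihc_window()] shared by all fields.
#' @return A list with `fields` (manifest data.frame) and `patterns`.
#' @export
read_patterns_csv <- function(path, window) {
  df <- utils::read.csv(path)
  need <- c("sample_id", "field_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("point CSV must have columns: ", paste(need, collapse = ", "))
  key <- interaction(df$sample_id, df$field_id, drop = TRUE)
  idx <- split(seq_len(nrow(df)), key)
  patterns <- lapply(idx, function(i)
    point_pattern(df$x[i], df$y[i], window))
  fields <- do.call(rbind, lapply(idx, function(i)
    data.frame(sample_id = df$sample_id[i[1]], field_id = df$field_id[i[1]],
               group = if ("label" %in% names(df)) df$label[i[1]] else NA,
               n = length(i))))
  rownames(fields) <- NULL
  list(fields = fields, patterns = unname(patterns))
}
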