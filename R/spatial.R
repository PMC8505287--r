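#' Default distance grid for K-function analysis
#'
#' 50 equal steps from `d_max/50` up to `d_max` = one quarter of the shorter
#' window side, standard practice for rectangular windows.
#'
#' @param window An [ihc_window()].
#' @param n_steps Number of grid points (default 50).
#' @param d_max Largest distance; default `min(width, height) / 4`.
#' @return Ascending numeric vector of distances.
#' @export
k_distance_grid <- function(window, n_steps = 50, d_max = NULL) {
  stopifnot(inherits(window, "ihc_window"))
  if (is.null(d_max)) d_max <- min(window$width, window$height) / 4
  seq(d_max / n_steps, d_max, length.out = n_steps)
}

#' Ripley's K-function of a point pattern
#'
#' Estimates `K(d)`, the expected number of further points within distance
#' `d` of a typical point divided by the intensity; `pi d^2` under complete
#' spatial randomness.
#'
#' Two estimators are available. The default `"none"` is the naive
#' (uncorrected) estimator
#' `K(d) = |W| / (n (n-1)) * sum_{i != j} 1(||p_i - p_j|| <= d)`
#' over ordered pairs; the pipeline applies the same estimator to observed
#' and simulated patterns so edge bias cancels in the Monte-Carlo
#' comparison. `"translation"` applies the translation edge correction for a
#' rectangular window, giving an unbiased estimate of the absolute K under
#' CSR (use it when comparing against the `pi d^2` closed form rather than
#' against a matched simulation).
#'
#' @param pattern An `ihc_pattern` with at least 2 points.
#' @param d_grid Ascending distance grid; defaults to
#'   [k_distance_grid()] of the pattern's window. `d_max` should not exceed
#'   half the shorter window side.
#' @param correction `"none"` (default) or `"translation"`.
#' @return Numeric vector of `K` estimates along `d_grid`.
#' @examples
#' p <- generate_pattern(pattern_spec("csr", 100), ihc_window(100, 100),
#'                       seed = 1)
#' K <- ripley_k(p)
#' @export
ripley_k <- function(pattern, d_grid = NULL,
                     correction = c("none", "translation")) {
  stopifnot(inherits(pattern, "ihc_pattern"))
  correction <- match.arg(correction)
  n <- pattern$n
  if (n < 2) stop("Ripley's K is undefined for patterns with fewer than 2 points")
  w <- pattern$window
  if (is.null(d_grid)) d_grid <- k_distance_grid(w)
  if (is.unsorted(d_grid, strictly = FALSE)) stop("d_grid must be ascending")
  A <- window_area(w)
  dd <- sort(stats::dist(cbind(pattern$x, pattern$y))) # unordered pairs
  if (correction == "none") {
    # findInterval on the sorted distances counts pairs with d_ij <= d;
    # each unordered pair contributes twice to the ordered-pair sum
    counts <- findInterval(d_grid, dd)
    return(2 * counts * A / (n * (n - 1)))
  }
  # translation correction: weight each pair by |W| / |W intersect W+t|
  dx <- abs(outer(pattern$x, pattern$x, "-"))
  dy <- abs(outer(pattern$y, pattern$y, "-"))
  keep <- upper.tri(dx)
  dx <- dx[keep]; dy <- dy[keep]
  dv <- sqrt(dx^2 + dy^2)
  wt <- A / ((w$width - dx) * (w$height - dy))
  ord <- order(dv)
  cumw <- c(0, cumsum(wt[ord]))
  cumw[findInterval(d_grid, dv[ord]) + 1] * 2 * A / (n * (n - 1))
}

#' Monte-Carlo CSR envelope for the K-function
#'
#' Simulates `n_sim` complete-spatial-randomness patterns with the same
#' number of points as observed and the same window (the matched null of the
#' analysis), evaluates the same K estimator on each, and returns the
#' per-distance mean `K0(d)` with pointwise 95% envelopes. Envelope bounds
#' are the order statistics at ranks `ceiling((n_sim + 1) * alpha / 2)` from
#' each end: for `n_sim = 100` and `alpha = 0.05`, the 3rd-smallest and
#' 3rd-largest simulated values.
#'
#' @param n Number of points per simulated pattern (>= 2).
#' @param window An [ihc_window()].
#' @param d_grid Ascending distance grid; default [k_distance_grid()].
#' @param n_sim Number of simulations (default 100).
#' @param alpha Envelope level (default 0.05, i.e. 95% envelopes).
#' @param seed Optional seed; identical seeds give identical envelopes.
#' @param correction K estimator passed to [ripley_k()].
#' @return List with `d_grid`, `K0_mean`, `env_lo`, `env_hi`, `n_sim`,
#'   `alpha`, `n`, `window`.
#' @export
csr_envelope <- function(n, window, d_grid = NULL, n_sim = 100,
                         alpha = 0.05, seed = NULL,
                         correction = c("none", "translation")) {
  stopifnot(inherits(window, "ihc_window"))
  correction <- match.arg(correction)
  if (n < 2) stop("envelope requires n >= 2 points")
  if (n_sim < 2) stop("envelope requires n_sim >= 2 simulations")
  if (is.null(d_grid)) d_grid <- k_distance_grid(window)
  if (!is.null(seed)) set.seed(seed)
  sims <- matrix(0, n_sim, length(d_grid))
  sp <- pattern_spec("csr", n)
  for (s in seq_len(n_sim)) {
    p <- generate_pattern(sp, window)
    sims[s, ] <- ripley_k(p, d_grid, correction)
  }
  r <- ceiling((n_sim + 1) * alpha / 2)
  r <- min(max(r, 1L), floor(n_sim / 2))
  sorted <- apply(sims, 2, sort)
  list(d_grid = d_grid, K0_mean = colMeans(sims),
       env_lo = sorted[r, ], env_hi = sorted[n_sim + 1 - r, ],
       n_sim = n_sim, alpha = alpha, n = n, window = window)
}

#' K-function analysis of one field
#'
#' Couples the observed K estimate with its matched CSR envelope and the
#' deviation curve `L(d) = K(d) - K0(d)` plotted in envelope displays.
#'
#' @param pattern An `ihc_pattern` (n >= 2).
#' @param d_grid Distance grid; default from the pattern's window.
#' @param n_sim Simulations for the envelope.
#' @param alpha Envelope level.
#' @param seed Seed for the envelope simulations.
#' @param correction K estimator for both observed and simulated patterns.
#' @return Object of class `ihc_kresult`: `d_grid`, `K_obs`, `K0_mean`,
#'   `env_lo`, `env_hi`, `L`, `n`, `window`, `n_sim`, `alpha`.
#' @export
k_analysis <- function(pattern, d_grid = NULL, n_sim = 100, alpha = 0.05,
                       seed = NULL, correction = c("none", "translation")) {
  stopifnot(inherits(pattern, "ihc_pattern"))
  correction <- match.arg(correction)
  if (is.null(d_grid)) d_grid <- k_distance_grid(pattern$window)
  K_obs <- ripley_k(pattern, d_grid, correction)
  env <- csr_envelope(pattern$n, pattern$window, d_grid, n_sim, alpha,
                      seed, correction)
  structure(list(d_grid = d_grid, K_obs = K_obs, K0_mean = env$K0_mean,
                 env_lo = env$env_lo, env_hi = env$env_hi,
                 L = K_obs - env$K0_mean, n = pattern$n,
                 window = pattern$window, n_sim = n_sim, alpha = alpha),
            class = "ihc_kresult")
}

#' Plot the L(d) = K(d) - K0(d) deviation curve with envelopes
#'
#' Standard envelope display: solid observed deviation, dashed 95% envelope
#' bounds (both re-centred on the simulated mean).
#'
#' @param x An `ihc_kresult`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ihc_kresult <- function(x, ...) {
  lo <- x$env_lo - x$K0_mean; hi <- x$env_hi - x$K0_mean
  graphics::plot(x$d_grid, x$L, type = "l", xlab = "d",
                 ylab = "L(d) = K(d) - K0(d)",
                 ylim = range(c(x$L, lo, hi)), ...)
  graphics::lines(x$d_grid, lo, lty = 2)
  graphics::lines(x$d_grid, hi, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Classify a pattern as clustered, random, avoidance, or mixed
#'
#' A pattern is called clustered when the observed K exceeds the upper
#' envelope over a contiguous run of at least `min_run_fraction` of the
#' distance grid (a sustained excursion, not an isolated grid point);
#' avoidance is the symmetric call below the lower envelope; `mixed` flags
#' both; `random` neither.
#'
#' @param k An `ihc_kresult` (or any list with `d_grid`, `K_obs`, `env_lo`,
#'   `env_hi`).
#' @param min_run_fraction Minimum contiguous run length as a fraction of
#'   the grid (default 0.2).
#' @return List of class `ihc_verdict`: `verdict`, `frac_above`,
#'   `frac_below`, `longest_run_above`, `longest_run_below`.
#' @export
classify_pattern <- function(k, min_run_fraction = 0.2) {
  stopifnot(length(k$K_obs) == length(k$d_grid),
            length(k$env_hi) == length(k$d_grid))
  above <- k$K_obs > k$env_hi
  below <- k$K_obs < k$env_lo
  longest_run <- function(b) {
    if (!any(b)) return(0L)
    r <- rle(b)
    max(r$lengths[r$values])
  }
  need <- min_run_fraction * length(k$d_grid)
  ra <- longest_run(above); rb <- longest_run(below)
  clustered <- ra >= need; avoid <- rb >= need
  verdict <- if (clustered && avoid) "mixed"
             else if (clustered) "clustered"
             else if (avoid) "avoidance"
             else "random"
  structure(list(verdict = verdict,
                 frac_above = mean(above), frac_below = mean(below),
                 longest_run_above = ra, longest_run_below = rb),
            class = "ihc_verdict")
}

#' @export
print.ihc_verdict <- function(x, ...) {
  cat(sprintf("spatial verdict: %s (%.0f%% of grid above envelope, %.0f%% below)\n",
              x$verdict, 100 * x$frac_above, 100 * x$frac_below))
  invisible(x)
}

#' Nearest-neighbour uniformity index
#'
#' Scalar in \[0, 1\] summarizing the regularity of a point pattern: 0 at
#' maximal clustering (all points coincident) and 1 for an ideal regular
#' array. Implemented as a normalized Clark-Evans nearest-neighbour ratio:
#' `R = mean observed NN distance / (0.5 / sqrt(lambda))` with
#' `lambda = n / |W|`, then `index = min(R / 2.1491, 1)` where 2.1491 is the
#' theoretical maximum of R, attained by the hexagonal lattice.
#'
#' An optional Donnelly edge correction adds the boundary term
#' `(0.0514 + 0.041 / sqrt(n)) * P / n` (P = window perimeter) to the
#' expected CSR nearest-neighbour distance; off by default.
#'
#' @param pattern An `ihc_pattern`.
#' @param edge_correction `"none"` (default) or `"donnelly"`.
#' @return Object of class `ihc_uniformity`: `index`, `mean_nn`,
#'   `expected_nn`, `clark_evans`, `n`, `defined` (FALSE when n < 2, in
#'   which case `index` is `NA` and the result is flagged rather than an
#'   error).
#' @examples
#' p <- generate_pattern(pattern_spec("csr", 200), ihc_window(1000, 1000),
#'                       seed = 2)
#' uniformity_index(p)$index
#' @export
uniformity_index <- function(pattern,
                             edge_correction = c("none", "donnelly")) {
  stopifnot(inherits(pattern, "ihc_pattern"))
  edge_correction <- match.arg(edge_correction)
  n <- pattern$n
  if (n < 2)
    return(structure(list(index = NA_real_, mean_nn = NA_real_,
                          expected_nn = NA_real_, clark_evans = NA_real_,
                          n = n, defined = FALSE),
                     class = "ihc_uniformity"))
  dd <- as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
  diag(dd) <- Inf
  nn <- apply(dd, 1, min)
  lambda <- intensity(pattern)
  expected <- 0.5 / sqrt(lambda)
  if (edge_correction == "donnelly") {
    P <- 2 * (pattern$window$width + pattern$window$height)
    expected <- expected + (0.0514 + 0.041 / sqrt(n)) * P / n
  }
  R <- mean(nn) / expected
  R_HEX <- 2 / sqrt(sqrt(3) / 2) # 2.1491, hexagonal-lattice maximum
  structure(list(index = min(R / R_HEX, 1), mean_nn = mean(nn),
                 expected_nn = expected, clark_evans = R, n = n,
                 defined = TRUE),
            class = "ihc_uniformity")
}

#' @export
print.ihc_uniformity <- function(x, ...) {
  if (!x$defined)
    cat("uniformity index: undefined (fewer than 2 points)\n")
  else
    cat(sprintf("uniformity index: %.3f (Clark-Evans R = %.3f, n = %d)\n",
                x$index, x$clark_evans, x$n))
  invisible(x)
}
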