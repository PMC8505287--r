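#' Planar point pattern of positive-cell coordinates
#'
#' The central object of the statistical path: the (x, y) centroids of
#' marker-positive cells inside a rectangular observation window.
#' Coordinates are pixel-center based with the origin at the top-left of the
#' field, x increasing along columns and y along rows; any consistent length
#' unit is acceptable as long as the window uses the same one.
#'
#' @param x,y Numeric coordinate vectors of equal length.
#' @param window An [ihc_window()] containing all points.
#' @param marker Optional marker label (e.g. `"CD8"`, `"synthetic"`).
#' @return An object of class `ihc_pattern` with elements `x`, `y`, `n`,
#'   `window`, `marker`.
#' @examples
#' p <- point_pattern(c(10, 20), c(30, 40), ihc_window(100, 100))
#' p$n
#' @export
point_pattern <- function(x, y, window, marker = "synthetic") {
  stopifnot(inherits(window, "ihc_window"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y))))
    stop("coordinates must be finite")
  if (length(x) && (any(x < 0) || any(x > window$width) ||
                    any(y < 0) || any(y > window$height)))
    stop("all points must lie inside the observation window")
  structure(list(x = x, y = y, n = length(x), window = window,
                 marker = marker),
            class = "ihc_pattern")
}

#' @export
print.ihc_pattern <- function(x, ...) {
  cat(sprintf("planar point pattern: %d points (marker %s)\n", x$n, x$marker))
  print(x$window)
  invisible(x)
}

#' @export
as.data.frame.ihc_pattern <- function(x, ...) {
  data.frame(x = x$x, y = x$y)
}

#' Intensity (points per unit area) of a pattern
#' @param p An `ihc_pattern`.
#' @return Estimated intensity `n / |W|`.
#' @export
intensity <- function(p) {
  stopifnot(inherits(p, "ihc_pattern"))
  p$n / window_area(p$window)
}

#' Specification of a synthetic point-pattern regime
#'
#' Describes one of four generating regimes spanning the clustered -> random
#' -> regular spectrum the analysis is designed to discriminate:
#' \describe{
#'   \item{`csr`}{homogeneous binomial process (complete spatial randomness
#'     conditioned on the point count), the Monte-Carlo null.}
#'   \item{`thomas_cluster`}{Thomas process conditioned on `n_points`:
#'     Poisson parents with intensity `parent_intensity`, isotropic Gaussian
#'     offspring displacement with SD `offspring_spread`.}
#'   \item{`jittered_lattice`}{hexagonal (triangular) lattice filling the
#'     window, each point jittered uniformly by up to `jitter * spacing / 2`
#'     per coordinate.}
#'   \item{`coincident`}{all points at one shared location -- the maximal
#'     clustering degenerate case.}
#' }
#'
#' @param regime One of `"csr"`, `"thomas_cluster"`, `"jittered_lattice"`,
#'   `"coincident"`.
#' @param n_points Number of points to generate (>= 0).
#' @param parent_intensity Thomas parent intensity per unit area.
#' @param offspring_spread Thomas offspring displacement SD (same unit as
#'   the window).
#' @param jitter Lattice jitter fraction in \[0, 1\]; 0 gives the ideal
#'   regular array.
#' @param min_sep Optional hard-core minimum separation for `csr`
#'   (simple sequential inhibition); `0` disables it.
#' @return An object of class `ihc_pattern_spec`.
#' @export
pattern_spec <- function(regime = c("csr", "thomas_cluster",
                                    "jittered_lattice", "coincident"),
                         n_points,
                         parent_intensity = 1e-5,
                         offspring_spread = 20,
                         jitter = 0.1,
                         min_sep = 0) {
  regime <- match.arg(regime)
  if (!is.numeric(n_points) || length(n_points) != 1L ||
      !is.finite(n_points) || n_points < 0 || n_points != round(n_points))
    stop("n_points must be a non-negative integer")
  if (parent_intensity < 0 || offspring_spread < 0 || min_sep < 0)
    stop("rates and spreads must be non-negative")
  if (jitter < 0 || jitter > 1) stop("jitter must lie in [0, 1]")
  structure(list(regime = regime, n_points = as.integer(n_points),
                 parent_intensity = parent_intensity,
                 offspring_spread = offspring_spread,
                 jitter = jitter, min_sep = min_sep),
            class = "ihc_pattern_spec")
}

#' Generate a synthetic point pattern
#'
#' Draws exactly `spec$n_points` points inside `window` under the regime
#' described by `spec`. All generators condition on the point count, matching
#' the Monte-Carlo null of the analysis, which simulates random patterns with
#' the same number of points as observed in each field. Cluster offspring or
#' jittered lattice points falling outside the window are resampled until
#' inside, keeping the count exact.
#'
#' @param spec An [pattern_spec()].
#' @param window An [ihc_window()].
#' @param seed Optional integer seed; identical seeds give identical patterns.
#' @param marker Marker label passed to the pattern.
#' @return An `ihc_pattern`.
#' @examples
#' p <- generate_pattern(pattern_spec("csr", 100), ihc_window(1000, 1000),
#'                       seed = 1)
#' @export
generate_pattern <- function(spec, window, seed = NULL,
                             marker = "synthetic") {
  stopifnot(inherits(spec, "ihc_pattern_spec"), inherits(window, "ihc_window"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_points
  if (n == 0L)
    return(point_pattern(numeric(0), numeric(0), window, marker))
  xy <- switch(spec$regime,
    csr = .gen_csr(n, window, spec$min_sep),
    thomas_cluster = .gen_thomas(n, window, spec$parent_intensity,
                                 spec$offspring_spread),
    jittered_lattice = .gen_lattice(n, window, spec$jitter),
    coincident = {
      x0 <- stats::runif(1, 0, window$width)
      y0 <- stats::runif(1, 0, window$height)
      cbind(rep(x0, n), rep(y0, n))
    })
  point_pattern(xy[, 1], xy[, 2], window, marker)
}

.gen_csr <- function(n, window, min_sep = 0) {
  if (min_sep <= 0)
    return(cbind(stats::runif(n, 0, window$width),
                 stats::runif(n, 0, window$height)))
  # simple sequential inhibition: rejection-sample a hard core
  x <- numeric(n); y <- numeric(n); k <- 0L; tries <- 0L
  max_tries <- 10000L * n
  while (k < n) {
    px <- stats::runif(1, 0, window$width)
    py <- stats::runif(1, 0, window$height)
    if (k == 0L || min((x[seq_len(k)] - px)^2 +
                       (y[seq_len(k)] - py)^2) >= min_sep^2) {
      k <- k + 1L; x[k] <- px; y[k] <- py
    }
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " points with min_sep = ", min_sep)
  }
  cbind(x, y)
}

.gen_thomas <- function(n, window, kappa, sigma) {
  n_par <- max(1L, stats::rpois(1, kappa * window_area(window)))
  px <- stats::runif(n_par, 0, window$width)
  py <- stats::runif(n_par, 0, window$height)
  parent <- sample.int(n_par, n, replace = TRUE)
  x <- numeric(n); y <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x[todo] <- px[parent[todo]] + stats::rnorm(length(todo), 0, sigma)
    y[todo] <- py[parent[todo]] + stats::rnorm(length(todo), 0, sigma)
    todo <- todo[x[todo] < 0 | x[todo] > window$width |
                 y[todo] < 0 | y[todo] > window$height]
  }
  cbind(x, y)
}

# Hexagonal (triangular) lattice sized so that nx * ny ~ n with the hex
# aspect dy/dx = sqrt(3)/2 (the density at which the Clark-Evans ratio
# attains its theoretical maximum); the first n row-major points are kept.
.gen_lattice <- function(n, window, jitter) {
  W <- window$width; H <- window$height
  ny <- max(1L, round(sqrt(n * (H / W) * 2 / sqrt(3))))
  nx <- max(1L, ceiling(n / ny))
  dx <- W / nx; dy <- H / ny
  pts <- do.call(rbind, lapply(seq_len(ny), function(r) {
    off <- if (r %% 2L == 0L) dx / 2 else 0
    cbind(((seq_len(nx) - 0.5) * dx + off) %% W, (r - 0.5) * dy)
  }))
  pts <- pts[seq_len(n), , drop = FALSE]
  if (jitter > 0) {
    half <- jitter * dx / 2
    for (j in 1:2) {
      lim <- if (j == 1) W else H
      cand <- pts[, j] + stats::runif(n, -half, half)
      repeat {
        out <- which(cand < 0 | cand > lim)
        if (!length(out)) break
        cand[out] <- pts[out, j] + stats::runif(length(out), -half, half)
      }
      pts[, j] <- cand
    }
  }
  pts
}
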