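#' Two-stain absorbance system for colour deconvolution
#'
#' Holds the unit optical-density (absorbance) vectors of hematoxylin and
#' DAB plus a residual third vector, assembled into the 3x3 stain matrix and
#' its inverse used for linear unmixing. Stain amounts add linearly in
#' optical-density space (Beer-Lambert), so per-pixel concentrations are
#' recovered by a single 3x3 solve.
#'
#' Default vectors are the published H-DAB pair used by the ImageJ
#' colour-deconvolution plugin (hematoxylin (0.650, 0.704, 0.286) and DAB
#' (0.269, 0.568, 0.778), re-normalized); the residual vector is the
#' normalized cross product of the two, the standard orthogonal completion.
#'
#' @param hematoxylin,dab Length-3 absorbance direction vectors (any positive
#'   scale; they are normalized to unit Euclidean norm).
#' @return An object of class `ihc_stains` with unit rows `S_H`, `S_D`,
#'   `S_R`, the matrix `M` (rows in that order) and `M_inv`.
#' @examples
#' st <- stain_system()
#' st$M %*% st$M_inv   # identity to numerical precision
#' @export
stain_system <- function(hematoxylin = c(0.650, 0.704, 0.286),
                         dab = c(0.269, 0.568, 0.778)) {
  norm3 <- function(v) {
    v <- as.numeric(v)
    if (length(v) != 3L || any(!is.finite(v)))
      stop("stain vectors must be finite length-3 numerics")
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("stain vector must be non-zero")
    v / nv
  }
  s_h <- norm3(hematoxylin)
  s_d <- norm3(dab)
  cr <- c(s_h[2] * s_d[3] - s_h[3] * s_d[2],
          s_h[3] * s_d[1] - s_h[1] * s_d[3],
          s_h[1] * s_d[2] - s_h[2] * s_d[1])
  if (sqrt(sum(cr^2)) < 1e-8)
    stop("hematoxylin and DAB vectors are collinear: stain matrix singular")
  s_r <- cr / sqrt(sum(cr^2))
  M <- rbind(S_H = s_h, S_D = s_d, S_R = s_r)
  M_inv <- tryCatch(solve(M), error = function(e)
    stop("stain matrix is singular"))
  structure(list(S_H = s_h, S_D = s_d, S_R = s_r, M = M, M_inv = M_inv),
            class = "ihc_stains")
}

#' @export
print.ihc_stains <- function(x, ...) {
  cat("H-DAB stain system (rows are unit absorbance vectors):\n")
  print(round(x$M, 4))
  invisible(x)
}

#' Convert a brightfield RGB image to optical density
#'
#' Applies `OD_c = log10(I0 / max(I_c, eps))` per channel with `eps = 1`,
#' the documented clamp that keeps zero-intensity pixels finite. Optical
#' density is non-negative wherever intensity does not exceed the incident
#' level `I0`.
#'
#' @param image Numeric array `nrow x ncol x 3` of channel intensities in
#'   \[0, 255\] (or a single-channel matrix).
#' @param I0 Incident (background) intensity, default 255.
#' @param eps Intensity clamp; default 1.
#' @return Array of the same shape holding per-pixel OD values.
#' @export
to_optical_density <- function(image, I0 = 255, eps = 1) {
  if (I0 <= 0) stop("I0 must be positive")
  log10(I0 / pmax(image, eps))
}

#' Unmix an optical-density image into stain concentrations
#'
#' Solves `OD = t(M) c` per pixel, recovering the hematoxylin, DAB and
#' residual coefficients along the stain system's absorbance directions.
#' Negative concentrations (noise pushing a pixel outside the stain simplex)
#' are clipped to zero in the returned channels used for masking; the raw
#' unclipped values are kept for diagnostics.
#'
#' @param od Numeric array `nrow x ncol x 3` of optical densities (or a
#'   3-column matrix of OD vectors).
#' @param stains An [stain_system()].
#' @param clip Clip negative concentrations to zero in `$H`, `$D`, `$R`
#'   (default `TRUE`); `$raw` always holds the unclipped solution.
#' @return List with matrices `H`, `D`, `R` (per-pixel concentrations) and
#'   `raw`, an `n x 3` matrix of unclipped coefficients.
#' @export
unmix <- function(od, stains = stain_system(), clip = TRUE) {
  stopifnot(inherits(stains, "ihc_stains"))
  dm <- dim(od)
  if (is.null(dm) || !(length(dm) %in% c(2L, 3L)))
    stop("od must be an n x 3 matrix or an nrow x ncol x 3 array")
  if (length(dm) == 3L) {
    if (dm[3] != 3L) stop("od array must have 3 channels")
    flat <- matrix(od, ncol = 3L)
  } else {
    if (dm[2] != 3L) stop("od matrix must have 3 columns")
    flat <- od
  }
  # od = t(M) %*% c  =>  c = t(M_inv) %*% od  (per pixel, vectorized)
  conc <- flat %*% stains$M_inv
  dimnames(conc) <- NULL
  shape_back <- function(v) {
    if (length(dm) == 3L) matrix(v, dm[1], dm[2]) else v
  }
  cl <- if (clip) pmax(conc, 0) else conc
  list(H = shape_back(cl[, 1]), D = shape_back(cl[, 2]),
       R = shape_back(cl[, 3]), raw = conc)
}

#' Recompose optical density from stain concentrations
#'
#' Inverse of [unmix()]: `OD = c_H S_H + c_D S_D + c_R S_R`. With the
#' residual channel retained this reconstructs the input OD to numerical
#' precision.
#'
#' @param conc An `n x 3` concentration matrix (columns H, D, residual), as
#'   in the `raw` element returned by [unmix()].
#' @param stains An [stain_system()].
#' @return An `n x 3` matrix of OD vectors.
#' @export
od_compose <- function(conc, stains = stain_system()) {
  stopifnot(inherits(stains, "ihc_stains"))
  conc %*% stains$M
}

#' White-balance a brightfield image to its background
#'
#' Optional shading/illumination correction: rescales each channel so that
#' its 99th-percentile intensity (taken as clear background) maps to `I0`.
#' Off by default in the pipeline; synthetic renders need none.
#'
#' @param image `nrow x ncol x 3` intensity array.
#' @param I0 Target background level.
#' @param probs Background quantile per channel.
#' @return White-balanced array, clipped to \[0, I0\].
#' @export
white_balance <- function(image, I0 = 255, probs = 0.99) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  out <- image
  for (ch in 1:3) {
    bg <- stats::quantile(image[, , ch], probs, names = FALSE)
    if (bg > 0) out[, , ch] <- pmin(image[, , ch] * (I0 / bg), I0)
  }
  out
}
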