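#' Rendering specification for synthetic two-stain fields
#'
#' Parameters of the Beer-Lambert image model used to emulate a brightfield
#' H-DAB field with known ground truth. Every nucleus deposits hematoxylin
#' absorbance over a disk; marker-positive nuclei additionally deposit DAB.
#' Per-pixel intensity is `I_c = I0 * 10^(-A_c)` with
#' `A = c_H * S_H + c_D * S_D` accumulated over overlapping nuclei.
#'
#' @param width,height Image size in pixels.
#' @param I0 Background intensity per channel (default 255).
#' @param stains An [stain_system()] providing the unit absorbance vectors.
#' @param nucleus_radius Disk radius in pixels.
#' @param h_amplitude Hematoxylin absorbance amplitude per nucleus.
#' @param d_amplitude DAB absorbance amplitude per positive nucleus.
#' @param noise_sd SD of additive zero-mean Gaussian intensity noise
#'   (clipped to \[0, 255\]); 0 disables noise.
#' @return An object of class `ihc_render_spec`.
#' @export
render_spec <- function(width = 512, height = 512, I0 = 255,
                        stains = stain_system(), nucleus_radius = 4,
                        h_amplitude = 0.6, d_amplitude = 0.8,
                        noise_sd = 0) {
  stopifnot(inherits(stains, "ihc_stains"))
  if (h_amplitude < 0 || d_amplitude < 0 || noise_sd < 0 ||
      nucleus_radius <= 0)
    stop("amplitudes, noise SD and radius must be non-negative")
  for (v in list(stains$S_H, stains$S_D))
    if (abs(sqrt(sum(v^2)) - 1) > 1e-8)
      stop("absorbance vectors must have unit Euclidean norm")
  structure(list(width = as.integer(width), height = as.integer(height),
                 I0 = I0, stains = stains, nucleus_radius = nucleus_radius,
                 h_amplitude = h_amplitude, d_amplitude = d_amplitude,
                 noise_sd = noise_sd),
            class = "ihc_render_spec")
}

# accumulate `amp` over a disk of radius r around each point, on a
# height x width concentration canvas (pixel centers at (col-0.5, row-0.5))
.splat_disks <- function(canvas, x, y, r, amp) {
  h <- nrow(canvas); w <- ncol(canvas)
  for (k in seq_along(x)) {
    cols <- max(1L, floor(x[k] - r + 0.5)):min(w, ceiling(x[k] + r + 0.5))
    rows <- max(1L, floor(y[k] - r + 0.5)):min(h, ceiling(y[k] + r + 0.5))
    dx2 <- ((cols - 0.5) - x[k])^2
    dy2 <- ((rows - 0.5) - y[k])^2
    inside <- outer(dy2, dx2, "+") <= r^2
    canvas[rows, cols] <- canvas[rows, cols] + amp * inside
  }
  canvas
}

#' Render a synthetic H-DAB field with ground truth
#'
#' Produces an RGB intensity image following the Beer-Lambert composition of
#' the render spec, together with the exact binary masks of DAB-positive
#' regions and of all nuclei, and the generating coordinates. `positives`
#' carry both hematoxylin and DAB; `negatives` carry hematoxylin only.
#'
#' Intensities are returned as doubles (ideal optics); quantization to 8-bit
#' happens when the field is written to disk with [write_field()].
#'
#' @param positives An `ihc_pattern` of marker-positive nucleus centers.
#' @param negatives An `ihc_pattern` of marker-negative nucleus centers
#'   (may be empty).
#' @param spec An [render_spec()]. Its width/height must cover both
#'   patterns' windows.
#' @param seed Optional seed for the noise draw.
#' @return List of class `ihc_field`: `image` (height x width x 3 array),
#'   `dab_mask`, `nuclei_mask` (logical matrices), `conc_H`, `conc_D`
#'   (ground-truth concentration canvases), `positives`, `negatives`, `spec`.
#' @export
render_field <- function(positives, negatives = NULL, spec = render_spec(),
                         seed = NULL) {
  stopifnot(inherits(positives, "ihc_pattern"),
            inherits(spec, "ihc_render_spec"))
  if (is.null(negatives))
    negatives <- point_pattern(numeric(0), numeric(0), positives$window)
  w <- spec$width; h <- spec$height
  for (p in list(positives, negatives))
    if (p$n && (max(p$x) > w || max(p$y) > h))
      stop("all points must lie inside the image bounds")
  zero <- matrix(0, h, w)
  r <- spec$nucleus_radius
  cH <- .splat_disks(.splat_disks(zero, positives$x, positives$y, r,
                                  spec$h_amplitude),
                     negatives$x, negatives$y, r, spec$h_amplitude)
  cD <- .splat_disks(zero, positives$x, positives$y, r, spec$d_amplitude)
  img <- array(0, c(h, w, 3))
  S <- spec$stains
  for (ch in 1:3) {
    A <- cH * S$S_H[ch] + cD * S$S_D[ch]
    img[, , ch] <- spec$I0 * 10^(-A)
  }
  if (spec$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    img <- pmin(pmax(img, 0), 255)
  }
  structure(list(image = img, dab_mask = cD > 0, nuclei_mask = cH > 0,
                 conc_H = cH, conc_D = cD,
                 positives = positives, negatives = negatives, spec = spec),
            class = "ihc_field")
}

#' @export
print.ihc_field <- function(x, ...) {
  cat(sprintf("synthetic H-DAB field: %d x %d px, %d positive / %d negative nuclei\n",
              x$spec$width, x$spec$height, x$positives$n, x$negatives$n))
  invisible(x)
}
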