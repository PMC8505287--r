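#' Threshold an unmixed stain channel
#'
#' Produces a binary mask of the pixels above threshold. `"otsu"` (the
#' default conventional method) picks the threshold maximizing the
#' between-class variance of the 256-bin channel histogram; `"fixed"` uses
#' the supplied value.
#'
#' @param channel Numeric matrix (an unmixed concentration image, or any
#'   single-channel image).
#' @param method `"otsu"` or `"fixed"`.
#' @param t Threshold value when `method = "fixed"`.
#' @return Logical matrix of the same shape (class `ihc_mask`), with the
#'   chosen threshold in attribute `"threshold"`.
#' @export
threshold_channel <- function(channel, method = c("otsu", "fixed"), t = NULL) {
  stopifnot(is.matrix(channel))
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(t)) stop("fixed thresholding requires t")
    thr <- t
  } else {
    rng <- range(channel)
    if (diff(rng) == 0)
      stop("degenerate histogram: constant image has no Otsu threshold ",
           "(use method = 'fixed')")
    thr <- EBImage::otsu(EBImage::Image(channel), range = rng, levels = 256)
  }
  mask <- channel > thr
  attr(mask, "threshold") <- thr
  class(mask) <- c("ihc_mask", class(mask))
  mask
}

#' Clean a binary mask by opening and small-object removal
#'
#' Applies morphological opening with a disc brush of the given radius, then
#' removes connected components (8-connectivity) smaller than `min_area`
#' pixels.
#'
#' @param mask Logical matrix.
#' @param min_area Minimum component area in pixels (>= 0).
#' @param opening_radius Disc radius for the opening; 0 skips it.
#' @return Logical matrix of the same shape.
#' @export
clean_mask <- function(mask, min_area = 0, opening_radius = 0) {
  stopifnot(is.matrix(mask))
  if (min_area < 0) stop("min_area must be >= 0")
  m <- mask * 1
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
    m <- EBImage::opening(EBImage::Image(m), brush)
  }
  if (min_area > 0 && any(m > 0)) {
    lab <- EBImage::bwlabel(EBImage::Image(m))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= min_area)
    m <- matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
  }
  out <- matrix(as.logical(m), nrow(mask), ncol(mask))
  class(out) <- c("ihc_mask", class(out))
  out
}

#' Detect positive cells from the nuclei and immunoreactivity masks
#'
#' Emits the centroid of every connected nuclear component whose overlap
#' with the immunoreactive mask is at least `min_overlap_fraction` of its
#' area -- the "nuclei co-localized with immunoreactivity" selection step.
#' Coordinates are pixel-center based, origin at the top-left: a pixel in
#' row r, column c has center (c - 0.5, r - 0.5).
#'
#' @param nuclei_mask,immuno_mask Logical matrices of identical shape.
#' @param min_overlap_fraction Required overlap fraction, default 0.5.
#' @param window Optional [ihc_window()]; defaults to the image extent.
#' @param marker Marker label for the output pattern.
#' @return An `ihc_pattern` of positive-cell centroids.
#' @export
detect_positive_cells <- function(nuclei_mask, immuno_mask,
                                  min_overlap_fraction = 0.5,
                                  window = NULL, marker = "synthetic") {
  stopifnot(is.matrix(nuclei_mask), is.matrix(immuno_mask))
  if (!all(dim(nuclei_mask) == dim(immuno_mask)))
    stop("nuclei and immunoreactivity masks must have the same shape")
  if (is.null(window))
    window <- ihc_window(ncol(nuclei_mask), nrow(nuclei_mask))
  lab <- as.integer(EBImage::bwlabel(EBImage::Image(nuclei_mask * 1)))
  if (max(lab) == 0L)
    return(point_pattern(numeric(0), numeric(0), window, marker))
  on <- which(lab > 0L)
  lab_on <- lab[on]
  area <- tabulate(lab_on)
  overlap <- tabulate(lab_on[immuno_mask[on]], nbins = length(area))
  sel <- which(overlap / area >= min_overlap_fraction)
  if (!length(sel))
    return(point_pattern(numeric(0), numeric(0), window, marker))
  nr <- nrow(nuclei_mask)
  rows <- ((on - 1L) %% nr) + 1L
  cols <- ((on - 1L) %/% nr) + 1L
  cx <- tapply(cols - 0.5, lab_on, mean)[as.character(sel)]
  cy <- tapply(rows - 0.5, lab_on, mean)[as.character(sel)]
  point_pattern(as.numeric(cx), as.numeric(cy), window, marker)
}

#' Immunoreactive area percentage
#'
#' Percentage of image pixels occupied by the immunoreactive (DAB-positive)
#' mask: `100 * true pixels / total pixels`.
#'
#' @param immuno_mask Logical matrix (non-empty).
#' @return Percentage in \[0, 100\].
#' @export
area_percent <- function(immuno_mask) {
  stopifnot(is.matrix(immuno_mask), length(immuno_mask) > 0)
  100 * sum(immuno_mask) / length(immuno_mask)
}

#' Split touching nuclei by distance-transform watershed
#'
#' Optional refinement for fields where nuclei touch: the binary nuclei mask
#' is split along watershed lines of its distance transform. Off by default
#' in the pipeline.
#'
#' @param mask Logical matrix of nuclei.
#' @return Integer label matrix (0 = background).
#' @export
split_nuclei <- function(mask) {
  stopifnot(is.matrix(mask))
  dmap <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dmap)
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}
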