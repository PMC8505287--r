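#' Rectangular observation window
#'
#' Observation region of a single analyzed field. The origin is fixed at
#' (0, 0); `width` extends along x and `height` along y, in pixels (or any
#' consistent length unit such as micrometres).
#'
#' @param width,height Positive side lengths.
#' @return An object of class `ihc_window` with elements `width`, `height`.
#' @examples
#' w <- ihc_window(1000, 866)
#' window_area(w)
#' @export
ihc_window <- function(width, height) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1L,
            length(height) == 1L)
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("window sides must be positive and finite")
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "ihc_window")
}

#' @rdname ihc_window
#' @param w An `ihc_window`.
#' @export
window_area <- function(w) {
  stopifnot(inherits(w, "ihc_window"))
  w$width * w$height
}

#' @export
print.ihc_window <- function(x, ...) {
  cat(sprintf("observation window: [0, %g] x [0, %g]\n", x$width, x$height))
  invisible(x)
}
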