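#' Read a brightfield field image
#'
#' Reads an RGB TIFF or PNG into an `nrow x ncol x 3` intensity array on the
#' 0-255 scale (files store either 8-bit integers or normalized \[0, 1\]
#' doubles; both are mapped to 0-255).
#'
#' @param path Image path; format inferred from the extension.
#' @return Numeric array `nrow x ncol x 3`.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("cannot read field image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE] # drop alpha
  img * 255
}

#' Write a rendered field to disk as 8-bit RGB
#'
#' Quantizes the continuous intensities of a render to 8 bits and writes a
#' TIFF or PNG (by extension).
#'
#' @param field An `ihc_field` from [render_field()], or a raw
#'   `nrow x ncol x 3` intensity array.
#' @param path Output path ending in .tif/.tiff/.png.
#' @return Invisibly, `path`.
#' @export
write_field <- function(field, path) {
  img <- if (inherits(field, "ihc_field")) field$image else field
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  q <- round(pmin(pmax(img, 0), 255)) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
         png = png::writePNG(q, path),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Write a binary mask as a single-channel PNG
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
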