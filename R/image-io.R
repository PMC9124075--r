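#' Read an RGB patch from disk
#'
#' Reads a PNG (or, via EBImage, JPEG) file into the package's working
#' representation: a numeric `H x W x 3` array of 8-bit values in
#' `[0, 255]`. Grayscale images are replicated across channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path file path of the image.
#' @return numeric array `H x W x 3`, values in `[0, 255]`.
#' @export
read_patch <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    img <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores x,y (W,H); transpose to H,W
    img <- if (length(dim(img)) == 2) t(img) else aperm(img, c(2, 1, 3))
  }
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1) img <- array(img[, , 1], c(dim(img)[1:2], 3))
  round(img * 255)
}

#' Write an RGB patch to disk as PNG
#'
#' @param image numeric array `H x W x 3` with values in `[0, 255]`.
#' @param path output file path (directories are created as needed).
#' @return `path`, invisibly.
#' @export
write_patch <- function(image, path) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  image <- pmin(pmax(image, 0), 255)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Resize an RGB patch
#'
#' Bilinear resize to `size x size` pixels (no-op when already that size).
#'
#' @param image numeric array `H x W x 3`, values in `[0, 255]`.
#' @param size target side length in pixels.
#' @return numeric array `size x size x 3`.
#' @export
resize_patch <- function(image, size) {
  d <- dim(image)
  if (d[1] == size && d[2] == size) return(image)
  # EBImage works in (x = W, y = H) order
  img <- EBImage::Image(aperm(image / 255, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = size, h = size)
  pmin(pmax(aperm(EBImage::imageData(out), c(2, 1, 3)) * 255, 0), 255)
}
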