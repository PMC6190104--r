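#' @import methods
#' @importFrom stats rnorm dnorm setNames
NULL

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Clamp intensities to the 8-bit range [0, 255].
clamp8 <- function(m) {
  m[m < 0] <- 0
  m[m > 255] <- 255
  m
}

#' Coerce an array to an 8-bit grayscale intensity matrix
#'
#' Images in this package are plain numeric matrices with rows indexing y
#' (row 1 is y = 0) and columns indexing x, intensities in \[0, 255\].
#' Color arrays (h x w x 3) are converted to luminance
#' (0.299 R + 0.587 G + 0.114 B); values in \[0, 1\] are rescaled to \[0, 255\].
#'
#' @param img a numeric matrix or an h x w x 3 array.
#' @return a numeric matrix with values in \[0, 255\].
#' @export
asGrayImage <- function(img) {
  if (is.array(img) && length(dim(img)) == 3L) {
    d <- dim(img)
    if (d[3] >= 3L)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img <- img[, , 1]
  }
  if (!is.matrix(img)) stop("'img' must be a matrix or h x w x 3 array")
  img <- img * 1.0
  if (max(img) <= 1 && min(img) >= 0) img <- img * 255
  clamp8(img)
}

checkGray <- function(img, minH = 1L, minW = 1L, what = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("'%s' must be a numeric matrix", what))
  if (nrow(img) < minH || ncol(img) < minW)
    stop(sprintf("'%s' must be at least %d x %d", what, minH, minW))
  invisible(TRUE)
}

#' Read / write 8-bit grayscale images
#'
#' Thin wrappers over EBImage I/O. PNG and TIFF are supported. On read, color
#' images are converted to luminance and values are rescaled to \[0, 255\];
#' the returned matrix has rows = y, columns = x.
#'
#' @param path file path (.png or .tif/.tiff).
#' @param img intensity matrix in \[0, 255\].
#' @return `readGrayImage` returns an intensity matrix; `writeGrayImage`
#'   returns `path` invisibly.
#' @export
readGrayImage <- function(path) {
  im <- EBImage::readImage(path)
  d <- dim(im)
  a <- as.array(im)
  if (length(d) == 3L) {
    # EBImage stores x as the first dimension; channels third
    a <- aperm(a, c(2, 1, 3))
    return(asGrayImage(a * 255))
  }
  t(a) * 255
}

#' @rdname readGrayImage
#' @export
writeGrayImage <- function(img, path) {
  checkGray(img)
  EBImage::writeImage(EBImage::Image(t(img / 255)), path)
  invisible(path)
}
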