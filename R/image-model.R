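#' @noRd
assert_gray <- function(g, arg = "g") {
  if (!is.matrix(g) || !is.numeric(g))
    stop(arg, " must be a numeric matrix", call. = FALSE)
  if (nrow(g) < 1L || ncol(g) < 1L)
    stop(arg, " must have at least one row and one column", call. = FALSE)
  if (anyNA(g) || any(g < 0) || any(g > 255) || any(g != round(g)))
    stop(arg, " must hold integer intensities in [0, 255]", call. = FALSE)
  invisible(g)
}

#' @noRd
assert_binary <- function(b, arg = "b") {
  if (!is.matrix(b) || !is.numeric(b))
    stop(arg, " must be a numeric matrix", call. = FALSE)
  if (anyNA(b) || !all(b == 0L | b == 1L))
    stop(arg, " must hold only 0/1 values", call. = FALSE)
  invisible(b)
}

#' @noRd
as_int_matrix <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' Read a grayscale boundary image
#'
#' Reads an 8-bit PNG or TIFF and returns it as an integer matrix with
#' values in 0..255 (`[row, col]`, origin top-left).  RGB inputs are
#' converted by the standard luma weighting 0.299 R + 0.587 G + 0.114 B and
#' rounded; an alpha channel is ignored.
#'
#' @param path Path to a PNG (`.png`) or TIFF (`.tif`/`.tiff`) file.
#' @return Integer matrix of intensities in \[0, 255\].
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' write_gray(matrix(0:255, 16, 16), f)
#' g <- read_gray(f)
#' range(g)
read_gray <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3L]
    a <- if (nc >= 3L)
      0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
    else
      a[, , 1L]
  }
  if (!is.matrix(a) || nrow(a) < 1L || ncol(a) < 1L)
    stop("zero-sized or malformed image: ", path)
  g <- round(a * 255)
  g[g < 0] <- 0
  g[g > 255] <- 255
  as_int_matrix(g)
}

#' Write a grayscale image as an 8-bit PNG
#'
#' @param g Integer matrix with values in \[0, 255\].
#' @param path Output path (PNG).
#' @return Invisibly, `path`.
#' @export
write_gray <- function(g, path) {
  assert_gray(g)
  png::writePNG(g / 255, target = path)
  invisible(path)
}

#' Write a binary edge map as an 8-bit PNG
#'
#' Foreground (1) pixels are written as 255, background (0) as 0.
#'
#' @param img Binary matrix with values in {0, 1}.
#' @param path Output path (PNG).
#' @return Invisibly, `path`.
#' @export
write_edge_map <- function(img, path) {
  assert_binary(img, "img")
  png::writePNG(img + 0, target = path)
  invisible(path)
}

#' Read a binary edge map
#'
#' Reads an image and binarizes it: any positive intensity becomes 1.
#'
#' @param path Path to a PNG or TIFF edge map.
#' @return Integer matrix with values in {0, 1}.
#' @export
read_edge_map <- function(path) {
  binarize(read_gray(path))
}

#' Binarize a grayscale image
#'
#' Every pixel with a positive intensity contributes to the boundary (1);
#' zero-valued pixels belong to the background (0).
#'
#' @param g Integer matrix with values in \[0, 255\].
#' @return Integer matrix with values in {0, 1}.
#' @export
#' @examples
#' binarize(matrix(c(0L, 0L, 7L), 1))
binarize <- function(g) {
  assert_gray(g)
  as_int_matrix((g > 0) + 0L)
}

#' Count foreground 8-neighbours of every pixel
#'
#' Positions outside the image count as background.
#'
#' @param b Binary matrix.
#' @return Integer matrix of neighbour counts (0..8).
#' @export
fg_neighbor_count <- function(b) {
  assert_binary(b)
  h <- nrow(b)
  w <- ncol(b)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1), 2:(w + 1)] <- b
  n <- matrix(0L, h, w)
  for (di in -1:1)
    for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      n <- n + p[(2:(h + 1)) + di, (2:(w + 1)) + dj, drop = FALSE]
    }
  as_int_matrix(n)
}
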