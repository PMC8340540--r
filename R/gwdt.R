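#' Gray-weighted distance transform
#'
#' For every foreground (positive) pixel, the minimal accumulated intensity
#' cost over all 4-connected paths that end at a background (zero) pixel.
#' The path cost sums the intensity of the start pixel and of every
#' intermediate foreground pixel; the terminal background pixel contributes
#' zero.  Background pixels map to cost 0.  The result is exact: it is
#' computed by multi-source lowest-cost-first propagation (Dijkstra) over
#' the 4-connected grid with node costs, not by a raster-scan approximation.
#'
#' Image borders are not treated as background: a path must end at an
#' in-image zero pixel, so an image without any zero is a degenerate input
#' and raises an error.
#'
#' @param g Integer matrix with intensities in \[0, 255\] containing at least
#'   one zero pixel.
#' @return Numeric matrix of non-negative integer-valued costs, zero exactly
#'   where `g` is zero.
#' @export
#' @examples
#' gwdt(matrix(c(0L, 5L, 3L, 0L), 1))   # costs 0 5 3 0
gwdt <- function(g) {
  assert_gray(g)
  if (!any(g == 0))
    stop("no background reachable: image contains no zero-valued pixel")
  gwdt_cpp(as_int_matrix(g))
}
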