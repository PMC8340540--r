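#' Eight-way neighbourhood number
#'
#' The local connectivity count of a pixel's 3x3 neighbourhood,
#' \deqn{N_c = \sum_{k \in \{1,3,5,7\}} \bar x_k - \bar x_k \bar x_{k+1}
#' \bar x_{k+2}, \quad \bar x = 1 - x,}
#' with the neighbours numbered counterclockwise from the east,
#' `x1 = E, x2 = NE, x3 = N, x4 = NW, x5 = W, x6 = SW, x7 = S, x8 = SE`,
#' and the cyclic wrap `x9 == x1`.  The sum runs over the 4-neighbours.
#' `N_c` counts the 8-connected foreground components meeting the centre:
#' a foreground pixel with `N_c == 1` is simple, i.e. removing it does not
#' change the local connectivity structure.
#'
#' @param neighbors Vector of eight 0/1 values in the order `x1..x8` above.
#' @return Integer in 0..4.
#' @export
#' @examples
#' neighborhood_number(rep(0, 8))                    # isolated centre: 0
#' neighborhood_number(c(1, 0, 0, 0, 1, 0, 0, 0))    # straight line: 2
neighborhood_number <- function(neighbors) {
  if (length(neighbors) != 8L || anyNA(neighbors) ||
      !all(neighbors == 0 | neighbors == 1))
    stop("neighbors must be eight 0/1 values (x1..x8)")
  xb <- 1 - c(neighbors, neighbors[1L])
  k <- c(1L, 3L, 5L, 7L)
  sum(xb[k] - xb[k] * xb[k + 1L] * xb[k + 2L])
}

#' Gray-weighted path skeletonize
#'
#' Extracts the ridge of a gray-weighted distance transform surface as a
#' one-pixel-wide, eight-connected thin edge.  Foreground pixels (positive
#' cost) are visited in ascending cost order, ties broken by row-major
#' position; a pixel is deleted iff its neighbourhood number is 1 (it is
#' simple) and it has at least two foreground 8-neighbours, so endpoints
#' and isolated pixels are never deleted.  Deleting a pixel re-enqueues its
#' foreground neighbours, and the pass runs to a fixed point.  The surviving
#' pixels lie along the high-cost crest of the surface, the number of
#' 8-connected components is preserved, and the operation is idempotent.
#'
#' @param t Numeric matrix of non-negative costs (zero on background), as
#'   produced by [gwdt()].
#' @return Binary matrix; foreground is a subset of the foreground of `t`.
#' @export
gwps <- function(t) {
  if (!is.matrix(t) || !is.numeric(t) || anyNA(t) || any(t < 0))
    stop("t must be a non-negative numeric cost matrix")
  gwps_cpp(t)
}

#' Skeletonize a boundary image
#'
#' Reduces a grayscale boundary to a thin edge with the method selected by
#' `beta`:
#' \describe{
#'   \item{`"GWPS"`}{gray-weighted path skeletonize: [gwps()] applied to
#'     [gwdt()] of the image, so the per-pixel confidence steers the ridge.}
#'   \item{`"2D"`}{Zhang-Suen two-subiteration medial-axis thinning of the
#'     binarized image.}
#'   \item{`"3D"`}{directional border thinning of the binarized image
#'     embedded as a single-slice volume (the volumetric six-subiteration
#'     scheme with the two out-of-plane directions vacuous).}
#' }
#' In all cases the output foreground is a subset of the binarized input
#' foreground.
#'
#' @param g Integer matrix with intensities in \[0, 255\].
#' @param beta One of `"2D"`, `"3D"`, `"GWPS"` (case-insensitive).
#' @return Binary matrix holding the thin edge.
#' @export
apply_skeletonize <- function(g, beta) {
  assert_gray(g)
  if (!is.character(beta) || length(beta) != 1L)
    stop("beta must be one of '2D', '3D', 'GWPS'")
  method <- toupper(beta)
  if (!method %in% c("2D", "3D", "GWPS"))
    stop("unknown skeletonize method: ", beta)
  g <- as_int_matrix(g)
  switch(method,
    "GWPS" = gwps(gwdt(g)),
    "2D"   = zhang_suen_cpp(binarize(g)),
    "3D"   = dir_thin_cpp(binarize(g))
  )
}

#' Label 8-connected foreground components
#'
#' @param b Binary matrix.
#' @return Integer matrix of component labels (0 = background, 1..k).
#' @export
label_components <- function(b) {
  assert_binary(b)
  label8_cpp(as_int_matrix(b))
}

#' Count 8-connected foreground components
#'
#' @param b Binary matrix.
#' @return Integer count.
#' @export
count_components <- function(b) {
  max(label_components(b))
}
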