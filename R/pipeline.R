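#' Edge-extraction parameter set
#'
#' Bundles the three tunable parameters of the edge-extraction function:
#' the intensity threshold `alpha` (0..255), the skeletonize method `beta`
#' (`"2D"`, `"3D"` or `"GWPS"`), and the pruning percentage `gamma`
#' (0..100).
#'
#' @param alpha Integer intensity threshold in \[0, 255\].
#' @param beta Skeletonize method, one of `"2D"`, `"3D"`, `"GWPS"`
#'   (case-insensitive).
#' @param gamma Pruning percentage in \[0, 100\].
#' @return A `param_set` list with elements `alpha`, `beta`, `gamma`.
#' @export
#' @examples
#' param_set(40, "GWPS", 2)
param_set <- function(alpha, beta, gamma) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 255 || alpha != round(alpha))
    stop("alpha must be an integer in [0, 255]")
  if (!is.character(beta) || length(beta) != 1L ||
      !toupper(beta) %in% c("2D", "3D", "GWPS"))
    stop("beta must be one of '2D', '3D', 'GWPS'")
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 100)
    stop("gamma must be in [0, 100]")
  structure(list(alpha = as.integer(alpha), beta = toupper(beta),
                 gamma = gamma),
            class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat(sprintf("edge-extraction parameters: alpha = %d, beta = '%s', gamma = %g\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Threshold a boundary image
#'
#' Pixels with intensity strictly below `alpha` are set to zero; pixels at
#' or above `alpha` keep their value.  This is a rudimentary noise filter:
#' low-confidence boundary pixels are discarded before skeletonization.
#'
#' @param g Integer matrix with intensities in \[0, 255\].
#' @param alpha Integer threshold in \[0, 255\].
#' @return Integer matrix of the same size.
#' @export
#' @examples
#' threshold(matrix(c(39L, 40L, 41L), 1), 40)  # 0 40 41
threshold <- function(g, alpha) {
  assert_gray(g)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 255)
    stop("alpha must be in [0, 255]")
  g[g < alpha] <- 0L
  as_int_matrix(g)
}

#' Extract a thin edge from a predicted boundary
#'
#' The full edge-extraction function: threshold the boundary at
#' `params$alpha`, skeletonize with `params$beta`, then prune spurs up to
#' the length limit derived from `params$gamma` and the image diagonal.
#' With `gamma = 0` the pruning stage is the identity.
#'
#' @param g Integer matrix with intensities in \[0, 255\] (the predicted
#'   boundary).
#' @param params A [param_set()], or a list with elements `alpha`, `beta`,
#'   `gamma`.
#' @return Binary matrix holding the thin edge; its foreground is a subset
#'   of the pixels with `g >= alpha`.
#' @export
#' @examples
#' g <- matrix(0L, 5, 7)
#' g[2:4, 2:6] <- rep(c(1L, 5L, 1L), 5)
#' extract_edges(g, param_set(1, "GWPS", 0))  # the middle row survives
extract_edges <- function(g, params) {
  assert_gray(g)
  if (!inherits(params, "param_set"))
    params <- param_set(params$alpha, params$beta, params$gamma)
  thr <- threshold(g, params$alpha)
  skel <- apply_skeletonize(thr, params$beta)
  l <- spur_length_limit(params$gamma, w = ncol(g), h = nrow(g))
  prune_spurs(skel, l)
}
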