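#' Search grid over the edge-extraction parameters
#'
#' @param alphas Intensity thresholds, integers in \[0, 255\].
#' @param betas Skeletonize methods, a subset of `c("2D", "3D", "GWPS")`.
#' @param gammas Pruning percentages in \[0, 100\].
#' @return A `search_grid` list with elements `alphas`, `betas`, `gammas`.
#' @export
search_grid <- function(alphas, betas, gammas) {
  if (length(alphas) == 0L || anyNA(alphas) || any(alphas < 0 | alphas > 255) ||
      anyDuplicated(alphas))
    stop("alphas must be distinct values in [0, 255]")
  betas <- toupper(betas)
  if (length(betas) == 0L || !all(betas %in% c("2D", "3D", "GWPS")) ||
      anyDuplicated(betas))
    stop("betas must be distinct values among '2D', '3D', 'GWPS'")
  if (length(gammas) == 0L || anyNA(gammas) || any(gammas < 0 | gammas > 100) ||
      anyDuplicated(gammas))
    stop("gammas must be distinct values in [0, 100]")
  structure(list(alphas = as.integer(alphas), betas = betas, gammas = gammas),
            class = "search_grid")
}

#' Default parameter grid
#'
#' The non-exhaustive discrete grid used for combinatorial tuning: every
#' tenth threshold value (`alpha` in 0, 10, ..., 250; 26 values), all three
#' skeletonize methods, and for the pruning percentage every integer from 0
#' to 10 plus every tenth value from 20 to 100 (20 values) -- fine
#' resolution where pruning is typically useful, coarse above.  1560
#' combinations in total.
#'
#' @return A [search_grid()].
#' @export
default_grid <- function() {
  search_grid(alphas = seq(0L, 250L, by = 10L),
              betas = c("2D", "3D", "GWPS"),
              gammas = c(0:10, seq(20L, 100L, by = 10L)))
}

#' Grid search for the best edge-extraction parameters
#'
#' Evaluates every combination of the grid (alphas outermost, betas, then
#' gammas innermost, each in the declared order) by running
#' [extract_edges()] on all boundary images and scoring against the ground
#' truth with [sde()] and [iou_box()].  The selection criterion is the mean
#' SDE alone; IoU-box is reported but never used for selection.  Ties keep
#' the first combination in iteration order.  For speed the threshold +
#' skeletonize result is cached across the gamma values of a combination;
#' this cannot change any result since pruning is the only stage that
#' depends on gamma.
#'
#' A combination for which the pipeline fails on an image (e.g. GWPS on an
#' image that thresholding leaves without background) scores that image
#' through the empty-map centre-pixel correction instead of aborting the
#' search; the `n_failed` column of the table records how many images
#' failed.
#'
#' @param boundaries List of grayscale boundary matrices.
#' @param gts List of binary ground-truth edge maps, pairwise matching
#'   dimensions.
#' @param grid A [search_grid()]; defaults to [default_grid()].
#' @param verbose Log one line per combination to stderr.
#' @param csv,json Optional output paths for the full table (CSV) and the
#'   best parameter set (JSON).
#' @return An `edge_search_result`: list with `best` (a [param_set()]),
#'   `best_mean_sde`, and `table` (data frame with columns `alpha`, `beta`,
#'   `gamma`, `mean_sde`, `mean_iou_box`, `n_failed`).
#' @export
grid_search <- function(boundaries, gts, grid = default_grid(),
                        verbose = FALSE, csv = NULL, json = NULL) {
  if (!is.list(boundaries) || !is.list(gts) ||
      length(boundaries) != length(gts) || length(boundaries) == 0L)
    stop("boundaries and gts must be non-empty lists of equal length")
  for (k in seq_along(boundaries)) {
    assert_gray(boundaries[[k]], sprintf("boundaries[[%d]]", k))
    assert_binary(gts[[k]], sprintf("gts[[%d]]", k))
    if (!all(dim(boundaries[[k]]) == dim(gts[[k]])))
      stop("boundary/ground-truth dimensions differ for pair ", k)
  }
  if (!inherits(grid, "search_grid"))
    grid <- search_grid(grid$alphas, grid$betas, grid$gammas)
  n_img <- length(boundaries)
  n_comb <- length(grid$alphas) * length(grid$betas) * length(grid$gammas)
  tab_alpha <- integer(n_comb)
  tab_beta <- character(n_comb)
  tab_gamma <- numeric(n_comb)
  tab_sde <- numeric(n_comb)
  tab_iou <- numeric(n_comb)
  tab_fail <- integer(n_comb)
  best_idx <- 0L
  best_sde <- Inf
  row <- 0L
  for (alpha in grid$alphas) {
    for (beta in grid$betas) {
      skels <- lapply(boundaries, function(g) {
        tryCatch(apply_skeletonize(threshold(g, alpha), beta),
                 error = function(e) NULL)
      })
      for (gamma in grid$gammas) {
        sdes <- numeric(n_img)
        ious <- numeric(n_img)
        nf <- 0L
        for (k in seq_len(n_img)) {
          g <- boundaries[[k]]
          if (is.null(skels[[k]])) {
            nf <- nf + 1L
            pred <- matrix(0L, nrow(g), ncol(g))
          } else {
            l <- spur_length_limit(gamma, w = ncol(g), h = nrow(g))
            pred <- prune_spurs(skels[[k]], l)
          }
          sdes[k] <- sde(pred, gts[[k]])
          ious[k] <- iou_box(pred, gts[[k]])
        }
        row <- row + 1L
        tab_alpha[row] <- alpha
        tab_beta[row] <- beta
        tab_gamma[row] <- gamma
        tab_sde[row] <- mean(sdes)
        tab_iou[row] <- mean(ious)
        tab_fail[row] <- nf
        if (mean(sdes) < best_sde) {
          best_sde <- mean(sdes)
          best_idx <- row
        }
        if (verbose)
          message(sprintf("alpha=%3d beta=%-4s gamma=%5.1f  mean SDE %.4f  mean IoU-box %.4f",
                          alpha, beta, gamma, mean(sdes), mean(ious)))
      }
    }
  }
  tab <- data.frame(alpha = tab_alpha, beta = tab_beta, gamma = tab_gamma,
                    mean_sde = tab_sde, mean_iou_box = tab_iou,
                    n_failed = tab_fail, stringsAsFactors = FALSE)
  best <- param_set(tab$alpha[best_idx], tab$beta[best_idx], tab$gamma[best_idx])
  result <- structure(list(best = best, best_mean_sde = best_sde, table = tab),
                      class = "edge_search_result")
  if (!is.null(csv)) write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(alpha = best$alpha, beta = best$beta,
                              gamma = best$gamma, mean_sde = best_sde),
                         json, auto_unbox = TRUE, digits = NA)
  result
}

#' @export
print.edge_search_result <- function(x, ...) {
  cat(sprintf("parameter search over %d combination(s)\n", nrow(x$table)))
  cat(sprintf("best: alpha = %d, beta = '%s', gamma = %g  (mean SDE %.4f)\n",
              x$best$alpha, x$best$beta, x$best$gamma, x$best_mean_sde))
  invisible(x)
}
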