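#' Replace an empty edge map by a single centre pixel
#'
#' Distance-based scoring is undefined when one side has no edge pixel at
#' all.  Evaluation therefore treats an empty binary image as if it
#' contained a single edge pixel at the image centre,
#' `(floor(h/2), floor(w/2))` in 0-based coordinates.  Non-empty maps are
#' returned unchanged; the correction is applied inside the metrics, never
#' to saved outputs.
#'
#' @param b Binary matrix.
#' @return Binary matrix with at least one foreground pixel.
#' @export
ensure_nonempty <- function(b) {
  assert_binary(b)
  b <- as_int_matrix(b)
  if (any(b == 1L)) return(b)
  b[floor(nrow(b) / 2) + 1L, floor(ncol(b) / 2) + 1L] <- 1L
  b
}

# full-image Euclidean distance to the nearest foreground pixel of mask
#' @noRd
dist_to_mask <- function(mask) {
  co <- which(mask == 1L, arr.ind = TRUE)
  nearest_to_coords_cpp(nrow(mask), ncol(mask),
                        as.integer(co[, 1L] - 1L), as.integer(co[, 2L] - 1L))$dist
}

#' Symmetric distance error between two edge maps
#'
#' After applying the empty-map centre-pixel correction
#' ([ensure_nonempty()]) to both sides, returns
#' \deqn{\mathrm{SDE} = \tfrac12\Big(\mathrm{mean}_{p \in P} d(p, G) +
#'   \mathrm{mean}_{g \in G} d(g, P)\Big),}
#' the average of the two directional mean Euclidean distances between the
#' predicted pixel set P and the ground-truth pixel set G.  The first term
#' is precision-like (predictions far from any true edge are penalised),
#' the second recall-like (true edge pixels missed by the prediction are
#' penalised).  Lower is better; 0 iff the two pixel sets coincide.
#'
#' @param pred,gt Binary matrices of identical dimensions.
#' @return Non-negative real, in pixels.
#' @export
#' @examples
#' p <- matrix(0L, 1, 4); p[1, 1] <- 1L
#' g <- matrix(0L, 1, 4); g[1, 4] <- 1L
#' sde(p, g)  # 3
sde <- function(pred, gt) {
  assert_binary(pred, "pred")
  assert_binary(gt, "gt")
  if (!all(dim(pred) == dim(gt)))
    stop("pred and gt must have identical dimensions")
  pred <- ensure_nonempty(pred)
  gt <- ensure_nonempty(gt)
  d_pred <- mean(dist_to_mask(gt)[pred == 1L])
  d_gt <- mean(dist_to_mask(pred)[gt == 1L])
  (d_pred + d_gt) / 2
}

#' @noRd
component_boxes <- function(b) {
  lab <- label8_cpp(b)
  k <- max(lab)
  if (k == 0L) return(matrix(numeric(0), 0L, 4L))
  out <- matrix(0, k, 4L)
  colnames(out) <- c("rmin", "rmax", "cmin", "cmax")
  for (m in seq_len(k)) {
    co <- which(lab == m, arr.ind = TRUE)
    out[m, ] <- c(min(co[, 1L]), max(co[, 1L]), min(co[, 2L]), max(co[, 2L]))
  }
  out
}

# inclusive pixel-area IoU of two boxes given as (rmin, rmax, cmin, cmax)
#' @noRd
box_iou_one <- function(a, b) {
  ir <- min(a[2L], b[2L]) - max(a[1L], b[1L]) + 1
  ic <- min(a[4L], b[4L]) - max(a[3L], b[3L]) + 1
  inter <- max(0, ir) * max(0, ic)
  area_a <- (a[2L] - a[1L] + 1) * (a[4L] - a[3L] + 1)
  area_b <- (b[2L] - b[1L] + 1) * (b[4L] - b[3L] + 1)
  inter / (area_a + area_b - inter)
}

#' Bounding-box intersection-over-union of matched components
#'
#' After the empty-map centre-pixel correction, the axis-aligned bounding
#' box of every 8-connected component is computed on each side.
#' Ground-truth boxes are greedily matched to distinct predicted boxes in
#' descending pairwise box-IoU order (one-to-one, so a single sprawling
#' prediction cannot score against many components); the score is the mean
#' over ground-truth components of the matched IoU, with unmatched
#' components contributing 0.  Boxes use inclusive pixel areas, so a single
#' pixel is a 1x1 box.
#'
#' @param pred,gt Binary matrices of identical dimensions.
#' @return Real in \[0, 1\]; 1 iff the matched boxes coincide
#'   component-for-component.
#' @export
iou_box <- function(pred, gt) {
  assert_binary(pred, "pred")
  assert_binary(gt, "gt")
  if (!all(dim(pred) == dim(gt)))
    stop("pred and gt must have identical dimensions")
  pred <- ensure_nonempty(pred)
  gt <- ensure_nonempty(gt)
  gb <- component_boxes(gt)
  pb <- component_boxes(pred)
  ng <- nrow(gb)
  np <- nrow(pb)
  iou <- matrix(0, ng, np)
  for (a in seq_len(ng))
    for (b in seq_len(np))
      iou[a, b] <- box_iou_one(gb[a, ], pb[b, ])
  matched <- numeric(ng)
  free_g <- rep(TRUE, ng)
  free_p <- rep(TRUE, np)
  repeat {
    m <- iou
    m[!free_g, ] <- -1
    m[, !free_p] <- -1
    best <- max(m)
    if (best <= 0) break
    hit <- which(m == best, arr.ind = TRUE)[1L, ]  # earliest pair on ties
    matched[hit[1L]] <- best
    free_g[hit[1L]] <- FALSE
    free_p[hit[2L]] <- FALSE
  }
  mean(matched)
}

#' Score a set of predicted edge maps against ground truth
#'
#' Computes [sde()] and [iou_box()] for every prediction / ground-truth
#' pair and aggregates each metric with the mean, the median and the
#' population standard deviation.
#'
#' @param preds,gts Equal-length lists of binary matrices with pairwise
#'   matching dimensions.
#' @param names Optional character vector of image names (defaults to the
#'   list names or a running index).
#' @param csv,json Optional output paths; when given, the per-image table
#'   plus the aggregate block is written as CSV / JSON.
#' @return An `edge_eval_report`: a list with `per_image` (data frame with
#'   columns `image`, `sde`, `iou_box`) and `aggregates` (data frame with
#'   columns `metric`, `mean`, `median`, `sd`).
#' @export
evaluate_pairs <- function(preds, gts, names = NULL, csv = NULL, json = NULL) {
  if (!is.list(preds) || !is.list(gts) || length(preds) != length(gts) ||
      length(preds) == 0L)
    stop("preds and gts must be non-empty lists of equal length")
  if (is.null(names)) names <- base::names(preds)
  if (is.null(names)) names <- sprintf("%03d", seq_along(preds))
  sdes <- numeric(length(preds))
  ious <- numeric(length(preds))
  for (k in seq_along(preds)) {
    sdes[k] <- sde(preds[[k]], gts[[k]])
    ious[k] <- iou_box(preds[[k]], gts[[k]])
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  per_image <- data.frame(image = names, sde = sdes, iou_box = ious,
                          stringsAsFactors = FALSE)
  aggregates <- data.frame(
    metric = c("sde", "iou_box"),
    mean = c(mean(sdes), mean(ious)),
    median = c(median(sdes), median(ious)),
    sd = c(pop_sd(sdes), pop_sd(ious)),
    stringsAsFactors = FALSE
  )
  report <- structure(list(per_image = per_image, aggregates = aggregates),
                      class = "edge_eval_report")
  if (!is.null(csv)) {
    # flat layout: per-image rows, then one row per aggregate statistic
    agg_flat <- data.frame(
      image = c("<mean>", "<median>", "<sd>"),
      sde = c(aggregates$mean[1L], aggregates$median[1L], aggregates$sd[1L]),
      iou_box = c(aggregates$mean[2L], aggregates$median[2L], aggregates$sd[2L]),
      stringsAsFactors = FALSE)
    write.csv(rbind(per_image, agg_flat), csv, row.names = FALSE)
  }
  if (!is.null(json))
    jsonlite::write_json(list(per_image = per_image, aggregates = aggregates),
                         json, dataframe = "rows", digits = NA)
  report
}

#' @export
print.edge_eval_report <- function(x, ...) {
  cat(sprintf("edge evaluation over %d image(s)\n", nrow(x$per_image)))
  print(x$aggregates, row.names = FALSE)
  invisible(x)
}
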