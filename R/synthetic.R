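#' Configuration for the synthetic boundary generator
#'
#' The generator emulates the output of an upstream boundary predictor: a
#' known one-pixel ground-truth curve rendered as a ramp boundary with a
#' Gaussian cross-profile, optionally degraded by additive noise, small
#' irregularities and gaps (incomplete boundaries).
#'
#' @param height,width Image size in pixels (at least 16 each).
#' @param kind Curve type: `"open-spline"` (a smooth open curve crossing
#'   the image) or `"closed-ellipse"` (a perturbed elliptical loop).
#' @param sigma Width of the Gaussian cross-profile, pixels (> 0).
#' @param peak Peak intensity A at the curve, in \[1, 255\].
#' @param noise_sd Standard deviation of additive Gaussian pixel noise, in
#'   intensity units (>= 0).
#' @param gap_prob Probability in \[0, 1\] that a curve segment (8 curve
#'   pixels) loses a short run of the rendered boundary.
#' @param gap_len Length in curve pixels of each gap run (>= 1).
#' @param jitter Irregularity amplitude: pixels of smooth jitter applied to
#'   the curve (>= 0).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(height = 64L, width = 64L,
                             kind = c("open-spline", "closed-ellipse"),
                             sigma = 2, peak = 200L, noise_sd = 8,
                             gap_prob = 0, gap_len = 4L, jitter = 2,
                             seed = 1L) {
  kind <- match.arg(kind)
  if (height < 16L || width < 16L)
    stop("image too small: height and width must be at least 16")
  if (sigma <= 0) stop("sigma must be positive")
  if (peak < 1 || peak > 255) stop("peak must be in [1, 255]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (gap_prob < 0 || gap_prob > 1) stop("gap_prob must be in [0, 1]")
  if (gap_len < 1) stop("gap_len must be at least 1")
  if (jitter < 0) stop("jitter must be non-negative")
  structure(list(height = as.integer(height), width = as.integer(width),
                 kind = kind, sigma = sigma, peak = peak,
                 noise_sd = noise_sd, gap_prob = gap_prob,
                 gap_len = as.integer(gap_len), jitter = jitter,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Drop loop points whose circular neighbours are already 8-adjacent, until
# the polygonal pixel chain is taut (no chord shortcuts remain).
#' @noRd
simplify_loop <- function(pts) {
  repeat {
    dropped <- FALSE
    i <- 1L
    while (i <= nrow(pts) && nrow(pts) > 4L) {
      n <- nrow(pts)
      ip <- if (i == 1L) n else i - 1L
      inx <- if (i == n) 1L else i + 1L
      if (max(abs(pts[ip, ] - pts[inx, ])) <= 1L) {
        pts <- pts[-i, , drop = FALSE]
        dropped <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!dropped) break
  }
  pts
}

#' @noRd
curve_open_spline <- function(h, w, margin, jitter) {
  cols <- (margin + 1L):(w - margin)
  nc <- length(cols)
  cx <- seq(cols[1L], cols[nc], length.out = 4L)
  cy <- runif(4L, margin + 2, h - margin - 1)
  base <- spline(cx, cy, xout = cols)$y
  if (jitter > 0) {
    fx <- seq(cols[1L], cols[nc], length.out = max(4L, ceiling(nc / 6)))
    fy <- rnorm(length(fx), 0, jitter)
    base <- base + spline(fx, fy, xout = cols)$y
  }
  # clamp successive steps to +/- 1 row so the one-pixel-per-column chain
  # stays 8-connected and thin
  rows <- integer(nc)
  r <- min(max(round(base[1L]), margin + 1L), h - margin)
  rows[1L] <- r
  for (k in seq_len(nc)[-1L]) {
    step <- max(-1L, min(1L, round(base[k]) - r))
    r <- min(max(r + step, margin + 1L), h - margin)
    rows[k] <- r
  }
  cbind(rows, cols)
}

#' @noRd
curve_closed_ellipse <- function(h, w, margin, jitter) {
  ci <- h / 2 + runif(1, -2, 2)
  cj <- w / 2 + runif(1, -2, 2)
  ra <- max(4, (min(ci, h + 1 - ci) - margin - 1 - jitter) * runif(1, 0.7, 0.95))
  rb <- max(4, (min(cj, w + 1 - cj) - margin - 1 - jitter) * runif(1, 0.7, 0.95))
  a1 <- rnorm(2, 0, jitter / 2)
  b1 <- rnorm(2, 0, jitter / 2)
  theta <- seq(0, 2 * pi, length.out = ceiling(16 * pi * max(ra, rb)))
  theta <- theta[-length(theta)]
  pert <- a1[1L] * cos(theta) + b1[1L] * sin(theta) +
    a1[2L] * cos(2 * theta) + b1[2L] * sin(2 * theta)
  ri <- round(ci + (ra + pert) * sin(theta))
  rj <- round(cj + (rb + pert) * cos(theta))
  ri <- pmin(pmax(ri, margin + 1L), h - margin)
  rj <- pmin(pmax(rj, margin + 1L), w - margin)
  pts <- cbind(as.integer(ri), as.integer(rj))
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) > 1L && all(pts[1L, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  simplify_loop(pts)
}

#' Generate a one-pixel ground-truth curve
#'
#' Rasterizes a smooth random curve as an 8-connected one-pixel path lying
#' strictly inside the image, at least 2 pixels from every border.  An open
#' spline has exactly two endpoints; a closed ellipse is a single loop in
#' which every pixel has exactly two foreground 8-neighbours.  The result
#' is fully determined by `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return Binary matrix; the ordered pixel chain is attached as the
#'   `"curve_path"` attribute (an n x 2 matrix of `(row, col)`).
#' @export
generate_curve <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  h <- cfg$height
  w <- cfg$width
  margin <- 2L
  if (w - 2L * margin < 8L || h - 2L * margin < 8L)
    stop("image too small for the requested curve")
  withr::with_seed(cfg$seed, {
    if (cfg$kind == "open-spline") {
      pts <- curve_open_spline(h, w, margin, cfg$jitter)
    } else {
      pts <- NULL
      for (attempt in 1:40) {
        cand <- curve_closed_ellipse(h, w, margin, cfg$jitter)
        mask <- matrix(0L, h, w)
        mask[cand] <- 1L
        ok <- sum(mask) == nrow(cand) &&
          all(fg_neighbor_count(mask)[mask == 1L] == 2L) &&
          count_components(mask) == 1L
        if (ok) { pts <- cand; break }
      }
      if (is.null(pts))
        stop("failed to rasterize a valid closed curve; ",
             "try a larger image or less jitter")
    }
  })
  out <- matrix(0L, h, w)
  out[pts] <- 1L
  attr(out, "curve_path") <- pts
  out
}

# recover the ordered pixel chain of a thin curve by walking it
#' @noRd
order_curve <- function(mask) {
  n_fg <- sum(mask == 1L)
  if (n_fg == 0L) stop("mask is empty")
  nb <- fg_neighbor_count(mask)
  h <- nrow(mask)
  eps <- which(mask == 1L & nb == 1L)
  start <- if (length(eps)) eps[1L] else which(mask == 1L)[1L]
  visited <- matrix(FALSE, h, ncol(mask))
  cur <- c((start - 1L) %% h + 1L, (start - 1L) %/% h + 1L)
  path <- matrix(0L, n_fg, 2L)
  for (k in seq_len(n_fg)) {
    path[k, ] <- cur
    visited[cur[1L], cur[2L]] <- TRUE
    nbrs <- fg_neighbors_at(mask, cur[1L], cur[2L])
    nbrs <- nbrs[!visited[nbrs], , drop = FALSE]
    if (nrow(nbrs) == 0L) {
      if (k < n_fg) stop("mask is not a single thin curve")
      break
    }
    cur <- nbrs[1L, ]
  }
  path
}

#' Render a ground-truth curve as a ramp boundary
#'
#' Produces the grayscale boundary a predictor would emit for the curve:
#' \deqn{g(i,j) = \mathrm{round}\big(A\, e^{-d(i,j)^2 / (2\sigma^2)}\big),}
#' where `d` is the Euclidean distance to the nearest curve pixel, zeroed
#' where the rounded value falls below 1.  Gaps (short zeroed runs of the
#' boundary, cut perpendicular to the curve) and additive Gaussian noise
#' are then applied per the configuration, and the result is clipped to
#' \[0, 255\].  All randomness is seeded from `cfg$seed` (with a fixed
#' offset, so curve and rendering draw from independent streams).
#'
#' @param gt Binary matrix holding a thin curve (ideally from
#'   [generate_curve()], whose pixel ordering it reuses).
#' @param cfg A [generator_config()].
#' @return Integer matrix with intensities in \[0, 255\].
#' @export
render_boundary <- function(gt, cfg) {
  assert_binary(gt, "gt")
  stopifnot(inherits(cfg, "generator_config"))
  if (!any(gt == 1L)) stop("gt must contain at least one curve pixel")
  path <- attr(gt, "curve_path")
  if (is.null(path)) path <- order_curve(gt)
  h <- nrow(gt)
  w <- ncol(gt)
  nn <- nearest_to_coords_cpp(h, w, as.integer(path[, 1L] - 1L),
                              as.integer(path[, 2L] - 1L))
  img <- round(cfg$peak * exp(-nn$dist^2 / (2 * cfg$sigma^2)))
  img[img < 1] <- 0
  withr::with_seed(cfg$seed + 131071L, {
    if (cfg$gap_prob > 0) {
      npix <- nrow(path)
      gapped <- integer(0)
      for (s in seq(1L, npix, by = 8L)) {
        seg_end <- min(s + 7L, npix)
        if (runif(1) < cfg$gap_prob) {
          len <- min(cfg$gap_len, seg_end - s + 1L)
          slack <- seg_end - s + 1L - len
          off <- if (slack > 0L) sample.int(slack + 1L, 1L) - 1L else 0L
          gapped <- c(gapped, (s + off):(s + off + len - 1L))
        }
      }
      if (length(gapped)) img[nn$index %in% gapped] <- 0
    }
    if (cfg$noise_sd > 0)
      img <- img + rnorm(h * w, 0, cfg$noise_sd)
  })
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  as_int_matrix(img)
}

#' Generate a synthetic boundary / ground-truth sample
#'
#' @param cfg A [generator_config()].
#' @return A `synthetic_sample` list with elements `boundary` (grayscale
#'   matrix), `gt_edge` (binary matrix) and `config`.
#' @export
generate_sample <- function(cfg) {
  gt <- generate_curve(cfg)
  structure(list(boundary = render_boundary(gt, cfg), gt_edge = gt,
                 config = cfg),
            class = "synthetic_sample")
}

#' Generate a reproducible synthetic data set
#'
#' Sample `k` uses the derived seed `cfg$seed + k - 1`, so data sets are
#' reproducible and extendable.  When `dir` is given, the samples are
#' written as paired PNG directories (`boundaries/NNN.png`,
#' `gt/NNN.png`) plus a `manifest.json` recording the configuration.
#'
#' @param n Number of samples (>= 1).
#' @param cfg A [generator_config()]; per-sample seeds derive from
#'   `cfg$seed`.
#' @param dir Optional output directory.
#' @return List of `synthetic_sample` objects, invisibly when writing to
#'   disk.
#' @export
generate_dataset <- function(n, cfg, dir = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("n must be at least 1")
  n <- as.integer(n)
  samples <- vector("list", n)
  for (k in seq_len(n)) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k - 1L
    samples[[k]] <- generate_sample(cfg_k)
  }
  if (!is.null(dir)) {
    dir.create(file.path(dir, "boundaries"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "gt"), recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(n)) {
      name <- sprintf("%03d.png", k)
      write_gray(samples[[k]]$boundary, file.path(dir, "boundaries", name))
      write_edge_map(samples[[k]]$gt_edge, file.path(dir, "gt", name))
    }
    jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(samples))
  }
  samples
}
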