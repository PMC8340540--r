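#' Maximum spur length for a pruning percentage
#'
#' The pruning parameter `gamma` is a percentage of the image diagonal:
#' \deqn{l = \frac{\gamma}{100}\sqrt{w^2 + h^2},}
#' which makes pruning effectiveness comparable across image sizes.
#'
#' @param gamma Percentage in \[0, 100\].
#' @param w,h Image width and height in pixels.
#' @return Maximum spur length `l` in pixels (real-valued).
#' @export
#' @examples
#' spur_length_limit(100, 3, 4)  # 5
spur_length_limit <- function(gamma, w, h) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 100)
    stop("gamma must be a percentage in [0, 100]")
  if (w < 1 || h < 1) stop("w and h must be at least 1")
  gamma / 100 * sqrt(w^2 + h^2)
}

# foreground 8-neighbours of (i, j) as a 2-column matrix
#' @noRd
fg_neighbors_at <- function(edge, i, j) {
  h <- nrow(edge)
  w <- ncol(edge)
  di <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dj <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  ni <- i + di
  nj <- j + dj
  ok <- ni >= 1L & ni <= h & nj >= 1L & nj <= w
  ni <- ni[ok]
  nj <- nj[ok]
  fg <- edge[cbind(ni, nj)] == 1L
  cbind(ni[fg], nj[fg])
}

# Neighbours of (i, j) in the skeleton graph: foreground 8-neighbours with
# redundant diagonal links suppressed.  A diagonal link is redundant when
# the two pixels share a foreground 4-neighbour -- the connection then
# already runs through that pixel, and counting the shortcut would turn the
# base of a spur that meets a line into a spurious junction.
#' @noRd
skel_neighbors_at <- function(edge, i, j) {
  nb <- fg_neighbors_at(edge, i, j)
  if (nrow(nb) == 0L) return(nb)
  keep <- rep(TRUE, nrow(nb))
  for (k in seq_len(nrow(nb))) {
    di <- nb[k, 1L] - i
    dj <- nb[k, 2L] - j
    if (di != 0L && dj != 0L &&
        (edge[i, j + dj] == 1L || edge[i + di, j] == 1L))
      keep[k] <- FALSE
  }
  nb[keep, , drop = FALSE]
}

#' @noRd
skel_degree_at <- function(edge, i, j) {
  nrow(skel_neighbors_at(edge, i, j))
}

# Walk the skeleton graph from an endpoint until a junction (degree >= 3),
# another endpoint (degree 1), or a revisit.  Returns the branch pixels
# (endpoint first, terminator excluded) and the terminator kind; stops
# early with kind "long" once the branch exceeds max_len pixels.
#' @noRd
walk_branch <- function(edge, i, j, max_len) {
  branch <- matrix(c(i, j), 1L, 2L)
  prev <- c(NA_integer_, NA_integer_)
  cur <- c(i, j)
  repeat {
    nbrs <- skel_neighbors_at(edge, cur[1L], cur[2L])
    if (!is.na(prev[1L])) {
      keep <- !(nbrs[, 1L] == prev[1L] & nbrs[, 2L] == prev[2L])
      nbrs <- nbrs[keep, , drop = FALSE]
    }
    if (nrow(nbrs) == 0L)
      return(list(pixels = branch, kind = "none"))
    nxt <- nbrs[1L, ]
    if (any(branch[, 1L] == nxt[1L] & branch[, 2L] == nxt[2L]))
      return(list(pixels = branch, kind = "none"))
    deg <- skel_degree_at(edge, nxt[1L], nxt[2L])
    if (deg >= 3L)
      return(list(pixels = branch, kind = "junction"))
    if (deg == 1L)
      return(list(pixels = branch, kind = "endpoint"))
    branch <- rbind(branch, nxt)
    if (nrow(branch) > max_len)
      return(list(pixels = branch, kind = "long"))
    prev <- cur
    cur <- nxt
  }
}

#' Prune short spurs from a thin edge
#'
#' A spur is a branch that starts at an endpoint and terminates at a
#' junction.  Every spur whose pixel count -- excluding the junction pixel
#' -- is at most `l` is removed; the junction pixel is kept even if it then
#' stops being a junction.  Removal repeats to a fixed point, since
#' deleting one spur can expose another.  Components that are entire open
#' curves (endpoint to endpoint, no junction) and closed loops are never
#' removed: pruning targets artifacts off a main edge, not the edge
#' itself.
#'
#' Endpoints (degree 1) and junctions (degree 3 or more) are defined on
#' the skeleton graph: foreground 8-neighbours, with a diagonal link
#' suppressed when the two pixels share a foreground 4-neighbour.  Without
#' this, the pixel where a spur meets a line would itself count as a
#' junction through the diagonal shortcuts, and spur lengths would come
#' out one pixel short.  Endpoints are scanned in row-major order, which
#' fixes the outcome when two removable spurs share a junction.
#'
#' @param edge Binary matrix holding a thin edge map.
#' @param l Maximum spur length in pixels (real-valued, see
#'   [spur_length_limit()]).
#' @return Binary matrix with qualifying spurs removed.
#' @export
prune_spurs <- function(edge, l) {
  assert_binary(edge, "edge")
  if (!is.numeric(l) || length(l) != 1L || is.na(l) || l < 0)
    stop("l must be a non-negative length")
  edge <- as_int_matrix(edge)
  if (l < 1) return(edge)  # the shortest possible spur has one pixel
  h <- nrow(edge)
  max_len <- floor(l)
  repeat {
    removed <- FALSE
    fg <- which(edge == 1L)
    fg <- fg[order((fg - 1L) %% h, (fg - 1L) %/% h)]  # row-major scan order
    for (e in fg) {
      ei <- (e - 1L) %% h + 1L
      ej <- (e - 1L) %/% h + 1L
      if (edge[ei, ej] == 0L) next
      if (skel_degree_at(edge, ei, ej) != 1L) next  # not an endpoint
      br <- walk_branch(edge, ei, ej, max_len)
      if (br$kind == "junction" && nrow(br$pixels) <= l) {
        edge[br$pixels] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  edge
}
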