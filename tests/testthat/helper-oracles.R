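# Independent oracles used by the tests.  These deliberately use different
# algorithms from the package implementation: Bellman value iteration instead
# of Dijkstra, igraph instead of BFS labelling, brute-force distance scans.

# shift a matrix by (di, dj), padding with Inf
shift_inf <- function(m, di, dj) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(Inf, h, w)
  src_r <- (1:h) - di
  src_c <- (1:w) - dj
  vr <- which(src_r >= 1 & src_r <= h)
  vc <- which(src_c >= 1 & src_c <= w)
  out[vr, vc] <- m[src_r[vr], src_c[vc]]
  out
}

# gray-weighted distance transform by value iteration to a fixed point:
# t = 0 on background, else f + min over 4-neighbours of t
oracle_gwdt <- function(f) {
  t <- ifelse(f == 0, 0, Inf)
  repeat {
    nmin <- pmin(shift_inf(t, 1, 0), shift_inf(t, -1, 0),
                 shift_inf(t, 0, 1), shift_inf(t, 0, -1))
    tn <- ifelse(f == 0, 0, pmin(t, f + nmin))
    if (identical(tn, t)) break
    t <- tn
  }
  t
}

# literal evaluation of the eight-way neighbourhood number, with modular
# index wrap-around instead of an appended element
oracle_nc <- function(x) {
  xb <- function(k) 1 - x[((k - 1) %% 8) + 1]
  s <- 0
  for (k in c(1, 3, 5, 7)) s <- s + xb(k) - xb(k) * xb(k + 1) * xb(k + 2)
  s
}

# number of 8-connected foreground components, via igraph
oracle_components <- function(b) {
  h <- nrow(b)
  w <- ncol(b)
  idx <- which(b == 1L)
  if (length(idx) == 0L) return(0L)
  el <- NULL
  i <- (idx - 1L) %% h + 1L
  j <- (idx - 1L) %/% h + 1L
  for (d in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
    ni <- i + d[1L]
    nj <- j + d[2L]
    ok <- ni >= 1L & ni <= h & nj >= 1L & nj <= w
    to <- (nj[ok] - 1L) * h + ni[ok]
    from <- idx[ok]
    fg <- b[to] == 1L
    if (any(fg))
      el <- rbind(el, cbind(match(from[fg], idx), match(to[fg], idx)))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  igraph::components(g)$no
}

# mean over foreground of `from` of the Euclidean distance to the nearest
# foreground pixel of `to` (brute force)
oracle_dir_mean_dist <- function(from, to) {
  a <- which(from == 1L, arr.ind = TRUE)
  b <- which(to == 1L, arr.ind = TRUE)
  mean(apply(a, 1L, function(p) {
    min(sqrt((p[1L] - b[, 1L])^2 + (p[2L] - b[, 2L])^2))
  }))
}

oracle_sde <- function(pred, gt) {
  pred <- ensure_nonempty(pred)
  gt <- ensure_nonempty(gt)
  (oracle_dir_mean_dist(pred, gt) + oracle_dir_mean_dist(gt, pred)) / 2
}

# random grayscale image with a guaranteed background fraction
random_gray <- function(h, w, min_zero_frac = 0.1) {
  g <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
  nz <- max(ceiling(min_zero_frac * h * w),
            sample(ceiling(min_zero_frac * h * w):(h * w %/% 2), 1L))
  g[sample(h * w, nz)] <- 0L
  storage.mode(g) <- "integer"
  g
}

# random thin edge map: a rasterized synthetic curve
random_thin_map <- function(seed, kind = "open-spline") {
  generate_curve(generator_config(kind = kind, seed = seed))
}

# a horizontal line skeleton with vertical spurs of known lengths attached
# at well-separated columns; returns the map and the spur bookkeeping
make_spur_skeleton <- function(seed) {
  withr::with_seed(seed, {
    h <- 40L
    w <- 60L
    r <- sample(12:(h - 12L), 1L)
    edge <- matrix(0L, h, w)
    edge[r, 5:(w - 4L)] <- 1L
    # keep the junctions far from the line ends so the end segments can
    # never themselves qualify as prunable branches at the tested limits
    cand <- seq(16L, 46L, by = 5L)
    cols <- sort(sample(cand, sample(2:5, 1L)))
    lens <- sample(1:6, length(cols), replace = TRUE)
    dirs <- sample(c(-1L, 1L), length(cols), replace = TRUE)
    for (k in seq_along(cols)) {
      edge[r + dirs[k] * seq_len(lens[k]), cols[k]] <- 1L
    }
    list(edge = edge, row = r, cols = cols, lens = lens, dirs = dirs,
         line_px = sum(edge[r, ] == 1L))
  })
}

# independent branch scan: returns the lengths of all endpoint-to-junction
# branches of a thin map, on the skeleton graph with redundant diagonal
# links dropped
oracle_branch_lengths <- function(edge, max_len = 1e6) {
  h <- nrow(edge)
  w <- ncol(edge)
  deg_nbrs <- function(i, j) {
    out <- NULL
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ni <- i + di
      nj <- j + dj
      if (ni < 1L || ni > h || nj < 1L || nj > w) next
      if (edge[ni, nj] != 1L) next
      if (di != 0L && dj != 0L &&
          (edge[i, nj] == 1L || edge[ni, j] == 1L)) next
      out <- rbind(out, c(ni, nj))
    }
    if (is.null(out)) matrix(integer(0), 0L, 2L) else out
  }
  lens <- numeric(0)
  fg <- which(edge == 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) {
    i <- fg[k, 1L]
    j <- fg[k, 2L]
    if (nrow(deg_nbrs(i, j)) != 1L) next  # not an endpoint
    path <- matrix(c(i, j), 1L)
    prev <- c(NA, NA)
    cur <- c(i, j)
    repeat {
      nb <- deg_nbrs(cur[1L], cur[2L])
      if (!is.na(prev[1L]))
        nb <- nb[!(nb[, 1L] == prev[1L] & nb[, 2L] == prev[2L]), , drop = FALSE]
      if (nrow(nb) == 0L) break
      nxt <- nb[1L, ]
      d <- nrow(deg_nbrs(nxt[1L], nxt[2L]))
      if (d >= 3L) { lens <- c(lens, nrow(path)); break }
      if (d == 1L) break
      path <- rbind(path, nxt)
      if (nrow(path) > max_len) break
      prev <- cur
      cur <- nxt
    }
  }
  lens
}
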