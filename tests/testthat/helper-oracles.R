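## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: ray casting instead of mgcv, brute-force path
## enumeration instead of igraph, dense eigen instead of power iteration.

## ray-casting point-in-polygon (crossing number)
pip_oracle <- function(poly, pt) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

## all-pairs shortest-path betweenness by explicit path enumeration
## (unweighted hops, directed); adj is a 0/1 matrix, diagonal ignored
bc_bruteforce <- function(adj) {
  n <- nrow(adj)
  a <- adj > 0
  diag(a) <- FALSE
  bc <- numeric(n)
  ## BFS distances
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) nxt <- union(nxt, which(a[v, ]))
      nxt <- nxt[dist[s, nxt] == Inf]
      dist[s, nxt] <- d
      frontier <- nxt
    }
  }
  ## count shortest paths sigma(s, t) and sigma through v by DFS enumeration
  paths_through <- function(s, t) {
    ## enumerate all shortest s->t paths, return (count, per-node transit)
    res <- numeric(n)
    cnt <- 0
    rec <- function(v, trail) {
      if (v == t) {
        cnt <<- cnt + 1
        mid <- setdiff(trail, c(s, t))
        res[mid] <<- res[mid] + 1
        return()
      }
      for (w in which(a[v, ]))
        if (dist[s, w] == dist[s, v] + 1 && dist[w, t] == dist[s, t] -
            dist[s, w])
          rec(w, c(trail, w))
    }
    if (is.finite(dist[s, t]) && s != t) rec(s, s)
    list(count = cnt, through = res)
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(dist[s, t])) next
    pt <- paths_through(s, t)
    if (pt$count > 0) bc <- bc + pt$through / pt$count
  }
  bc
}

## left leading eigenvector by dense decomposition, max-scaled, per the full
## matrix (call on one component at a time)
ec_dense_oracle <- function(w) {
  ev <- eigen(t(w))
  lead <- which.max(abs(Re(ev$values)))
  v <- abs(Re(ev$vectors[, lead]))
  if (max(v) > 0) v / max(v) else v
}

## random small directed weighted graph as a connectivity_matrix-like object
random_cm <- function(n, p = 0.35, loops = TRUE) {
  e <- matrix(0, n, n)
  idx <- which(matrix(stats::runif(n * n), n) < p)
  e[idx] <- stats::runif(length(idx), 0.01, 0.9)
  if (!loops) diag(e) <- 0
  ids <- sprintf("N%02d", seq_len(n))
  dimnames(e) <- list(ids, ids)
  structure(list(e = e, released = stats::setNames(rep(1, n), ids),
                 source_realm = stats::setNames(rep("R1", n), ids),
                 target_realm = stats::setNames(rep("R1", n), ids),
                 level = "all"),
            class = "connectivity_matrix")
}

## hand-built steady velocity field for interpolation tests
manual_field <- function(u, v, times, cell_length = 1000, mask = NULL,
                         bathymetry = NULL, origin = c(0, 0)) {
  nx <- dim(u)[1]; ny <- dim(u)[2]
  if (is.null(mask)) mask <- matrix(FALSE, nx, ny)
  if (is.null(bathymetry)) bathymetry <- matrix(4000, nx, ny)
  structure(list(u = u, v = v, times = times, cell_length = cell_length,
                 mask = mask, bathymetry = bathymetry, origin = origin,
                 kind = "manual"),
            class = "velocity_field")
}

## square polygon helper
square_poly <- function(x0, y0, w) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + w, y0 + w))
}
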