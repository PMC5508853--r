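#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own RNG stream from one
#' master seed, so that stages are individually reproducible and inserting or
#' re-running a stage does not perturb the others.
#'
#' @param master integer master seed.
#' @param k integer stream index (>= 1).
#' @return An integer seed in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(master, k) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master),
            is.numeric(k), length(k) == 1, k >= 1)
  m <- 2147483647  # 2^31 - 1, Mersenne prime used by the Lehmer generator
  s <- (abs(as.numeric(master)) %% m)
  for (i in seq_len(2 + (k %% 7))) s <- (48271 * s + k * 16807) %% m
  as.integer(max(1, s %% (m - 1)))
}

#' Format a count pair as a printed integer percentage
#'
#' Rounds \code{100 * count / total} to the nearest integer, the convention
#' used when reporting shares of protected areas (for example 969 of 3,061
#' prints as 32).
#'
#' @param count,total non-negative counts, \code{total > 0}.
#' @return Integer percentage.
#' @export
format_percent <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  as.integer(round(100 * count / total))
}

## ---- planar polygon helpers -------------------------------------------------
## Polygons are n x 2 matrices of vertex coordinates (metres), implicitly
## closed, counter-clockwise or clockwise.

#' Signed area of a planar polygon (shoelace formula)
#' @param poly n x 2 matrix of vertices.
#' @return Signed area in squared coordinate units.
#' @keywords internal
polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Area of a planar polygon
#' @inheritParams polygon_area_signed
#' @return Non-negative area.
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' Centroid of a planar polygon
#' @inheritParams polygon_area_signed
#' @return Length-2 numeric vector (x, y).
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Clip a polygon against the half-plane y <= y0 (Sutherland-Hodgman)
#'
#' Used to extract the coastal (shallow) portion of a polygon when depth is a
#' monotone function of the cross-shore coordinate.
#'
#' @param poly n x 2 matrix of vertices.
#' @param y0 clip level.
#' @return Matrix of vertices of the clipped polygon (possibly 0 rows).
#' @keywords internal
clip_polygon_below <- function(poly, y0) {
  n <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    p <- poly[i, ]
    q <- poly[if (i == n) 1 else i + 1, ]
    pin <- p[2] <= y0
    qin <- q[2] <= y0
    if (pin) out <- rbind(out, p)
    if (xor(pin, qin)) {
      t <- (y0 - p[2]) / (q[2] - p[2])
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

#' Test whether points fall inside a polygon
#'
#' Thin wrapper around \code{mgcv::in.out}; boundary behaviour follows that
#' routine. Vectorised over points.
#'
#' @param poly n x 2 vertex matrix.
#' @param pts m x 2 matrix of query points.
#' @return Logical vector of length m.
#' @export
points_in_polygon <- function(poly, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  if (nrow(pts) == 0L) return(logical(0))
  ## closed boundary for in.out
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, pts)
}

#' Bilinear interpolation of a node grid at arbitrary points
#'
#' The grid value array is indexed \code{[ix, iy]} with node coordinates
#' \code{x = origin[1] + (ix - 1) * cell_length}. Points outside the grid
#' extent return \code{NA}.
#'
#' @param grid numeric matrix (nx x ny) of node values.
#' @param pts m x 2 point matrix.
#' @param cell_length node spacing (metres).
#' @param origin coordinates of node (1, 1).
#' @return Numeric vector of length m.
#' @export
interp_grid <- function(grid, pts, cell_length, origin = c(0, 0)) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  nx <- nrow(grid); ny <- ncol(grid)
  fx <- (pts[, 1] - origin[1]) / cell_length + 1
  fy <- (pts[, 2] - origin[2]) / cell_length + 1
  ok <- fx >= 1 & fx <= nx & fy >= 1 & fy <= ny & is.finite(fx) & is.finite(fy)
  i0 <- pmin(pmax(floor(fx), 1), nx - 1)
  j0 <- pmin(pmax(floor(fy), 1), ny - 1)
  tx <- fx - i0; ty <- fy - j0
  out <- rep(NA_real_, nrow(pts))
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; txk <- tx[ok]; tyk <- ty[ok]
    g <- function(i, j) grid[cbind(i, j)]
    out[ok] <- g(i0k, j0k)     * (1 - txk) * (1 - tyk) +
               g(i0k + 1, j0k) * txk       * (1 - tyk) +
               g(i0k, j0k + 1) * (1 - txk) * tyk +
               g(i0k + 1, j0k + 1) * txk   * tyk
  }
  out
}

#' Min-max index a vector to the 0-100 scale
#'
#' Subtracts the minimum, divides by the max-min deviation and multiplies by
#' 100, the indexing shared by the larval-density index and the three
#' fisheries-dependency indicators. When all values are equal the deviation is
#' zero; all values then map to 0 with a warning.
#'
#' @param x numeric vector (non-negative for the pipeline's uses).
#' @return Numeric vector in \code{[0, 100]}.
#' @export
minmax_index <- function(x) {
  stopifnot(length(x) >= 1, all(is.finite(x)))
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("min-max indexing is degenerate (all values equal); returning 0")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / diff(rng) * 100
}
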