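#' Specification of a synthetic surface-current field
#'
#' Describes one of four analytic flow families used to emulate a gridded
#' surface-velocity reanalysis at desk scale. \code{uniform} is a constant
#' drift of \code{magnitude} m/s towards \code{direction_deg} (0 = east,
#' counter-clockwise); \code{solid_body} rotates rigidly about the domain
#' centre at \code{angular_rate} rad/s; \code{double_gyre} is the classical
#' two-cell recirculation (divergence-free stream function); and
#' \code{gyre_plus_noise} adds node-level Gaussian noise of standard deviation
#' \code{noise_amplitude} to the double gyre, redrawn per stored snapshot.
#'
#' @param kind one of "uniform", "solid_body", "double_gyre",
#'   "gyre_plus_noise".
#' @param magnitude flow speed scale, m/s (>= 0).
#' @param direction_deg drift direction for the uniform kind, degrees.
#' @param angular_rate rotation rate for the solid-body kind, rad/s.
#' @param noise_amplitude noise standard deviation, m/s (gyre_plus_noise).
#' @param time_span length of the stored record, days.
#' @param snapshot_interval spacing of stored snapshots, days (> 0).
#' @param seed integer RNG seed for the noisy kind.
#' @return A \code{flow_spec} object.
#' @export
flow_spec <- function(kind = c("uniform", "solid_body", "double_gyre",
                               "gyre_plus_noise"),
                      magnitude = 0.1, direction_deg = 0,
                      angular_rate = 1e-6, noise_amplitude = 0,
                      time_span = 60, snapshot_interval = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(magnitude) || magnitude < 0)
    stop("magnitude must be >= 0")
  if (snapshot_interval <= 0) stop("snapshot_interval must be > 0")
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0")
  structure(list(kind = kind, magnitude = magnitude,
                 direction_deg = direction_deg, angular_rate = angular_rate,
                 noise_amplitude = noise_amplitude, time_span = time_span,
                 snapshot_interval = snapshot_interval,
                 seed = as.integer(seed)),
            class = "flow_spec")
}

#' Generate a gridded velocity field from an analytic flow specification
#'
#' Evaluates the chosen analytic flow on a regular node grid at each stored
#' time. Analytic kinds reproduce their closed form at the nodes exactly.
#' Velocities on land nodes (per \code{mask}) are set to zero; a bathymetry
#' grid (positive depth, metres) travels with the field for the 100 m
#' recruitment rule downstream.
#'
#' @param spec a \code{\link{flow_spec}}.
#' @param grid_shape integer pair (nx, ny) of node counts, each >= 2.
#' @param cell_length node spacing l in metres (> 0); also the length scale
#'   entering the diffusion coefficient.
#' @param mask optional logical nx x ny matrix, TRUE = land.
#' @param bathymetry optional numeric nx x ny matrix of positive depths (m).
#' @param origin coordinates of node (1, 1); default (0, 0).
#' @return A \code{velocity_field}: list with arrays \code{u}, \code{v}
#'   (nx x ny x nt, m/s), \code{times} (days), \code{cell_length},
#'   \code{mask}, \code{bathymetry}, \code{origin}.
#' @export
make_velocity_field <- function(spec, grid_shape, cell_length,
                                mask = NULL, bathymetry = NULL,
                                origin = c(0, 0)) {
  if (!inherits(spec, "flow_spec")) stop("configuration error: not a flow_spec")
  nx <- as.integer(grid_shape[1]); ny <- as.integer(grid_shape[2])
  if (nx < 2 || ny < 2) stop("grid_shape must be at least 2 x 2")
  if (cell_length <= 0) stop("cell_length must be > 0")
  times <- seq(0, spec$time_span, by = spec$snapshot_interval)
  nt <- length(times)
  x <- origin[1] + (seq_len(nx) - 1) * cell_length
  y <- origin[2] + (seq_len(ny) - 1) * cell_length
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  Lx <- diff(range(x)); Ly <- diff(range(y))
  base_uv <- switch(spec$kind,
    uniform = {
      th <- spec$direction_deg * pi / 180
      list(u = matrix(spec$magnitude * cos(th), nx, ny),
           v = matrix(spec$magnitude * sin(th), nx, ny))
    },
    solid_body = {
      cx <- mean(range(x)); cy <- mean(range(y))
      list(u = -spec$angular_rate * (Y - cy),
           v =  spec$angular_rate * (X - cx))
    },
    double_gyre = ,
    gyre_plus_noise = {
      ## psi = A sin(2 pi x / Lx) sin(pi y / Ly); u = -dpsi/dy, v = dpsi/dx
      A <- spec$magnitude * Ly / pi
      list(u = -A * (pi / Ly) * sin(2 * pi * (X - x[1]) / Lx) *
               cos(pi * (Y - y[1]) / Ly),
           v =  A * (2 * pi / Lx) * cos(2 * pi * (X - x[1]) / Lx) *
               sin(pi * (Y - y[1]) / Ly))
    })
  u <- array(base_uv$u, dim = c(nx, ny, nt))
  v <- array(base_uv$v, dim = c(nx, ny, nt))
  if (spec$kind == "gyre_plus_noise" && spec$noise_amplitude > 0) {
    withr::with_seed(spec$seed, {
      for (k in seq_len(nt)) {
        u[, , k] <- u[, , k] + matrix(stats::rnorm(nx * ny, 0,
                                                   spec$noise_amplitude), nx, ny)
        v[, , k] <- v[, , k] + matrix(stats::rnorm(nx * ny, 0,
                                                   spec$noise_amplitude), nx, ny)
      }
    })
  }
  if (is.null(mask)) mask <- matrix(FALSE, nx, ny)
  if (is.null(bathymetry)) bathymetry <- matrix(4000, nx, ny)
  stopifnot(identical(dim(mask), c(nx, ny)),
            identical(dim(bathymetry), c(nx, ny)))
  if (any(mask)) {
    land <- which(mask)
    for (k in seq_len(nt)) {
      uk <- u[, , k]; vk <- v[, , k]
      uk[land] <- 0; vk[land] <- 0
      u[, , k] <- uk; v[, , k] <- vk
    }
  }
  structure(list(u = u, v = v, times = times, cell_length = cell_length,
                 mask = mask, bathymetry = bathymetry, origin = origin,
                 kind = spec$kind),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %s, %d x %d nodes, %d times, l = %g m\n",
              x$kind, dim(x$u)[1], dim(x$u)[2], length(x$times),
              x$cell_length))
  invisible(x)
}
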