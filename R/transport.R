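#' Interpolate gridded velocities at particle positions
#'
#' Bilinear interpolation in space and linear interpolation in time between
#' the two bracketing stored snapshots. Land nodes carry zero velocity by
#' construction, so a query surrounded by land returns (0, 0). Positions or
#' times outside the stored domain return \code{NA} rows (an out-of-domain
#' signal, not an error: the stepping loop treats them as exits).
#'
#' @param field a \code{velocity_field}.
#' @param position n x 2 matrix of positions (metres) or a length-2 vector.
#' @param time scalar time in days since the start of the record.
#' @return n x 2 matrix of (u, v) in m/s; \code{NA} where out of domain.
#' @export
interpolate_velocity <- function(field, position, time) {
  if (!is.matrix(position)) position <- matrix(position, ncol = 2)
  n <- nrow(position)
  nx <- dim(field$u)[1]; ny <- dim(field$u)[2]
  times <- field$times; nt <- length(times)
  out <- matrix(NA_real_, n, 2)
  if (time < times[1] - 1e-9 || time > times[nt] + 1e-9) return(out)
  if (nt == 1L) { k <- 1L; wt <- 0 } else {
    k <- min(max(findInterval(time, times), 1L), nt - 1L)
    wt <- (time - times[k]) / (times[k + 1] - times[k])
  }
  l <- field$cell_length; o <- field$origin
  fx <- (position[, 1] - o[1]) / l + 1
  fy <- (position[, 2] - o[2]) / l + 1
  ok <- fx >= 1 & fx <= nx & fy >= 1 & fy <= ny &
    is.finite(fx) & is.finite(fy)
  if (!any(ok)) return(out)
  i0 <- pmin(pmax(floor(fx[ok]), 1), nx - 1)
  j0 <- pmin(pmax(floor(fy[ok]), 1), ny - 1)
  tx <- fx[ok] - i0; ty <- fy[ok] - j0
  w00 <- (1 - tx) * (1 - ty); w10 <- tx * (1 - ty)
  w01 <- (1 - tx) * ty;       w11 <- tx * ty
  ## direct linear indices into the (nx, ny, nt) arrays: no slice copies
  base <- (k - 1L) * nx * ny
  i00 <- base + (j0 - 1) * nx + i0
  blend <- function(a) {
    val <- w00 * a[i00] + w10 * a[i00 + 1] + w01 * a[i00 + nx] +
      w11 * a[i00 + nx + 1]
    if (wt > 0) {
      i2 <- i00 + nx * ny
      v2 <- w00 * a[i2] + w10 * a[i2 + 1] + w01 * a[i2 + nx] +
        w11 * a[i2 + nx + 1]
      val <- (1 - wt) * val + wt * v2
    }
    val
  }
  out[ok, 1] <- blend(field$u)
  out[ok, 2] <- blend(field$v)
  out
}

#' One classical fourth-order Runge-Kutta advection step
#'
#' Four velocity evaluations (start, two midpoints, end of step) combined
#' with the classical 1-2-2-1 weights. A particle whose substage leaves the
#' stored domain is flagged exited and its position frozen at the step start.
#'
#' @param field a \code{velocity_field}.
#' @param position n x 2 matrix of positions (metres).
#' @param time step start time, days.
#' @param dt step length, seconds (may be negative for reverse stepping).
#' @return List with \code{position} (n x 2) and \code{exited} (logical n).
#' @export
rk4_step <- function(field, position, time, dt) {
  if (!is.matrix(position)) position <- matrix(position, ncol = 2)
  if (dt == 0) stop("dt must be nonzero")
  hd <- dt / 86400  # days
  k1 <- interpolate_velocity(field, position, time)
  k2 <- interpolate_velocity(field, position + 0.5 * dt * k1, time + hd / 2)
  k3 <- interpolate_velocity(field, position + 0.5 * dt * k2, time + hd / 2)
  k4 <- interpolate_velocity(field, position + dt * k3, time + hd)
  newpos <- position + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  exited <- !stats::complete.cases(cbind(k1, k2, k3, k4, newpos))
  newpos[exited, ] <- position[exited, ]
  list(position = newpos, exited = exited)
}

#' Horizontal diffusion coefficient from the turbulent dissipation rate
#'
#' \code{K = epsilon^(1/3) * l^(4/3)}, with \code{epsilon} the constant
#' turbulent dissipation rate (m^2 s^-3) and \code{l} the grid cell length
#' (m). Accounts for sub-grid-scale hydrodynamics not resolved by the stored
#' currents.
#'
#' @param epsilon turbulent dissipation rate, m^2 s^-3 (>= 0).
#' @param l grid cell length, metres (> 0).
#' @return Diffusion coefficient K in m^2/s.
#' @export
diffusion_coefficient <- function(epsilon, l) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (l <= 0) stop("l must be > 0")
  epsilon^(1 / 3) * l^(4 / 3)
}

#' Random-walk diffusion displacements
#'
#' Independent Gaussian increments per axis with mean zero and variance
#' \code{2 * K * dt}, the diffusion-limit form of the random walk.
#'
#' @param K diffusion coefficient, m^2/s (>= 0).
#' @param dt step length, seconds (> 0).
#' @param n number of particles.
#' @return n x 2 matrix of displacements (metres).
#' @export
diffusion_step <- function(K, dt, n = 1L) {
  stopifnot(K >= 0, dt > 0)
  if (K == 0) return(matrix(0, n, 2))
  matrix(stats::rnorm(2L * n, 0, sqrt(2 * K * dt)), n, 2)
}

#' Build a larval release schedule
#'
#' Releases \code{larvae_per_event} particles from every site at each release
#' event. With four events per year the event dates are the season midpoints
#' (2 February, 5 May, 6 August, 11 November; days 33, 125, 218, 315 of a
#' 365-day year); other event counts space events evenly through the year.
#'
#' @param sites either an integer site count (for release arithmetic) or a
#'   data frame with columns \code{site_id}, \code{x}, \code{y}.
#' @param larvae_per_event particles released per site per event (>= 1).
#' @param events_per_year release events per year (>= 1).
#' @param years number of years (>= 1).
#' @param pld pelagic larval duration, days of drift before settlement
#'   competence (default 30; 20 is the behaviour-proxy sensitivity value).
#' @param dt iteration time step, seconds (default 3,600).
#' @return A \code{release_schedule}: list with \code{sites},
#'   \code{larvae_per_event}, \code{events} (event_id, year, doy, day),
#'   \code{pld}, \code{dt} and \code{total} released.
#' @export
build_release_schedule <- function(sites, larvae_per_event,
                                   events_per_year = 4, years = 6,
                                   pld = 30, dt = 3600) {
  stopifnot(larvae_per_event >= 1, events_per_year >= 1, years >= 1,
            pld > 0, dt > 0)
  if (is.numeric(sites) && length(sites) == 1) {
    n_sites <- as.integer(sites); site_df <- NULL
  } else {
    stopifnot(is.data.frame(sites),
              all(c("site_id", "x", "y") %in% names(sites)))
    n_sites <- nrow(sites); site_df <- sites
  }
  doy <- if (events_per_year == 4) c(33, 125, 218, 315) else
    round(365 * (seq_len(events_per_year) - 0.5) / events_per_year)
  ev <- expand.grid(doy = doy, year = seq_len(years))
  events <- data.frame(event_id = seq_len(nrow(ev)), year = ev$year,
                       doy = ev$doy, day = (ev$year - 1) * 365 + ev$doy)
  total <- as.numeric(n_sites) * larvae_per_event * events_per_year * years
  structure(list(sites = site_df, n_sites = n_sites,
                 larvae_per_event = as.integer(larvae_per_event),
                 events = events, pld = pld, dt = dt, total = total),
            class = "release_schedule")
}

## TRUE where the nearest grid node is land; NA outside the domain
on_land <- function(field, position) {
  nx <- dim(field$u)[1]; ny <- dim(field$u)[2]
  l <- field$cell_length; o <- field$origin
  fx <- (position[, 1] - o[1]) / l + 1
  fy <- (position[, 2] - o[2]) / l + 1
  out <- rep(NA, nrow(position))
  ok <- fx >= 1 & fx <= nx & fy >= 1 & fy <= ny &
    is.finite(fx) & is.finite(fy)
  out[ok] <- field$mask[cbind(pmin(pmax(round(fx[ok]), 1), nx),
                              pmin(pmax(round(fy[ok]), 1), ny))]
  out
}

## move landing particles back along the segment to the last ocean point
truncate_at_coast <- function(field, from, to, iters = 8L) {
  land <- on_land(field, to)
  bad <- which(!is.na(land) & land)
  if (length(bad) == 0) return(to)
  lo <- from[bad, , drop = FALSE]  # known ocean
  hi <- to[bad, , drop = FALSE]    # known land
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    ml <- on_land(field, mid)
    ml[is.na(ml)] <- TRUE
    lo[!ml, ] <- mid[!ml, ]
    hi[ml, ] <- mid[ml, ]
  }
  to[bad, ] <- lo
  to
}

#' Run the Lagrangian dispersal simulation
#'
#' Advances every released particle through \code{pld * 86400 / dt} steps of
#' RK4 advection plus random-walk diffusion and records its endpoint.
#' Advection sub-steps that would beach a particle are truncated at the
#' coast; diffusion displacements onto land are redrawn (up to 20 times, then
#' dropped for that step). Particles leaving the open boundary are frozen at
#' their last valid position and flagged exited; they count as released but
#' settle nowhere. Deterministic given the seed (one derived RNG stream per
#' release event).
#'
#' @param field a \code{velocity_field} whose record covers every release
#'   date plus the PLD.
#' @param schedule a \code{\link{build_release_schedule}} result carrying
#'   site positions.
#' @param epsilon turbulent dissipation rate, m^2 s^-3 (default 1e-9).
#' @param seed integer master seed.
#' @return An endpoint data frame (\code{source_id}, \code{event_id},
#'   \code{particle_id}, \code{x}, \code{y}, \code{exited}) with one row per
#'   released particle; attribute \code{K} records the diffusion coefficient.
#' @export
run_dispersal <- function(field, schedule, epsilon = 1e-9, seed = 1L) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(schedule, "release_schedule"))
  if (is.null(schedule$sites))
    stop("schedule carries no site positions")
  tspan <- range(field$times)
  need <- range(schedule$events$day) + c(0, schedule$pld)
  if (need[1] < tspan[1] || need[2] > tspan[2])
    stop("configuration error: field record [", tspan[1], ", ", tspan[2],
         "] days does not cover releases plus PLD [", need[1], ", ",
         need[2], "]")
  vmax <- max(abs(field$u), abs(field$v))
  if (vmax * schedule$dt > field$cell_length)
    warning("dt lets particles cross more than one cell per step at peak speed")
  K <- diffusion_coefficient(epsilon, field$cell_length)
  sd1 <- sqrt(2 * K * schedule$dt)
  nsteps <- round(schedule$pld * 86400 / schedule$dt)
  ns <- schedule$n_sites; lpe <- schedule$larvae_per_event
  n <- ns * lpe
  src <- rep(schedule$sites$site_id, each = lpe)
  pid <- rep(seq_len(lpe), times = ns)
  start <- cbind(rep(schedule$sites$x, each = lpe),
                 rep(schedule$sites$y, each = lpe))
  res <- vector("list", nrow(schedule$events))
  for (e in seq_len(nrow(schedule$events))) {
    day0 <- schedule$events$day[e]
    pos <- start
    exited <- rep(FALSE, n)
    withr::with_seed(derive_seed(seed, 1000L + e), {
      for (s in seq_len(nsteps)) {
        act <- which(!exited)
        if (length(act) == 0) break
        t <- day0 + (s - 1) * schedule$dt / 86400
        stp <- rk4_step(field, pos[act, , drop = FALSE], t, schedule$dt)
        newp <- truncate_at_coast(field, pos[act, , drop = FALSE],
                                  stp$position)
        if (K > 0) {
          alive <- !stp$exited
          na <- sum(alive)
          if (na > 0) {
            cur <- newp[alive, , drop = FALSE]
            disp <- matrix(stats::rnorm(2L * na, 0, sd1), na, 2)
            cand <- cur + disp
            landed <- on_land(field, cand)
            bad <- which(!is.na(landed) & landed)
            tries <- 0L
            while (length(bad) > 0 && tries < 20L) {
              disp2 <- matrix(stats::rnorm(2L * length(bad), 0, sd1),
                              length(bad), 2)
              cand[bad, ] <- cur[bad, , drop = FALSE] + disp2
              landed_b <- on_land(field, cand[bad, , drop = FALSE])
              bad <- bad[!is.na(landed_b) & landed_b]
              tries <- tries + 1L
            }
            if (length(bad) > 0) cand[bad, ] <- cur[bad, , drop = FALSE]
            out <- is.na(on_land(field, cand))
            cand[out, ] <- cur[out, , drop = FALSE]
            ex2 <- stp$exited
            ex2[alive][out] <- TRUE
            newp[alive, ] <- cand
            stp$exited <- ex2
          }
        }
        pos[act, ] <- newp
        exited[act] <- stp$exited
      }
    })
    res[[e]] <- data.frame(source_id = src,
                           event_id = schedule$events$event_id[e],
                           particle_id = pid, x = pos[, 1], y = pos[, 2],
                           exited = exited, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "K") <- K
  attr(out, "released_per_source") <- lpe * nrow(schedule$events)
  out
}
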