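#' Specification of a synthetic coastal domain
#'
#' Describes a planar coastal domain: the coastline runs along y = 0, depth
#' increases linearly offshore at \code{shelf_slope} (m of depth per m of
#' distance), exclusive economic zones (EEZs) are contiguous alongshore bands,
#' and marine protected areas (MPAs) are simple star-shaped polygons placed on
#' the shelf, each inside exactly one EEZ. EEZ bands are grouped into
#' \code{n_realms} contiguous biogeographic realms; connectivity is only ever
#' evaluated within a realm.
#'
#' @param extent numeric (xmin, xmax, ymin, ymax) in metres.
#' @param n_mpa number of MPAs (>= 1).
#' @param mr_fraction fraction of MPAs that qualify as no-take marine
#'   reserves, in \code{[0, 1]}.
#' @param n_eez number of EEZ bands (>= 1).
#' @param n_realms number of contiguous realm blocks (<= n_eez).
#' @param shelf_slope depth gain per metre offshore; the 100 m isobath sits at
#'   y = 100 / shelf_slope.
#' @param mpa_radius range (min, max) of MPA polygon base radii, metres.
#' @param coastal_band y-range (metres) in which MPA centres are placed.
#' @param seed integer RNG seed.
#' @return A \code{domain_spec} object.
#' @export
domain_spec <- function(extent = c(0, 1800e3, 0, 300e3),
                        n_mpa = 20, mr_fraction = 0.25, n_eez = 6,
                        n_realms = 2, shelf_slope = 100 / 150e3,
                        mpa_radius = c(3e3, 8e3),
                        coastal_band = c(10e3, 60e3), seed = 1L) {
  if (n_mpa < 1) stop("n_mpa must be >= 1")
  if (n_eez < 1) stop("n_eez must be >= 1")
  if (mr_fraction < 0 || mr_fraction > 1)
    stop("mr_fraction must be in [0, 1]")
  if (n_realms < 1 || n_realms > n_eez)
    stop("n_realms must be between 1 and n_eez")
  if (shelf_slope <= 0) stop("shelf_slope must be > 0")
  structure(list(extent = extent, n_mpa = as.integer(n_mpa),
                 mr_fraction = mr_fraction, n_eez = as.integer(n_eez),
                 n_realms = as.integer(n_realms), shelf_slope = shelf_slope,
                 mpa_radius = mpa_radius, coastal_band = coastal_band,
                 seed = as.integer(seed)),
            class = "domain_spec")
}

## one simple star-shaped polygon around a centre (vertices in angular order,
## hence non-self-intersecting)
make_mpa_polygon <- function(cx, cy, r, n_vert = 8) {
  th <- sort(2 * pi * (seq_len(n_vert) - 1) / n_vert +
             stats::runif(n_vert, -0.15, 0.15))
  rr <- r * (1 + stats::runif(n_vert, -0.3, 0.3))
  cbind(cx + rr * cos(th), cy + rr * sin(th))
}

#' Generate a synthetic coastal domain with MPA and EEZ polygons
#'
#' Places \code{n_mpa} non-overlapping simple polygons on the shelf
#' (round-robin across EEZ bands so every band is populated when
#' \code{n_mpa >= n_eez}), builds EEZ band polygons, assigns realms, IUCN
#' categories and no-take flags such that exactly
#' \code{round(mr_fraction * n_mpa)} MPAs satisfy the reserve rule, and
#' attaches standardized environmental/socio-economic covariates used by the
#' biomass model. Release sites are polygon centroids, stored in the
#' attribute table. Identical spec (including seed) gives identical output.
#'
#' @param spec a \code{\link{domain_spec}}.
#' @return A \code{reserve_domain}: list with \code{mpa_polys} (named list of
#'   vertex matrices), \code{eez_polys}, \code{mpa} (attribute data frame:
#'   id, eez_id, realm, iucn_cat, fully_no_take, partly_no_take, centroid,
#'   areas, covariates), \code{eez} (band table), \code{y100} (offshore
#'   position of the 100 m isobath), \code{shelf_slope}, \code{extent}.
#' @export
make_domain <- function(spec) {
  if (!inherits(spec, "domain_spec")) stop("not a domain_spec")
  ex <- spec$extent
  band_w <- (ex[2] - ex[1]) / spec$n_eez
  rmax <- spec$mpa_radius[2] * 1.3
  if (band_w < 2 * (rmax + 1e3))
    stop("generation error: extent too small to place MPAs in ",
         spec$n_eez, " bands (band width ", round(band_w), " m)")
  ## contiguous realm blocks along the coast
  realm_of_band <- paste0("R", sort(rep(seq_len(spec$n_realms),
                                        length.out = spec$n_eez)))
  y100 <- 100 / spec$shelf_slope

  withr::with_seed(spec$seed, {
    ## EEZ band polygons spanning the full extent
    eez_polys <- lapply(seq_len(spec$n_eez), function(b) {
      x0 <- ex[1] + (b - 1) * band_w; x1 <- ex[1] + b * band_w
      cbind(c(x0, x1, x1, x0), c(ex[3], ex[3], ex[4], ex[4]))
    })
    names(eez_polys) <- sprintf("EEZ%02d", seq_len(spec$n_eez))

    ## MPA placement: round-robin across bands, rejection on overlap
    band <- rep(seq_len(spec$n_eez), length.out = spec$n_mpa)
    centers <- matrix(NA_real_, spec$n_mpa, 2)
    radii <- numeric(spec$n_mpa)
    for (i in seq_len(spec$n_mpa)) {
      placed <- FALSE
      for (try in seq_len(400)) {
        r <- stats::runif(1, spec$mpa_radius[1], spec$mpa_radius[2])
        x0 <- ex[1] + (band[i] - 1) * band_w + 1.3 * r + 500
        x1 <- ex[1] + band[i] * band_w - 1.3 * r - 500
        cx <- stats::runif(1, x0, x1)
        cy <- stats::runif(1, max(spec$coastal_band[1], 1.3 * r + 500),
                           spec$coastal_band[2])
        sep <- TRUE
        if (i > 1) {
          d <- sqrt((centers[seq_len(i - 1), 1] - cx)^2 +
                    (centers[seq_len(i - 1), 2] - cy)^2)
          sep <- all(d > 1.3 * (radii[seq_len(i - 1)] + r) + 1e3,
                     na.rm = TRUE)
        }
        if (sep) { centers[i, ] <- c(cx, cy); radii[i] <- r; placed <- TRUE; break }
      }
      if (!placed)
        stop("generation error: could not place MPA ", i,
             " without overlap; enlarge the extent or reduce n_mpa")
    }
    mpa_polys <- lapply(seq_len(spec$n_mpa), function(i)
      make_mpa_polygon(centers[i, 1], centers[i, 2], radii[i]))
    names(mpa_polys) <- sprintf("MPA%03d", seq_len(spec$n_mpa))

    ## reserve rule attributes: exactly n_mr qualify
    n_mr <- round(spec$mr_fraction * spec$n_mpa)
    mr_idx <- if (n_mr > 0) sample(spec$n_mpa, n_mr) else integer(0)
    fully <- partly <- rep(FALSE, spec$n_mpa)
    iucn <- sample(c("II", "IV", "V", "VI"), spec$n_mpa, replace = TRUE)
    mech <- rep_len(c("fully", "partly", "Ia", "Ib"), n_mr)
    for (k in seq_along(mr_idx)) {
      i <- mr_idx[k]
      switch(mech[k],
             fully = { fully[i] <- TRUE },
             partly = { partly[i] <- TRUE },
             Ia = { iucn[i] <- "Ia" },
             Ib = { iucn[i] <- "Ib" })
    }
    covs <- make_covariates(spec$n_mpa,
                            seed = derive_seed(spec$seed, 11))
  })

  cents <- t(vapply(mpa_polys, polygon_centroid, numeric(2)))
  area_km2 <- vapply(mpa_polys, polygon_area, numeric(1)) / 1e6
  coastal_km2 <- vapply(mpa_polys, function(p) {
    cp <- clip_polygon_below(p, y100)
    if (nrow(cp) < 3) 0 else polygon_area(cp) / 1e6
  }, numeric(1))
  mpa <- data.frame(id = names(mpa_polys),
                    eez_id = names(eez_polys)[band],
                    realm = realm_of_band[band],
                    iucn_cat = iucn,
                    fully_no_take = fully, partly_no_take = partly,
                    centroid_x = cents[, 1], centroid_y = cents[, 2],
                    area_km2 = area_km2, coastal_area_km2 = coastal_km2,
                    stringsAsFactors = FALSE)
  mpa <- cbind(mpa, covs)
  eez_coastal <- vapply(eez_polys, function(p)
    polygon_area(clip_polygon_below(p, y100)) / 1e6, numeric(1))
  eez <- data.frame(eez_id = names(eez_polys), realm = realm_of_band,
                    xmin = ex[1] + (seq_len(spec$n_eez) - 1) * band_w,
                    xmax = ex[1] + seq_len(spec$n_eez) * band_w,
                    coastal_area_km2 = eez_coastal,
                    stringsAsFactors = FALSE)
  structure(list(spec = spec, mpa_polys = mpa_polys, eez_polys = eez_polys,
                 mpa = mpa, eez = eez, y100 = y100,
                 shelf_slope = spec$shelf_slope, extent = ex),
            class = "reserve_domain")
}

#' Bathymetry and land mask of a domain on a node grid
#'
#' Depth increases linearly offshore (positive metres); the y = 0 node row
#' has zero depth and is flagged as land (the coastline).
#'
#' @param domain a \code{reserve_domain}.
#' @param grid_shape integer pair (nx, ny).
#' @param cell_length node spacing, metres.
#' @return List with \code{bathymetry} (nx x ny, m) and \code{mask}
#'   (logical, TRUE = land).
#' @export
domain_bathymetry <- function(domain, grid_shape, cell_length) {
  nx <- grid_shape[1]; ny <- grid_shape[2]
  y <- domain$extent[3] + (seq_len(ny) - 1) * cell_length
  depth <- matrix(rep(pmax(0, y * domain$shelf_slope), each = nx), nx, ny)
  mask <- depth <= 0
  list(bathymetry = depth, mask = mask)
}

#' Coastal surface areas of domain polygons
#'
#' The coastal portion of a polygon is its intersection with the shelf strip
#' shallower than 100 m (depth is monotone offshore, so the clip is against
#' the 100 m isobath). For EEZs the area open to fishing removes the coastal
#' area of the marine reserves they contain (reserves are erased from the
#' fishing zone).
#'
#' @param domain a \code{reserve_domain}.
#' @param mr_flags logical vector over MPAs marking marine reserves (default:
#'   \code{\link{classify_reserves}} on the attribute table).
#' @return List with data frames \code{mpa} (id, coastal_area_km2) and
#'   \code{eez} (eez_id, coastal_area_km2, fishing_area_km2).
#' @export
coastal_mask <- function(domain, mr_flags = classify_reserves(domain$mpa)) {
  mpa <- domain$mpa[, c("id", "eez_id", "coastal_area_km2")]
  mr_area_by_eez <- tapply(mpa$coastal_area_km2[mr_flags],
                           mpa$eez_id[mr_flags], sum)
  eez <- domain$eez[, c("eez_id", "coastal_area_km2")]
  sub <- mr_area_by_eez[eez$eez_id]
  sub[is.na(sub)] <- 0
  eez$fishing_area_km2 <- pmax(eez$coastal_area_km2 - sub, 0)
  list(mpa = mpa[, c("id", "coastal_area_km2")], eez = eez)
}
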