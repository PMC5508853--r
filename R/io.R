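#' Write a velocity field as plain-text CSV with a JSON header
#'
#' Long-format CSV with one row per (time, y, x) node carrying u, v, mask
#' and depth, plus a JSON sidecar recording the grid layout and cell length.
#'
#' @param field a \code{velocity_field}.
#' @param path CSV path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_velocity_field <- function(field, path) {
  nx <- dim(field$u)[1]; ny <- dim(field$u)[2]; nt <- length(field$times)
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny),
                      it = seq_len(nt))
  df <- data.frame(time = field$times[grid$it],
                   x = field$origin[1] + (grid$ix - 1) * field$cell_length,
                   y = field$origin[2] + (grid$iy - 1) * field$cell_length,
                   u = as.vector(field$u), v = as.vector(field$v),
                   mask = as.vector(field$mask)[(grid$iy - 1) * nx + grid$ix],
                   depth = as.vector(field$bathymetry)[(grid$iy - 1) * nx +
                                                       grid$ix])
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(nx = nx, ny = ny, nt = nt,
                            cell_length = field$cell_length,
                            origin = field$origin, times = field$times),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a velocity field written by \code{\link{write_velocity_field}}
#' @param path CSV path.
#' @return A \code{velocity_field}.
#' @export
read_velocity_field <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  nx <- hdr$nx; ny <- hdr$ny; nt <- hdr$nt
  structure(list(u = array(df$u, c(nx, ny, nt)),
                 v = array(df$v, c(nx, ny, nt)),
                 times = hdr$times, cell_length = hdr$cell_length,
                 mask = matrix(df$mask[seq_len(nx * ny)], nx, ny),
                 bathymetry = matrix(df$depth[seq_len(nx * ny)], nx, ny),
                 origin = hdr$origin, kind = "file"),
            class = "velocity_field")
}

#' Write domain polygons as a GeoJSON FeatureCollection
#'
#' MPA and EEZ polygons with properties id, kind, realm, iucn_cat and the
#' no-take flags.
#'
#' @param domain a \code{reserve_domain}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_domain_geojson <- function(domain, path) {
  poly_coords <- function(p) {
    ring <- rbind(p, p[1, , drop = FALSE])
    list(lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ])))
  }
  feat <- function(id, kind, realm, iucn, fnt, pnt, poly) {
    list(type = "Feature",
         properties = list(id = id, kind = kind, realm = realm,
                           iucn_cat = iucn, fully_no_take = fnt,
                           partly_no_take = pnt),
         geometry = list(type = "Polygon", coordinates = poly_coords(poly)))
  }
  feats <- c(
    lapply(seq_along(domain$mpa_polys), function(i) {
      a <- domain$mpa[i, ]
      feat(a$id, "MPA", a$realm, a$iucn_cat, a$fully_no_take,
           a$partly_no_take, domain$mpa_polys[[i]])
    }),
    lapply(seq_along(domain$eez_polys), function(i) {
      a <- domain$eez[i, ]
      feat(a$eez_id, "EEZ", a$realm, NA, NA, NA, domain$eez_polys[[i]])
    }))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a connectivity matrix as sparse triplets plus a JSON sidecar
#'
#' @param cm a \code{connectivity_matrix}.
#' @param path CSV path (source_id, target_id, e); released counts, realm
#'   maps and the threshold level go to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  idx <- which(cm$e > 0, arr.ind = TRUE)
  df <- data.frame(source_id = colnames(cm$e)[idx[, 2]],
                   target_id = rownames(cm$e)[idx[, 1]],
                   e = cm$e[idx])
  df <- df[order(df$source_id, df$target_id), ]
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(released = as.list(cm$released),
                            source_realm = as.list(cm$source_realm),
                            target_realm = as.list(cm$target_realm),
                            level = cm$level),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
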