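#' Classify MPAs as no-take marine reserves
#'
#' An MPA is a marine reserve (MR) if it is fully no-take, includes a no-take
#' zone, or is classified as a strict nature reserve or wilderness area (IUCN
#' category Ia or Ib).
#'
#' @param attributes data frame with columns \code{iucn_cat},
#'   \code{fully_no_take}, \code{partly_no_take}.
#' @return Logical vector of MR flags.
#' @export
classify_reserves <- function(attributes) {
  need <- c("iucn_cat", "fully_no_take", "partly_no_take")
  if (!all(need %in% names(attributes)))
    stop("attribute table must carry ", paste(need, collapse = ", "))
  attributes$fully_no_take | attributes$partly_no_take |
    attributes$iucn_cat %in% c("Ia", "Ib")
}

#' Assign larval endpoints to target polygons under the coastal rule
#'
#' An endpoint counts for a target polygon iff it lies inside the polygon and
#' the (bilinearly interpolated) local depth does not exceed
#' \code{depth_limit} metres — only the coastal portion of a target is
#' suitable for recruitment. Exited particles and endpoints matching no
#' target are unsettled. Endpoints falling inside any \code{exclude} polygon
#' (for example reserves erased from a fishing zone) are unsettled too.
#' Overlapping targets raise an ambiguity error unless
#' \code{priority = "smallest_area"}, which assigns the smallest-area match.
#'
#' @param endpoints endpoint data frame from \code{\link{run_dispersal}}.
#' @param targets named list of polygon vertex matrices.
#' @param bathymetry nx x ny positive-depth grid on the field's node layout.
#' @param cell_length node spacing of the bathymetry grid, metres.
#' @param origin grid origin (node 1,1 coordinates).
#' @param depth_limit recruitment depth limit, metres (default 100).
#' @param exclude optional list of polygons whose interior is closed to
#'   settlement.
#' @param priority "error" (default) or "smallest_area" for overlap
#'   resolution.
#' @return List with \code{counts} (data frame source_id, target_id, n),
#'   \code{assigned} (per-endpoint target id or NA) and \code{unsettled}
#'   count per source.
#' @export
assign_endpoints <- function(endpoints, targets, bathymetry, cell_length,
                             origin = c(0, 0), depth_limit = 100,
                             exclude = NULL,
                             priority = c("error", "smallest_area")) {
  priority <- match.arg(priority)
  pts <- cbind(endpoints$x, endpoints$y)
  m <- nrow(pts)
  eligible <- !endpoints$exited
  depth <- interp_grid(bathymetry, pts, cell_length, origin)
  eligible <- eligible & !is.na(depth) & depth <= depth_limit
  if (!is.null(exclude)) {
    for (p in exclude) {
      idx <- which(eligible)
      if (length(idx) == 0) break
      bb <- apply(p, 2, range)
      cand <- idx[pts[idx, 1] >= bb[1, 1] & pts[idx, 1] <= bb[2, 1] &
                  pts[idx, 2] >= bb[1, 2] & pts[idx, 2] <= bb[2, 2]]
      if (length(cand))
        eligible[cand][points_in_polygon(p, pts[cand, , drop = FALSE])] <- FALSE
    }
  }
  hits <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    p <- targets[[ti]]
    bb <- apply(p, 2, range)
    idx <- which(eligible & pts[, 1] >= bb[1, 1] & pts[, 1] <= bb[2, 1] &
                 pts[, 2] >= bb[1, 2] & pts[, 2] <= bb[2, 2])
    if (length(idx))
      hits[[ti]] <- idx[points_in_polygon(p, pts[idx, , drop = FALSE])]
    else hits[[ti]] <- integer(0)
  }
  assigned <- rep(NA_character_, m)
  n_hits <- integer(m)
  for (ti in seq_along(targets)) n_hits[hits[[ti]]] <- n_hits[hits[[ti]]] + 1L
  if (any(n_hits > 1L)) {
    if (priority == "error")
      stop("ambiguity error: ", sum(n_hits > 1L),
           " endpoints fall in overlapping targets; set priority = ",
           "\"smallest_area\" to resolve")
    areas <- vapply(targets, polygon_area, numeric(1))
    ord <- order(areas, decreasing = TRUE)  # smallest assigned last, wins
    for (ti in ord) assigned[hits[[ti]]] <- names(targets)[ti]
  } else {
    for (ti in seq_along(targets)) assigned[hits[[ti]]] <- names(targets)[ti]
  }
  settled <- !is.na(assigned)
  if (any(settled)) {
    counts <- as.data.frame(table(source_id = endpoints$source_id[settled],
                                  target_id = assigned[settled]),
                            stringsAsFactors = FALSE)
    names(counts)[3] <- "n"
    counts <- counts[counts$n > 0, ]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(source_id = character(0), target_id = character(0),
                         n = integer(0))
  }
  unsettled <- tapply(!settled, endpoints$source_id, sum)
  list(counts = counts, assigned = assigned,
       unsettled = data.frame(source_id = names(unsettled),
                              n = as.integer(unsettled)))
}

#' Build a connection-probability matrix
#'
#' Entry \code{e[i, j]} is the fraction of larvae released at source j whose
#' endpoint settled in target i. Source-target pairs lying in different
#' biogeographic realms are forced to zero: connectivity is only evaluated
#' within a realm.
#'
#' @param counts settlement counts (source_id, target_id, n).
#' @param released_per_source named vector of released larvae per source
#'   (> 0 for every source).
#' @param source_realms,target_realms named character vectors of realm
#'   labels.
#' @return A \code{connectivity_matrix}: list with matrix \code{e}
#'   (targets x sources), \code{released}, realm labels and a threshold
#'   \code{level} marker.
#' @export
connection_matrix <- function(counts, released_per_source,
                              source_realms, target_realms) {
  stopifnot(all(released_per_source > 0))
  src <- names(released_per_source)
  tgt <- names(target_realms)
  e <- matrix(0, length(tgt), length(src), dimnames = list(tgt, src))
  if (nrow(counts) > 0) {
    unknown <- setdiff(counts$source_id, src)
    if (length(unknown)) stop("counts reference unknown sources: ",
                              paste(unknown, collapse = ", "))
    if (any(counts$n > released_per_source[counts$source_id]))
      stop("integrity error: settled count exceeds released count")
    keep <- counts$target_id %in% tgt
    cc <- counts[keep, ]
    e[cbind(match(cc$target_id, tgt), match(cc$source_id, src))] <-
      cc$n / released_per_source[cc$source_id]
  }
  cross <- outer(target_realms[tgt], source_realms[src], FUN = "!=")
  e[cross] <- 0
  structure(list(e = e, released = released_per_source,
                 source_realm = source_realms[src],
                 target_realm = target_realms[tgt], level = "all"),
            class = "connectivity_matrix")
}

#' Threshold a connectivity matrix at tertiles of its positive entries
#'
#' Tertile boundaries are the 1/3 and 2/3 empirical quantiles (linear
#' interpolation) of the positive connection probabilities; zeros are
#' excluded from the distribution. \code{medium_strong} keeps the second and
#' third tertiles, \code{strong} the third only; boundary-valued entries are
#' kept. \code{all} returns the matrix unchanged.
#'
#' @param matrix a \code{connectivity_matrix}.
#' @param level one of "all", "medium_strong", "strong".
#' @return A thresholded \code{connectivity_matrix} with the level marker
#'   updated.
#' @export
threshold_by_tertile <- function(matrix, level = c("all", "medium_strong",
                                                   "strong")) {
  level <- match.arg(level)
  if (level == "all") { matrix$level <- "all"; return(matrix) }
  pos <- matrix$e[matrix$e > 0]
  if (length(pos) == 0) { matrix$level <- level; return(matrix) }
  q <- stats::quantile(pos, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  cut <- if (level == "medium_strong") q[1] else q[2]
  matrix$e[matrix$e > 0 & matrix$e < cut] <- 0
  matrix$level <- level
  matrix
}

#' Within-EEZ retention of larvae released in marine reserves
#'
#' For each reserve, the fraction of its settled larvae that recruited in the
#' EEZ where the reserve sits (retained) versus elsewhere (exported).
#' Reserves with no settled larvae are excluded from the summary and listed.
#'
#' @param matrix an MR-to-EEZ \code{connectivity_matrix}.
#' @param home_map named character vector mapping every MR source to its home
#'   EEZ.
#' @return List with \code{per_source} (source_id, settled, retained
#'   fraction), \code{median}, \code{mean} (retention over sources with
#'   settlers) and \code{excluded} source ids.
#' @export
retention_fractions <- function(matrix, home_map) {
  src <- colnames(matrix$e)
  if (!all(src %in% names(home_map)))
    stop("unmapped MR source(s): ",
         paste(setdiff(src, names(home_map)), collapse = ", "))
  home <- home_map[src]
  if (!all(home %in% rownames(matrix$e)))
    stop("home EEZ missing from matrix targets for: ",
         paste(src[!home %in% rownames(matrix$e)], collapse = ", "))
  settled <- colSums(matrix$e)
  retained <- matrix$e[cbind(match(home, rownames(matrix$e)),
                             seq_along(src))]
  frac <- ifelse(settled > 0, retained / settled, NA_real_)
  ok <- settled > 0
  list(per_source = data.frame(source_id = src, settled = settled,
                               retention = frac, row.names = NULL),
       median = stats::median(frac[ok]), mean = mean(frac[ok]),
       excluded = src[!ok])
}
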