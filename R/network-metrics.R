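#' Build the directed MPA graph from a connectivity matrix
#'
#' Nodes are MPAs, directed edges are positive connection probabilities
#' (self-loops kept: a reserve can seed itself).
#'
#' @param cm a square MPA-to-MPA \code{connectivity_matrix} (identical row
#'   and column ids).
#' @param mr_flags named logical vector of reserve flags per node.
#' @return An \code{mpa_network}: list with the igraph \code{graph}, the
#'   weight matrix \code{w} (source -> target orientation) and \code{mr}.
#' @export
build_mpa_network <- function(cm, mr_flags = NULL) {
  stopifnot(inherits(cm, "connectivity_matrix"),
            identical(rownames(cm$e), colnames(cm$e)))
  ## cm$e is targets x sources; adjacency wants [from, to]
  w <- t(cm$e)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  if (is.null(mr_flags)) mr_flags <- stats::setNames(rep(FALSE, nrow(w)),
                                                     rownames(w))
  structure(list(graph = g, w = w, mr = mr_flags[rownames(w)]),
            class = "mpa_network")
}

#' Identify networks (connected components) and isolation flags
#'
#' A "network" is a weakly connected component of the directed MPA graph.
#' Self-loops are ignored when flagging isolation: \code{not_seeded} marks
#' nodes with no incoming connection from any other MPA, \code{isolated}
#' marks nodes with neither incoming nor outgoing connections to others.
#'
#' @param net an \code{mpa_network}.
#' @param mode "weak" (default) or "strong" component connectivity.
#' @return List with \code{membership} (component id per node), \code{sizes}
#'   table, \code{n_networks}, and logical \code{not_seeded} and
#'   \code{isolated} vectors.
#' @export
find_networks <- function(net, mode = c("weak", "strong")) {
  mode <- match.arg(mode)
  comp <- igraph::components(net$graph, mode = mode)
  w0 <- net$w; diag(w0) <- 0
  in_other <- colSums(w0 > 0)
  out_other <- rowSums(w0 > 0)
  list(membership = comp$membership, sizes = comp$csize,
       n_networks = comp$no,
       not_seeded = stats::setNames(in_other == 0, rownames(w0)),
       isolated = stats::setNames(in_other == 0 & out_other == 0,
                                  rownames(w0)))
}

#' Self-loop-inclusive in- and out-degrees
#'
#' The in-degree counts the MPAs acting as donors for the focal MPA
#' (including itself when local retention makes a self-loop); the out-degree
#' counts its receivers.
#'
#' @param net an \code{mpa_network}.
#' @return Data frame (node, in_degree, out_degree).
#' @export
node_degrees <- function(net) {
  data.frame(node = rownames(net$w),
             in_degree = as.integer(igraph::degree(net$graph, mode = "in",
                                                   loops = TRUE)),
             out_degree = as.integer(igraph::degree(net$graph, mode = "out",
                                                    loops = TRUE)),
             row.names = NULL)
}

#' Normalized directed betweenness centrality per network
#'
#' The number of shortest paths between ordered node pairs that pass through
#' the focal node, computed per connected component and normalized by
#' \code{(n - 1)(n - 2)} (0 for components with fewer than 3 nodes). By
#' default paths are unweighted hops; \code{weighted = TRUE} uses
#' \code{-log(e)} edge lengths so that strong connections make short paths.
#'
#' @param net an \code{mpa_network}.
#' @param weighted logical; default FALSE.
#' @return Named numeric vector of normalized BC values.
#' @export
betweenness_centrality <- function(net, weighted = FALSE) {
  g <- net$graph
  wts <- if (weighted) pmax(-log(igraph::E(g)$weight), 1e-12) else NA
  comp <- igraph::components(g, mode = "weak")
  bc <- rep(0, igraph::vcount(g))
  names(bc) <- rownames(net$w)
  for (cid in seq_len(comp$no)) {
    vids <- which(comp$membership == cid)
    n <- length(vids)
    if (n < 3) next
    sg <- igraph::induced_subgraph(g, vids)
    swts <- if (weighted) pmax(-log(igraph::E(sg)$weight), 1e-12) else NA
    raw <- igraph::betweenness(sg, directed = TRUE, weights = swts,
                               normalized = FALSE)
    bc[vids] <- raw / ((n - 1) * (n - 2))
  }
  bc
}

#' Left eigenvector centrality per network, scaled to [0, 1]
#'
#' The left Perron eigenvector of the within-component connection-probability
#' matrix, proportional to the reduction in metapopulation size that the loss
#' of each node would cause. Computed by power iteration on the transposed
#' weight matrix with a dense eigen-decomposition fallback on
#' non-convergence; each component's vector is scaled so its maximum is 1
#' (nodes of zero-weight components score 0).
#'
#' @param net an \code{mpa_network}.
#' @param tol convergence tolerance of the power iteration.
#' @param max_iter iteration cap before falling back to \code{eigen}.
#' @return Named numeric vector of EC values in \code{[0, 1]}.
#' @export
eigenvector_centrality_left <- function(net, tol = 1e-12, max_iter = 1000L) {
  w <- net$w
  comp <- igraph::components(net$graph, mode = "weak")
  ec <- rep(0, nrow(w))
  names(ec) <- rownames(w)
  for (cid in seq_len(comp$no)) {
    vids <- which(comp$membership == cid)
    ec[vids] <- left_eigencentrality(w[vids, vids, drop = FALSE], tol,
                                     max_iter)
  }
  ec
}

#' Max-scaled left leading eigenvector of a non-negative weight matrix
#'
#' The workhorse behind \code{\link{eigenvector_centrality_left}}: power
#' iteration on the transposed matrix with a dense \code{eigen} fallback
#' when the iteration fails to settle (for example on periodic structures),
#' scaled so the largest entry is 1. An all-zero matrix scores all nodes 0.
#'
#' @param w square non-negative weight matrix, \code{w[from, to]}.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return Numeric vector in \code{[0, 1]}.
#' @export
left_eigencentrality <- function(w, tol = 1e-12, max_iter = 1000L) {
  if (any(w < 0)) stop("weights must be non-negative")
  if (all(w == 0)) return(rep(0, nrow(w)))
  a <- t(w)  # left eigenvector of w = right eigenvector of t(w)
  v <- rep(1 / sqrt(nrow(a)), nrow(a))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    v2 <- as.numeric(a %*% v)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) break
    v2 <- v2 / nv
    if (max(abs(v2 - v)) < tol) { v <- v2; converged <- TRUE; break }
    v <- v2
  }
  if (!converged) {
    ev <- eigen(a)
    lead <- which.max(abs(Re(ev$values)))
    v <- abs(Re(ev$vectors[, lead]))
  }
  v <- abs(v)
  if (max(v) > 0) v <- v / max(v)
  v
}

#' Compute all node metrics of an MPA network
#'
#' @param net an \code{mpa_network}.
#' @param weighted_bc use \code{-log(e)} path weights for BC (default FALSE).
#' @return Data frame: node, component, in/out degree, BC, EC, is_mr,
#'   not_seeded, isolated.
#' @export
node_metrics <- function(net, weighted_bc = FALSE) {
  nets <- find_networks(net)
  deg <- node_degrees(net)
  data.frame(node = deg$node, component = as.integer(nets$membership),
             in_degree = deg$in_degree, out_degree = deg$out_degree,
             bc = as.numeric(betweenness_centrality(net, weighted_bc)),
             ec = as.numeric(eigenvector_centrality_left(net)),
             is_mr = as.logical(net$mr),
             not_seeded = as.logical(nets$not_seeded),
             isolated = as.logical(nets$isolated), row.names = NULL)
}

#' Per-network Spearman correlations between centrality metrics
#'
#' Rank correlations between BC and EC, total degree and BC, and total degree
#' and EC within every network of at least \code{min_size} nodes; networks
#' where a metric is constant yield an undefined correlation and are excluded
#' from that pair's summary. The summary reports the fraction of usable
#' networks with rho below \code{threshold} (weakly or un-correlated
#' metrics).
#'
#' @param metrics a \code{\link{node_metrics}} data frame.
#' @param min_size smallest network size considered (default 3).
#' @param threshold correlation criterion (default 0.7).
#' @return List with \code{per_network} (component, n, rho_bc_ec,
#'   rho_deg_bc, rho_deg_ec) and \code{fraction_below} per pair.
#' @export
metric_correlations <- function(metrics, min_size = 3, threshold = 0.7) {
  metrics$degree <- metrics$in_degree + metrics$out_degree
  comps <- split(metrics, metrics$component)
  comps <- comps[vapply(comps, nrow, 1L) >= min_size]
  sp <- function(x, y) {
    if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }
  per <- do.call(rbind, lapply(comps, function(d) {
    data.frame(component = d$component[1], n = nrow(d),
               rho_bc_ec = sp(d$bc, d$ec),
               rho_deg_bc = sp(d$degree, d$bc),
               rho_deg_ec = sp(d$degree, d$ec))
  }))
  if (is.null(per))
    per <- data.frame(component = integer(0), n = integer(0),
                      rho_bc_ec = numeric(0), rho_deg_bc = numeric(0),
                      rho_deg_ec = numeric(0))
  frac <- vapply(c("rho_bc_ec", "rho_deg_bc", "rho_deg_ec"), function(cl) {
    v <- per[[cl]]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v < threshold)
  }, numeric(1))
  list(per_network = per, fraction_below = frac)
}

#' Compare a centrality metric between reserves and other MPAs
#'
#' Wilcoxon rank-sum (Mann-Whitney) test of the metric between MR and non-MR
#' nodes; mid-ranks for ties, exact enumeration for small untied samples and
#' the continuity-corrected normal approximation otherwise.
#'
#' @param values numeric metric per node.
#' @param is_mr logical reserve flag per node.
#' @param side "two_sided" or "one_sided" (alternative: MR values lower).
#' @return List with \code{W} and \code{p}.
#' @export
compare_protection <- function(values, is_mr, side = c("two_sided",
                                                       "one_sided")) {
  side <- match.arg(side)
  x <- values[is_mr]; y <- values[!is_mr]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty")
  alt <- if (side == "two_sided") "two.sided" else "less"
  ties <- anyDuplicated(c(x, y)) > 0
  ex <- !ties && min(length(x), length(y)) <= 20
  ht <- stats::wilcox.test(x, y, alternative = alt, exact = ex,
                           correct = TRUE)
  list(W = unname(ht$statistic), p = ht$p.value)
}
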