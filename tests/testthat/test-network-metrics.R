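cm_from_edges <- function(n, edges, ids = sprintf("N%d", seq_len(n))) {
  e <- matrix(0, n, n, dimnames = list(ids, ids))
  for (ed in edges) e[ed[2], ed[1]] <- if (length(ed) > 2) ed[3] else 0.1
  structure(list(e = e, released = setNames(rep(1, n), ids),
                 source_realm = setNames(rep("R1", n), ids),
                 target_realm = setNames(rep("R1", n), ids),
                 level = "all"), class = "connectivity_matrix")
}

test_that("degrees count donors and receivers, self-loops included", {
  ## A -> B only
  net <- build_mpa_network(cm_from_edges(2, list(c(1, 2))))
  d <- node_degrees(net)
  expect_equal(d$out_degree, c(1L, 0L))
  expect_equal(d$in_degree, c(0L, 1L))
  ## self-loop contributes to both degrees
  net2 <- build_mpa_network(cm_from_edges(1, list(c(1, 1))))
  d2 <- node_degrees(net2)
  expect_equal(d2$in_degree, 1L)
  expect_equal(d2$out_degree, 1L)
  ## complete digraph on 3 nodes without self-loops: all degrees 2
  ed <- list(c(1,2), c(2,1), c(1,3), c(3,1), c(2,3), c(3,2))
  d3 <- node_degrees(build_mpa_network(cm_from_edges(3, ed)))
  expect_true(all(d3$in_degree == 2L) && all(d3$out_degree == 2L))
})

test_that("networks are weak components with self-loop-aware isolation
           flags", {
  ## two disjoint directed 3-chains
  net <- build_mpa_network(cm_from_edges(6, list(c(1,2), c(2,3), c(4,5),
                                                 c(5,6))))
  nw <- find_networks(net)
  expect_equal(nw$n_networks, 2)
  expect_equal(sort(nw$sizes), c(3, 3))
  ## empty edge set: all singletons, all isolated
  net0 <- build_mpa_network(cm_from_edges(5, list()))
  nw0 <- find_networks(net0)
  expect_equal(nw0$n_networks, 5)
  expect_true(all(nw0$isolated))
  ## a node with only a self-loop: singleton component, counted by degree
  ## (in = out = 1) yet isolated from all other MPAs
  net1 <- build_mpa_network(cm_from_edges(2, list(c(1, 1))))
  nw1 <- find_networks(net1)
  expect_equal(nw1$n_networks, 2)
  expect_true(nw1$isolated[1])
  expect_true(nw1$not_seeded[1])
  expect_equal(node_degrees(net1)$in_degree[1], 1L)
})

test_that("betweenness matches hand counts and brute-force enumeration", {
  ## directed path A -> B -> C: B transits the single (A, C) pair;
  ## normalized by (n-1)(n-2) = 2
  net <- build_mpa_network(cm_from_edges(3, list(c(1,2), c(2,3))))
  bc <- betweenness_centrality(net)
  expect_equal(unname(bc), c(0, 0.5, 0))
  ## 4-node star routed through the hub: 6 ordered leaf pairs transit it
  ed <- c(lapply(2:4, function(i) c(i, 1)), lapply(2:4, function(i) c(1, i)))
  net2 <- build_mpa_network(cm_from_edges(4, ed))
  bc2 <- betweenness_centrality(net2)
  expect_equal(unname(bc2[1]) * (3 * 2), 6)
  expect_equal(unname(bc2[-1]), rep(0, 3))

  ## random graphs: normalized BC agrees with brute-force shortest-path
  ## enumeration, and the BC sum equals the transited pair count
  withr::with_seed(7, {
    for (i in 1:15) {
      n <- sample(3:8, 1)
      cm <- random_cm(n, p = 0.3)
      net <- build_mpa_network(cm)
      comp <- find_networks(net)
      bc <- betweenness_centrality(net)
      oracle <- numeric(n)
      for (cid in unique(comp$membership)) {
        vs <- which(comp$membership == cid)
        if (length(vs) < 3) next
        oracle[vs] <- bc_bruteforce(cm$e[vs, vs, drop = FALSE] |> t()) /
          ((length(vs) - 1) * (length(vs) - 2))
      }
      expect_equal(unname(bc), oracle, tolerance = 1e-10)
    }
  })
})

test_that("eigenvector centrality is the max-scaled left Perron vector", {
  ## diagonal weights as one subgraph: the leading eigenpair concentrates
  ## on the heavier self-loop
  expect_equal(left_eigencentrality(diag(c(1, 0.5))), c(1, 0))
  ## symmetric 2-cycle: both nodes maximal
  nets <- build_mpa_network(cm_from_edges(2, list(c(1, 2, 1), c(2, 1, 1))))
  expect_equal(unname(eigenvector_centrality_left(nets)), c(1, 1))
  ## random 6-node components match the dense eigen-decomposition oracle
  withr::with_seed(11, {
    for (i in 1:10) {
      w <- matrix(runif(36), 6) * (matrix(runif(36), 6) < 0.6)
      ids <- sprintf("N%d", 1:6)
      dimnames(w) <- list(ids, ids)
      cm <- structure(list(e = t(w), released = setNames(rep(1, 6), ids),
                           source_realm = setNames(rep("R1", 6), ids),
                           target_realm = setNames(rep("R1", 6), ids),
                           level = "all"), class = "connectivity_matrix")
      net <- build_mpa_network(cm)
      comp <- igraph::components(net$graph, mode = "weak")
      ec <- eigenvector_centrality_left(net)
      for (cid in seq_len(comp$no)) {
        vs <- which(comp$membership == cid)
        if (length(vs) < 2) next
        expect_equal(unname(ec[vs]), ec_dense_oracle(w[vs, vs]),
                     tolerance = 1e-8)
      }
      ## invariant to uniform weight scaling
      cm2 <- cm; cm2$e <- cm$e * 7.5
      expect_equal(eigenvector_centrality_left(build_mpa_network(cm2)), ec,
                   tolerance = 1e-9)
    }
  })
})

test_that("removing the top-EC node shrinks the metapopulation growth rate
           most", {
  ## EC ranks nodes by the leading-eigenvalue (metapopulation size) loss
  ## their extinction would cause
  withr::with_seed(23, {
    for (i in 1:10) {
      w <- matrix(runif(36, 0.05, 1), 6)  # strictly positive: Perron regime
      lam <- function(m) max(Re(eigen(m, only.values = TRUE)$values))
      ids <- sprintf("N%d", 1:6); dimnames(w) <- list(ids, ids)
      cm <- structure(list(e = t(w), released = setNames(rep(1, 6), ids),
                           source_realm = setNames(rep("R1", 6), ids),
                           target_realm = setNames(rep("R1", 6), ids),
                           level = "all"), class = "connectivity_matrix")
      ec <- eigenvector_centrality_left(build_mpa_network(cm))
      hi <- which.max(ec); lo <- which.min(ec)
      drop_hi <- lam(w[-hi, -hi])
      drop_lo <- lam(w[-lo, -lo])
      expect_lte(drop_hi, drop_lo + 1e-12)
    }
  })
})

test_that("metric correlations report rank agreement per network", {
  m <- data.frame(node = sprintf("N%d", 1:5), component = 1L,
                  in_degree = 1:5, out_degree = 1:5,
                  bc = c(0.1, 0.2, 0.3, 0.4, 0.5),
                  ec = c(0.5, 0.4, 0.3, 0.2, 0.1),
                  is_mr = FALSE, not_seeded = FALSE, isolated = FALSE)
  mc <- metric_correlations(m)
  expect_equal(mc$per_network$rho_bc_ec, -1)   # exactly reversed ranking
  expect_equal(mc$per_network$rho_deg_bc, 1)   # identical ranking
  expect_equal(unname(mc$fraction_below["rho_bc_ec"]), 1)
  ## mixed fixture agrees with the rank-formula oracle
  withr::with_seed(5, {
    bc <- runif(8); ec <- runif(8)
  })
  m2 <- m[0, ]
  m2 <- data.frame(node = sprintf("N%d", 1:8), component = 2L,
                   in_degree = 0L, out_degree = 0L, bc = bc, ec = ec,
                   is_mr = FALSE, not_seeded = FALSE, isolated = FALSE)
  mc2 <- metric_correlations(m2)
  d <- rank(bc) - rank(ec)
  rho_oracle <- 1 - 6 * sum(d^2) / (8 * (8^2 - 1))
  expect_equal(mc2$per_network$rho_bc_ec, rho_oracle)
  ## constant metric: correlation undefined, network excluded
  m3 <- m2; m3$ec <- 0.3
  expect_true(is.na(metric_correlations(m3)$per_network$rho_bc_ec))
})

test_that("protection comparison is the Wilcoxon rank-sum on MR status", {
  ## identical groups: two-sided p near 1
  v <- rep(1:10, 2)
  flags <- rep(c(TRUE, FALSE), each = 10)
  p1 <- compare_protection(v, flags, "two_sided")
  expect_gt(p1$p, 0.9)
  ## complete separation at n = 10 + 10: W at an extreme of 100 or 0
  v2 <- c(1:10, 101:110)
  p2 <- compare_protection(v2, rep(c(TRUE, FALSE), each = 10), "two_sided")
  expect_true(p2$W %in% c(0, 100))
  ## fixture against a direct rank-sum computation
  withr::with_seed(8, { x <- rnorm(12); y <- rnorm(15, 0.5) })
  res <- compare_protection(c(x, y), rep(c(TRUE, FALSE), c(12, 15)),
                            "two_sided")
  r <- rank(c(x, y))
  W_oracle <- sum(r[1:12]) - 12 * 13 / 2
  expect_equal(res$W, W_oracle)
  expect_error(compare_protection(1:5, rep(TRUE, 5)), "non-empty")
})
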