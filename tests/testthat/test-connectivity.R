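test_that("reserve classification implements the no-take / IUCN rule", {
  tab <- data.frame(
    iucn_cat = c("Ia", "IV", "IV", "Ib", "II"),
    fully_no_take = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    partly_no_take = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(classify_reserves(tab), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_error(classify_reserves(data.frame(iucn_cat = "Ia")), "carry")
})

test_that("endpoint assignment enforces polygon membership and the 100 m
           coastal rule", {
  ## flat 50 m shelf except a deep pocket
  bathy <- matrix(50, 21, 21)
  bathy[11:21, 11:21] <- 150
  targets <- list(T1 = square_poly(2e3, 2e3, 4e3),
                  T2 = square_poly(12e3, 12e3, 4e3))  # deep pocket
  ep <- data.frame(source_id = "S",
                   event_id = 1L, particle_id = 1:4,
                   x = c(3e3, 13e3, 19e3, 3e3),
                   y = c(3e3, 13e3, 1e3, 3e3),
                   exited = c(FALSE, FALSE, FALSE, TRUE))
  asg <- assign_endpoints(ep, targets, bathy, 1000)
  ## inside + shallow assigned; inside + deep unsettled; outside unsettled;
  ## exited unsettled
  expect_identical(asg$assigned, c("T1", NA, NA, NA))
  expect_equal(asg$counts$n[asg$counts$target_id == "T1"], 1L)

  ## excluded polygons (reserves erased from fishing zones) block settlement
  asg2 <- assign_endpoints(ep, targets, bathy, 1000,
                           exclude = list(square_poly(2500, 2500, 1000)))
  expect_identical(asg2$assigned, c(NA_character_, NA, NA, NA))

  ## overlapping targets: error by default, smallest-area priority on demand
  ov <- list(BIG = square_poly(0, 0, 10e3), SMALL = square_poly(2e3, 2e3, 2e3))
  ep1 <- ep[1, ]
  expect_error(assign_endpoints(ep1, ov, bathy, 1000), "ambiguity")
  asg3 <- assign_endpoints(ep1, ov, bathy, 1000, priority = "smallest_area")
  expect_identical(asg3$assigned, "SMALL")
})

test_that("point-in-polygon assignment agrees with a ray-casting oracle", {
  withr::with_seed(42, {
    d <- make_domain(domain_spec(seed = 8))
    pts <- cbind(runif(1000, 0, 1800e3), runif(1000, 0, 300e3))
  })
  for (poly in d$mpa_polys[1:6]) {
    mine <- points_in_polygon(poly, pts)
    oracle <- apply(pts, 1, function(p) pip_oracle(poly, p))
    expect_identical(mine, oracle)
  }
})

test_that("connection matrices are released-count fractions, zeroed across
           realms", {
  counts <- data.frame(source_id = c("A", "A", "B"),
                       target_id = c("T1", "T2", "T1"),
                       n = c(500L, 100L, 400L))
  released <- c(A = 10000, B = 8000)
  srealm <- c(A = "R1", B = "R2")
  trealm <- c(T1 = "R1", T2 = "R2")
  cm <- connection_matrix(counts, released, srealm, trealm)
  expect_equal(cm$e["T1", "A"], 0.05)
  expect_equal(cm$e["T2", "A"], 0)   # cross-realm forced to zero
  expect_equal(cm$e["T1", "B"], 0)   # cross-realm forced to zero
  expect_true(all(cm$e >= 0 & cm$e <= 1))
  expect_true(all(colSums(cm$e) <= 1))

  ## zero settlers give the zero matrix
  cm0 <- connection_matrix(counts[0, ], released, srealm, trealm)
  expect_true(all(cm0$e == 0))

  ## settled > released is an integrity error
  bad <- data.frame(source_id = "A", target_id = "T1", n = 20000L)
  expect_error(connection_matrix(bad, released, srealm, trealm),
               "integrity")
})

test_that("tertile thresholding keeps the right entries and is monotone", {
  mk <- function(vals) {
    n <- length(vals)
    e <- matrix(0, n, n, dimnames = list(sprintf("T%d", 1:n),
                                         sprintf("S%d", 1:n)))
    diag(e) <- vals
    structure(list(e = e, released = setNames(rep(1, n), colnames(e)),
                   source_realm = setNames(rep("R1", n), colnames(e)),
                   target_realm = setNames(rep("R1", n), rownames(e)),
                   level = "all"), class = "connectivity_matrix")
  }
  cm <- mk(1:9 / 10)
  expect_identical(threshold_by_tertile(cm, "all")$e, cm$e)
  ## quantile oracle: strong keeps entries >= the 2/3 empirical quantile
  q <- quantile(1:9 / 10, 2/3, type = 7, names = FALSE)
  st <- threshold_by_tertile(cm, "strong")
  expect_equal(sum(st$e > 0), sum(1:9 / 10 >= q))
  expect_equal(sum(st$e > 0), 3)
  ms <- threshold_by_tertile(cm, "medium_strong")
  expect_equal(sum(ms$e > 0), 6)

  ## all-equal positives survive every level
  ce <- mk(rep(0.2, 5))
  expect_equal(sum(threshold_by_tertile(ce, "strong")$e > 0), 5)

  ## monotone on random matrices: thresholding never increases entries and
  ## supports nest strong within medium_strong within all
  withr::with_seed(3, {
    for (i in 1:10) {
      cmr <- random_cm(7)
      m1 <- threshold_by_tertile(cmr, "medium_strong")
      m2 <- threshold_by_tertile(cmr, "strong")
      expect_true(all(m1$e <= cmr$e) && all(m2$e <= m1$e))
      expect_true(all(m2$e[m2$e > 0] == cmr$e[m2$e > 0]))
    }
  })
})

test_that("retention fractions split home-EEZ and exported settlement", {
  e <- matrix(c(0.6, 0.4, 0, 0,
                0, 0, 0.3, 0,
                0, 0, 0, 0), nrow = 4,
              dimnames = list(c("E1", "E2", "E3", "E4"),
                              c("M1", "M2", "M3")))
  cm <- structure(list(e = e, released = c(M1 = 1, M2 = 1, M3 = 1),
                       source_realm = c(M1 = "R1", M2 = "R1", M3 = "R1"),
                       target_realm = setNames(rep("R1", 4), rownames(e)),
                       level = "all"), class = "connectivity_matrix")
  home <- c(M1 = "E1", M2 = "E3", M3 = "E2")
  rf <- retention_fractions(cm, home)
  expect_equal(rf$per_source$retention[1], 0.6)  # 60/40 split
  expect_equal(rf$per_source$retention[2], 1.0)  # all settlers at home
  expect_identical(rf$excluded, "M3")            # no settlers: excluded
  expect_equal(rf$median, 0.8)
  expect_error(retention_fractions(cm, home[1:2]), "unmapped")
})

test_that("settlement bookkeeping conserves particles per source", {
  ## small dispersal, then settled + unsettled = released for every source
  sites <- data.frame(site_id = c("A", "B"), x = c(8e3, 16e3), y = c(8e3, 8e3))
  sch <- build_release_schedule(sites, 40, 2, 1, pld = 2, dt = 3600)
  f <- make_velocity_field(flow_spec("uniform", magnitude = 0.02,
                                     time_span = 400,
                                     snapshot_interval = 200),
                           c(31, 31), 1000)
  ep <- run_dispersal(f, sch, epsilon = 1e-9, seed = 4)
  targets <- list(T1 = square_poly(4e3, 4e3, 8e3),
                  T2 = square_poly(14e3, 4e3, 8e3))
  asg <- assign_endpoints(ep, targets, f$bathymetry * 0 + 50, 1000)
  per_source <- table(ep$source_id)
  settled <- tapply(asg$counts$n, asg$counts$source_id, sum)
  for (s in names(per_source)) {
    st <- if (s %in% names(settled)) settled[[s]] else 0
    un <- asg$unsettled$n[asg$unsettled$source_id == s]
    expect_equal(st + un, as.integer(per_source[[s]]))
  }
})
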