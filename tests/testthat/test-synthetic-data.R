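test_that("analytic velocity fields reproduce their closed forms at nodes", {
  ## uniform eastward drift
  f <- make_velocity_field(flow_spec("uniform", magnitude = 0.1),
                           c(8, 6), 1000)
  expect_true(all(f$u == 0.1))
  expect_true(all(f$v == 0))

  ## rigid rotation about the domain centre: node at offset (r, 0) moves
  ## tangentially with speed omega * r
  om <- 2e-6
  f2 <- make_velocity_field(flow_spec("solid_body", angular_rate = om),
                            c(11, 11), 1000)
  centre <- c(5000, 5000)
  i <- 9; j <- 6  # node at (8000, 5000): offset (3000, 0)
  expect_equal(f2$u[i, j, 1], 0)
  expect_equal(f2$v[i, j, 1], om * 3000)
  ## divergence-free at interior nodes to machine precision
  du_dx <- (f2$u[3:11, 2:10, 1] - f2$u[1:9, 2:10, 1]) / 2000
  dv_dy <- (f2$v[2:10, 3:11, 1] - f2$v[2:10, 1:9, 1]) / 2000
  expect_lt(max(abs(du_dx + dv_dy)), 1e-12)

  ## zero-noise gyre identical to the deterministic gyre for any seed
  g0 <- make_velocity_field(flow_spec("double_gyre", magnitude = 0.2),
                            c(21, 11), 1000)
  for (s in c(1, 99)) {
    gn <- make_velocity_field(flow_spec("gyre_plus_noise", magnitude = 0.2,
                                        noise_amplitude = 0, seed = s),
                              c(21, 11), 1000)
    expect_identical(gn$u, g0$u)
    expect_identical(gn$v, g0$v)
  }
  ## double gyre divergence vanishes to discretization order
  du_dx <- (g0$u[3:21, 2:10, 1] - g0$u[1:19, 2:10, 1]) / 2000
  dv_dy <- (g0$v[2:20, 3:11, 1] - g0$v[2:20, 1:9, 1]) / 2000
  expect_lt(max(abs(du_dx + dv_dy)) / max(abs(g0$u)), 5e-3)
})

test_that("velocity fields carry zero velocity on land and reject bad specs", {
  mask <- matrix(FALSE, 8, 6); mask[, 1] <- TRUE
  f <- make_velocity_field(flow_spec("uniform", magnitude = 0.3),
                           c(8, 6), 1000, mask = mask)
  expect_true(all(f$u[, 1, ] == 0))
  expect_true(all(f$u[, 2, ] == 0.3))
  expect_error(flow_spec("uniform", magnitude = -1), "magnitude")
  expect_error(make_velocity_field(structure(list(), class = "list"),
                                   c(4, 4), 1000), "flow_spec")
  expect_error(flow_spec("vortex_sheet"))
})

test_that("domain generation honours counts, reserve fraction and realms", {
  d <- make_domain(domain_spec(seed = 7))
  expect_equal(nrow(d$mpa), 20)
  expect_equal(nrow(d$eez), 6)
  expect_equal(sum(classify_reserves(d$mpa)), round(0.25 * 20))
  ## every MPA inside exactly one EEZ band, realm inherited from it
  for (i in seq_len(nrow(d$mpa))) {
    poly <- d$mpa_polys[[i]]
    band <- d$eez[d$eez$eez_id == d$mpa$eez_id[i], ]
    expect_true(all(poly[, 1] >= band$xmin & poly[, 1] <= band$xmax))
    expect_identical(d$mpa$realm[i], band$realm)
    ## simple polygon: area from the shoelace formula is positive and the
    ## centroid falls inside (star-shaped construction)
    expect_gt(polygon_area(poly), 0)
    expect_true(pip_oracle(poly, polygon_centroid(poly)))
  }
  ## depth exceeds 100 m somewhere inside each EEZ (coastal mask non-trivial)
  expect_true(all(d$eez$coastal_area_km2 <
                    sapply(d$eez_polys, polygon_area) / 1e6))

  ## degenerate and extreme configurations
  d1 <- make_domain(domain_spec(n_mpa = 1, n_eez = 1, n_realms = 1,
                                seed = 3))
  expect_equal(nrow(d1$mpa), 1)
  expect_identical(d1$mpa$eez_id, "EEZ01")
  dall <- make_domain(domain_spec(n_mpa = 8, mr_fraction = 1, seed = 3))
  expect_true(all(classify_reserves(dall$mpa)))
  expect_error(make_domain(domain_spec(extent = c(0, 30e3, 0, 30e3),
                                       n_eez = 4, n_mpa = 4)),
               "generation error")
})

test_that("generators are deterministic in the seed", {
  s <- domain_spec(seed = 42)
  expect_identical(make_domain(s), make_domain(s))
  fs <- flow_spec("gyre_plus_noise", magnitude = 0.1,
                  noise_amplitude = 0.05, seed = 11)
  f1 <- make_velocity_field(fs, c(9, 9), 2000)
  f2 <- make_velocity_field(fs, c(9, 9), 2000)
  expect_identical(f1, f2)
  expect_identical(make_biomass_survey(seed = 5), make_biomass_survey(seed = 5))
  expect_identical(make_dependency_tables(seed = 5),
                   make_dependency_tables(seed = 5))
  ## different seeds differ
  expect_false(identical(make_biomass_survey(seed = 5)$log10_biomass,
                         make_biomass_survey(seed = 6)$log10_biomass))
})

test_that("biomass surveys realise the stated covariate model", {
  ## noiseless survey equals the ground-truth function exactly
  s0 <- make_biomass_survey(n_sites = 40, noise_sd = 0, seed = 2)
  truth <- attr(s0, "truth")
  expect_equal(s0$log10_biomass, as.numeric(truth(s0)))

  ## zero effects: response independent of every covariate
  z <- make_biomass_survey(n_sites = 400,
                           effect_vector = setNames(rep(0, 12),
                                                    covariate_names()),
                           noise_sd = 1, seed = 3)
  cors <- vapply(covariate_names(),
                 function(v) abs(cor(z$log10_biomass, z[[v]])), numeric(1))
  expect_lt(max(cors), 4 / sqrt(nrow(z)))  # all within sampling noise

  ## survey dimensions match the study design: 121 sites, 12 covariates
  s <- make_biomass_survey(n_sites = 121, seed = 1)
  expect_equal(dim(s), c(121, 13))
  expect_error(make_biomass_survey(noise_sd = -1), "noise_sd")
  expect_error(make_biomass_survey(n_sites = 5), "n_sites")
})

test_that("dependency tables induce the requested supply-dependency rank
           correlation", {
  ## strength 0: supply and dependency rank-uncorrelated in expectation
  rhos <- vapply(1:50, function(s) {
    tab <- make_dependency_tables(100, mismatch_strength = 0, seed = s)
    ind <- dependency_indicators(tab)
    cor(tab$supply, ind$food_index, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.06)

  ## strength -0.9: sample Spearman negative in at least 95% of seeds
  neg <- vapply(1:200, function(s) {
    tab <- make_dependency_tables(100, mismatch_strength = -0.9, seed = s)
    ind <- dependency_indicators(tab)
    cor(tab$supply, ind$food_index, method = "spearman") < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)

  expect_error(make_dependency_tables(100, mismatch_strength = -1.2),
               "mismatch_strength")
  expect_error(make_dependency_tables(4), "n_countries")
})
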