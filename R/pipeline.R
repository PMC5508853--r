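#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. The numeric defaults
#' are the reference values of the study design: a 30-day pelagic larval
#' duration (20 days as the behaviour-proxy sensitivity setting), a 3,600 s
#' iteration step, a turbulent dissipation rate of 1e-9 m^2 s^-3, 10,000
#' larvae per site per event, four release events per year (season
#' midpoints) over six years. Overrides are recorded in the run manifest.
#'
#' @param domain a \code{\link{domain_spec}}.
#' @param flow a \code{\link{flow_spec}}.
#' @param grid_shape velocity-grid node counts (nx, ny).
#' @param cell_length grid cell length l, metres.
#' @param pld pelagic larval duration, days.
#' @param dt iteration time step, seconds.
#' @param epsilon turbulent dissipation rate, m^2 s^-3.
#' @param larvae_per_event larvae released per site per event.
#' @param events_per_year release events per year.
#' @param years number of release years.
#' @param threshold connection-strength threshold level ("all",
#'   "medium_strong", "strong").
#' @param mismatch_strength target supply-dependency rank correlation of the
#'   synthetic country tables.
#' @param n_survey biomass survey size.
#' @param n_keep covariates kept in the simplified biomass model.
#' @param seed master seed; every stage derives its own stream.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(domain = domain_spec(),
                            flow = flow_spec(),
                            grid_shape = c(361, 61), cell_length = 5000,
                            pld = 30, dt = 3600, epsilon = 1e-9,
                            larvae_per_event = 10000, events_per_year = 4,
                            years = 6, threshold = "all",
                            mismatch_strength = -0.6, n_survey = 121,
                            n_keep = 8, seed = 1L) {
  structure(list(domain = domain, flow = flow, grid_shape = grid_shape,
                 cell_length = cell_length, pld = pld, dt = dt,
                 epsilon = epsilon, larvae_per_event = larvae_per_event,
                 events_per_year = events_per_year, years = years,
                 threshold = threshold,
                 mismatch_strength = mismatch_strength,
                 n_survey = n_survey, n_keep = n_keep,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Desk-scale demonstration configuration
#'
#' A small coastal domain (20 MPAs in 6 EEZ bands over 2 realms, 600 x 300
#' km shelf) under a steady drift of 5.4 cm/s directed 22 degrees off the
#' alongshore axis — an alongshore current with a mild offshore component,
#' the setting used for the PLD sensitivity contrast. 200 larvae per site
#' per event over 2 years keep runs fast while leaving enough endpoints for
#' stable connection probabilities.
#'
#' @param seed master seed.
#' @param ... overrides passed to \code{\link{pipeline_config}}.
#' @return A \code{pipeline_config}.
#' @export
demo_config <- function(seed = 1L, ...) {
  pipeline_config(
    domain = domain_spec(seed = derive_seed(seed, 2)),
    flow = flow_spec("uniform", magnitude = 0.054, direction_deg = 22,
                     time_span = 720, snapshot_interval = 360,
                     seed = derive_seed(seed, 3)),
    larvae_per_event = 200, years = 2, seed = seed, ...)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes generate -> simulate -> connect -> networks -> supply ->
#' dependency from one configuration. All randomness flows from the master
#' seed through per-stage derived streams, so a second run with the same
#' configuration reproduces every artifact bit-identically.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional directory; when given, CSV/JSON artifacts and a
#'   manifest are written there.
#' @return A list with all stage outputs and a \code{summary} of headline
#'   quantities (connection counts, isolation and retention statistics,
#'   coverage-supply regression, dependency tests).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  ## ---- generate -------------------------------------------------------
  gen <- run_stage("generate", {
    domain <- make_domain(config$domain)
    bm <- domain_bathymetry(domain, config$grid_shape, config$cell_length)
    field <- make_velocity_field(config$flow, config$grid_shape,
                                 config$cell_length, mask = bm$mask,
                                 bathymetry = bm$bathymetry)
    survey <- make_biomass_survey(n_sites = config$n_survey,
                                  seed = derive_seed(seed, 21))
    model <- fit_biomass_model(survey, n_keep = config$n_keep,
                               seed = derive_seed(seed, 22))
    mr <- classify_reserves(domain$mpa)
    biomass <- stats::setNames(predict(model, domain$mpa)$biomass,
                               domain$mpa$id)
    list(domain = domain, field = field, survey = survey, model = model,
         mr = mr, biomass = biomass)
  })
  domain <- gen$domain; field <- gen$field; mr <- gen$mr

  ## ---- simulate -------------------------------------------------------
  sim <- run_stage("simulate", {
    sites <- data.frame(site_id = domain$mpa$id, x = domain$mpa$centroid_x,
                        y = domain$mpa$centroid_y)
    schedule <- build_release_schedule(sites, config$larvae_per_event,
                                       config$events_per_year, config$years,
                                       pld = config$pld, dt = config$dt)
    endpoints <- run_dispersal(field, schedule, epsilon = config$epsilon,
                               seed = derive_seed(seed, 31))
    list(schedule = schedule, endpoints = endpoints)
  })
  endpoints <- sim$endpoints
  released <- stats::setNames(rep(attr(endpoints, "released_per_source"),
                                  nrow(domain$mpa)), domain$mpa$id)

  ## ---- connect --------------------------------------------------------
  con <- run_stage("connect", {
    realms_mpa <- stats::setNames(domain$mpa$realm, domain$mpa$id)
    realms_eez <- stats::setNames(domain$eez$realm, domain$eez$eez_id)
    asg_mpa <- assign_endpoints(endpoints, domain$mpa_polys,
                                field$bathymetry, config$cell_length,
                                field$origin)
    cm_mpa <- connection_matrix(asg_mpa$counts, released, realms_mpa,
                                realms_mpa)
    mr_ids <- domain$mpa$id[mr]
    ep_mr <- endpoints[endpoints$source_id %in% mr_ids, ]
    asg_eez <- assign_endpoints(ep_mr, domain$eez_polys, field$bathymetry,
                                config$cell_length, field$origin,
                                exclude = domain$mpa_polys[mr])
    cm_mr_eez <- connection_matrix(asg_eez$counts, released[mr_ids],
                                   realms_mpa[mr_ids], realms_eez)
    home <- stats::setNames(domain$mpa$eez_id, domain$mpa$id)
    retention <- if (length(mr_ids) > 0 && any(cm_mr_eez$e > 0))
      retention_fractions(cm_mr_eez, home) else NULL
    list(cm_mpa = cm_mpa, cm_mr_eez = cm_mr_eez, retention = retention)
  })

  ## ---- networks -------------------------------------------------------
  nw <- run_stage("networks", {
    cm_lvl <- threshold_by_tertile(con$cm_mpa, config$threshold)
    net <- build_mpa_network(cm_lvl, stats::setNames(mr, domain$mpa$id))
    metrics <- node_metrics(net)
    corr <- metric_correlations(metrics)
    prot <- if (any(mr) && any(!mr))
      list(bc = compare_protection(metrics$bc, metrics$is_mr, "two_sided"),
           ec = compare_protection(metrics$ec, metrics$is_mr, "one_sided"))
    else NULL
    iso_by_level <- vapply(c("all", "medium_strong", "strong"),
      function(lv) {
        n2 <- build_mpa_network(threshold_by_tertile(con$cm_mpa, lv))
        sum(find_networks(n2)$isolated)
      }, numeric(1))
    list(net = net, metrics = metrics, correlations = corr,
         protection = prot, iso_by_level = iso_by_level)
  })

  ## ---- supply ---------------------------------------------------------
  sup <- run_stage("supply", {
    cmask <- coastal_mask(domain, mr)
    a_mr <- stats::setNames(cmask$mpa$coastal_area_km2, cmask$mpa$id)
    a_eez <- stats::setNames(cmask$eez$fishing_area_km2, cmask$eez$eez_id)
    ld <- larval_density(con$cm_mr_eez, gen$biomass, a_mr, a_eez)
    ld$ld_index <- if (length(unique(ld$ld_raw)) > 1)
      minmax_index(ld$ld_raw) else rep(0, nrow(ld))
    mr_area_eez <- tapply(domain$mpa$coastal_area_km2[mr],
                          domain$mpa$eez_id[mr], sum)
    cov_pct <- 100 * as.numeric(mr_area_eez[ld$eez_id]) /
      cmask$eez$coastal_area_km2[match(ld$eez_id, cmask$eez$eez_id)]
    cov_pct[is.na(cov_pct)] <- 0
    ld$coverage_pct <- cov_pct
    reg <- tryCatch(coverage_supply_regression(cov_pct, ld$ld_index),
                    error = function(e) list(error = conditionMessage(e)))
    list(ld = ld, regression = reg, coastal = cmask)
  })

  ## ---- dependency -----------------------------------------------------
  dep <- run_stage("dependency", {
    tab <- make_dependency_tables(n_countries = nrow(sup$ld),
                                  mismatch_strength =
                                    config$mismatch_strength,
                                  seed = derive_seed(seed, 61),
                                  supply = sup$ld$ld_index)
    tab$eez_id <- sup$ld$eez_id
    ind <- dependency_indicators(tab)
    tests <- lapply(c(economic = "economic_index",
                      employment = "employment_index",
                      food = "food_index"), function(cl) {
      grp <- group_by_dependency(ind[[cl]])
      tst <- tryCatch(test_supply_by_group(sup$ld$ld_index, grp),
                      error = function(e) list(error = conditionMessage(e)))
      list(groups = grp, test = tst)
    })
    list(table = tab, indicators = ind, tests = tests)
  })

  summary <- list(
    n_mpa = nrow(domain$mpa), n_mr = sum(mr), n_eez = nrow(domain$eez),
    total_released = sim$schedule$total,
    pct_mr = format_percent(sum(mr), nrow(domain$mpa)),
    n_connections = sum(con$cm_mpa$e > 0),
    n_networks = find_networks(nw$net)$n_networks,
    n_not_seeded = sum(nw$metrics$not_seeded),
    n_isolated = sum(nw$metrics$isolated),
    pct_not_seeded = format_percent(sum(nw$metrics$not_seeded),
                                    nrow(domain$mpa)),
    pct_isolated = format_percent(sum(nw$metrics$isolated),
                                  nrow(domain$mpa)),
    iso_by_level = nw$iso_by_level,
    retention_median = if (!is.null(con$retention)) con$retention$median
                       else NA_real_,
    retention_mean = if (!is.null(con$retention)) con$retention$mean
                     else NA_real_,
    n_unseeded_eez = sum(sup$ld$ld_raw == 0),
    pct_unseeded_eez = format_percent(sum(sup$ld$ld_raw == 0),
                                      nrow(sup$ld)),
    regression = sup$regression[c("slope", "p", "r2", "n_used",
                                  "n_dropped")],
    kw = lapply(dep$tests, function(t)
      if (!is.null(t$test$H)) list(H = t$test$H, p = t$test$p)
      else t$test),
    biomass_fit = list(r2_insample = gen$model$r2_insample,
                       pearson_r = gen$model$pearson_r,
                       r2_cv = gen$model$r2_cv))

  result <- list(config = config, domain = domain, field = field,
                 model = gen$model, biomass = gen$biomass, mr = mr,
                 schedule = sim$schedule, endpoints = endpoints,
                 cm_mpa = con$cm_mpa, cm_mr_eez = con$cm_mr_eez,
                 retention = con$retention, metrics = nw$metrics,
                 correlations = nw$correlations,
                 protection = nw$protection, ld = sup$ld,
                 regression = sup$regression, dependency = dep,
                 summary = summary)

  if (!is.null(out_dir)) write_run_artifacts(result, out_dir)
  result
}

## serialise a run into text artifacts + manifest
write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(result$endpoints, p("endpoints.csv"), row.names = FALSE)
  write_connectivity(result$cm_mpa, p("connectivity_mpa.csv"))
  write_connectivity(result$cm_mr_eez, p("connectivity_mr_eez.csv"))
  utils::write.csv(result$metrics, p("node_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$ld, p("larval_density.csv"), row.names = FALSE)
  utils::write.csv(result$dependency$indicators, p("dependency.csv"),
                   row.names = FALSE)
  write_domain_geojson(result$domain, p("domain.geojson"))
  cfg <- result$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("larvalink")),
    seed = cfg$seed,
    parameters = list(pld = cfg$pld, dt = cfg$dt, epsilon = cfg$epsilon,
                      larvae_per_event = cfg$larvae_per_event,
                      events_per_year = cfg$events_per_year,
                      years = cfg$years, threshold = cfg$threshold,
                      mismatch_strength = cfg$mismatch_strength,
                      n_survey = cfg$n_survey, n_keep = cfg$n_keep,
                      grid_shape = cfg$grid_shape,
                      cell_length = cfg$cell_length),
    reference_defaults = list(pld = 30, dt = 3600, epsilon = 1e-9,
                              larvae_per_event = 10000,
                              events_per_year = 4, years = 6),
    total_released = result$schedule$total)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(result$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Compare two pipeline runs (PLD or threshold sensitivity)
#'
#' Side-by-side counts of connections, isolated and unseeded MPAs, unseeded
#' EEZs and Kruskal-Wallis outcomes for two runs sharing a domain.
#'
#' @param run_a,run_b results of \code{\link{run_pipeline}} on the same
#'   domain specification.
#' @return Data frame (quantity, run_a, run_b, delta).
#' @export
sensitivity_report <- function(run_a, run_b) {
  if (!identical(run_a$config$domain, run_b$config$domain))
    stop("runs do not share a domain")
  g <- function(r) c(n_connections = r$summary$n_connections,
                     n_networks = r$summary$n_networks,
                     n_not_seeded = r$summary$n_not_seeded,
                     n_isolated = r$summary$n_isolated,
                     n_unseeded_eez = r$summary$n_unseeded_eez,
                     kw_p_economic = r$summary$kw$economic$p %||% NA_real_,
                     kw_p_employment = r$summary$kw$employment$p %||%
                       NA_real_,
                     kw_p_food = r$summary$kw$food$p %||% NA_real_)
  a <- g(run_a); b <- g(run_b)
  data.frame(quantity = names(a), run_a = unname(a), run_b = unname(b),
             delta = unname(b - a), row.names = NULL)
}
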