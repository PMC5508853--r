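#!/usr/bin/env Rscript
## Step 3 — connection probabilities and network metrics.
## Assigns endpoints to the coastal (<= 100 m) portions of MPAs and fishing
## zones, builds the within-realm connectivity matrices, and computes
## degrees, betweenness and eigenvector centrality per network, with the
## reserve-vs-MPA centrality comparison.
source("analysis/00_config.R")

domain <- make_domain(CFG$domain)
bm <- domain_bathymetry(domain, CFG$grid_shape, CFG$cell_length)
mr <- classify_reserves(domain$mpa)
endpoints <- read.csv(res_path("endpoints.csv"))
released <- setNames(rep(CFG$larvae_per_event * CFG$events_per_year *
                           CFG$years, nrow(domain$mpa)), domain$mpa$id)
realms_mpa <- setNames(domain$mpa$realm, domain$mpa$id)
realms_eez <- setNames(domain$eez$realm, domain$eez$eez_id)

asg <- assign_endpoints(endpoints, domain$mpa_polys, bm$bathymetry,
                        CFG$cell_length)
cm_mpa <- connection_matrix(asg$counts, released, realms_mpa, realms_mpa)
message(sprintf("MPA-to-MPA: %d positive connections among %d MPAs (within realm).",
                sum(cm_mpa$e > 0), nrow(domain$mpa)))

net <- build_mpa_network(cm_mpa, setNames(mr, domain$mpa$id))
metrics <- node_metrics(net)
nets <- find_networks(net)
message(sprintf("%d networks; %d MPAs not seeded by any other (%d%%); %d fully isolated (%d%%).",
                nets$n_networks, sum(metrics$not_seeded),
                format_percent(sum(metrics$not_seeded), nrow(metrics)),
                sum(metrics$isolated),
                format_percent(sum(metrics$isolated), nrow(metrics))))

corr <- metric_correlations(metrics)
if (nrow(corr$per_network) > 0)
  message(sprintf("Networks (>= 3 nodes) with Spearman rho(BC, EC) < 0.7: %.0f%%.",
                  100 * corr$fraction_below["rho_bc_ec"]))
if (any(mr) && any(!mr)) {
  bc_test <- compare_protection(metrics$bc, metrics$is_mr, "two_sided")
  ec_test <- compare_protection(metrics$ec, metrics$is_mr, "one_sided")
  message(sprintf("Rank-sum MR vs MPA: BC W = %.0f (P = %.2f); EC one-sided W = %.0f (P = %.2f).",
                  bc_test$W, bc_test$p, ec_test$W, ec_test$p))
}

## reserve-to-fishing-zone connectivity (reserves erased from the zones)
mr_ids <- domain$mpa$id[mr]
ep_mr <- endpoints[endpoints$source_id %in% mr_ids, ]
asg_eez <- assign_endpoints(ep_mr, domain$eez_polys, bm$bathymetry,
                            CFG$cell_length, exclude = domain$mpa_polys[mr])
cm_mr_eez <- connection_matrix(asg_eez$counts, released[mr_ids],
                               realms_mpa[mr_ids], realms_eez)
home <- setNames(domain$mpa$eez_id, domain$mpa$id)
ret <- retention_fractions(cm_mr_eez, home)
message(sprintf("Within-EEZ retention across reserves: median %.0f%%, mean %.0f%%.",
                100 * ret$median, 100 * ret$mean))

write_connectivity(cm_mpa, res_path("connectivity_mpa.csv"))
write_connectivity(cm_mr_eez, res_path("connectivity_mr_eez.csv"))
write.csv(metrics, res_path("node_metrics.csv"), row.names = FALSE)
write.csv(ret$per_source, res_path("retention.csv"), row.names = FALSE)
message("Wrote connectivity_mpa.csv, connectivity_mr_eez.csv, node_metrics.csv, retention.csv")
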