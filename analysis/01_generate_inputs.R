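#!/usr/bin/env Rscript
## Step 1 — synthetic inputs with known ground truth.
## Builds the coastal domain (MPA and EEZ polygons, bathymetry, reserve
## attributes), the steady drift field, and the reserve biomass survey, and
## writes them under results/.
source("analysis/00_config.R")

domain <- make_domain(CFG$domain)
mr <- classify_reserves(domain$mpa)
message(sprintf("Domain: %d MPAs (%d marine reserves) across %d EEZ bands,",
                nrow(domain$mpa), sum(mr), nrow(domain$eez)))
message(sprintf("  100 m isobath at %.0f km offshore; coastal EEZ areas %.0f-%.0f km2.",
                domain$y100 / 1e3, min(domain$eez$coastal_area_km2),
                max(domain$eez$coastal_area_km2)))

bm <- domain_bathymetry(domain, CFG$grid_shape, CFG$cell_length)
field <- make_velocity_field(CFG$flow, CFG$grid_shape, CFG$cell_length,
                             mask = bm$mask, bathymetry = bm$bathymetry)
message(sprintf("Drift field: uniform %.1f cm/s at %.0f deg (alongshore + mild offshore).",
                100 * CFG$flow$magnitude, CFG$flow$direction_deg))

survey <- make_biomass_survey(n_sites = CFG$n_survey,
                              seed = derive_seed(SEED, 21))
message(sprintf("Biomass survey: %d reserves x %d covariates, noise sd %.2f (log10 scale).",
                nrow(survey), length(covariate_names()), 0.3))

write_domain_geojson(domain, res_path("domain.geojson"))
write_velocity_field(field, res_path("field.csv"))
write.csv(domain$mpa, res_path("mpa_attributes.csv"), row.names = FALSE)
write.csv(survey, res_path("biomass_survey.csv"), row.names = FALSE)
message("Wrote domain.geojson, field.csv, mpa_attributes.csv, biomass_survey.csv")
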