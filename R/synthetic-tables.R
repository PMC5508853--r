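#' Names of the twelve standardized site covariates
#' @return Character vector of length 12.
#' @export
covariate_names <- function() {
  c("sst_mean", "sst_range", "chl_a", "npp", "depth_mean", "wave_exposure",
    "reserve_age", "reserve_size", "enforcement", "pop_pressure",
    "dist_market", "hdi")
}

#' Draw standardized environmental and socio-economic covariates
#'
#' Twelve independent standard-normal covariates per site (the generators work
#' on the standardized scale; units are irrelevant to the fitted model).
#'
#' @param n number of sites.
#' @param seed integer RNG seed.
#' @return n x 12 data frame.
#' @export
make_covariates <- function(n, seed = 1L) {
  nm <- covariate_names()
  withr::with_seed(as.integer(seed), {
    out <- as.data.frame(matrix(stats::rnorm(n * length(nm)), n,
                                length(nm)))
  })
  names(out) <- nm
  out
}

## default covariate effects on log10 biomass: eight informative slopes and
## four null ones, sized so that with noise_sd = 0.3 the survey R^2 sits near
## 0.8 (signal variance 0.368 vs noise variance 0.09)
default_biomass_effects <- function() {
  stats::setNames(c(0.35, -0.30, 0.25, 0.20, -0.15, 0.12, -0.10, 0.08,
                    0, 0, 0, 0), covariate_names())
}

#' Generate a synthetic reserve biomass survey
#'
#' log10 fish biomass per unit area (g per square metre) is a known linear
#' function of the twelve standardized covariates plus Gaussian noise. The
#' ground-truth function is attached as an attribute so model-recovery tests
#' can score fitted predictors against it.
#'
#' @param n_sites number of surveyed reserves (>= 10).
#' @param effect_vector named length-12 vector of per-covariate slopes on
#'   log10 biomass.
#' @param noise_sd residual standard deviation on the log10 scale (>= 0).
#' @param intercept baseline log10 biomass (default 2, i.e. 100 g/m^2).
#' @param seed integer RNG seed.
#' @return Data frame with \code{log10_biomass} and the 12 covariates;
#'   attributes \code{truth} (the noiseless predictor function) and
#'   \code{effects}.
#' @export
make_biomass_survey <- function(n_sites = 121,
                                effect_vector = default_biomass_effects(),
                                noise_sd = 0.3, intercept = 2, seed = 1L) {
  if (n_sites < 10) stop("n_sites must be >= 10")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(length(effect_vector) == 12)
  X <- make_covariates(n_sites, seed = derive_seed(seed, 1))
  truth <- function(covs) {
    intercept + as.matrix(covs[, covariate_names(), drop = FALSE]) %*%
      as.numeric(effect_vector)
  }
  mu <- as.numeric(truth(X))
  withr::with_seed(derive_seed(seed, 2), {
    y <- mu + stats::rnorm(n_sites, 0, noise_sd)
  })
  out <- cbind(data.frame(log10_biomass = y), X)
  attr(out, "truth") <- truth
  attr(out, "effects") <- effect_vector
  out
}

#' Generate country-level fisheries statistics with a controlled
#' supply-dependency correlation
#'
#' Emits the raw inputs of the three dependency indicators (landed value, GDP,
#' small-scale fisher counts as reported and extrapolated estimates,
#' economically active population, catch per capita, daily animal protein
#' intake) for \code{n_countries}. A Gaussian copula on the rank scores of
#' \code{supply} induces a rank correlation of about \code{mismatch_strength}
#' between the (later recomputed) larval-supply index and each dependency
#' indicator; indicator-specific noise (loading 0.95 on the shared latent)
#' keeps the three indicators distinct, slightly attenuating the realized
#' correlation. The raw inputs are back-solved so that the dependency module
#' reproduces the intended indicator values exactly.
#'
#' @param n_countries number of countries (>= 6).
#' @param mismatch_strength target rank correlation in \code{[-1, 1]}
#'   (negative = the mismatch: high supply where dependency is low).
#' @param seed integer RNG seed.
#' @param supply optional numeric vector of larval-supply values per country;
#'   when missing, a latent log-normal supply is drawn and returned in the
#'   table.
#' @return Data frame with columns country, supply, landed_value, gdp,
#'   fishers_reported, fishers_extrapolated, active_population,
#'   catch_per_capita, protein_per_capita.
#' @export
make_dependency_tables <- function(n_countries = 120,
                                   mismatch_strength = -0.6, seed = 1L,
                                   supply = NULL) {
  if (n_countries < 6) stop("n_countries must be >= 6")
  if (abs(mismatch_strength) > 1)
    stop("mismatch_strength must be in [-1, 1]")
  if (!is.null(supply) && length(supply) != n_countries)
    stop("supply must have one value per country")
  withr::with_seed(as.integer(seed), {
    if (is.null(supply)) supply <- exp(stats::rnorm(n_countries, 0, 1))
    ## normal scores of the supply ranks (Gaussian copula margin)
    r <- rank(supply, ties.method = "average")
    zs <- stats::qnorm((r - 0.5) / n_countries)
    rho <- mismatch_strength
    shared <- rho * zs + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_countries)
    lat <- function() 0.95 * shared + sqrt(1 - 0.95^2) *
      stats::rnorm(n_countries)
    ## indicator raw values as monotone transforms of their latents
    econ_raw <- exp(-7 + 1.2 * lat())            # landed value / GDP
    empl_raw <- stats::plogis(1.0 * lat() - 4.5) # fishers / active pop
    food_raw <- exp(2 + 1.0 * lat())             # scaled catch per capita
    gdp <- exp(stats::rnorm(n_countries, 24, 1))
    active_pop <- round(exp(stats::rnorm(n_countries, 14.5, 0.8)))
    protein <- exp(log(50) + 0.3 * stats::rnorm(n_countries))
    d <- stats::runif(n_countries, 0, 0.3)
    fishers <- empl_raw * active_pop
  })
  data.frame(country = sprintf("C%03d", seq_len(n_countries)),
             supply = supply,
             landed_value = econ_raw * gdp,
             gdp = gdp,
             fishers_reported = fishers * (1 - d),
             fishers_extrapolated = fishers * (1 + d),
             active_population = active_pop,
             catch_per_capita = food_raw * (protein / 36),
             protein_per_capita = protein,
             stringsAsFactors = FALSE)
}
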