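#' Fit the gradient-boosted biomass model and simplify it
#'
#' Fits a gradient-boosted tree regressor (xgboost) of log10 fish biomass per
#' unit area on the survey covariates, choosing the boosting round count by
#' cross-validated deviance with early stopping (the CV-based stopping rule
#' of the standard BRT protocol); ranks covariates by relative influence
#' (gain) and
#' refits on the top \code{n_keep}, the simplified model used to predict
#' biomass in unsurveyed reserves. Reports the in-sample R^2 and Pearson r
#' between observed and predicted values, and a k-fold cross-validated R^2
#' (the honest counterpart).
#'
#' @param survey data frame with \code{log10_biomass} and covariate columns.
#' @param n_keep covariates retained in the simplified model (default 8).
#' @param params list of learner settings: \code{eta} (learning rate),
#'   \code{max_depth}, \code{subsample} (bag fraction), \code{nrounds_max},
#'   \code{early_stopping} patience, \code{nfold} CV folds.
#' @param seed integer seed for the holdout split and folds.
#' @param min_rows smallest acceptable survey (default 30).
#' @return A \code{biomass_model}: list with the fitted booster, kept
#'   covariates, influence table and fit statistics (\code{r2_insample},
#'   \code{pearson_r}, \code{r2_cv}).
#' @export
fit_biomass_model <- function(survey, n_keep = 8,
                              params = list(eta = 0.05, max_depth = 3,
                                            subsample = 0.7,
                                            nrounds_max = 1500,
                                            early_stopping = 50,
                                            nfold = 5),
                              seed = 1L, min_rows = 30) {
  covs <- intersect(covariate_names(), names(survey))
  if (length(covs) == 0) covs <- setdiff(names(survey), "log10_biomass")
  if (n_keep > length(covs)) stop("n_keep exceeds the number of covariates")
  if (nrow(survey) < min_rows)
    stop("survey has fewer than ", min_rows, " rows")
  y <- survey$log10_biomass
  xp <- list(eta = params$eta, max_depth = params$max_depth,
             subsample = params$subsample, objective = "reg:squarederror")
  train_boost <- function(cols, seed_k) {
    X <- as.matrix(survey[, cols, drop = FALSE])
    withr::with_seed(seed_k, {
      dall <- xgboost::xgb.DMatrix(X, label = y)
      ## round count chosen by cross-validated deviance with early stopping
      cv <- xgboost::xgb.cv(params = xp, data = dall,
                            nrounds = params$nrounds_max,
                            nfold = params$nfold,
                            early_stopping_rounds = params$early_stopping,
                            verbose = 0)
      best <- cv$early_stop$best_iteration
      if (is.null(best)) best <- cv$best_iteration  # older xgboost layout
      if (is.null(best) || is.na(best)) best <- params$nrounds_max
      list(fit = xgboost::xgb.train(params = xp, data = dall,
                                    nrounds = best, verbose = 0),
           nrounds = best)
    })
  }
  full <- train_boost(covs, derive_seed(seed, 1))
  imp <- xgboost::xgb.importance(model = full$fit)
  ranked <- c(imp$Feature, setdiff(covs, imp$Feature))
  keep <- ranked[seq_len(n_keep)]
  simp <- train_boost(keep, derive_seed(seed, 2))
  fit <- simp$fit
  Xk <- as.matrix(survey[, keep, drop = FALSE])
  pred <- predict(fit, xgboost::xgb.DMatrix(Xk))
  r2_in <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  r_pear <- stats::cor(y, pred)
  ## k-fold CV R^2 of the simplified model
  withr::with_seed(derive_seed(seed, 3), {
    fold <- sample(rep(seq_len(params$nfold), length.out = nrow(survey)))
  })
  cvp <- rep(NA_real_, nrow(survey))
  for (f in seq_len(params$nfold)) {
    tr <- fold != f
    dtr <- xgboost::xgb.DMatrix(Xk[tr, , drop = FALSE], label = y[tr])
    mdl <- withr::with_seed(derive_seed(seed, 100 + f),
      xgboost::xgb.train(params = xp, data = dtr,
                         nrounds = simp$nrounds, verbose = 0))
    cvp[!tr] <- predict(mdl, xgboost::xgb.DMatrix(Xk[!tr, , drop = FALSE]))
  }
  r2_cv <- 1 - sum((y - cvp)^2) / sum((y - mean(y))^2)
  structure(list(booster = fit, covariates = keep, influence = imp,
                 r2_insample = r2_in, pearson_r = r_pear, r2_cv = r2_cv),
            class = "biomass_model")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Predict log10 biomass (and natural-scale biomass) for new sites
#'
#' @param object a \code{biomass_model}.
#' @param newdata data frame carrying the model's covariates.
#' @param ... unused.
#' @return Data frame with \code{log10_biomass} and \code{biomass}
#'   (g per square metre).
#' @export
predict.biomass_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$covariates, drop = FALSE])
  lg <- predict(object$booster, xgboost::xgb.DMatrix(X))
  data.frame(log10_biomass = lg, biomass = 10^lg)
}

#' Biomass-weighted larval density received by each EEZ
#'
#' \code{LD_i = sum_j e_ij * B_j * A_j / A_i}: the fraction of larvae
#' released in reserve j that seed EEZ i, weighted by the predicted fish
#' biomass of the reserve (\code{B_j}, biomass per unit area times coastal
#' area \code{A_j} gives the reserve's larval release potential) and scaled
#' by the receiving EEZ's coastal surface area \code{A_i}.
#'
#' @param matrix MR-to-EEZ \code{connectivity_matrix} (targets = EEZs,
#'   sources = MRs).
#' @param biomass named vector of natural-scale biomass per unit area B_j
#'   (g/m^2) for every MR.
#' @param area_mr named vector of MR coastal areas A_j (km^2).
#' @param area_eez named vector of EEZ coastal areas A_i (km^2, > 0).
#' @return Data frame (eez_id, ld_raw, n_donor_mrs).
#' @export
larval_density <- function(matrix, biomass, area_mr, area_eez) {
  e <- matrix$e
  src <- colnames(e); tgt <- rownames(e)
  contributing <- src[colSums(e) > 0]
  miss <- contributing[!(contributing %in% names(biomass)) |
                       is.na(biomass[contributing])]
  if (length(miss))
    stop("missing biomass for contributing MR(s): ",
         paste(miss, collapse = ", "))
  miss_a <- contributing[!(contributing %in% names(area_mr))]
  if (length(miss_a))
    stop("missing coastal area for MR(s): ", paste(miss_a, collapse = ", "))
  if (!all(tgt %in% names(area_eez)) || any(area_eez[tgt] <= 0))
    stop("every EEZ target needs a positive coastal area")
  b <- biomass[src]; b[is.na(b)] <- 0
  a <- area_mr[src]; a[is.na(a)] <- 0
  ld <- as.numeric(e %*% (b * a)) / area_eez[tgt]
  data.frame(eez_id = tgt, ld_raw = unname(ld),
             n_donor_mrs = as.integer(rowSums(e > 0)), row.names = NULL)
}

#' Log-log regression of larval supply on reserve coverage
#'
#' Ordinary least squares of log larval-density index on log percent coastal
#' area in reserves. Records with zero coverage or zero supply fall outside
#' the log domain; they are excluded and counted.
#'
#' @param coverage_pct percent of EEZ coastal area in reserves.
#' @param ld_index larval-density index per EEZ (0-100).
#' @return List with \code{slope}, \code{p}, \code{r2}, \code{n_used},
#'   \code{n_dropped} and the fitted \code{lm}.
#' @export
coverage_supply_regression <- function(coverage_pct, ld_index) {
  stopifnot(length(coverage_pct) == length(ld_index))
  ok <- is.finite(coverage_pct) & is.finite(ld_index) &
    coverage_pct > 0 & ld_index > 0
  if (sum(ok) < 3)
    stop("fewer than 3 EEZs with positive coverage and supply")
  d <- data.frame(lx = log(coverage_pct[ok]), ly = log(ld_index[ok]))
  fit <- stats::lm(ly ~ lx, data = d)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       p = unname(sm$coefficients[2, 4]),
       r2 = sm$r.squared, n_used = sum(ok), n_dropped = sum(!ok),
       fit = fit)
}
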