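#' Economic fisheries-dependency indicator
#'
#' Ratio of the landed value of small-scale marine fishing to the country's
#' gross domestic product. Multi-year inputs (matrix with years in columns)
#' are averaged before the ratio is taken.
#'
#' @param landed_value currency per year: vector, or matrix (countries x
#'   years).
#' @param gdp currency per year, same shape (> 0).
#' @return Raw dimensionless ratio per country.
#' @export
economic_index <- function(landed_value, gdp) {
  lv <- if (is.matrix(landed_value)) rowMeans(landed_value) else landed_value
  g <- if (is.matrix(gdp)) rowMeans(gdp) else gdp
  if (any(g <= 0)) stop("gdp must be > 0")
  lv / g
}

#' Employment fisheries-dependency indicator
#'
#' Ratio of the number of small-scale marine fishers to the economically
#' active population. When two fisher estimates are supplied (reported and
#' extrapolated), their mean is taken before the ratio.
#'
#' @param fishers fisher count: vector, or matrix/data frame with one column
#'   per source estimate.
#' @param active_population economically active population (> 0).
#' @return Raw dimensionless ratio per country.
#' @export
employment_index <- function(fishers, active_population) {
  f <- if (is.matrix(fishers) || is.data.frame(fishers))
    rowMeans(as.matrix(fishers)) else fishers
  if (any(active_population <= 0)) stop("active_population must be > 0")
  f / active_population
}

#' Food-security fisheries-dependency indicator
#'
#' Small-scale catch per capita scaled by national diet adequacy: the ratio
#' of average animal protein intake to the 36 g per capita per day reference.
#' High catch combined with an inadequate diet gives high dependency.
#'
#' @param catch_per_capita kg per capita per year.
#' @param protein_per_capita g animal protein per capita per day (> 0).
#' @param reference adequacy reference, g per capita per day (default 36).
#' @return Raw scaled catch per capita.
#' @export
food_security_index <- function(catch_per_capita, protein_per_capita,
                                reference = 36) {
  if (any(protein_per_capita <= 0)) stop("protein_per_capita must be > 0")
  catch_per_capita / (protein_per_capita / reference)
}

#' Compute all three dependency indicators from a country table
#'
#' @param tab data frame with columns landed_value, gdp, fishers_reported,
#'   fishers_extrapolated, active_population, catch_per_capita,
#'   protein_per_capita.
#' @return Data frame with raw and 0-100 indexed indicators per country.
#' @export
dependency_indicators <- function(tab) {
  econ <- economic_index(tab$landed_value, tab$gdp)
  empl <- employment_index(cbind(tab$fishers_reported,
                                 tab$fishers_extrapolated),
                           tab$active_population)
  food <- food_security_index(tab$catch_per_capita, tab$protein_per_capita)
  data.frame(country = tab$country,
             economic_raw = econ, employment_raw = empl, food_raw = food,
             economic_index = minmax_index(econ),
             employment_index = minmax_index(empl),
             food_index = minmax_index(food),
             stringsAsFactors = FALSE)
}

#' Group countries into low/medium/high dependency levels
#'
#' Tertile split on the indexed indicator (1/3 and 2/3 empirical quantiles,
#' linear interpolation; values at or below a boundary fall in the lower
#' group). If heavy ties collapse the tertiles, groups are formed by ordinal
#' rank into three near-equal blocks with a warning; if all values are equal
#' a single "low" group is returned with a warning.
#'
#' @param indexed numeric indicator values (>= 3 defined values).
#' @return Factor with levels low, medium, high (present levels only when
#'   degenerate).
#' @export
group_by_dependency <- function(indexed) {
  ok <- is.finite(indexed)
  if (sum(ok) < 3) stop("need at least 3 countries with defined values")
  out <- factor(rep(NA_character_, length(indexed)),
                levels = c("low", "medium", "high"))
  x <- indexed[ok]
  if (length(unique(x)) == 1) {
    warning("all dependency values equal; single group")
    out[ok] <- "low"
    return(out)
  }
  q <- stats::quantile(x, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  if (q[1] == q[2]) {
    warning("degenerate tertiles from ties; grouping by ordinal rank")
    r <- rank(x, ties.method = "first")
    out[ok] <- c("low", "medium", "high")[ceiling(3 * r / length(x))]
    return(out)
  }
  out[ok] <- ifelse(x <= q[1], "low", ifelse(x <= q[2], "medium", "high"))
  out
}

#' Conover-Iman all-pairs rank comparison after a Kruskal-Wallis test
#'
#' Pairwise t statistics on the pooled ranks using the tie-corrected
#' Kruskal-Wallis variance, df = N - k; two-sided p-values adjusted by
#' Benjamini-Hochberg within the family of pairwise tests.
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @return Data frame (group_a, group_b, t, p, p_adj).
#' @export
conover_test <- function(x, g) {
  g <- droplevels(as.factor(g))
  k <- nlevels(g)
  stopifnot(k >= 2)
  N <- length(x)
  r <- rank(x)
  H <- unname(stats::kruskal.test(x, g)$statistic)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  rbar <- tapply(r, g, mean)
  ng <- tabulate(g)
  pairs <- utils::combn(levels(g), 2)
  tt <- pp <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- match(pairs[1, j], levels(g)); b <- match(pairs[2, j], levels(g))
    se <- sqrt(S2 * ((N - 1 - H) / (N - k)) * (1 / ng[a] + 1 / ng[b]))
    tt[j] <- (rbar[a] - rbar[b]) / se
    pp[j] <- 2 * stats::pt(-abs(tt[j]), df = N - k)
  }
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], t = tt, p = pp,
             p_adj = stats::p.adjust(pp, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Test larval supply across dependency groups
#'
#' Kruskal-Wallis test (with tie correction) of the larval-density index
#' across the low/medium/high dependency groups, followed by Conover-Iman
#' pairwise comparisons with Benjamini-Hochberg adjustment. Groups with fewer
#' than 2 members are excluded with a warning.
#'
#' @param ld larval-density index per country.
#' @param groups dependency level factor from
#'   \code{\link{group_by_dependency}}.
#' @return List with \code{H}, \code{df}, \code{p}, \code{posthoc} data
#'   frame and group sizes \code{n}.
#' @export
test_supply_by_group <- function(ld, groups) {
  ok <- is.finite(ld) & !is.na(groups)
  g <- droplevels(factor(groups[ok]))
  x <- ld[ok]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    x <- x[keep]; g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups")
  if (length(unique(x)) == 1) {
    ## no variation at all: the rank statistic is 0 by definition
    pairs <- utils::combn(levels(g), 2)
    post <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                       t = 0, p = 1, p_adj = 1, stringsAsFactors = FALSE)
    return(list(H = 0, df = nlevels(g) - 1, p = 1, posthoc = post,
                n = as.integer(table(g))))
  }
  kw <- stats::kruskal.test(x, g)
  post <- if (nlevels(g) >= 2 && length(unique(x)) > 1)
    conover_test(x, g)
  else data.frame(group_a = character(0), group_b = character(0),
                  t = numeric(0), p = numeric(0), p_adj = numeric(0))
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, posthoc = post, n = as.integer(table(g)))
}
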