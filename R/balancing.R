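# Carbon and ATP balancing of reference phenotypes. Carbon recovery checks
# how much substrate carbon is explained by biomass, measured products and
# the theoretical CO2 release of product synthesis; the ATP balance regresses
# the substrate-level-phosphorylation ATP rate of each cluster against its
# growth rate to estimate the ATP-specific biomass yield Y_BM/ATP and the
# maintenance demand q_ATP^m.

# pull a dimension out of a centroid vector named "mu"/"r_<abbrev>" (or bare
# abbreviations)
zeta_get <- function(zeta, what) {
  nm <- names(zeta)
  if (is.null(nm)) stop("centroid vector must be named")
  for (cand in c(what, paste0("r_", what))) {
    if (cand %in% nm) return(unname(zeta[[cand]]))
  }
  stop("centroid is missing dimension: ", what)
}

#' Theoretical CO2 production rate of a reference phenotype
#'
#' Clostridial product synthesis releases CO2 at pyruvate decarboxylation:
#' one CO2 per ethanol and acetate, two per butanol (two pyruvates), and by
#' default two per butyrate (`buac_co2 = 2`; set 1 to count a single
#' decarboxylation). Formate counts negative: it is the still-undissolved
#' C1 pool.
#'
#' @param zeta Named centroid vector (`mu`, `r_<abbrev>` or bare
#'   abbreviations).
#' @param buac_co2 CO2 stoichiometry per butyrate (2 or 1).
#' @return CO2 rate in mmol/g/h.
#' @export
co2_rate <- function(zeta, buac_co2 = 2) {
  zeta_get(zeta, "EtOH") + zeta_get(zeta, "AcAc") +
    2 * zeta_get(zeta, "BuOH") + buac_co2 * zeta_get(zeta, "BuAc") -
    zeta_get(zeta, "FoAc")
}

#' Carbon recovery of a reference phenotype
#'
#' Percentage of consumed substrate carbon recovered in biomass, measured
#' products and theoretical CO2:
#' `R_C = 100 * (n_C^BM * mu * 1000 / M_BM + sum(n_C^D * zeta_D) + r_CO2) /
#' sum(n_C^S * |zeta_S|)`, the sum in the denominator running over consumed
#' substrates. The growth rate (1/h) is converted to a biomass carbon rate
#' through the monomer molar mass, hence the 1000 g-to-mmol factor.
#' Product dimensions with net consumption keep their negative sign. A
#' substrate with net production is ignored in the denominator (warning);
#' with no consumed substrate at all the recovery is not computable and
#' `NA` is returned.
#'
#' @inheritParams co2_rate
#' @param registry Compound registry (carbon counts, molar masses, roles).
#' @return Recovery in percent, or `NA` if not computable.
#' @export
carbon_recovery <- function(zeta, registry = default_registry(),
                            buac_co2 = 2) {
  bm <- registry[registry$role == "biomass", ]
  num <- bm$n_carbons * zeta_get(zeta, "mu") * 1000 / bm$molar_mass
  prods <- registry[registry$role == "product", ]
  for (i in seq_len(nrow(prods))) {
    num <- num + prods$n_carbons[i] * zeta_get(zeta, prods$abbreviation[i])
  }
  num <- num + co2_rate(zeta, buac_co2 = buac_co2)
  subs <- registry[registry$role == "substrate", ]
  den <- 0
  for (i in seq_len(nrow(subs))) {
    z <- zeta_get(zeta, subs$abbreviation[i])
    if (z > 0) {
      warning("substrate ", subs$abbreviation[i],
              " has net production; ignored in the recovery denominator")
    } else {
      den <- den + subs$n_carbons[i] * abs(z)
    }
  }
  if (den == 0) {
    message("carbon recovery not computable: no net substrate consumption")
    return(NA_real_)
  }
  100 * num / den
}

#' Specific ATP production rate of a reference phenotype
#'
#' Sum of product rates weighted by their substrate-level-phosphorylation
#' ATP stoichiometry. Products without a defined stoichiometry contribute
#' zero (noted once per call).
#'
#' @inheritParams carbon_recovery
#' @return ATP rate in mmol/g/h.
#' @export
atp_rate <- function(zeta, registry = default_registry()) {
  prods <- registry[registry$role == "product", ]
  undef <- prods$abbreviation[is.na(prods$atp_stoich)]
  if (length(undef)) {
    message("no ATP stoichiometry for ", paste(undef, collapse = ", "),
            "; contributing 0")
  }
  q <- 0
  for (i in seq_len(nrow(prods))) {
    s <- prods$atp_stoich[i]
    if (!is.na(s)) q <- q + s * zeta_get(zeta, prods$abbreviation[i])
  }
  q
}

#' ATP balance regression across reference phenotypes
#'
#' Assuming ATP synthesis by substrate-level phosphorylation only, each
#' cluster obeys `q_ATP = (1000 / Y_BM_ATP) * mu + q_ATP_m`. Clusters whose
#' carbon recovery deviates from 100 % by more than `recovery_threshold`
#' percentage points (or is not computable) are excluded; over the included
#' clusters an unweighted ordinary least-squares line of `q_ATP` against
#' `mu` is fitted. The ATP-specific biomass yield is `Y = 1000 / slope`
#' (g/mol) with a delta-method standard error; the intercept is the
#' maintenance coefficient `q_ATP_m` (mmol/g/h).
#'
#' @param centroids Matrix of raw reference phenotypes (rows = clusters,
#'   columns named `mu`, `r_<abbrev>`), e.g. `model$raw_centroids`.
#' @param registry Compound registry.
#' @param recovery_threshold Maximum allowed `|R_C - 100|` in percentage
#'   points.
#' @param buac_co2 CO2 stoichiometry per butyrate (see [co2_rate()]).
#' @param conf_level Confidence level of the pointwise band.
#' @return A `balance_result`: per-cluster table (`r_co2`, `recovery_pct`,
#'   `q_atp`, `included`), the regression coefficients with standard
#'   errors, `Y_BM_ATP` (+ SE; `NA` and `physical = FALSE` when the slope
#'   is not positive), residuals, and a pointwise confidence band over the
#'   included growth-rate range.
#' @export
fit_atp_regression <- function(centroids, registry = default_registry(),
                               recovery_threshold = 19, buac_co2 = 2,
                               conf_level = 0.95) {
  stopifnot(is.matrix(centroids) || is.data.frame(centroids))
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  per <- data.frame(
    cluster = if (!is.null(rownames(centroids))) rownames(centroids) else paste0("CL", seq_len(k)),
    mu = NA_real_, r_co2 = NA_real_, recovery_pct = NA_real_,
    q_atp = NA_real_, included = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    z <- centroids[i, ]
    per$mu[i] <- zeta_get(z, "mu")
    per$r_co2[i] <- co2_rate(z, buac_co2 = buac_co2)
    per$recovery_pct[i] <- suppressWarnings(
      carbon_recovery(z, registry, buac_co2 = buac_co2))
    per$q_atp[i] <- atp_rate(z, registry)
  }
  per$included <- !is.na(per$recovery_pct) &
    abs(per$recovery_pct - 100) <= recovery_threshold
  if (sum(per$included) < 3) {
    stop("fewer than 3 clusters pass the carbon-recovery inclusion rule")
  }
  inc <- per[per$included, ]
  fit <- stats::lm(q_atp ~ mu, data = inc)
  cf <- summary(fit)$coefficients
  slope <- cf["mu", "Estimate"]; slope_se <- cf["mu", "Std. Error"]
  qm <- cf["(Intercept)", "Estimate"]; qm_se <- cf["(Intercept)", "Std. Error"]
  physical <- slope > 0
  if (!physical) {
    message("non-positive slope: Y_BM_ATP is not physical for this cluster set")
  }
  Y <- if (physical) 1000 / slope else NA_real_
  Y_se <- if (physical) 1000 * slope_se / slope^2 else NA_real_
  mu_grid <- seq(min(inc$mu), max(inc$mu), length.out = 50)
  band <- cbind(mu = mu_grid,
                stats::predict(fit, newdata = data.frame(mu = mu_grid),
                               interval = "confidence", level = conf_level))
  structure(list(
    per_cluster = per,
    slope = slope, slope_se = slope_se,
    q_atp_m = qm, q_atp_m_se = qm_se,
    Y_BM_ATP = Y, Y_BM_ATP_se = Y_se, physical = physical,
    residuals = stats::setNames(stats::residuals(fit), inc$cluster),
    conf_band = as.data.frame(band), conf_level = conf_level,
    recovery_threshold = recovery_threshold, buac_co2 = buac_co2,
    fit = fit
  ), class = "balance_result")
}

#' @export
print.balance_result <- function(x, ...) {
  cat("<balance_result>\n")
  cat(sprintf("  %d/%d clusters within %.0f%% of full carbon recovery\n",
              sum(x$per_cluster$included), nrow(x$per_cluster),
              x$recovery_threshold))
  if (x$physical) {
    cat(sprintf("  Y_BM/ATP = %.2f +/- %.2f g/mol, q_ATP^m = %.2f +/- %.2f mmol/g/h\n",
                x$Y_BM_ATP, x$Y_BM_ATP_se, x$q_atp_m, x$q_atp_m_se))
  } else {
    cat("  slope not positive: Y_BM/ATP not physical\n")
  }
  invisible(x)
}
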