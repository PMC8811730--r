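# From concentrations to phenotype vectors: each interior sampling time of a
# cultivation yields one vector (mu, r_D...) of biomass-specific rates.
# Derivatives are taken as centered finite differences on a shape-preserving
# PCHIP interpolant; mu comes from a local exponential fit of raw biomass.

#' Shape-preserving interpolation of a concentration series
#'
#' Piecewise cubic Hermite interpolation (PCHIP, Fritsch-Carlson slopes):
#' passes exactly through the knots and never overshoots, so interpolated
#' concentrations stay monotone wherever the data are.
#'
#' @param times Strictly increasing knot times (h).
#' @param values Concentrations at the knots.
#' @param query_times Times at which to evaluate; must lie within the knot
#'   range.
#' @return Interpolated values at `query_times`.
#' @export
interpolate_concentration <- function(times, values, query_times) {
  keep <- !is.na(values)
  times <- times[keep]; values <- values[keep]
  if (length(times) < 2) stop("need at least 2 knots to interpolate")
  if (is.unsorted(times, strictly = TRUE)) stop("knot times must be strictly increasing")
  if (length(query_times) == 0) return(numeric(0))
  if (min(query_times) < times[1] || max(query_times) > times[length(times)]) {
    stop("query time outside the knot range [", times[1], ", ",
         times[length(times)], "]")
  }
  if (length(times) == 2) {
    # two knots: the Hermite interpolant degenerates to the secant line
    return(values[1] + (values[2] - values[1]) *
             (query_times - times[1]) / (times[2] - times[1]))
  }
  pracma::pchip(times, values, query_times)
}

#' Biomass-specific rate from a volumetric slope
#'
#' Divides a concentration time derivative (mmol/L/h) by the biomass
#' concentration (g/L), preserving sign: consumption is negative.
#'
#' @param biomass_at_t Biomass concentration at the evaluation time (g/L);
#'   must be positive.
#' @param slope Concentration time derivative (mmol/L/h).
#' @return Specific rate in mmol/g/h.
#' @export
specific_rate <- function(biomass_at_t, slope) {
  if (!is.finite(biomass_at_t) || biomass_at_t <= 0) {
    stop("specific rate undefined: biomass must be positive at the evaluation time")
  }
  slope / biomass_at_t
}

# OLS slope of ln(biomass) over the points inside [lo, hi]; NA if fewer than
# two usable (positive-biomass) points.
fit_log_slope <- function(times, biomass, lo, hi) {
  sel <- which(times >= lo & times <= hi & !is.na(biomass) & biomass > 0)
  if (length(sel) < 2) return(NA_real_)
  tt <- times[sel]
  if (length(unique(tt)) < 2) return(NA_real_)
  y <- log(biomass[sel])
  sum((tt - mean(tt)) * (y - mean(y))) / sum((tt - mean(tt))^2)
}

#' Specific growth rate by local exponential fit
#'
#' Fits an ordinary least-squares line to `ln(biomass)` versus time over a
#' window centered at `t_query`; the slope is the specific growth rate
#' (1/h), possibly negative. Points with non-positive biomass are unusable.
#'
#' @param times Sampling times (h).
#' @param biomass Biomass concentrations (g/L) at `times`.
#' @param t_query Center of the fitting window (h).
#' @param window Full window width (h).
#' @return Growth rate in 1/h.
#' @export
growth_rate <- function(times, biomass, t_query, window) {
  stopifnot(length(times) == length(biomass), window > 0)
  mu <- fit_log_slope(times, biomass, t_query - window / 2, t_query + window / 2)
  if (is.na(mu)) {
    stop("growth rate undefined: fewer than 2 positive biomass points in the window")
  }
  mu
}

#' Compute phenotype vectors of biomass-specific rates for one experiment
#'
#' One vector per interior sampling time t_j (the first and last time are
#' dropped: the centered derivative is undefined there). For every compound,
#' the slope at t_j is the centered finite difference of the PCHIP
#' interpolant over `2 * grid_step`, divided by interpolated biomass. The
#' growth rate comes from an exponential fit of the raw biomass points
#' between the neighboring sampling times. Fed-batch cumulative columns are
#' differentiated the same way and negated, giving a consumption (negative)
#' rate; their "concentration" is excluded downstream from
#' concentration-based conditionality.
#'
#' @param exp A [cultivation_experiment()].
#' @param registry Compound registry.
#' @param grid_step Half-width of the centered difference stencil (h).
#' @return A `rate_table` data frame with columns `experiment_id`, `time_h`,
#'   `mu`, one `r_<abbrev>` and one `c_<abbrev>` column per non-biomass
#'   registry compound present, `c_BM`, `cum_<abbrev>` flags for cumulative
#'   columns, and `tag_<key>` columns carrying the experiment tags.
#' @export
compute_rate_vectors <- function(exp, registry = default_registry(),
                                 grid_step = 0.1) {
  stopifnot(inherits(exp, "cultivation_experiment"), grid_step > 0)
  s <- exp$samples
  if (nrow(s) < 3) {
    warning("experiment ", exp$experiment_id,
            ": fewer than 3 samples, no rate vectors computed")
    return(empty_rate_table(exp, registry))
  }
  bm_keep <- !is.na(s$BM)
  bm_t <- s$time_h[bm_keep]; bm_v <- s$BM[bm_keep]
  if (sum(bm_v > 0) < 2) {
    warning("experiment ", exp$experiment_id,
            ": fewer than 2 positive biomass points, no rate vectors computed")
    return(empty_rate_table(exp, registry))
  }
  abbrevs <- registry$abbreviation[registry$dimension_index >= 2]
  abbrevs <- intersect(abbrevs, names(s))
  n <- nrow(s)
  interior <- 2:(n - 1)

  rows <- lapply(interior, function(j) {
    tj <- s$time_h[j]
    if (tj < bm_t[1] || tj > bm_t[length(bm_t)]) return(NULL)
    c1 <- interpolate_concentration(bm_t, bm_v, tj)
    if (!is.finite(c1) || c1 <= 0) {
      message("experiment ", exp$experiment_id, ", t = ", tj,
              " h: non-positive biomass, vector dropped")
      return(NULL)
    }
    mu <- fit_log_slope(s$time_h, s$BM, s$time_h[j - 1], s$time_h[j + 1])
    if (is.na(mu)) {
      message("experiment ", exp$experiment_id, ", t = ", tj,
              " h: exponential fit undefined, vector dropped")
      return(NULL)
    }
    row <- list(experiment_id = exp$experiment_id, time_h = tj,
                mu = mu, c_BM = c1)
    for (a in abbrevs) {
      keep <- !is.na(s[[a]])
      r_val <- NA_real_; c_val <- NA_real_
      if (sum(keep) >= 2) {
        kt <- s$time_h[keep]
        h <- min(grid_step, tj - kt[1], kt[length(kt)] - tj)
        if (h > 0) {
          f <- interpolate_concentration(kt, s[[a]][keep],
                                         c(tj - h, tj, tj + h))
          slope <- (f[3] - f[1]) / (2 * h)
          r_val <- slope / c1
          if (a %in% exp$cumulative) r_val <- -r_val
          c_val <- f[2]
        }
      }
      row[[paste0("r_", a)]] <- r_val
      row[[paste0("c_", a)]] <- c_val
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_rate_table(exp, registry))
  out <- do.call(rbind, rows)
  for (a in exp$cumulative) out[[paste0("cum_", a)]] <- TRUE
  for (k in names(exp$tags)) out[[paste0("tag_", k)]] <- unname(exp$tags[[k]])
  rownames(out) <- NULL
  class(out) <- c("rate_table", "data.frame")
  out
}

empty_rate_table <- function(exp, registry) {
  abbrevs <- registry$abbreviation[registry$dimension_index >= 2]
  cols <- c("experiment_id", "time_h", "mu", "c_BM",
            as.vector(rbind(paste0("r_", abbrevs), paste0("c_", abbrevs))))
  out <- as.data.frame(stats::setNames(
    lapply(cols, function(x) if (x == "experiment_id") character(0) else numeric(0)),
    cols))
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Bind per-experiment rate tables into one pooled table
#'
#' @param rate_tables List of `rate_table` data frames from
#'   [compute_rate_vectors()].
#' @return One pooled `rate_table`; missing columns (tags, cumulative flags)
#'   are filled with `NA`/`FALSE`.
#' @export
bind_rate_tables <- function(rate_tables) {
  rate_tables <- rate_tables[vapply(rate_tables, nrow, integer(1)) > 0]
  if (!length(rate_tables)) stop("no rate vectors to bind")
  all_cols <- Reduce(union, lapply(rate_tables, names))
  filled <- lapply(rate_tables, function(df) {
    for (cc in setdiff(all_cols, names(df))) {
      df[[cc]] <- if (startsWith(cc, "cum_")) FALSE else NA
    }
    df[all_cols]
  })
  out <- do.call(rbind, filled)
  rownames(out) <- NULL
  class(out) <- c("rate_table", "data.frame")
  out
}

# names of the phenotype dimensions in a rate table, mu first
rate_dimensions <- function(rates) {
  c("mu", grep("^r_", names(rates), value = TRUE))
}

#' Percentile-based outlier trimming of rate vectors
#'
#' For every phenotype dimension (mu and each specific rate), the
#' `lower_pct` and `upper_pct` empirical percentiles are computed over all
#' vectors pooled across experiments (linear interpolation between order
#' statistics). A vector is removed when any of its dimensions falls
#' strictly outside its band. This damps the rate blow-ups that occur at
#' very low biomass concentrations and would otherwise distort k-means
#' centroids; DBSCAN, which has its own noise notion, is typically run
#' without trimming.
#'
#' @param rates Pooled `rate_table`.
#' @param lower_pct,upper_pct Percentile bounds in \[0, 100\].
#' @return List with elements `kept` and `removed`, both `rate_table`s,
#'   input order preserved.
#' @export
remove_outliers <- function(rates, lower_pct = 3, upper_pct = 97) {
  stopifnot(nrow(rates) > 0, lower_pct >= 0, upper_pct <= 100,
            lower_pct < upper_pct)
  dims <- rate_dimensions(rates)
  outside <- rep(FALSE, nrow(rates))
  for (d in dims) {
    v <- rates[[d]]
    qs <- stats::quantile(v, c(lower_pct, upper_pct) / 100,
                          na.rm = TRUE, names = FALSE, type = 7)
    bad <- !is.na(v) & (v < qs[1] | v > qs[2])
    outside <- outside | bad
  }
  if (any(outside)) {
    message(sum(outside), " of ", nrow(rates),
            " vectors removed by percentile trimming [", lower_pct, ", ",
            upper_pct, "]")
  }
  list(kept = rates[!outside, , drop = FALSE],
       removed = rates[outside, , drop = FALSE])
}

#' Extract the phenotype matrix (mu and specific rates) from a rate table
#'
#' @param rates A `rate_table`.
#' @param drop_incomplete Drop rows containing `NA` in any dimension
#'   (compounds with too few measurements to differentiate).
#' @return Numeric matrix, one row per phenotype vector, columns `mu`,
#'   `r_<abbrev>`, with row identity in `attr(, "ids")` (a data frame of
#'   `experiment_id`, `time_h`).
#' @export
rate_matrix <- function(rates, drop_incomplete = TRUE) {
  dims <- rate_dimensions(rates)
  m <- as.matrix(rates[, dims, drop = FALSE])
  keep <- rep(TRUE, nrow(m))
  if (drop_incomplete) {
    keep <- stats::complete.cases(m)
    if (!all(keep)) {
      message(sum(!keep), " incomplete vectors dropped (unmeasured compounds)")
    }
  }
  m <- m[keep, , drop = FALSE]
  attr(m, "ids") <- data.frame(experiment_id = rates$experiment_id[keep],
                               time_h = rates$time_h[keep],
                               stringsAsFactors = FALSE)
  m
}
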