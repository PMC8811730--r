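# Conditionality screening: is a cluster over- or under-represented under a
# condition (a tag value, or a concentration range) relative to the pooled
# dataset? Quantified as the log10 deviation of proportions; positive means
# over-representation.

#' Pool concentrations into half-open ranges
#'
#' Concentrations are pooled into left-closed bins anchored at 0:
#' `label = [floor(v / step) * step, + step)`. The canonical metabolite
#' steps are 1, 5, 10, 20, 50 and 100 mmol/L; biomass uses analogous g/L
#' steps (e.g. 0.05).
#'
#' @param values Non-negative concentrations.
#' @param step Bin width (> 0).
#' @return Character vector of bin labels like `"[60, 80)"`, with the bin
#'   lower edge in `attr(, "lower")`.
#' @export
bin_concentration <- function(values, step) {
  stopifnot(length(step) == 1, step > 0)
  if (any(values < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  lower <- floor(values / step) * step
  labels <- ifelse(is.na(lower), NA_character_,
                   paste0("[", format(lower, trim = TRUE, scientific = FALSE),
                          ", ", format(lower + step, trim = TRUE,
                                       scientific = FALSE), ")"))
  attr(labels, "lower") <- lower
  labels
}

#' Log-deviation of cluster proportions under a condition
#'
#' For each cluster CL and condition bin, computes
#' `delta = log10[(n_CL,cond / n_CL) / (n_cond / n)]`: the log10 ratio of
#' the condition's share within the cluster to its share in the pooled
#' dataset. `delta > 0` marks over-representation of the condition in the
#' cluster, `delta < 0` under-representation; it is `NA` ("undefined")
#' whenever any of the four counts is zero. Conditions come either from an
#' experiment tag or from binned interpolated concentrations; the condition
#' itself was not used for cluster formation. Noise-labeled vectors
#' (DBSCAN) are excluded from both populations, as are vectors whose
#' concentration column records a fed-batch cumulative amount when binning
#' that compound.
#'
#' @param model A `cluster_model` whose labels align row-for-row with
#'   `rates`.
#' @param rates The `rate_table` the model was fitted on (same row order).
#' @param tag Tag name (a `tag_<name>` column of `rates`), or `NULL`.
#' @param compound Registry abbreviation (a `c_<abbrev>` column, `"BM"` for
#'   biomass), or `NULL`. Exactly one of `tag`/`compound` must be given.
#' @param step Bin width for `compound` conditions (mmol/L; g/L for `"BM"`).
#' @return Data frame of `conditionality_result` rows: `cluster`,
#'   `condition`, `bin`, the four counts, and `delta`.
#' @export
log_deviation <- function(model, rates, tag = NULL, compound = NULL,
                          step = 20) {
  stopifnot(inherits(model, "cluster_model"),
            length(model$labels) == nrow(rates))
  if (is.null(tag) == is.null(compound)) {
    stop("give exactly one of `tag` or `compound`")
  }
  labels <- model$labels
  keep <- labels > 0
  if (!is.null(tag)) {
    col <- paste0("tag_", tag)
    if (!col %in% names(rates)) stop("unknown condition tag: ", tag)
    bins <- as.character(rates[[col]])
    condition <- paste0("tag:", tag)
  } else {
    col <- paste0("c_", compound)
    if (!col %in% names(rates)) stop("unknown compound: ", compound)
    cum_col <- paste0("cum_", compound)
    if (cum_col %in% names(rates)) {
      keep <- keep & !isTRUE_vec(rates[[cum_col]])
    }
    bins <- as.character(bin_concentration(rates[[col]], step))
    condition <- paste0("conc:", compound, ":", format(step, trim = TRUE))
  }
  keep <- keep & !is.na(bins)
  labels <- labels[keep]; bins <- bins[keep]
  n <- length(labels)
  if (n == 0) stop("no vectors left after exclusions")
  clusters <- sort(unique(labels))
  bin_levels <- unique(bins[order(suppressWarnings(as.numeric(
    sub("^\\[", "", sub(",.*$", "", bins)))), bins)])
  rows <- list()
  for (cl in clusters) {
    n_cl <- sum(labels == cl)
    for (b in bin_levels) {
      n_cond <- sum(bins == b)
      n_cc <- sum(labels == cl & bins == b)
      delta <- if (n_cc > 0 && n_cl > 0 && n_cond > 0) {
        log10((n_cc / n_cl) / (n_cond / n))
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, condition = condition, bin = b,
        n_cluster_cond = n_cc, n_cluster = n_cl,
        n_total_cond = n_cond, n_total = n, delta = delta,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("conditionality_result", "data.frame")
  out
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE)
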