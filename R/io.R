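# Reading/writing the delimited experiment tables, tag files and run manifests.
# Samples are wide: one row per sampling point, one concentration column per
# compound (biomass in g/L, everything else in mmol/L).

# delimiter auto-detection: tab wins if the header contains one, else comma
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

#' Construct a cultivation experiment
#'
#' Bundles one cultivation's sampled concentration series with its condition
#' tags. Concentrations are instantaneous, except for columns named in
#' `cumulative`, which record the accumulated amount consumed (the usual way
#' fed-batch substrate feeds are logged) and must be non-decreasing.
#'
#' @param experiment_id Identifier of the cultivation.
#' @param samples Data frame with a `time_h` column and one column per
#'   measured compound, named by registry abbreviation (`BM` in g/L, others
#'   in mmol/L). `NA` means "not measured at this time point".
#' @param tags Named character vector of condition tags (untyped text).
#' @param cumulative Character vector of abbreviations whose column is a
#'   cumulative consumed amount rather than a concentration.
#' @return A `cultivation_experiment` object.
#' @export
cultivation_experiment <- function(experiment_id, samples,
                                   tags = character(0),
                                   cumulative = character(0)) {
  stopifnot(is.data.frame(samples), "time_h" %in% names(samples))
  ord <- order(samples$time_h)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  if (anyDuplicated(samples$time_h)) {
    stop("experiment ", experiment_id, ": duplicated sampling times")
  }
  conc_cols <- setdiff(names(samples), "time_h")
  for (cc in conc_cols) {
    v <- samples[[cc]]
    if (any(v < 0, na.rm = TRUE)) {
      stop("experiment ", experiment_id, ": negative concentration in ", cc)
    }
  }
  for (cc in intersect(cumulative, conc_cols)) {
    v <- samples[[cc]][!is.na(samples[[cc]])]
    if (is.unsorted(v)) {
      stop("experiment ", experiment_id,
           ": cumulative column ", cc, " must be non-decreasing")
    }
  }
  tags <- if (length(tags)) stats::setNames(as.character(tags), names(tags)) else character(0)
  structure(
    list(experiment_id = as.character(experiment_id), samples = samples,
         tags = tags, cumulative = intersect(cumulative, conc_cols)),
    class = "cultivation_experiment"
  )
}

#' @export
print.cultivation_experiment <- function(x, ...) {
  cat("<cultivation_experiment>", x$experiment_id, "\n")
  cat(sprintf("  %d samples over %.2f-%.2f h, compounds: %s\n",
              nrow(x$samples), min(x$samples$time_h), max(x$samples$time_h),
              paste(setdiff(names(x$samples), "time_h"), collapse = ", ")))
  if (length(x$cumulative)) {
    cat("  cumulative (fed-batch) columns:", paste(x$cumulative, collapse = ", "), "\n")
  }
  if (length(x$tags)) {
    cat("  tags:", paste(names(x$tags), x$tags, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Load cultivation experiments from delimited sample and tag tables
#'
#' The samples file is wide delimited text (comma or tab, auto-detected) with
#' header `experiment_id, time_h, biomass_gL, <abbrev>_mM, ...` using the
#' registry abbreviations, plus optional boolean columns `<abbrev>_cumulative`
#' (constant within an experiment) flagging fed-batch cumulative columns.
#' The tags file has header `experiment_id, key, value`.
#'
#' @param samples_path Path to the samples table.
#' @param tags_path Optional path to the tag table.
#' @param registry Compound registry used to validate column names.
#' @return A list of [cultivation_experiment()] objects, one per distinct
#'   `experiment_id`, samples sorted by time.
#' @export
load_experiments <- function(samples_path, tags_path = NULL,
                             registry = default_registry()) {
  raw <- read_delimited(samples_path)
  if (!all(c("experiment_id", "time_h", "biomass_gL") %in% names(raw))) {
    stop("samples file must have columns experiment_id, time_h, biomass_gL")
  }
  conc_cols <- grep("_mM$", names(raw), value = TRUE)
  abbrevs <- sub("_mM$", "", conc_cols)
  unknown <- setdiff(abbrevs, registry$abbreviation)
  if (length(unknown)) {
    stop("unknown compound column(s): ", paste(unknown, collapse = ", "))
  }
  cum_cols <- grep("_cumulative$", names(raw), value = TRUE)

  tag_tab <- NULL
  if (!is.null(tags_path)) {
    tag_tab <- read_delimited(tags_path)
    if (!all(c("experiment_id", "key", "value") %in% names(tag_tab))) {
      stop("tags file must have columns experiment_id, key, value")
    }
  }

  out <- lapply(split(raw, raw$experiment_id), function(df) {
    samples <- data.frame(time_h = df$time_h, BM = df$biomass_gL)
    for (i in seq_along(conc_cols)) samples[[abbrevs[i]]] <- df[[conc_cols[i]]]
    cumulative <- character(0)
    for (cc in cum_cols) {
      flag <- unique(df[[cc]][!is.na(df[[cc]])])
      if (length(flag) > 1) {
        stop("experiment ", df$experiment_id[1], ": ", cc,
             " must be constant within an experiment")
      }
      if (length(flag) == 1 && (isTRUE(flag) || flag %in% c("TRUE", "true", "1", 1))) {
        cumulative <- c(cumulative, sub("_cumulative$", "", cc))
      }
    }
    tags <- character(0)
    if (!is.null(tag_tab)) {
      tt <- tag_tab[tag_tab$experiment_id == df$experiment_id[1], , drop = FALSE]
      tags <- stats::setNames(as.character(tt$value), tt$key)
    }
    cultivation_experiment(df$experiment_id[1], samples, tags, cumulative)
  })
  unname(out)
}

#' Write cultivation experiments back to the delimited format
#'
#' Inverse of [load_experiments()]; round-trips up to float formatting.
#'
#' @param experiments List of `cultivation_experiment` objects.
#' @param samples_path Output path for the samples table.
#' @param tags_path Optional output path for the tag table.
#' @export
write_experiments <- function(experiments, samples_path, tags_path = NULL) {
  abbrevs <- unique(unlist(lapply(experiments, function(e)
    setdiff(names(e$samples), c("time_h", "BM")))))
  rows <- lapply(experiments, function(e) {
    df <- data.frame(experiment_id = e$experiment_id,
                     time_h = e$samples$time_h,
                     biomass_gL = e$samples$BM)
    for (a in abbrevs) {
      df[[paste0(a, "_mM")]] <- if (a %in% names(e$samples)) e$samples[[a]] else NA
    }
    for (a in intersect(e$cumulative, abbrevs)) {
      df[[paste0(a, "_cumulative")]] <- TRUE
    }
    df
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(df) {
    for (cc in setdiff(all_cols, names(df))) {
      df[[cc]] <- if (grepl("_cumulative$", cc)) FALSE else NA
    }
    df[all_cols]
  })
  utils::write.csv(do.call(rbind, rows), samples_path, row.names = FALSE, na = "")
  if (!is.null(tags_path)) {
    tag_rows <- do.call(rbind, lapply(experiments, function(e) {
      if (!length(e$tags)) return(NULL)
      data.frame(experiment_id = e$experiment_id, key = names(e$tags),
                 value = unname(e$tags))
    }))
    if (is.null(tag_rows)) {
      tag_rows <- data.frame(experiment_id = character(0), key = character(0),
                             value = character(0))
    }
    utils::write.csv(tag_rows, tags_path, row.names = FALSE)
  }
  invisible(samples_path)
}

#' Write and read a run manifest
#'
#' A manifest is a flat `key = value` text file recording the command,
#' parameters and seed of a run so that deterministic stages can be
#' reproduced bit-for-bit.
#'
#' @param params Named list of parameters (scalars; vectors are
#'   comma-joined).
#' @param path Output path.
#' @export
write_manifest <- function(params, path) {
  stopifnot(!is.null(names(params)), all(nzchar(names(params))))
  lines <- vapply(names(params), function(k) {
    v <- params[[k]]
    paste0(k, " = ", paste(format(v, trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("malformed manifest line: ", lines[bad][1])
  stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, character(1), 2))
}
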