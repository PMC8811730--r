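#' Built-in compound registry for Clostridium pasteurianum fermentations
#'
#' Returns the default registry of the 11 dimensions used for phenotype
#' clustering of *C. pasteurianum* cultivations: biomass (dimension 1),
#' the substrates glucose and glycerol, and eight extracellular products.
#' Each row carries the molar mass, carbon count and the stoichiometric ATP
#' yield of substrate-level phosphorylation for product synthesis
#' (`NA` where no single stoichiometry is defined, e.g. substrates and
#' 2-oxobutyric acid).
#'
#' @return A `compound_registry` data frame with columns `dimension_index`,
#'   `name`, `abbreviation`, `molar_mass` (g/mol), `formula`, `n_carbons`,
#'   `atp_stoich` (mol ATP per mol compound, `NA` if undefined) and `role`
#'   (`"biomass"`, `"substrate"` or `"product"`).
#' @examples
#' reg <- default_registry()
#' reg[reg$abbreviation == "BuOH", ]
#' @export
default_registry <- function() {
  reg <- data.frame(
    dimension_index = 1:11,
    name = c("Biomass", "Glucose", "Glycerol", "1,3-Propanediol", "Ethanol",
             "Butanol", "Lactic acid", "Formic acid", "Acetic acid",
             "Butyric acid", "2-Oxobutyric acid"),
    abbreviation = c("BM", "Glc", "Gly", "PDO", "EtOH", "BuOH", "LaAc",
                     "FoAc", "AcAc", "BuAc", "OBuAc"),
    molar_mass = c(101.1, 180.2, 92.09, 76.09, 46.07, 74.12, 90.08, 46.03,
                   60.05, 88.11, 102.1),
    formula = c("C4H7O2N", "C6H12O6", "C3H8O3", "C3H8O2", "C2H6O", "C4H10O",
                "C3H6O3", "CH2O2", "C2H4O2", "C4H8O2", "C4H6O3"),
    n_carbons = c(4L, 6L, 3L, 3L, 2L, 4L, 3L, 1L, 2L, 4L, 4L),
    atp_stoich = c(NA, NA, NA, 0, 1, 2, 1, 0, 2, 3, NA),
    role = c("biomass", "substrate", "substrate", rep("product", 8)),
    stringsAsFactors = FALSE
  )
  class(reg) <- c("compound_registry", "data.frame")
  reg
}

validate_registry <- function(reg) {
  req <- c("dimension_index", "name", "abbreviation", "molar_mass",
           "n_carbons", "atp_stoich", "role")
  missing_cols <- setdiff(req, names(reg))
  if (length(missing_cols) > 0) {
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(reg$dimension_index)) {
    stop("registry has duplicate dimension_index values")
  }
  if (anyDuplicated(reg$abbreviation)) {
    stop("registry has duplicate abbreviations")
  }
  if (any(!is.finite(reg$molar_mass)) || any(reg$molar_mass <= 0)) {
    stop("registry molar_mass must be positive and finite")
  }
  if (any(reg$n_carbons < 0)) stop("registry n_carbons must be >= 0")
  if (!all(reg$role %in% c("biomass", "substrate", "product"))) {
    stop("registry role must be one of biomass/substrate/product")
  }
  bm <- which(reg$role == "biomass")
  if (length(bm) != 1) stop("registry must contain exactly one biomass row")
  if (reg$dimension_index[bm] != 1L) {
    stop("the biomass row must occupy dimension_index 1")
  }
  reg <- reg[order(reg$dimension_index), , drop = FALSE]
  rownames(reg) <- NULL
  class(reg) <- c("compound_registry", "data.frame")
  reg
}

#' Load a compound registry from a delimited file or use the built-in one
#'
#' @param path Path to a comma- or tab-delimited registry file mirroring the
#'   columns of [default_registry()]. With `path = NULL` the built-in
#'   11-compound registry is returned.
#' @return A validated `compound_registry`.
#' @export
load_compound_registry <- function(path = NULL) {
  if (is.null(path)) return(validate_registry(default_registry()))
  reg <- read_delimited(path)
  if ("atp_stoich" %in% names(reg)) {
    reg$atp_stoich <- suppressWarnings(as.numeric(reg$atp_stoich))
  }
  reg$n_carbons <- as.integer(reg$n_carbons)
  reg$dimension_index <- as.integer(reg$dimension_index)
  validate_registry(reg)
}

#' @export
#' @rdname load_compound_registry
#' @param registry A `compound_registry` to write.
write_compound_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE, na = "")
  invisible(path)
}
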