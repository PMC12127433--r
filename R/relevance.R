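# Physiological relevance of benchmark concentrations.
#
# A BMC observed in vitro matters for hazard assessment when it falls within
# (or below) the range at which the receptor's natural ligands circulate in
# fetal cord blood. Literature ranges are reported as mass concentrations
# (ng/ml or µg/ml); conversion to molar units uses the ligand's molar mass.

#' Convert a mass concentration to nanomolar
#'
#' `ng/ml` is equivalent to `µg/L`, so `nM = value * 1000 / molar_mass`;
#' `µg/ml` values are 1000-fold larger.
#'
#' @param value Mass concentration (> 0).
#' @param molar_mass Molar mass in g/mol (> 0).
#' @param unit `"ng/ml"` (default) or `"ug/ml"`.
#' @return Concentration in nM.
#' @export
mass_to_nM <- function(value, molar_mass, unit = c("ng/ml", "ug/ml")) {
  unit <- match.arg(unit)
  if (any(value <= 0, na.rm = TRUE) || any(molar_mass <= 0, na.rm = TRUE)) {
    abort("mass concentration and molar mass must be positive",
          class = "bmcscreen_domain_error")
  }
  scale <- if (unit == "ug/ml") 1e6 else 1e3
  value * scale / molar_mass
}

#' Read a cord-blood ligand reference table
#'
#' @param path CSV with columns `receptor, ligand, conc_low, conc_high,
#'   conc_unit, molar_mass_g_per_mol`; defaults to the reference table
#'   shipped with the package (fetal cord blood ranges of the natural
#'   ligands of the screened hormone receptors).
#' @return Tibble with added `nm_low`, `nm_high` molar columns (`NA` when no
#'   concentration range is reported for a ligand).
#' @export
read_cordblood_reference <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "cord_blood_reference.csv", package = "bmcscreen")
  ref <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("receptor", "ligand", "conc_low", "conc_high", "conc_unit",
              "molar_mass_g_per_mol")
  missing_cols <- setdiff(needed, names(ref))
  if (length(missing_cols) > 0) {
    abort(paste0("reference table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "bmcscreen_schema_error")
  }
  conv <- function(v, u, mm) {
    ifelse(is.na(v) | is.na(u) | is.na(mm), NA_real_,
           v * ifelse(u == "ug/ml", 1e6, 1e3) / mm)
  }
  dplyr::mutate(
    tibble::as_tibble(ref),
    nm_low = conv(.data$conc_low, .data$conc_unit, .data$molar_mass_g_per_mol),
    nm_high = conv(.data$conc_high, .data$conc_unit, .data$molar_mass_g_per_mol)
  )
}

#' Flag whether a BMC is physiologically relevant
#'
#' A BMC is relevant (`"yes"`) when it lies within or below the upper bound
#' of the physiological ligand range, `"no"` when it exceeds it, and
#' `"questionable"` when no reference range exists for the receptor.
#'
#' @param bmc BMC in nM (non-censored).
#' @param nm_high Upper bound of the physiological range in nM, or `NA` when
#'   absent.
#' @return Character verdict: `"yes"`, `"no"` or `"questionable"`.
#' @export
flag_relevance <- function(bmc, nm_high) {
  stopifnot(length(bmc) == length(nm_high) || length(nm_high) == 1)
  nm_high <- rep_len(nm_high, length(bmc))
  dplyr::case_when(
    is.na(nm_high) ~ "questionable",
    bmc <= nm_high ~ "yes",
    TRUE ~ "no"
  )
}

#' Join relevance verdicts onto a BMC summary table
#'
#' The reference is collapsed per receptor (maximum `nm_high` over its
#' ligands with a reported range) and the verdict of [flag_relevance()]
#' applied to each receptor's BMC.
#'
#' @param bmc_table Tibble with columns `receptor` and `bmc_nM`.
#' @param reference Reference tibble from [read_cordblood_reference()].
#' @return `bmc_table` with added `nm_low`, `nm_high` and `relevant` columns.
#' @export
annotate_relevance <- function(bmc_table, reference = read_cordblood_reference()) {
  by_receptor <- dplyr::summarise(
    dplyr::group_by(reference, .data$receptor),
    nm_low = if (all(is.na(.data$nm_low))) NA_real_ else
      min(.data$nm_low, na.rm = TRUE),
    nm_high = if (all(is.na(.data$nm_high))) NA_real_ else
      max(.data$nm_high, na.rm = TRUE),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble::as_tibble(bmc_table), by_receptor,
                          by = "receptor")
  dplyr::mutate(out, relevant = flag_relevance(.data$bmc_nM, .data$nm_high))
}
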