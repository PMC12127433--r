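#' Read a plate-level response table
#'
#' Reads the tidy CSV schema used throughout the package: one row per well
#' and endpoint, with columns `compound, endpoint, species, sex, donor_id,
#' plate_id, well_type, concentration_uM, replicate, value`. Enum columns are
#' validated against the allowed labels, concentrations must be non-negative
#' (0 µM denotes solvent wells) and values must be present, finite and
#' non-negative raw instrument units.
#'
#' @param path Path to a CSV file with the schema above.
#' @return A tibble of validated response records.
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("response table not found: ", path), class = "bmcscreen_io_error")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_response_table(tbl)
}

#' Validate a response table against the package schema
#'
#' @param tbl A data frame shaped like the schema of [read_response_table()].
#' @return The validated tibble (invisibly the same data, with
#'   `concentration_uM`, `replicate` and `value` coerced to numeric).
#' @export
validate_response_table <- function(tbl) {
  missing_cols <- setdiff(RESPONSE_COLUMNS, names(tbl))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "response table is missing required column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "bmcscreen_schema_error"
    )
  }
  tbl <- tibble::as_tibble(tbl)
  check_enum <- function(x, levels, what) {
    bad <- setdiff(unique(as.character(x)), levels)
    if (length(bad) > 0) {
      abort(
        paste0(
          "unknown ", what, " label(s): ", paste(bad, collapse = ", "),
          "; allowed: ", paste(levels, collapse = ", ")
        ),
        class = "bmcscreen_validation_error"
      )
    }
  }
  check_enum(tbl$endpoint, ENDPOINT_LEVELS, "endpoint")
  check_enum(tbl$species, SPECIES_LEVELS, "species")
  check_enum(tbl$sex, SEX_LEVELS, "sex")
  check_enum(tbl$well_type, WELL_TYPE_LEVELS, "well_type")

  tbl$concentration_uM <- as.numeric(tbl$concentration_uM)
  tbl$replicate <- as.integer(tbl$replicate)
  tbl$value <- as.numeric(tbl$value)

  if (anyNA(tbl$value) || any(!is.finite(tbl$value))) {
    abort("response values must be present and finite",
          class = "bmcscreen_validation_error")
  }
  if (anyNA(tbl$concentration_uM) || any(tbl$concentration_uM < 0)) {
    abort("concentrations must be non-negative (0 for solvent wells)",
          class = "bmcscreen_validation_error")
  }
  solv <- tbl$well_type == "solvent"
  if (any(tbl$concentration_uM[solv] != 0)) {
    abort("solvent wells must have concentration_uM = 0",
          class = "bmcscreen_validation_error")
  }
  tbl
}

#' Write a response table
#'
#' @param tbl A response-record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(tbl, path) {
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Subtract plate background fluorescence
#'
#' Wells containing medium without cells ("blank" wells) measure background
#' fluorescence. Within each group defined by `blank_key` the median blank
#' value is subtracted from every well; corrected values below zero are
#' clipped to zero (signal below background is physically meaningless noise).
#' Blank wells are removed from the output.
#'
#' @param tbl Response records.
#' @param blank_key Character vector of grouping columns sharing one
#'   background level; default `c("plate_id", "endpoint")`.
#' @return Tibble of corrected records without blank wells.
#' @export
background_correct <- function(tbl, blank_key = c("plate_id", "endpoint")) {
  tbl <- tibble::as_tibble(tbl)
  grouped <- dplyr::group_by(tbl, dplyr::across(dplyr::all_of(blank_key)))
  no_blank <- dplyr::filter(
    dplyr::summarise(grouped, n_blank = sum(.data$well_type == "blank"),
                     .groups = "drop"),
    .data$n_blank == 0
  )
  if (nrow(no_blank) > 0) {
    key <- do.call(paste, c(no_blank[blank_key], sep = "/"))
    abort(
      paste0("no blank wells in group(s): ", paste(key, collapse = "; ")),
      class = "bmcscreen_blank_error"
    )
  }
  out <- dplyr::mutate(
    grouped,
    value = pmax(.data$value - median(.data$value[.data$well_type == "blank"]), 0)
  )
  out <- dplyr::ungroup(out)
  dplyr::filter(out, .data$well_type != "blank")
}

#' Normalize responses to the plate solvent control
#'
#' Expresses every well as a percentage of the median solvent-control value
#' of the same `(plate_id, endpoint)` group, so that the solvent median maps
#' to exactly 100 %. Run after [background_correct()].
#'
#' @param tbl Background-corrected response records.
#' @return The input tibble with an added `percent_of_control` column.
#' @export
normalize_to_control <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  grouped <- dplyr::group_by(tbl, .data$plate_id, .data$endpoint)
  meds <- dplyr::summarise(
    grouped,
    solvent_median = if (any(.data$well_type == "solvent")) {
      median(.data$value[.data$well_type == "solvent"])
    } else NA_real_,
    .groups = "drop"
  )
  bad <- dplyr::filter(meds, is.na(.data$solvent_median) | .data$solvent_median <= 0)
  if (nrow(bad) > 0) {
    key <- paste(bad$plate_id, bad$endpoint, sep = "/")
    abort(
      paste0(
        "solvent control missing or non-positive median in group(s): ",
        paste(key, collapse = "; ")
      ),
      class = "bmcscreen_normalization_error"
    )
  }
  out <- dplyr::left_join(tbl, meds, by = c("plate_id", "endpoint"))
  out <- dplyr::mutate(out,
                       percent_of_control = 100 * .data$value / .data$solvent_median)
  dplyr::select(out, -"solvent_median")
}

#' Aggregate technical replicates
#'
#' Collapses the technical replicates of each condition within a biological
#' replicate to their median, the robust summary used for all downstream
#' statistics. A biological replicate is identified by `(donor_id, plate_id)`:
#' technical replicate wells share a plate and are not independent, so tests
#' and curve fits operate on these aggregated values.
#'
#' @param tbl Normalized response records (output of [normalize_to_control()]).
#' @param value_col Column to aggregate; default `"percent_of_control"`.
#' @return A tibble with one row per (compound, endpoint, species, sex,
#'   donor_id, plate_id, well_type, concentration), carrying the median
#'   response and the number of contributing technical replicates `n_tech`.
#' @export
aggregate_technical <- function(tbl, value_col = "percent_of_control") {
  if (!value_col %in% names(tbl)) {
    abort(paste0("column not found: ", value_col),
          class = "bmcscreen_validation_error")
  }
  grouped <- dplyr::group_by(
    tibble::as_tibble(tbl),
    .data$compound, .data$endpoint, .data$species, .data$sex,
    .data$donor_id, .data$plate_id, .data$well_type, .data$concentration_uM
  )
  dplyr::summarise(
    grouped,
    response = median(.data[[value_col]]),
    n_tech = dplyr::n(),
    .groups = "drop"
  )
}
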