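# End-to-end screening pipeline:
# normalize -> gate on cytotoxicity -> fit -> BMC -> hit call -> MSE
# (-> relevance), deterministic under one root seed. Each stage's randomness
# (bootstrap bands, Monte-Carlo critical values) draws from a named
# substream derived from the root seed and the stratum, so reruns with the
# same configuration give identical result bundles.

#' Run the full benchmark-concentration screening pipeline
#'
#' @param records Raw plate-level response table (schema of
#'   [read_response_table()]), containing the endpoint channels and,
#'   optionally, an `LDH` cytotoxicity channel per stratum.
#' @param bmr_table Tibble `endpoint`, `bmr_percent` (e.g. built with
#'   [derive_bmr()] from historical control data). Endpoints missing from
#'   the table fall back to `default_bmr`.
#' @param seed Root seed; all stage randomness derives from it.
#' @param n_boot Bootstrap resamples per confidence band.
#' @param alpha Family-wise error level of the step-down test.
#' @param families Optional subset of the model catalog.
#' @param ci_rule Band-crossing rule of [classify_hit()].
#' @param default_bmr BMR used for endpoints absent from `bmr_table`.
#' @param reference Optional cord-blood reference
#'   ([read_cordblood_reference()]) for relevance flagging.
#' @param receptor_map Optional tibble `compound`, `receptor` linking test
#'   compounds to the receptor whose ligand range applies.
#' @return A `bmc_pipeline` list: `bmc_table` (one row per stratum/endpoint
#'   with BMC, bounds, hit call and basis), `mse_table`, optional
#'   `relevance_table`, `gates`, `log` and `provenance`.
#' @export
run_pipeline <- function(records, bmr_table = NULL, seed = 1, n_boot = 200,
                         alpha = 0.05, families = NULL,
                         ci_rule = c("both_edges", "either_edge"),
                         default_bmr = 20,
                         reference = NULL, receptor_map = NULL) {
  ci_rule <- match.arg(ci_rule)
  records <- validate_response_table(records)
  normalized <- records |>
    background_correct() |>
    normalize_to_control()
  responses <- aggregate_technical(normalized)

  bmr_lookup <- function(ep) {
    if (!is.null(bmr_table) && ep %in% bmr_table$endpoint) {
      bmr_table$bmr_percent[match(ep, bmr_table$endpoint)]
    } else default_bmr
  }

  strata <- dplyr::distinct(responses, .data$compound, .data$species, .data$sex)
  gates <- list()
  log_rows <- list()
  bmc_rows <- list()

  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    sub <- dplyr::semi_join(responses, st, by = c("compound", "species", "sex"))
    tested <- sort(unique(sub$concentration_uM[sub$concentration_uM > 0]))
    st_key <- paste(st$compound, st$species, st$sex, sep = "/")

    # cytotoxicity gate from the LDH channel, BMC10 in the increase direction
    ldh <- dplyr::filter(sub, .data$endpoint == "LDH",
                         .data$well_type == "treated")
    gate <- NULL
    if (nrow(ldh) > 0) {
      ldh_data <- tibble::tibble(
        concentration_uM = ldh$concentration_uM,
        response = ldh$response,
        block = ldh$plate_id
      )
      ldh_fit <- select_best(fit_curves(ldh_data, families))
      ldh_bmc <- estimate_bmc(ldh_fit, band = NULL, bmr = 10,
                              direction = "increase")
      gate <- gate_cytotoxicity(ldh_bmc, tested)
    }
    allowed <- if (is.null(gate)) tested else gate$allowed_concentrations
    gates[[st_key]] <- gate

    endpoints <- setdiff(unique(sub$endpoint), "LDH")
    for (ep in endpoints) {
      epd <- dplyr::filter(sub, .data$endpoint == ep,
                           .data$well_type == "treated",
                           .data$concentration_uM %in% allowed)
      data_ep <- tibble::tibble(
        concentration_uM = epd$concentration_uM,
        response = epd$response,
        block = epd$plate_id
      )
      stratum <- tibble::tibble(
        compound = st$compound, endpoint = ep,
        species = st$species, sex = st$sex
      )
      stage_seed <- child_seed(seed, paste(st_key, ep))
      fits <- fit_curves(data_ep, families, stratum = stratum)
      n_conv <- sum(vapply(fits, `[[`, TRUE, "converged"))
      fit <- tryCatch(select_best(fits), error = function(e) NULL)
      if (is.null(fit)) {
        abort(paste0("model selection failed for stratum ", st_key, "/", ep),
              class = "bmcscreen_stage_error")
      }
      band <- confidence_band(fit, n_boot = n_boot, seed = stage_seed)
      bmr_ep <- bmr_lookup(ep)
      bmc <- estimate_bmc(fit, band, bmr = bmr_ep, direction = "auto")
      sdres <- stepdown_dunnett_tamhane(data_ep, alpha = alpha,
                                        seed = stage_seed)
      hit <- classify_hit(sdres, band, bmr_ep, gate, ci_rule = ci_rule)
      bmc_rows[[paste(st_key, ep)]] <- dplyr::bind_cols(bmc, hit)
      log_rows[[paste(st_key, ep)]] <- tibble::tibble(
        stratum = st_key, endpoint = ep,
        fits_attempted = length(fits), fits_converged = n_conv,
        censored = bmc$censored, gated_out = length(tested) - length(allowed)
      )
    }
  }
  bmc_table <- dplyr::bind_rows(bmc_rows)

  mse_table <- bmc_table |>
    dplyr::group_by(.data$compound, .data$species, .data$sex) |>
    dplyr::group_modify(~ most_sensitive_endpoint(.x)) |>
    dplyr::ungroup()

  relevance_table <- NULL
  if (!is.null(reference) && !is.null(receptor_map)) {
    relevance_table <- mse_table |>
      dplyr::filter(!is.na(.data$mse)) |>
      dplyr::left_join(receptor_map, by = "compound") |>
      dplyr::mutate(bmc_nM = .data$bmc * 1000) |>
      annotate_relevance(reference)
  }

  structure(
    list(
      normalized = normalized,
      responses = responses,
      bmc_table = bmc_table,
      mse_table = mse_table,
      relevance_table = relevance_table,
      gates = gates,
      log = dplyr::bind_rows(log_rows),
      provenance = list(
        seed = seed, alpha = alpha, n_boot = n_boot, ci_rule = ci_rule,
        package_version = as.character(utils::packageVersion("bmcscreen")),
        config_hash = rlang::hash(list(seed, n_boot, alpha, families,
                                       ci_rule, default_bmr))
      )
    ),
    class = "bmc_pipeline"
  )
}

#' @export
print.bmc_pipeline <- function(x, ...) {
  cat("<bmc_pipeline> seed", x$provenance$seed, "\n")
  cat("  strata x endpoints:", nrow(x$bmc_table),
      " hits:", sum(x$bmc_table$is_hit), "\n")
  print(x$bmc_table)
  invisible(x)
}

#' Write the pipeline result bundle to CSV files
#'
#' @param result A `bmc_pipeline`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "bmc_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(result$bmc_table, file.path(dir, "bmc_summary.csv"),
                   progress = FALSE)
  readr::write_csv(result$mse_table, file.path(dir, "mse_table.csv"),
                   progress = FALSE)
  if (!is.null(result$relevance_table)) {
    readr::write_csv(result$relevance_table,
                     file.path(dir, "relevance_table.csv"), progress = FALSE)
  }
  jsonlite::write_json(result$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
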