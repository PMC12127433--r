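# Synthetic neurosphere-assay data with known ground truth.
#
# The generator reproduces the assay design: seven serial concentrations at
# dilution factor three (the top concentration a 1000-fold dilution of the
# stock), five technical replicates per condition, at least three biological
# replicates per sex, solvent and blank wells on every plate, and a paired
# cytotoxicity (LDH) channel. The noise model combines a multiplicative
# lognormal plate scale, a per-biological-replicate random effect, and
# additive Gaussian well noise, which exercises the median-based background
# correction and normalization exactly where real fluorescence data do.

#' Serial concentration ladder of the assay design
#'
#' The highest test concentration is a 1000-fold dilution of the stock
#' (1 volume into 999); successive concentrations divide by the dilution
#' factor.
#'
#' @param stock_mM Stock concentration in mM (> 0).
#' @param n_concentrations Number of test concentrations; default 7.
#' @param dilution_factor Serial dilution factor; default 3.
#' @return Numeric vector of concentrations in µM, decreasing.
#' @export
make_concentration_ladder <- function(stock_mM, n_concentrations = 7,
                                      dilution_factor = 3) {
  stopifnot(stock_mM > 0)
  top_uM <- stock_mM * 1000 / 1000  # mM -> µM, then 1:999 into medium
  top_uM * dilution_factor^(-(seq_len(n_concentrations) - 1))
}

#' Define the ground truth of a synthetic assay campaign
#'
#' @param compound Compound id.
#' @param endpoint Endpoint label (one of [endpoint_levels()]).
#' @param species,sex Stratum labels.
#' @param family_id Model family of the true effect curve.
#' @param params True parameters (% of control scale).
#' @param cytotox_params Optional true LDH-channel curve (same family
#'   mechanics, direction increase); `NULL` means no cytotoxicity (flat
#'   100 %).
#' @param cytotox_family_id Family of the cytotoxicity curve.
#' @param stock_mM Stock used to build the concentration ladder.
#' @param n_technical,n_biological Replicate structure (5 technical wells,
#'   >= 3 biological replicates).
#' @param noise_sd Additive well noise, in % of the control level.
#' @param plate_sdlog SD of the lognormal plate scale.
#' @param bio_sd SD of the multiplicative biological-replicate effect.
#' @param control_level Mean raw fluorescence of solvent wells.
#' @param background Raw background fluorescence (blank wells).
#' @param seed Integer seed; all randomness of [simulate_assay()] flows
#'   from it.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(compound = "CMP1", endpoint = "NPC1",
                             species = "human", sex = "male",
                             family_id = "loglogistic4",
                             params = c(top = 100, bottom = 20, e = 0.1, b = 1.5),
                             cytotox_params = NULL,
                             cytotox_family_id = "loglogistic4",
                             stock_mM = 5,
                             n_technical = 5, n_biological = 3,
                             noise_sd = 5, plate_sdlog = 0.05, bio_sd = 0.03,
                             control_level = 1000, background = 50,
                             seed = 1) {
  stopifnot(n_technical >= 1, n_biological >= 1)
  structure(
    list(
      compound = compound, endpoint = endpoint, species = species, sex = sex,
      family_id = family_id, params = params,
      cytotox_params = cytotox_params,
      cytotox_family_id = cytotox_family_id,
      concentrations = make_concentration_ladder(stock_mM),
      n_technical = n_technical, n_biological = n_biological,
      noise_sd = noise_sd, plate_sdlog = plate_sdlog, bio_sd = bio_sd,
      control_level = control_level, background = background,
      seed = seed
    ),
    class = "simulation_truth"
  )
}

simulate_channel <- function(truth, endpoint, fam, params, plate_meta) {
  conc_all <- c(0, sort(truth$concentrations))
  rows <- lapply(seq_len(nrow(plate_meta)), function(i) {
    pm <- plate_meta[i, ]
    truth_pct <- ifelse(conc_all == 0, 100, fam$fun(params, conc_all))
    grid <- expand.grid(concentration_uM = conc_all,
                        replicate = seq_len(truth$n_technical))
    truth_w <- rep(truth_pct, truth$n_technical)
    mu <- pm$plate_scale * truth$control_level * (truth_w / 100) *
      (1 + pm$bio_effect)
    value <- mu + rnorm(nrow(grid), 0,
                        truth$noise_sd / 100 * truth$control_level *
                          pm$plate_scale) + truth$background
    blanks <- tibble::tibble(
      concentration_uM = 0, replicate = seq_len(3),
      well_type = "blank",
      value = truth$background + rnorm(3, 0, truth$noise_sd / 100 *
                                         truth$control_level * 0.05)
    )
    treated <- tibble::tibble(
      concentration_uM = grid$concentration_uM,
      replicate = grid$replicate,
      well_type = ifelse(grid$concentration_uM == 0, "solvent", "treated"),
      value = value
    )
    out <- dplyr::bind_rows(treated, blanks)
    out$donor_id <- pm$donor_id
    out$plate_id <- pm$plate_id
    out
  })
  out <- dplyr::bind_rows(rows)
  out$compound <- truth$compound
  out$endpoint <- endpoint
  out$species <- truth$species
  out$sex <- truth$sex
  out$value <- pmax(out$value, 0)
  out[, RESPONSE_COLUMNS]
}

#' Simulate a raw plate-level assay campaign
#'
#' Generates raw well values for the endpoint channel of a
#' [simulation_truth()] and, in parallel on the same plates, the
#' cytotoxicity (LDH) channel. One biological replicate occupies one plate;
#' each plate carries treated wells at the seven ladder concentrations,
#' solvent wells (concentration 0) and blank wells. Raw values follow
#' `plate_scale x control_level x truth%/100 x (1 + bio_effect) + noise +
#' background`, clipped at 0. Identical seeds give identical tables.
#'
#' @param truth A `simulation_truth`.
#' @return Tibble in the raw response-record schema (endpoint channel plus
#'   LDH rows).
#' @export
simulate_assay <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  fam <- cr_families(truth$family_id)[[1]]
  cyto_fam <- cr_families(truth$cytotox_family_id)[[1]]
  with_seed(truth$seed, {
    plate_meta <- tibble::tibble(
      bio = seq_len(truth$n_biological),
      donor_id = sprintf("donor_%s_%02d", substr(truth$sex, 1, 1), bio),
      plate_id = sprintf("%s_%s_p%02d", truth$compound, truth$sex, bio),
      plate_scale = rlnorm(truth$n_biological, 0, truth$plate_sdlog),
      bio_effect = rnorm(truth$n_biological, 0, truth$bio_sd)
    )
    main <- simulate_channel(truth, truth$endpoint, fam, truth$params,
                             plate_meta)
    ldh <- if (!is.null(truth$cytotox_params)) {
      simulate_channel(truth, "LDH", cyto_fam, truth$cytotox_params,
                       plate_meta)
    } else NULL
    dplyr::bind_rows(main, ldh)
  })
}

#' Simulate normalized concentration-response points
#'
#' Lightweight generator for fitting studies: responses already on the % of
#' control scale, one value per (concentration, biological replicate), with
#' additive Gaussian noise.
#'
#' @param concentrations Positive test concentrations (µM).
#' @param family_id,params True curve.
#' @param n_biological Replicates per concentration.
#' @param noise_sd Gaussian noise SD in % of control.
#' @param seed Integer seed.
#' @return Tibble with `concentration_uM`, `response`, `block`.
#' @export
simulate_curve_data <- function(concentrations, family_id = "loglogistic4",
                                params = c(top = 100, bottom = 20, e = 0.1, b = 1.5),
                                n_biological = 3, noise_sd = 5, seed = 1) {
  fam <- cr_families(family_id)[[1]]
  truth_pct <- fam$fun(params, concentrations)
  with_seed(seed, {
    grid <- expand.grid(concentration_uM = concentrations,
                        block = seq_len(n_biological))
    grid$response <- rep(truth_pct, n_biological) +
      rnorm(nrow(grid), 0, noise_sd)
    tibble::as_tibble(grid[, c("concentration_uM", "response", "block")])
  })
}

#' Simulate a DEG table with planted truth
#'
#' Planted genes satisfy all three DEG criteria; non-planted genes violate
#' at least one (small fold change, low FPKM, or non-significant q-value).
#'
#' @param n_genes Total genes.
#' @param n_planted Number of true DEGs (<= `n_genes`).
#' @param lfc_range Absolute log2 fold-change range of planted genes
#'   (must exceed the 0.486 cutoff).
#' @param seed Integer seed.
#' @return Tibble with `gene`, `log2_fc`, `fpkm`, `q_value` and the truth
#'   label `planted`.
#' @export
simulate_deg_table <- function(n_genes = 1000, n_planted = 100,
                               lfc_range = c(0.6, 2.5), seed = 1) {
  stopifnot(n_planted <= n_genes, lfc_range[1] > 0.486)
  with_seed(seed, {
    gene <- sprintf("G%05d", seq_len(n_genes))
    planted <- seq_len(n_genes) <= n_planted
    sign_ <- sample(c(-1, 1), n_genes, replace = TRUE)
    lfc <- numeric(n_genes); fpkm <- numeric(n_genes); q <- numeric(n_genes)
    # planted: pass all criteria
    lfc[planted] <- sign_[planted] * runif(n_planted, lfc_range[1], lfc_range[2])
    fpkm[planted] <- runif(n_planted, 1, 100)
    q[planted] <- runif(n_planted, 0, 0.049)
    # non-planted: pick one criterion to violate; others drawn freely
    n0 <- n_genes - n_planted
    mode <- sample(1:3, n0, replace = TRUE)
    lfc0 <- sign_[!planted] * runif(n0, 0.6, 2.5)
    lfc0[mode == 1] <- sign_[!planted][mode == 1] * runif(sum(mode == 1), 0, 0.486)
    fpkm0 <- runif(n0, 1, 100)
    fpkm0[mode == 2] <- runif(sum(mode == 2), 0, 0.999)
    q0 <- runif(n0, 0, 0.049)
    q0[mode == 3] <- runif(sum(mode == 3), 0.05, 1)
    lfc[!planted] <- lfc0; fpkm[!planted] <- fpkm0; q[!planted] <- q0
    tbl <- tibble::tibble(gene = gene, log2_fc = lfc, fpkm = fpkm,
                          q_value = q, planted = planted)
    tbl[sample.int(n_genes), ]
  })
}
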