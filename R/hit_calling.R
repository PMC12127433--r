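# Hit classification for concentration-response screening.
#
# Significance testing uses the Dunnett-Tamhane step-down many-to-one
# procedure on Welch (unequal-variance) t statistics: comparisons of each
# concentration group against the reference (lowest tested concentration)
# are ordered by |t|, and at each step the adjusted p-value is the tail
# probability of the maximum of the remaining comparisons' joint null
# distribution, evaluated by seeded Monte Carlo with the correlation induced
# by the shared reference group. The final remaining comparison uses the
# exact Welch t p-value, so the two-group case reduces to the Welch t-test.

welch_stat <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, df = df)
}

#' Dunnett-Tamhane step-down many-to-one test
#'
#' @param data Data frame with one row per biological-replicate observation.
#' @param group Name of the grouping column (numeric concentration or ordered
#'   group labels); the reference is the lowest group unless given.
#' @param value Name of the response column.
#' @param reference Optional reference group id; default the lowest group.
#' @param alpha Family-wise error level; default 0.05.
#' @param n_mc Monte-Carlo draws for the max-|t| critical values; default 10000.
#' @param seed Integer seed for the Monte-Carlo draws.
#' @return A `stepdown_result`: list with a `comparisons` tibble (ordered by
#'   rejection rank, with `raw_t`, `df`, `raw_p`, `adjusted_p`, `rejected`),
#'   `reference`, `alpha` and `seed`.
#' @export
stepdown_dunnett_tamhane <- function(data, group = "concentration_uM",
                                     value = "response", reference = NULL,
                                     alpha = 0.05, n_mc = 10000, seed = 1) {
  g <- data[[group]]
  v <- data[[value]]
  levels_ <- sort(unique(g))
  if (length(levels_) < 2) {
    abort("at least 2 groups are required", class = "bmcscreen_validation_error")
  }
  reference <- reference %||% levels_[1]
  if (!reference %in% levels_) {
    abort("reference group not present in the data",
          class = "bmcscreen_validation_error")
  }
  sets <- lapply(levels_, function(l) v[g == l])
  names(sets) <- as.character(levels_)
  n_i <- lengths(sets)
  if (any(n_i < 2)) {
    abort(
      paste0("insufficient replication (need >= 2 values per group) in group(s): ",
             paste(levels_[n_i < 2], collapse = ", ")),
      class = "bmcscreen_replication_error"
    )
  }
  ref_vals <- sets[[as.character(reference)]]
  cmp_levels <- levels_[levels_ != reference]
  stats_ <- lapply(cmp_levels, function(l) welch_stat(sets[[as.character(l)]], ref_vals))
  t_obs <- vapply(stats_, `[[`, 0, "t")
  df_obs <- vapply(stats_, `[[`, 0, "df")
  raw_p <- 2 * pt(-abs(t_obs), df_obs)

  ord <- order(-abs(t_obs))
  K <- length(ord)

  # Monte-Carlo draws of the joint null Welch-t vector (plug-in variances,
  # chi-square variance draws, shared reference draw -> many-to-one
  # correlation). Rows: draws, columns: comparisons in `cmp_levels` order.
  s2 <- vapply(sets, stats::var, 0)
  n_all <- lengths(sets)
  ref_ix <- match(as.character(reference), names(sets))
  cmp_ix <- match(as.character(cmp_levels), names(sets))
  Tmc <- with_seed(child_seed(seed, "stepdown"), {
    m <- matrix(rnorm(n_mc * length(sets)), n_mc) *
      rep(sqrt(s2 / n_all), each = n_mc)
    vdf <- n_all - 1
    vv <- matrix(rchisq(n_mc * length(sets), df = rep(vdf, each = n_mc)), n_mc) *
      rep(s2 / vdf, each = n_mc)
    num <- m[, cmp_ix, drop = FALSE] - m[, ref_ix]
    den <- sqrt(sweep(vv[, cmp_ix, drop = FALSE], 2, n_all[cmp_ix], `/`) +
                  vv[, ref_ix] / n_all[ref_ix])
    abs(num / den)
  })

  p_step <- numeric(K)
  for (k in seq_len(K)) {
    remaining <- ord[k:K]
    if (length(remaining) == 1) {
      p_step[k] <- raw_p[remaining]
    } else {
      maxT <- do.call(pmax, as.data.frame(Tmc[, remaining, drop = FALSE]))
      # adjusted p can never undercut the exact marginal Welch p
      p_step[k] <- max(mean(maxT >= abs(t_obs[ord[k]])), raw_p[ord[k]])
    }
  }
  adj_p <- cummax(p_step)
  rejected <- logical(K)
  for (k in seq_len(K)) {
    if (adj_p[k] <= alpha && (k == 1 || rejected[k - 1])) {
      rejected[k] <- TRUE
    } else break
  }
  comparisons <- tibble::tibble(
    group = cmp_levels[ord],
    reference = reference,
    n = n_all[cmp_ix][ord],
    raw_t = t_obs[ord],
    df = df_obs[ord],
    raw_p = raw_p[ord],
    adjusted_p = adj_p,
    rejected = rejected,
    rank = seq_len(K)
  )
  structure(
    list(comparisons = comparisons, reference = reference,
         alpha = alpha, n_mc = n_mc, seed = seed),
    class = "stepdown_result"
  )
}

#' @export
print.stepdown_result <- function(x, ...) {
  cat(sprintf("<stepdown_result> reference = %s, alpha = %g\n",
              format(x$reference), x$alpha))
  print(x$comparisons)
  invisible(x)
}

#' Classify a compound/endpoint stratum as a hit
#'
#' Applies the dual hit rule: a stratum is a hit if (a) the highest
#' non-cytotoxic concentration differs significantly from the lowest tested
#' concentration under the step-down procedure (`stat_test`), and/or (b) the
#' complete confidence band of the fitted curve crosses the BMR line at some
#' allowed concentration, i.e. both band edges lie beyond `100 - bmr`
#' (decrease line) or beyond `100 + bmr` (increase line) (`ci_crossing`).
#' The weaker single-edge reading of (b) is available via `ci_rule`.
#'
#' @param stepdown A `stepdown_result` computed on gated concentrations.
#' @param band A `cr_band` fitted on gated concentrations.
#' @param bmr `bmr_percent` number or [derive_bmr()] row.
#' @param gate A `cytotox_gate`; when `NULL` all tested concentrations are
#'   treated as allowed.
#' @param ci_rule `"both_edges"` (default) or `"either_edge"`.
#' @return One-row tibble: `is_hit`, `basis` (comma-joined subset of
#'   `stat_test`, `ci_crossing`), plus the two indicator columns.
#' @export
classify_hit <- function(stepdown, band, bmr, gate = NULL,
                         ci_rule = c("both_edges", "either_edge")) {
  ci_rule <- match.arg(ci_rule)
  bmr_percent <- if (is.data.frame(bmr)) bmr$bmr_percent[1] else as.numeric(bmr)
  allowed <- gate$allowed_concentrations %||%
    unique(stepdown$comparisons$group)

  top_allowed <- max(allowed)
  cmp <- stepdown$comparisons
  in_gate <- cmp$group <= top_allowed + 1e-12
  stat_test <- any(in_gate) &&
    cmp$rejected[in_gate][which.max(cmp$group[in_gate])]

  test_conc <- allowed[allowed >= min(band$grid) & allowed <= max(band$grid)]
  lo <- approx(log(band$grid), band$lower, xout = log(test_conc),
               ties = "ordered")$y
  hi <- approx(log(band$grid), band$upper, xout = log(test_conc),
               ties = "ordered")$y
  below_line <- 100 - bmr_percent
  above_line <- 100 + bmr_percent
  ci_crossing <- if (ci_rule == "both_edges") {
    any(hi <= below_line) || any(lo >= above_line)
  } else {
    any(lo <= below_line) || any(hi >= above_line)
  }

  basis <- c(if (isTRUE(stat_test)) "stat_test",
             if (isTRUE(ci_crossing)) "ci_crossing")
  tibble::tibble(
    is_hit = length(basis) > 0,
    basis = paste(basis, collapse = "+"),
    stat_test = isTRUE(stat_test),
    ci_crossing = isTRUE(ci_crossing)
  )
}

#' Determine the most sensitive endpoint (MSE)
#'
#' Among non-censored hits for one receptor modulator, the endpoint with the
#' lowest BMC. Endpoints whose BMCs lie within each other's [BMCL, BMCU]
#' intervals are reported as a tie set (no clear MSE).
#'
#' @param bmc_table Tibble with columns `endpoint`, `bmc`, `bmcl`, `bmcu`,
#'   `censored` and `is_hit`.
#' @return One-row tibble: `mse` (endpoint id or `NA` when there is no hit),
#'   `bmc`, `tie` and `tie_set` (comma-joined endpoints, including the MSE,
#'   when no clear winner exists).
#' @export
most_sensitive_endpoint <- function(bmc_table) {
  cand <- dplyr::filter(tibble::as_tibble(bmc_table),
                        .data$is_hit, !.data$censored, is.finite(.data$bmc))
  if (nrow(cand) == 0) {
    return(tibble::tibble(mse = NA_character_, bmc = NA_real_,
                          tie = FALSE, tie_set = NA_character_))
  }
  cand <- dplyr::arrange(cand, .data$bmc)
  best <- cand[1, ]
  mutual_tie <- function(a, b) {
    ok_ab <- !is.na(b$bmcl) && !is.na(b$bmcu) &&
      a$bmc >= b$bmcl && a$bmc <= b$bmcu
    ok_ba <- !is.na(a$bmcl) && !is.na(a$bmcu) &&
      b$bmc >= a$bmcl && b$bmc <= a$bmcu
    ok_ab && ok_ba
  }
  ties <- best$endpoint
  if (nrow(cand) > 1) {
    for (i in 2:nrow(cand)) {
      if (mutual_tie(best, cand[i, ])) ties <- c(ties, cand$endpoint[i])
    }
  }
  tibble::tibble(
    mse = best$endpoint,
    bmc = best$bmc,
    tie = length(ties) > 1,
    tie_set = if (length(ties) > 1) paste(ties, collapse = ",") else NA_character_
  )
}

#' Assess an antagonist rescue (co-exposure) experiment
#'
#' An agonist applied at its BMC30 is co-exposed with serial antagonist
#' dilutions. The agonist effect is tested against the solvent control with a
#' two-tailed Welch t-test; the antagonist series is tested against the
#' agonist-alone arm with the step-down procedure. The phenotype counts as
#' antagonized (receptor-specific) when the agonist effect is significant and
#' at least one antagonist concentration is significantly shifted back toward
#' the solvent-control level.
#'
#' @param solvent Numeric responses of the solvent-control arm.
#' @param agonist_alone Numeric responses of the agonist-only arm (BMC30 dose).
#' @param antagonist_series Data frame with columns `concentration_uM`
#'   (antagonist dose) and `response`; at least 2 doses, 2 replicates each.
#' @param alpha Significance level; default 0.05.
#' @param n_mc,seed Monte-Carlo settings for the step-down test.
#' @return List of class `rescue_result`: `agonist_effect_p`,
#'   `antagonist_comparisons` (a `stepdown_result`), `antagonized`.
#' @export
assess_rescue <- function(solvent, agonist_alone, antagonist_series,
                          alpha = 0.05, n_mc = 10000, seed = 1) {
  if (length(agonist_alone) < 2) {
    abort("agonist-alone arm with >= 2 replicates is required",
          class = "bmcscreen_design_error")
  }
  antagonist_series <- tibble::as_tibble(antagonist_series)
  if (length(unique(antagonist_series$concentration_uM)) < 2) {
    abort("at least 2 antagonist concentrations are required",
          class = "bmcscreen_design_error")
  }
  agonist_p <- t.test(agonist_alone, solvent)$p.value
  # reference arm = agonist alone, encoded as antagonist dose 0
  combined <- dplyr::bind_rows(
    tibble::tibble(concentration_uM = 0, response = agonist_alone),
    antagonist_series[, c("concentration_uM", "response")]
  )
  sd_res <- stepdown_dunnett_tamhane(combined, alpha = alpha,
                                     n_mc = n_mc, seed = seed)
  # rescue must move the response back toward the solvent level
  toward_solvent <- sign(mean(solvent) - mean(agonist_alone))
  cmp <- sd_res$comparisons
  rescued <- any(cmp$rejected & sign(cmp$raw_t) == toward_solvent)
  structure(
    list(
      agonist_effect_p = agonist_p,
      antagonist_comparisons = sd_res,
      antagonized = agonist_p <= alpha && rescued
    ),
    class = "rescue_result"
  )
}

#' @export
print.rescue_result <- function(x, ...) {
  cat(sprintf("<rescue_result> agonist effect p = %.4g; antagonized: %s\n",
              x$agonist_effect_p, x$antagonized))
  invisible(x)
}

#' Compare hit calls and BMCs across strata (sex or species)
#'
#' @param bmc_table Tibble with one row per (stratum, endpoint): columns
#'   `stratum`, `endpoint`, `is_hit`, `bmc`, `bmcl`, `bmcu`, `censored`.
#' @return Tibble per endpoint: `status` in
#'   `concordant-hit` / `concordant-no-hit` / `discordant`; for concordant
#'   hits the sensitivity ratio `bmc_ratio` (= BMC of the first stratum over
#'   the second, strata in sort order) and `ci_nonoverlap`, flagged when the
#'   two confidence intervals do not overlap.
#' @export
compare_strata <- function(bmc_table) {
  tbl <- tibble::as_tibble(bmc_table)
  stopifnot(all(c("stratum", "endpoint", "is_hit", "bmc") %in% names(tbl)))
  out <- lapply(split(tbl, tbl$endpoint), function(d) {
    d <- dplyr::arrange(d, .data$stratum)
    if (nrow(d) != 2) {
      abort("compare_strata expects exactly 2 strata per endpoint",
            class = "bmcscreen_validation_error")
    }
    a <- d[1, ]; b <- d[2, ]
    hit_a <- isTRUE(a$is_hit) && !isTRUE(a$censored)
    hit_b <- isTRUE(b$is_hit) && !isTRUE(b$censored)
    status <- if (hit_a && hit_b) "concordant-hit"
      else if (!hit_a && !hit_b) "concordant-no-hit"
      else "discordant"
    ratio <- if (status == "concordant-hit") a$bmc / b$bmc else NA_real_
    nonoverlap <- if (status == "concordant-hit" &&
                        !anyNA(c(a$bmcl, a$bmcu, b$bmcl, b$bmcu))) {
      a$bmcu < b$bmcl || b$bmcu < a$bmcl
    } else NA
    tibble::tibble(
      endpoint = a$endpoint,
      stratum_a = as.character(a$stratum),
      stratum_b = as.character(b$stratum),
      status = status,
      bmc_a = a$bmc, bmc_b = b$bmc,
      bmc_ratio = ratio,
      ci_nonoverlap = nonoverlap
    )
  })
  dplyr::bind_rows(out)
}
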