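# Benchmark-response and benchmark-concentration estimation.
#
# The benchmark response (BMR) is derived from historical control
# variability: the coefficient of variation of normalized responses at the
# lowest tested concentration, scaled by 1.5 and rounded to the nearest
# multiple of 5 (half-up), with a floor of 5 %. The BMC is the lowest
# concentration in the tested range at which the fitted curve departs from
# the 100 % control level by at least the BMR; its confidence bounds BMCL
# and BMCU are the analogous first crossings of the bootstrap band edges.

#' Derive the benchmark response from historical control variability
#'
#' @param values Normalized responses (% of control) of the lowest tested
#'   concentration across historical experiments; at least 2 values.
#' @param endpoint Optional endpoint label carried into the result.
#' @return One-row tibble with `endpoint`, `cv` (sd/mean), `bmr_percent`
#'   (multiple of 5, floored at 5) and `n_experiments`.
#' @export
derive_bmr <- function(values, endpoint = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    abort("at least 2 historical values are required",
          class = "bmcscreen_validation_error")
  }
  m <- mean(values)
  if (m <= 0) {
    abort("mean of historical responses must be positive",
          class = "bmcscreen_validation_error")
  }
  cv <- sd(values) / m
  bmr <- max(5, round_to_multiple(cv * 150, 5))
  tibble::tibble(
    endpoint = endpoint,
    cv = cv,
    bmr_percent = bmr,
    n_experiments = length(values)
  )
}

# First concentration in [cmin, cmax] at which `fun` (a function of
# concentration) is beyond `threshold` in `direction`; NA when no crossing.
# Dense log-grid scan with uniroot refinement; exact to ~1e-9 relative.
first_crossing <- function(fun, cmin, cmax, threshold, direction,
                           n_grid = 1024) {
  beyond <- if (direction == "decrease") {
    function(y) y <= threshold
  } else {
    function(y) y >= threshold
  }
  grid <- exp(seq(log(cmin), log(cmax), length.out = n_grid))
  vals <- fun(grid)
  hit <- which(beyond(vals))
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(cmin)
  g <- function(c) fun(c) - threshold
  root <- tryCatch(
    uniroot(g, lower = grid[i - 1], upper = grid[i], tol = cmin * 1e-12)$root,
    error = function(e) grid[i]
  )
  root
}

# First-crossing of a band edge known only at grid points: scan the grid,
# then linearly interpolate in log-concentration between the bracketing
# points.
first_crossing_grid <- function(grid, vals, cmin, cmax, threshold, direction) {
  keep <- grid >= cmin & grid <= cmax
  grid <- grid[keep]; vals <- vals[keep]
  if (length(grid) == 0) return(NA_real_)
  beyond <- if (direction == "decrease") vals <= threshold else vals >= threshold
  hit <- which(beyond)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(grid[1])
  x0 <- log(grid[i - 1]); x1 <- log(grid[i])
  y0 <- vals[i - 1]; y1 <- vals[i]
  if (y1 == y0) return(grid[i])
  exp(x0 + (threshold - y0) * (x1 - x0) / (y1 - y0))
}

#' Estimate the benchmark concentration (BMC) with confidence bounds
#'
#' The BMC is the first in-range crossing, scanning from the lowest tested
#' concentration upward, of the fitted curve with the BMR line
#' `100 - bmr_percent` (decrease) or `100 + bmr_percent` (increase). BMCL and
#' BMCU are the first crossings of the band edge that reaches the BMR line
#' earlier resp. later. A fit that never reaches the BMR line within the
#' tested range yields a censored result, not an error.
#'
#' @param fit A converged `cr_fit`.
#' @param band Optional `cr_band` from [confidence_band()]; when absent,
#'   BMCL/BMCU are `NA`.
#' @param bmr A `bmr_percent` number or the one-row tibble from
#'   [derive_bmr()].
#' @param direction `"decrease"`, `"increase"`, or `"auto"` (sign of the
#'   fitted effect at the highest tested concentration).
#' @param conc_range Concentration range to search; defaults to the positive
#'   tested range of the fit.
#' @return One-row tibble with `bmr_percent`, `direction`, `bmc`, `bmcl`,
#'   `bmcu` (µM), `censored` and `family_id`, prefixed by any stratum
#'   columns stored on the fit.
#' @export
estimate_bmc <- function(fit, band = NULL, bmr,
                         direction = c("auto", "decrease", "increase"),
                         conc_range = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(fit, "cr_fit"))
  if (!fit$converged) {
    abort("BMC estimation requires a converged fit",
          class = "bmcscreen_validation_error")
  }
  bmr_percent <- if (is.data.frame(bmr)) bmr$bmr_percent[1] else as.numeric(bmr)
  conc <- fit$data$concentration_uM
  cpos <- conc[conc > 0]
  cmin <- if (is.null(conc_range)) min(cpos) else conc_range[1]
  cmax <- if (is.null(conc_range)) max(cpos) else conc_range[2]

  f <- function(c) fit$family$fun(fit$params, c)
  if (direction == "auto") {
    direction <- if (f(cmax) < 100) "decrease" else "increase"
  }
  threshold <- if (direction == "decrease") 100 - bmr_percent else 100 + bmr_percent

  bmc <- first_crossing(f, cmin, cmax, threshold, direction)
  bmcl <- bmcu <- NA_real_
  if (!is.null(band) && !is.na(bmc)) {
    # the edge closer to the BMR line crosses first and gives the lower bound
    if (direction == "decrease") {
      bmcl <- first_crossing_grid(band$grid, band$lower, cmin, cmax,
                                  threshold, direction)
      bmcu <- first_crossing_grid(band$grid, band$upper, cmin, cmax,
                                  threshold, direction)
    } else {
      bmcl <- first_crossing_grid(band$grid, band$upper, cmin, cmax,
                                  threshold, direction)
      bmcu <- first_crossing_grid(band$grid, band$lower, cmin, cmax,
                                  threshold, direction)
    }
  }
  res <- tibble::tibble(
    bmr_percent = bmr_percent,
    direction = direction,
    bmc = bmc,
    bmcl = bmcl,
    bmcu = bmcu,
    censored = is.na(bmc),
    family_id = fit$family_id
  )
  if (!is.null(fit$stratum)) {
    res <- dplyr::bind_cols(tibble::as_tibble(fit$stratum), res)
  }
  res
}

#' Gate test concentrations on cytotoxicity
#'
#' Concentrations above the BMC10 of the cytotoxicity (membrane-integrity)
#' channel are excluded from all downstream endpoint analysis, so that
#' specific effects on neurodevelopmental endpoints are not confounded with
#' unspecific cell death. A censored cytotoxicity BMC (never reaching 10 %
#' above control) leaves all concentrations allowed.
#'
#' @param ldh_bmc One-row BMC tibble for the cytotoxicity endpoint, computed
#'   with `bmr_percent = 10` and `direction = "increase"`.
#' @param tested_concentrations Positive tested concentrations (µM).
#' @return A `cytotox_gate`: list with `bmc10_cytotox` (µM or `NA` when
#'   censored) and `allowed_concentrations`.
#' @export
gate_cytotoxicity <- function(ldh_bmc, tested_concentrations) {
  stopifnot(is.data.frame(ldh_bmc), nrow(ldh_bmc) == 1)
  if (ldh_bmc$bmr_percent != 10 || ldh_bmc$direction != "increase") {
    abort("cytotoxicity gating requires a BMC10 with direction 'increase'",
          class = "bmcscreen_validation_error")
  }
  tested <- sort(unique(tested_concentrations[tested_concentrations > 0]))
  allowed <- if (ldh_bmc$censored) tested else tested[tested <= ldh_bmc$bmc]
  if (length(allowed) == 0) {
    abort(
      "cytotoxicity BMC10 lies below the lowest tested concentration: compound untestable",
      class = "bmcscreen_gating_error"
    )
  }
  structure(
    list(
      bmc10_cytotox = if (ldh_bmc$censored) NA_real_ else ldh_bmc$bmc,
      allowed_concentrations = allowed,
      censored = ldh_bmc$censored
    ),
    class = "cytotox_gate"
  )
}

#' @export
print.cytotox_gate <- function(x, ...) {
  cat("<cytotox_gate> BMC10:",
      if (x$censored) "censored (no cytotoxicity in range)"
      else sprintf("%.4g uM", x$bmc10_cytotox),
      "\n  allowed:", paste(signif(x$allowed_concentrations, 4), collapse = ", "),
      "uM\n")
  invisible(x)
}
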