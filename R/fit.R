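# Curve fitting over the model catalog.
#
# All fitting happens on normalized responses (% of solvent control) against
# concentration in µM. Internally the optimizer works on the family's native
# parameter scale with box bounds; concentration enters each family through
# log-concentration terms with the zero-concentration control asymptote
# handled in closed form by the evaluator.

new_cr_fit <- function(family, params, data, converged,
                       stratum = NULL, weights = NULL) {
  n <- nrow(data)
  k <- family$n_params + 1  # + residual variance
  if (converged) {
    pred <- family$fun(params, data$concentration_uM)
    rss <- sum((data$response - pred)^2 * (weights %||% 1))
    residual_sd <- sqrt(rss / max(n - family$n_params, 1))
    aicc <- if (n - k - 1 > 0) {
      n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    } else Inf
  } else {
    params <- rep(NA_real_, family$n_params)
    rss <- NA_real_; residual_sd <- NA_real_; aicc <- Inf
  }
  structure(
    list(
      family_id = family$family_id,
      family = family,
      params = setNames(params, family$param_names),
      fit_score = aicc,
      rss = rss,
      residual_sd = residual_sd,
      converged = converged,
      n = n,
      data = data,
      stratum = stratum
    ),
    class = "cr_fit"
  )
}

#' Fit one model family to concentration-response data
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) from a deterministic
#' grid of starting values; the best start by residual sum of squares wins.
#' Optimizer failure is reported through `converged = FALSE`, never as an
#' error, so that catalog-wide fitting can proceed.
#'
#' @param data Data frame with columns `concentration_uM` and `response`
#'   (% of control), optionally `block` identifying the biological replicate
#'   each point belongs to (used by [confidence_band()]).
#' @param family A `cr_family` object or family id (see [cr_families()]).
#' @param weights Optional non-negative case weights.
#' @param stratum Optional named list or tibble row describing the
#'   (compound, endpoint, species, sex) stratum, carried into results.
#' @return A `cr_fit` object with parameters, small-sample-corrected AIC
#'   (`fit_score`), residual SD and convergence flag.
#' @export
fit_family <- function(data, family, weights = NULL, stratum = NULL) {
  if (is.character(family)) family <- cr_families(family)[[1]]
  data <- tibble::as_tibble(data)
  stopifnot(all(c("concentration_uM", "response") %in% names(data)))
  data <- data[is.finite(data$response), ]
  conc <- data$concentration_uM
  resp <- data$response
  n_distinct <- length(unique(conc))
  if (n_distinct < family$n_params) {
    abort(
      paste0("degenerate design: ", n_distinct, " distinct concentrations for ",
             family$n_params, "-parameter family ", family$family_id),
      class = "bmcscreen_design_error"
    )
  }
  w <- sqrt(weights %||% rep(1, length(resp)))
  bounds <- family$bounds(conc, resp)
  starts <- family$starts(conc, resp)

  resid_fun <- function(p) (resp - family$fun(p, conc)) * w

  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, bounds$lower), bounds$upper)
    ans <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = p0, fn = resid_fun,
        lower = bounds$lower, upper = bounds$upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (is.null(ans) || !ans$info %in% 1:4) next
    rss <- sum(ans$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(par = ans$par, rss = rss)
  }
  if (is.null(best)) {
    return(new_cr_fit(family, NULL, data, converged = FALSE, stratum = stratum))
  }
  new_cr_fit(family, best$par, data, converged = TRUE,
             stratum = stratum, weights = weights)
}

#' Fit every family in a catalog
#'
#' @inheritParams fit_family
#' @param families Character vector of family ids or a catalog list;
#'   default the full 13-family catalog.
#' @return A list of `cr_fit` objects (class `cr_fit_set`), in catalog order.
#' @export
fit_curves <- function(data, families = NULL, weights = NULL, stratum = NULL) {
  cat_ <- if (is.list(families) && !is.character(families)) {
    families
  } else {
    cr_families(families)
  }
  fits <- lapply(cat_, function(f) {
    tryCatch(
      fit_family(data, f, weights, stratum),
      bmcscreen_design_error = function(e) {
        new_cr_fit(f, NULL, tibble::as_tibble(data), converged = FALSE,
                   stratum = stratum)
      }
    )
  })
  structure(fits, class = "cr_fit_set")
}

#' Select the best-fitting model
#'
#' Among converged fits, picks the minimizer of the small-sample-corrected
#' AIC; exact ties are broken by fewer parameters, then by fixed catalog
#' order. Families whose parameter count leaves no residual degrees of
#' freedom get an infinite score and are never selected while a finite-score
#' candidate exists.
#'
#' @param fits A `cr_fit_set` or list of `cr_fit` objects.
#' @return The winning `cr_fit`.
#' @export
select_best <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$converged) && is.finite(f$fit_score), fits)
  if (length(conv) == 0) {
    diag_ <- vapply(fits, function(f) {
      paste0(f$family_id, ": ",
             if (isTRUE(f$converged)) "no residual df" else "did not converge")
    }, "")
    abort(
      paste0("no converged fit among candidates (",
             paste(diag_, collapse = "; "), ")"),
      class = "bmcscreen_selection_error"
    )
  }
  order_in_catalog <- match(
    vapply(conv, `[[`, "", "family_id"), names(cr_families())
  )
  score <- vapply(conv, `[[`, 0, "fit_score")
  npar <- vapply(conv, function(f) f$family$n_params, 0)
  best <- order(score, npar, order_in_catalog)[1]
  conv[[best]]
}

#' Predict from a fitted curve
#'
#' @param object A `cr_fit`.
#' @param conc Concentrations (µM) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Numeric vector of predicted responses (% of control).
#' @export
predict.cr_fit <- function(object, conc = NULL, ...) {
  if (!object$converged) {
    abort("cannot predict from a non-converged fit",
          class = "bmcscreen_validation_error")
  }
  conc <- conc %||% object$data$concentration_uM
  object$family$fun(object$params, conc)
}

#' @export
print.cr_fit <- function(x, ...) {
  cat("<cr_fit> family:", x$family_id,
      if (x$converged) "" else "(NOT converged)", "\n")
  if (x$converged) {
    cat("  params:", paste(sprintf("%s=%.4g", names(x$params), x$params),
                           collapse = ", "), "\n")
    cat(sprintf("  AICc: %.3f  residual SD: %.2f %%  n: %d\n",
                x$fit_score, x$residual_sd, x$n))
  }
  invisible(x)
}

band_grid <- function(conc, n_grid = 201) {
  cpos <- sort(unique(conc[conc > 0]))
  grid <- exp(seq(log(min(cpos)), log(max(cpos)), length.out = n_grid))
  sort(unique(c(grid, cpos)))
}

#' Bootstrap confidence band for a fitted curve
#'
#' Nonparametric case-resampling bootstrap: within each biological-replicate
#' block, the (concentration, response) pairs are resampled with replacement
#' and the selected family refit; the bootstrap predictions over a
#' log-spaced concentration grid (always including the tested
#' concentrations) form the band. The default `"simultaneous"` band is a
#' sup-t band — deviations from the pointwise bootstrap center are
#' studentized by the pointwise bootstrap SD and the band half-width chosen
#' so that the whole curve lies inside for a `level` fraction of resamples —
#' which is the band the "complete confidence interval" hit rule and the
#' BMCL/BMCU bounds refer to. `"pointwise"` gives percentile bounds per grid
#' point. Reproducible under a fixed seed.
#'
#' @param fit A converged `cr_fit` whose data carry a `block` column (absent
#'   blocks are treated as one block).
#' @param level Band level; default 0.95.
#' @param n_boot Number of bootstrap resamples (>= 100); default 1000.
#' @param seed Integer seed.
#' @param n_grid Number of log-spaced grid points.
#' @param type `"simultaneous"` (default) or `"pointwise"`.
#' @return A `cr_band` with `grid`, `fitted`, `lower`, `upper`.
#' @export
confidence_band <- function(fit, level = 0.95, n_boot = 1000, seed = 1,
                            n_grid = 101,
                            type = c("simultaneous", "pointwise")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "cr_fit"))
  if (!fit$converged) {
    abort("confidence band requires a converged fit",
          class = "bmcscreen_validation_error")
  }
  if (n_boot < 100) {
    abort("n_boot must be at least 100", class = "bmcscreen_config_error")
  }
  data <- fit$data
  if (!"block" %in% names(data)) data$block <- 1L
  grid <- band_grid(data$concentration_uM, n_grid)
  fitted <- fit$family$fun(fit$params, grid)
  blocks <- split(seq_len(nrow(data)), data$block)
  family <- fit$family
  bounds <- family$bounds(data$concentration_uM, data$response)

  preds <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, length(grid))
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(blocks, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      conc_b <- data$concentration_uM[idx]
      resp_b <- data$response[idx]
      resid_fun <- function(p) resp_b - family$fun(p, conc_b)
      ans <- tryCatch(
        suppressWarnings(minpack.lm::nls.lm(
          par = fit$params, fn = resid_fun,
          lower = bounds$lower, upper = bounds$upper,
          control = minpack.lm::nls.lm.control(maxiter = 100)
        )),
        error = function(e) NULL
      )
      if (!is.null(ans) && ans$info %in% 1:4) {
        out[b, ] <- family$fun(ans$par, grid)
      }
    }
    out
  })
  ok <- stats::complete.cases(preds)
  if (sum(ok) < n_boot * 0.5) {
    abort("more than half of bootstrap refits failed",
          class = "bmcscreen_bootstrap_error")
  }
  P <- preds[ok, , drop = FALSE]
  if (type == "pointwise") {
    alpha <- (1 - level) / 2
    lower <- apply(P, 2, quantile, probs = alpha, names = FALSE)
    upper <- apply(P, 2, quantile, probs = 1 - alpha, names = FALSE)
  } else {
    center <- apply(P, 2, median)
    scale <- pmax(apply(P, 2, sd), 1e-9)
    dev <- apply(abs(sweep(sweep(P, 2, center), 2, scale, "/")), 1, max)
    cstar <- quantile(dev, probs = level, names = FALSE)
    lower <- center - cstar * scale
    upper <- center + cstar * scale
  }
  structure(
    list(
      level = level,
      type = type,
      grid = grid,
      fitted = fitted,
      lower = pmin(lower, fitted),
      upper = pmax(upper, fitted),
      method = "bootstrap",
      n_boot = n_boot,
      n_ok = sum(ok),
      seed = seed,
      family_id = fit$family_id
    ),
    class = "cr_band"
  )
}

#' @export
print.cr_band <- function(x, ...) {
  cat(sprintf("<cr_band> %.0f %% bootstrap band (%d/%d resamples), %s, %d grid points\n",
              100 * x$level, x$n_ok, x$n_boot, x$family_id, length(x$grid)))
  invisible(x)
}

#' Serialize a fit (with optional band) to JSON
#'
#' @param fit A `cr_fit`.
#' @param band Optional `cr_band`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return JSON string, invisibly when written to `path`.
#' @export
fit_to_json <- function(fit, band = NULL, path = NULL) {
  obj <- list(
    family_id = fit$family_id,
    params = as.list(fit$params),
    fit_score = fit$fit_score,
    residual_sd = fit$residual_sd,
    converged = fit$converged
  )
  if (!is.null(band)) {
    obj$band <- list(
      level = band$level, seed = band$seed, n_boot = band$n_boot,
      grid = band$grid, lower = band$lower, upper = band$upper
    )
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
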