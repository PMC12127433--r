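# Concentration-response model catalog.
#
# Thirteen families spanning the linear, sigmoidal, monotone and non-monotone
# classes used in benchmark-concentration screening. Each family declares a
# vectorized evaluator f(params, conc) defined for all conc >= 0 (the response
# at conc = 0 is the family's control asymptote in closed form -- log(0) is
# never taken), deterministic multi-start initial values, and box bounds that
# keep asymptotes within [-50, 250] % of control, half-maximal concentrations
# within [min tested / 100, max tested * 100], and slopes within [-20, 20].

new_family <- function(family_id, param_names, monotone, fun, starts, bounds) {
  structure(
    list(
      family_id = family_id,
      param_names = param_names,
      n_params = length(param_names),
      monotone = monotone,
      fun = fun,
      starts = starts,
      bounds = bounds
    ),
    class = "cr_family"
  )
}

#' @export
print.cr_family <- function(x, ...) {
  cat("<cr_family> ", x$family_id, ": ", x$n_params, " params (",
      paste(x$param_names, collapse = ", "), "), ",
      if (x$monotone) "monotone" else "non-monotone", "\n", sep = "")
  invisible(x)
}

# Shared helpers: power term (c/e)^b evaluated safely at c = 0 for b > 0.
pow_ratio <- function(conc, e, b) {
  out <- rep(0, length(conc))
  pos <- conc > 0
  out[pos] <- exp(b * (log(conc[pos]) - log(e)))
  out
}

asym_lo <- -50
asym_hi <- 250

ec50_bounds <- function(conc) {
  cpos <- conc[conc > 0]
  c(min(cpos) / 100, max(cpos) * 100)
}

ec50_starts <- function(conc) {
  cpos <- sort(unique(conc[conc > 0]))
  exp(quantile(log(cpos), c(0.25, 0.5, 0.75), names = FALSE))
}

make_catalog <- function() {
  list(
    # 1. straight line in concentration; intercept is the control level
    new_family(
      "linear", c("intercept", "slope"), monotone = TRUE,
      fun = function(p, conc) p[1] + p[2] * conc,
      starts = function(conc, resp) {
        cf <- stats::coef(stats::lm(resp ~ conc))
        list(c(cf[[1]], cf[[2]]))
      },
      bounds = function(conc, resp) {
        s <- 300 / max(conc)
        list(lower = c(asym_lo, -s), upper = c(asym_hi, s))
      }
    ),
    # 2. quadratic in concentration (non-monotone capable)
    new_family(
      "quadratic", c("intercept", "b1", "b2"), monotone = FALSE,
      fun = function(p, conc) p[1] + p[2] * conc + p[3] * conc^2,
      starts = function(conc, resp) {
        cf <- stats::coef(stats::lm(resp ~ conc + I(conc^2)))
        cf[is.na(cf)] <- 0
        list(c(cf[[1]], cf[[2]], cf[[3]]))
      },
      bounds = function(conc, resp) {
        s1 <- 300 / max(conc); s2 <- 300 / max(conc)^2
        list(lower = c(asym_lo, -s1, -s2), upper = c(asym_hi, s1, s2))
      }
    ),
    # 3. saturating exponential: control + span * (1 - exp(-conc/e))
    new_family(
      "exponential", c("control", "span", "e"), monotone = TRUE,
      fun = function(p, conc) p[1] + p[2] * (1 - exp(-conc / p[3])),
      starts = function(conc, resp) {
        e0 <- ec50_starts(conc)
        r0 <- resp[which.min(conc)]; r1 <- mean(resp[conc == max(conc)])
        lapply(e0, function(e) c(r0, r1 - r0, e))
      },
      bounds = function(conc, resp) {
        eb <- ec50_bounds(conc)
        list(lower = c(asym_lo, asym_lo - asym_hi, eb[1]),
             upper = c(asym_hi, asym_hi - asym_lo, eb[2]))
      }
    ),
    # 4. log-logistic, 2 parameters: 100 / (1 + (c/e)^b)
    new_family(
      "loglogistic2", c("e", "b"), monotone = TRUE,
      fun = function(p, conc) 100 / (1 + pow_ratio(conc, p[1], p[2])),
      starts = function(conc, resp) {
        e0 <- ec50_starts(conc)
        unlist(lapply(e0, function(e) list(c(e, 1), c(e, -1))),
               recursive = FALSE)
      },
      bounds = function(conc, resp) {
        eb <- ec50_bounds(conc)
        list(lower = c(eb[1], -20), upper = c(eb[2], 20))
      }
    ),
    # 5. log-logistic, 3 parameters: free top, bottom fixed at 0
    new_family(
      "loglogistic3", c("top", "e", "b"), monotone = TRUE,
      fun = function(p, conc) p[1] / (1 + pow_ratio(conc, p[2], p[3])),
      starts = function(conc, resp) {
        e0 <- ec50_starts(conc)
        top <- resp[which.min(conc)]
        unlist(lapply(e0, function(e) list(c(top, e, 1), c(top, e, -1))),
               recursive = FALSE)
      },
      bounds = function(conc, resp) {
        eb <- ec50_bounds(conc)
        list(lower = c(asym_lo, eb[1], -20), upper = c(asym_hi, eb[2], 20))
      }
    ),
    # 6. log-logistic, 4 parameters (4PL)
    new_family(
      "loglogistic4", c("top", "bottom", "e", "b"), monotone = TRUE,
      fun = function(p, conc) p[2] + (p[1] - p[2]) / (1 + pow_ratio(conc, p[3], p[4])),
      starts = function(conc, resp) {
        e0 <- ec50_starts(conc)
        top <- resp[which.min(conc)]
        bot <- mean(resp[conc == max(conc)])
        unlist(lapply(e0, function(e) {
          list(c(top, bot, e, 1), c(top, bot, e, 2))
        }), recursive = FALSE)
      },
      bounds = function(conc, resp) {
        eb <- ec50_bounds(conc)
        list(lower = c(asym_lo, asym_lo, eb[1], -20),
             upper = c(asym_hi, asym_hi, eb[2], 20))
      }
    ),
    # 7. Weibull type 1: control + (limit - control) * (1 - exp(-exp(b log(c/e))))
    new_family(
      "weibull1", c("control", "limit", "e", "b"), monotone = TRUE,
      fun = function(p, conc) {
        p[1] + (p[2] - p[1]) * (1 - exp(-pow_ratio(conc, p[3], p[4])))
      },
      starts = function(conc, resp) {
        e0 <- ec50_starts(conc)
        ctl <- resp[which.min(conc)]
        lim <- mean(resp[conc == max(conc)])
        lapply(e0, function(e) c(ctl, lim, e, 1))
      },
      bounds = function(conc, resp) {
        eb <- ec50_bounds(conc)
        list(lower = c(asym_lo, asym_lo, eb[1], 0.05),
             upper = c(asym_hi, asym_hi, eb[2], 20))
      }
    ),
    # 8. Weibull type 2: control + (limit - control) * exp(-exp(-b log(c/e)));
    # approaches the limit more slowly than type 1 near the control end
    new_family(
      "weibull2", c("control", "limit", "e", "b"), monotone = TRUE,
      fun = function(p, conc) {
        w <- rep(0, length(conc))
        pos <- conc > 0
        w[pos] <- exp(-exp(-p[4] * (log(conc[pos]) - log(p[3]))))
        p[1] + (p[2] - p[1]) * w
      },
      starts = function(conc, resp) {
        e0 <- ec50_starts(conc)
        ctl <- resp[which.min(conc)]
        lim <- mean(resp[conc == max(conc)])
        lapply(e0, function(e) c(ctl, lim, e, 1))
      },
      bounds = function(conc, resp) {
        eb <- ec50_bounds(conc)
        list(lower = c(asym_lo, asym_lo, eb[1], 0.05),
             upper = c(asym_hi, asym_hi, eb[2], 20))
      }
    ),
    # 9. Hill with the control asymptote fixed at 100 %
    new_family(
      "hill3", c("limit", "e", "h"), monotone = TRUE,
      fun = function(p, conc) {
        w <- pow_ratio(conc, p[2], p[3])
        100 + (p[1] - 100) * w / (1 + w)
      },
      starts = function(conc, resp) {
        e0 <- ec50_starts(conc)
        lim <- mean(resp[conc == max(conc)])
        lapply(e0, function(e) c(lim, e, 1))
      },
      bounds = function(conc, resp) {
        eb <- ec50_bounds(conc)
        list(lower = c(asym_lo, eb[1], 0.05), upper = c(asym_hi, eb[2], 20))
      }
    ),
    # 10. shifted Michaelis-Menten (hyperbolic monotone)
    new_family(
      "michaelis", c("control", "limit", "e"), monotone = TRUE,
      fun = function(p, conc) p[1] + (p[2] - p[1]) * conc / (p[3] + conc),
      starts = function(conc, resp) {
        e0 <- ec50_starts(conc)
        ctl <- resp[which.min(conc)]
        lim <- mean(resp[conc == max(conc)])
        lapply(e0, function(e) c(ctl, lim, e))
      },
      bounds = function(conc, resp) {
        eb <- ec50_bounds(conc)
        list(lower = c(asym_lo, asym_lo, eb[1]), upper = c(asym_hi, asym_hi, eb[2]))
      }
    ),
    # 11. Brain-Cousens hormesis: low-dose stimulation before decline
    new_family(
      "braincousens", c("top", "bottom", "e", "b", "f"), monotone = FALSE,
      fun = function(p, conc) {
        p[2] + (p[1] - p[2] + p[5] * conc) / (1 + pow_ratio(conc, p[3], p[4]))
      },
      starts = function(conc, resp) {
        e0 <- ec50_starts(conc)
        top <- resp[which.min(conc)]
        bot <- mean(resp[conc == max(conc)])
        lapply(e0, function(e) c(top, bot, e, 2, 1))
      },
      bounds = function(conc, resp) {
        eb <- ec50_bounds(conc)
        fmax <- 200 / max(conc)
        list(lower = c(asym_lo, asym_lo, eb[1], 0.05, -fmax),
             upper = c(asym_hi, asym_hi, eb[2], 20, fmax))
      }
    ),
    # 12. Cedergreen-Ritz-Streibig: hormesis with exp(-1/c) stimulation term
    new_family(
      "cedergreen", c("top", "bottom", "e", "b", "f"), monotone = FALSE,
      fun = function(p, conc) {
        g <- rep(0, length(conc))
        pos <- conc > 0
        g[pos] <- exp(-1 / conc[pos])
        p[2] + (p[1] - p[2] + p[5] * g) / (1 + pow_ratio(conc, p[3], p[4]))
      },
      starts = function(conc, resp) {
        e0 <- ec50_starts(conc)
        top <- resp[which.min(conc)]
        bot <- mean(resp[conc == max(conc)])
        lapply(e0, function(e) c(top, bot, e, 2, 10))
      },
      bounds = function(conc, resp) {
        eb <- ec50_bounds(conc)
        list(lower = c(asym_lo, asym_lo, eb[1], 0.05, -300),
             upper = c(asym_hi, asym_hi, eb[2], 20, 300))
      }
    ),
    # 13. Gaussian bell in log concentration
    new_family(
      "gaussian", c("control", "amplitude", "e", "width"), monotone = FALSE,
      fun = function(p, conc) {
        g <- rep(0, length(conc))
        pos <- conc > 0
        g[pos] <- exp(-((log(conc[pos]) - log(p[3]))^2) / (2 * p[4]^2))
        p[1] + p[2] * g
      },
      starts = function(conc, resp) {
        e0 <- ec50_starts(conc)
        ctl <- resp[which.min(conc)]
        amp <- max(abs(resp - ctl)) * sign(mean(resp) - ctl + 1e-9)
        lapply(e0, function(e) c(ctl, amp, e, 1))
      },
      bounds = function(conc, resp) {
        eb <- ec50_bounds(conc)
        list(lower = c(asym_lo, asym_lo - asym_hi, eb[1], 0.05),
             upper = c(asym_hi, asym_hi - asym_lo, eb[2], 10))
      }
    )
  )
}

.catalog_env <- new.env(parent = emptyenv())

#' The concentration-response model catalog
#'
#' Returns the fixed catalog of 13 model families used for curve fitting:
#' linear, quadratic, saturating exponential, log-logistic with 2/3/4
#' parameters, two Weibull types, a fixed-control Hill model, a shifted
#' Michaelis-Menten hyperbola, Brain-Cousens and Cedergreen-Ritz-Streibig
#' hormesis models, and a log-concentration Gaussian. Catalog order is the
#' deterministic tie-break order used by [select_best()].
#'
#' @param families Optional character vector of family ids to subset.
#' @return Named list of `cr_family` objects.
#' @export
cr_families <- function(families = NULL) {
  if (is.null(.catalog_env$catalog)) {
    cat_ <- make_catalog()
    names(cat_) <- vapply(cat_, `[[`, "", "family_id")
    .catalog_env$catalog <- cat_
  }
  cat_ <- .catalog_env$catalog
  if (is.null(families)) return(cat_)
  bad <- setdiff(families, names(cat_))
  if (length(bad) > 0) {
    abort(paste0("unknown model family id(s): ", paste(bad, collapse = ", ")),
          class = "bmcscreen_validation_error")
  }
  cat_[families]
}

#' Evaluate a model family
#'
#' @param family A `cr_family` object or family id.
#' @param params Numeric parameter vector in the family's declared order.
#' @param conc Concentrations (µM), all >= 0. A concentration of 0 returns
#'   the family's control asymptote in closed form.
#' @return Predicted response (% of control) at each concentration.
#' @export
cr_predict <- function(family, params, conc) {
  if (is.character(family)) family <- cr_families(family)[[1]]
  stopifnot(inherits(family, "cr_family"))
  if (length(params) != family$n_params) {
    abort(paste0(family$family_id, " expects ", family$n_params, " parameters"),
          class = "bmcscreen_validation_error")
  }
  if (any(conc < 0)) {
    abort("concentrations must be >= 0", class = "bmcscreen_validation_error")
  }
  family$fun(params, conc)
}
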