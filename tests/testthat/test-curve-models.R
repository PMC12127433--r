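ladder <- make_concentration_ladder(5)

test_that("the catalog holds 13 families and evaluates its control asymptote at 0", {
  cat_ <- cr_families()
  expect_length(cat_, 13)
  cases <- family_cases()
  # control level at concentration 0: the declared control parameter, or the
  # fixed 100 % asymptote for families without a free control parameter
  control_at_0 <- c(
    linear = 100, quadratic = 100, exponential = 100, loglogistic2 = 100,
    loglogistic3 = 100, loglogistic4 = 100, weibull1 = 100, weibull2 = 100,
    hill3 = 100, michaelis = 100, braincousens = 100, cedergreen = 100,
    gaussian = 100
  )
  for (id in names(cat_)) {
    expect_equal(cr_predict(id, cases[[id]], 0), unname(control_at_0[id]),
                 info = id)
    expect_true(all(is.finite(cr_predict(id, cases[[id]], c(0, ladder)))),
                info = id)
  }
})

test_that("families flagged monotone are monotone on a concentration grid", {
  grid <- exp(seq(log(min(ladder)), log(max(ladder)), length.out = 200))
  cases <- family_cases()
  for (id in names(cr_families())) {
    fam <- cr_families(id)[[1]]
    if (!fam$monotone) next
    y <- cr_predict(id, cases[[id]], grid)
    expect_true(all(diff(y) <= 1e-9) || all(diff(y) >= -1e-9), info = id)
  }
})

test_that("noiseless 4PL data are recovered to high precision", {
  params <- c(top = 100, bottom = 0, e = 1, b = 1)
  d <- tibble::tibble(
    concentration_uM = rep(ladder, 3),
    response = rep(cr_predict("loglogistic4", params, ladder), 3),
    block = rep(1:3, each = 7)
  )
  fit <- fit_family(d, "loglogistic4")
  expect_true(fit$converged)
  expect_equal(unname(fit$params[c("top", "e", "b")]), c(100, 1, 1),
               tolerance = 1e-6)
  expect_lt(abs(fit$params[["bottom"]]), 1e-4)
})

test_that("flat data give a linear fit with slope ~0 and intercept ~100", {
  d <- tibble::tibble(concentration_uM = rep(ladder, 3),
                      response = 100, block = rep(1:3, each = 7))
  fit <- fit_family(d, "linear")
  expect_equal(unname(fit$params[["intercept"]]), 100, tolerance = 1e-6)
  expect_lt(abs(fit$params[["slope"]]), 1e-6)
})

test_that("degenerate designs error and catalog fitting degrades gracefully", {
  d <- tibble::tibble(concentration_uM = rep(1, 5), response = rnorm(5, 100))
  expect_error(fit_family(d, "loglogistic4"),
               class = "bmcscreen_design_error")
  fits <- fit_curves(d, c("linear", "loglogistic4"))
  expect_false(fits$loglogistic4$converged)
})

test_that("select_best is permutation-invariant and honors parsimony ties", {
  d <- simulate_curve_data(ladder, "loglogistic4", c(100, 20, 0.1, 1.5),
                           noise_sd = 5, seed = 42)
  fits <- fit_curves(d)
  best <- select_best(fits)
  for (perm_seed in 1:5) {
    set.seed(perm_seed)
    shuffled <- fits[sample(length(fits))]
    expect_identical(select_best(shuffled)$family_id, best$family_id)
  }
  single <- list(fits$linear)
  expect_identical(select_best(single)$family_id, "linear")
  all_failed <- fit_curves(
    tibble::tibble(concentration_uM = rep(1:4, 2), response = rnorm(8, 100)),
    c("braincousens", "cedergreen")
  )
  expect_error(select_best(all_failed), class = "bmcscreen_selection_error")
})

test_that("model selection prefers sigmoidal families under strong signal and small families under pure noise", {
  sigmoidal <- vapply(1:60, function(i) {
    d <- simulate_curve_data(ladder, "loglogistic4", c(100, 20, 0.1, 1.5),
                             noise_sd = 5, seed = 300 + i)
    !select_best(fit_curves(d))$family_id %in% c("linear", "quadratic")
  }, TRUE)
  expect_gte(mean(sigmoidal), 0.95)

  parsimonious <- vapply(1:60, function(i) {
    d <- simulate_curve_data(ladder, "linear", c(100, 0),
                             noise_sd = 5, seed = 100 + i)
    select_best(fit_curves(d))$family$n_params <= 2
  }, TRUE)
  expect_gte(mean(parsimonious), 0.7)
})

test_that("confidence bands are deterministic, collapse without noise, and validate n_boot", {
  d <- simulate_curve_data(ladder, "loglogistic4", c(100, 20, 0.1, 1.5),
                           noise_sd = 5, seed = 7)
  fit <- fit_family(d, "loglogistic4")
  b1 <- confidence_band(fit, n_boot = 150, seed = 11)
  b2 <- confidence_band(fit, n_boot = 150, seed = 11)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= b1$fitted + 1e-9))
  expect_true(all(b1$upper >= b1$fitted - 1e-9))
  expect_error(confidence_band(fit, n_boot = 50),
               class = "bmcscreen_config_error")

  clean <- tibble::tibble(
    concentration_uM = rep(ladder, 3),
    response = rep(cr_predict("loglogistic4", c(100, 20, 0.1, 1.5), ladder), 3),
    block = rep(1:3, each = 7)
  )
  fit0 <- fit_family(clean, "loglogistic4")
  b0 <- confidence_band(fit0, n_boot = 150, seed = 3)
  expect_lt(max(b0$upper - b0$lower), 1e-3)
})

test_that("bands cover the true curve at the EC50 in most noisy replicates", {
  truth_mid <- 60  # 4PL midpoint between top 100 and bottom 20
  cov <- vapply(1:40, function(i) {
    d <- simulate_curve_data(ladder, "loglogistic4", c(100, 20, 0.1, 1.5),
                             noise_sd = 5, seed = 500 + i)
    fit <- select_best(fit_curves(d))
    band <- confidence_band(fit, n_boot = 200, seed = 500 + i)
    j <- which.min(abs(band$grid - 0.1))
    band$lower[j] <= truth_mid && truth_mid <= band$upper[j]
  }, TRUE)
  expect_gte(mean(cov), 0.85)
})

test_that("tidiers expose parameters, model summary and fit JSON", {
  d <- simulate_curve_data(ladder, "loglogistic4", c(100, 20, 0.1, 1.5),
                           noise_sd = 5, seed = 9)
  fit <- fit_family(d, "loglogistic4")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term, c("top", "bottom", "e", "b"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$nobs, 21L)
  au <- augment(fit)
  expect_equal(au$.resid, au$response - au$.fitted)
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_identical(js$family_id, "loglogistic4")
})
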