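make_groups <- function(means, n = 5, sd = 5, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    concentration_uM = rep(seq_along(means), each = n),
    response = rnorm(length(means) * n, rep(means, each = n), sd)
  )
}

test_that("the two-group case reduces exactly to the Welch t-test", {
  d <- make_groups(c(100, 90), seed = 3)
  res <- stepdown_dunnett_tamhane(d)
  w <- t.test(d$response[d$concentration_uM == 2],
              d$response[d$concentration_uM == 1])
  expect_equal(res$comparisons$adjusted_p, w$p.value)
  expect_equal(res$comparisons$raw_p, w$p.value)
})

test_that("step-down output is coherent: monotone adjusted p, contiguous rejections", {
  d <- make_groups(c(100, 100, 92, 85, 70), seed = 5)
  res <- stepdown_dunnett_tamhane(d, seed = 2)
  cmp <- res$comparisons
  expect_true(all(diff(cmp$adjusted_p) >= 0))
  expect_true(all(cmp$adjusted_p >= cmp$raw_p - 1e-12))
  if (any(!cmp$rejected)) {
    first_acc <- which(!cmp$rejected)[1]
    expect_true(all(!cmp$rejected[first_acc:nrow(cmp)]))
  }
  expect_equal(glance(res)$n_comparisons, 4L)
})

test_that("insufficient replication raises a dedicated error", {
  d <- tibble::tibble(concentration_uM = c(1, 1, 2), response = c(1, 2, 3))
  expect_error(stepdown_dunnett_tamhane(d),
               class = "bmcscreen_replication_error")
})

test_that("a 3-sd shifted group is reliably detected", {
  hits <- vapply(1:60, function(i) {
    set.seed(i)
    d <- tibble::tibble(
      concentration_uM = rep(1:5, each = 5),
      response = rnorm(25, rep(c(100, 100, 100, 100, 115), each = 5), 5)
    )
    res <- stepdown_dunnett_tamhane(d, n_mc = 4000, seed = 1000 + i)
    res$comparisons$rejected[res$comparisons$group == 5]
  }, TRUE)
  # detection probability ~0.92 at this design (Welch power at a 3-sd
  # shift with n = 5 under max-t multiplicity), measured over 200 seeds
  expect_gte(mean(hits), 0.85)
})

test_that("the dual hit rule combines step-down and band-crossing evidence", {
  # strong decreasing effect: stepdown rejects the top dose and the whole
  # band drops below the BMR line
  d <- simulate_curve_data(make_concentration_ladder(5), "loglogistic4",
                           c(100, 20, 0.1, 2), noise_sd = 3, seed = 8)
  fit <- select_best(fit_curves(d))
  band <- confidence_band(fit, n_boot = 200, seed = 8)
  sd_res <- stepdown_dunnett_tamhane(d, seed = 8)
  hit <- classify_hit(sd_res, band, bmr = 20)
  expect_true(hit$is_hit)
  expect_true(hit$ci_crossing)

  # hand-built band straddling the BMR line: only the stat test can fire
  straddle <- structure(list(
    level = 0.95, grid = band$grid,
    fitted = rep(90, length(band$grid)),
    lower = rep(70, length(band$grid)),
    upper = rep(110, length(band$grid)),
    method = "bootstrap", n_boot = 200, n_ok = 200, seed = 1,
    family_id = "loglogistic4"
  ), class = "cr_band")
  hit2 <- classify_hit(sd_res, straddle, bmr = 20)
  expect_identical(hit2$basis, if (hit2$stat_test) "stat_test" else "")
  expect_false(hit2$ci_crossing)
  # the weaker single-edge reading fires on the same band
  hit3 <- classify_hit(sd_res, straddle, bmr = 20, ci_rule = "either_edge")
  expect_true(hit3$ci_crossing)
})

test_that("classify_hit is invariant to the ordering of input rows", {
  d <- simulate_curve_data(make_concentration_ladder(5), "loglogistic4",
                           c(100, 30, 0.2, 1.5), noise_sd = 5, seed = 12)
  fit <- select_best(fit_curves(d))
  band <- confidence_band(fit, n_boot = 200, seed = 12)
  h1 <- classify_hit(stepdown_dunnett_tamhane(d, seed = 4), band, 20)
  set.seed(1)
  d_shuf <- d[sample(nrow(d)), ]
  h2 <- classify_hit(stepdown_dunnett_tamhane(d_shuf, seed = 4), band, 20)
  expect_identical(h1, h2)
})

test_that("the most sensitive endpoint is the lowest-BMC hit, with CI-overlap ties", {
  # GR-like pattern: proliferation BMC20 6.1 nM vs neuronal differentiation
  # BMC25 32.5 nM -> proliferation is the MSE
  tbl <- tibble::tibble(
    endpoint = c("NPC1", "NPC3"),
    bmc = c(6.1e-3, 3.25e-2),
    bmcl = c(4e-3, 2e-2), bmcu = c(9e-3, 5e-2),
    censored = FALSE, is_hit = TRUE
  )
  out <- most_sensitive_endpoint(tbl)
  expect_identical(out$mse, "NPC1")
  expect_false(out$tie)

  single <- tbl[2, ]
  expect_identical(most_sensitive_endpoint(single)$mse, "NPC3")

  none <- dplyr::mutate(tbl, is_hit = FALSE)
  expect_true(is.na(most_sensitive_endpoint(none)$mse))

  overlapping <- tibble::tibble(
    endpoint = c("NPC3", "NPC5"),
    bmc = c(0.010, 0.013),
    bmcl = c(0.005, 0.006), bmcu = c(0.020, 0.025),
    censored = FALSE, is_hit = TRUE
  )
  tie <- most_sensitive_endpoint(overlapping)
  expect_true(tie$tie)
  expect_identical(tie$tie_set, "NPC3,NPC5")
})

test_that("rescue assessment distinguishes restored from unrestored phenotypes", {
  set.seed(31)
  solvent <- rnorm(5, 100, 4)
  agonist <- rnorm(5, 60, 4)
  doses <- c(0.01, 0.1, 1, 10)
  full <- tibble::tibble(
    concentration_uM = rep(doses, each = 5),
    response = rnorm(20, 100, 4)
  )
  res <- assess_rescue(solvent, agonist, full, seed = 31)
  expect_true(res$antagonized)
  expect_lt(res$agonist_effect_p, 0.05)

  none <- tibble::tibble(
    concentration_uM = rep(doses, each = 5),
    response = rnorm(20, 60, 4)
  )
  expect_false(assess_rescue(solvent, agonist, none, seed = 31)$antagonized)

  expect_error(assess_rescue(solvent, numeric(1), full),
               class = "bmcscreen_design_error")
  expect_error(
    assess_rescue(solvent, agonist,
                  tibble::tibble(concentration_uM = 1, response = 1)),
    class = "bmcscreen_design_error"
  )
})

test_that("graded restoration is detected in most noisy replicates", {
  doses <- c(0.01, 0.1, 1, 10)
  detected <- vapply(1:40, function(i) {
    set.seed(i)
    solvent <- rnorm(5, 100, 5)
    agonist <- rnorm(5, 60, 5)
    restore <- 60 + 40 * c(0.1, 0.3, 0.6, 0.8)
    ant <- tibble::tibble(
      concentration_uM = rep(doses, each = 5),
      response = rnorm(20, rep(restore, each = 5), 5)
    )
    assess_rescue(solvent, agonist, ant, n_mc = 4000, seed = i)$antagonized
  }, TRUE)
  expect_gte(mean(detected), 0.9)
})

test_that("stratum comparison classifies concordance and sensitivity ratios", {
  # sex-discordant: hit in males only
  tbl <- tibble::tibble(
    stratum = c("male", "female"), endpoint = "NPC1",
    is_hit = c(TRUE, FALSE), bmc = c(0.0061, NA),
    bmcl = c(0.004, NA), bmcu = c(0.009, NA), censored = c(FALSE, TRUE)
  )
  out <- compare_strata(tbl)
  expect_identical(out$status, "discordant")

  same <- tibble::tibble(
    stratum = c("human", "rat"), endpoint = "NPC5",
    is_hit = TRUE, bmc = 0.02, bmcl = 0.01, bmcu = 0.04, censored = FALSE
  )
  out2 <- compare_strata(same)
  expect_identical(out2$status, "concordant-hit")
  expect_equal(out2$bmc_ratio, 1)

  # species comparison: human BMC 25.1 nM vs rat 387.1 nM
  hr <- tibble::tibble(
    stratum = c("human", "rat"), endpoint = "NPC5",
    is_hit = TRUE, bmc = c(25.1e-3, 387.1e-3),
    bmcl = c(18e-3, 300e-3), bmcu = c(33e-3, 500e-3), censored = FALSE
  )
  out3 <- compare_strata(hr)
  expect_identical(out3$status, "concordant-hit")
  expect_equal(out3$bmc_ratio, 25.1 / 387.1, tolerance = 1e-10)
  expect_true(out3$ci_nonoverlap)
})
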