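# Shared builders for small in-memory fixtures.

# Minimal well-level table on one plate: blanks, solvent and treated wells
# for one endpoint, raw-unit values chosen by the caller.
make_plate_tbl <- function(treated_values, solvent_values, blank_values,
                           concentrations = rep(1, length(treated_values)),
                           endpoint = "NPC1", plate_id = "p1") {
  tibble::tibble(
    compound = "CMP1",
    endpoint = endpoint,
    species = "human",
    sex = "male",
    donor_id = "d1",
    plate_id = plate_id,
    well_type = c(rep("treated", length(treated_values)),
                  rep("solvent", length(solvent_values)),
                  rep("blank", length(blank_values))),
    concentration_uM = c(concentrations, rep(0, length(solvent_values)),
                         rep(0, length(blank_values))),
    replicate = c(seq_along(treated_values), seq_along(solvent_values),
                  seq_along(blank_values)),
    value = c(treated_values, solvent_values, blank_values)
  )
}

# Values with an exact coefficient of variation: two points symmetric
# around `center`.
values_with_cv <- function(cv, center = 100) {
  x <- cv * center / sqrt(2)
  c(center - x, center + x)
}

# Independent brute-force BMC oracle: dense log-grid scan for the first
# point beyond the BMR line, then interval bisection on the curve itself.
bmc_oracle <- function(fun, cmin, cmax, threshold, direction,
                       n_grid = 100000, iters = 80) {
  beyond <- if (direction == "decrease") {
    function(y) y <= threshold
  } else {
    function(y) y >= threshold
  }
  grid <- exp(seq(log(cmin), log(cmax), length.out = n_grid))
  hit <- which(beyond(fun(grid)))
  if (length(hit) == 0) return(NA_real_)
  if (hit[1] == 1) return(cmin)
  lo <- grid[hit[1] - 1]; hi <- grid[hit[1]]
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (beyond(fun(mid))) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Admissible parameter sets, one per catalog family, each crossing the
# 80 % line (BMR 20, decrease) inside the ladder of a 5 mM stock.
family_cases <- function() {
  list(
    linear = c(100, -5),
    quadratic = c(100, -2, -0.5),
    exponential = c(100, -60, 1),
    loglogistic2 = c(1, 1),
    loglogistic3 = c(100, 1, 1),
    loglogistic4 = c(100, 0, 1, 1),
    weibull1 = c(100, 0, 1, 1),
    weibull2 = c(100, 0, 1, 1),
    hill3 = c(0, 1, 1),
    michaelis = c(100, 0, 1),
    braincousens = c(100, 0, 1, 2, 20),
    cedergreen = c(100, 0, 1, 2, 50),
    gaussian = c(100, -50, 1, 1)
  )
}
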