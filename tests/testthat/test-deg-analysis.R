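test_that("DEG thresholds use the printed strict/weak inequalities", {
  tbl <- tibble::tibble(
    gene = c("A", "B", "C", "D"),
    log2_fc = c(0.486, -0.50, 0.50, 0.50),
    fpkm = c(5, 1.0, 0.99, 5),
    q_value = c(0.01, 0.049, 0.01, 0.05)
  )
  out <- filter_degs(tbl)
  expect_identical(out$is_deg, c(FALSE, TRUE, FALSE, FALSE))

  bad <- dplyr::mutate(tbl, q_value = c(0.5, 1.2, 0.1, 0.1))
  expect_error(filter_degs(bad), class = "bmcscreen_validation_error")
  expect_error(filter_degs(tbl[, 1:3]), class = "bmcscreen_schema_error")

  # idempotent and row-order invariant
  twice <- filter_degs(out)
  expect_identical(twice$is_deg, out$is_deg)
  shuf <- filter_degs(tbl[c(3, 1, 4, 2), ])
  expect_identical(shuf$is_deg[match(tbl$gene, shuf$gene)], out$is_deg)
})

test_that("planted DEGs are recovered exactly, including the boundary case", {
  sim <- simulate_deg_table(1000, 100, seed = 1)
  out <- filter_degs(sim)
  expect_identical(out$is_deg, out$planted)
  expect_equal(sum(out$is_deg), 100)

  empty <- filter_degs(simulate_deg_table(200, 0, seed = 2))
  expect_equal(sum(empty$is_deg), 0)

  boundary <- tibble::tibble(gene = "X", log2_fc = 0.486, fpkm = 10,
                             q_value = 0.001)
  expect_false(filter_degs(boundary)$is_deg)
})

test_that("evidence classification applies brain-first precedence", {
  tbl <- filter_degs(tibble::tibble(
    gene = c("B1", "N1", "O1", "X1", "BN"),
    log2_fc = c(1, 1, 1, 0.1, 1),
    fpkm = 10, q_value = 0.001
  ))
  out <- classify_evidence(tbl, brain_evidence = c("B1", "BN"),
                           nonbrain_evidence = c("N1", "BN"))
  expect_identical(
    as.character(out$evidence),
    c("reported_target_in_brain", "newly_identified_target_in_brain",
      "newly_identified_target_overall", "no_evidence",
      "reported_target_in_brain")
  )
})

test_that("hypergeometric enrichment matches an exhaustive-enumeration oracle", {
  universe <- sprintf("g%02d", 1:16)
  gene_set <- universe[1:6]
  deg <- universe[c(1:4, 9, 10)]
  res <- overrepresentation(deg, universe, list(S = gene_set))
  # oracle: enumerate all C(16, 6) DEG subsets, count overlap >= observed
  combos <- utils::combn(16, 6)
  ov <- colSums(matrix(combos %in% 1:6, nrow = 6))
  p_oracle <- mean(ov >= 4)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(res$overlap, 4)

  # the DEG set exactly equal to a set, universe twice its size
  res2 <- overrepresentation(universe[1:8], universe, list(S = universe[1:8]))
  combos2 <- utils::combn(16, 8)
  p2 <- mean(colSums(matrix(combos2 %in% 1:8, nrow = 8)) >= 8)
  expect_equal(res2$p_value, p2, tolerance = 1e-10)

  # disjoint set: overlap 0, upper tail includes 0 -> p = 1
  res3 <- overrepresentation(universe[1:4], universe, list(S = universe[13:16]))
  expect_equal(res3$overlap, 0)
  expect_equal(res3$p_value, 1)
})

test_that("enrichment rows are ordered by overlap and flagged at raw p < 0.01", {
  universe <- sprintf("g%03d", 1:200)
  deg <- universe[1:20]
  sets <- list(big = universe[1:9], small = universe[c(1:5, 100:104)],
               null = universe[150:160])
  res <- overrepresentation(deg, universe, sets)
  expect_identical(res$set_id[1:2], c("big", "small"))
  expect_identical(res$reported, res$p_value < 0.01)
  # per-direction counts when up/down subsets are supplied
  res_dir <- overrepresentation(deg, universe, sets,
                                up_genes = universe[1:10],
                                down_genes = universe[11:20])
  expect_equal(res_dir$overlap_up[res_dir$set_id == "big"], 9)
  expect_equal(res_dir$overlap_down[res_dir$set_id == "big"], 0)
  expect_error(overrepresentation(deg, character(0), sets),
               class = "bmcscreen_validation_error")
  expect_error(overrepresentation(c(deg, "zz"), universe, sets),
               class = "bmcscreen_validation_error")
})

test_that("enrichment is conservative under a uniform-random null", {
  universe <- sprintf("g%03d", 1:100)
  sets <- list(A = universe[1:10], B = universe[11:40], C = universe[41:60])
  set.seed(77)
  frac <- mean(vapply(1:1000, function(i) {
    deg <- sample(universe, 15)
    mean(overrepresentation(deg, universe, sets)$p_value < 0.01)
  }, 0))
  expect_lte(frac, 0.02)
})

test_that("GMT gene-set files round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(sets$setB, c("g2", "g4"))
})
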