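# Differentially-expressed-gene filtering and gene-set overrepresentation.
#
# Differential expression estimates (fold changes, FPKM, q-values) are
# inputs; this module applies the screening thresholds, classifies literature
# evidence for receptor targets, and runs hypergeometric overrepresentation
# with raw p-values (no multiple-testing correction by default) ordered by
# DEG count, matching the reporting rule used for GO-term summaries.

#' Filter differentially expressed genes
#'
#' A gene is a DEG when `|log2_fc| > lfc_cutoff` (strict), `fpkm >=
#' fpkm_cutoff`, and `q_value < q_cutoff` (strict). Defaults correspond to a
#' 1.4-fold change (|log2 FC| > 0.486), FPKM >= 1 and q < 0.05.
#'
#' @param table Data frame with columns `gene`, `log2_fc`, `fpkm`, `q_value`.
#' @param lfc_cutoff,fpkm_cutoff,q_cutoff Threshold values.
#' @return The input as a tibble with an added logical `is_deg` column.
#' @export
filter_degs <- function(table, lfc_cutoff = 0.486, fpkm_cutoff = 1,
                        q_cutoff = 0.05) {
  table <- tibble::as_tibble(table)
  needed <- c("gene", "log2_fc", "fpkm", "q_value")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("DEG table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "bmcscreen_schema_error")
  }
  if (any(table$q_value < 0 | table$q_value > 1, na.rm = TRUE)) {
    abort("q_value must lie in [0, 1]", class = "bmcscreen_validation_error")
  }
  dplyr::mutate(
    table,
    is_deg = abs(.data$log2_fc) > lfc_cutoff &
      .data$fpkm >= fpkm_cutoff &
      .data$q_value < q_cutoff
  )
}

#' Classify literature evidence for receptor target genes
#'
#' DEGs are labelled by the strongest available literature evidence:
#' previously reported receptor targets in brain tissue or neural cultures
#' (`reported_target_in_brain`), targets reported only in non-brain tissues
#' and newly confirmed as neural targets (`newly_identified_target_in_brain`),
#' or genes with no prior receptor-target evidence at all
#' (`newly_identified_target_overall`). Brain evidence takes precedence when
#' a gene appears in both sets. Non-DEG genes get `no_evidence`.
#'
#' @param table Output of [filter_degs()] (needs `gene` and `is_deg`).
#' @param brain_evidence Character vector of genes with brain/neural
#'   receptor-target evidence.
#' @param nonbrain_evidence Character vector of genes with receptor-target
#'   evidence from other organs.
#' @return The table with an added `evidence` factor column.
#' @export
classify_evidence <- function(table, brain_evidence, nonbrain_evidence) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("gene", "is_deg") %in% names(table)))
  lv <- c("reported_target_in_brain", "newly_identified_target_in_brain",
          "newly_identified_target_overall", "no_evidence")
  dplyr::mutate(
    table,
    evidence = factor(
      dplyr::case_when(
        !.data$is_deg ~ "no_evidence",
        .data$gene %in% brain_evidence ~ "reported_target_in_brain",
        .data$gene %in% nonbrain_evidence ~ "newly_identified_target_in_brain",
        TRUE ~ "newly_identified_target_overall"
      ),
      levels = lv
    )
  )
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (set id, description, genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[[`, "", 1))
}

#' Gene-set overrepresentation of a DEG list
#'
#' One-sided hypergeometric upper-tail test of the overlap between the DEG
#' set and each gene set, both intersected with the universe. Sets with
#' `p < p_cutoff` are flagged `reported`; rows are ordered by overlap count
#' descending, ties by p ascending. Per-direction overlap counts are
#' reported when the DEG table distinguishes up- and downregulation.
#'
#' @param deg_genes Character vector of DEG ids (subset of `universe`).
#' @param universe Character vector of all measured genes.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param p_cutoff Reporting threshold on the raw p-value; default 0.01.
#' @param adjust Multiple-testing correction method passed to
#'   [stats::p.adjust()]; default `"none"`, matching the raw-p reporting rule.
#' @param up_genes,down_genes Optional subsets of `deg_genes` for
#'   per-direction counts.
#' @return Tibble with `set_id`, `overlap`, `set_size`, `deg_size`,
#'   `universe_size`, `p_value`, `reported` (and `overlap_up`/`overlap_down`
#'   when directions are given).
#' @export
overrepresentation <- function(deg_genes, universe, gene_sets,
                               p_cutoff = 0.01, adjust = "none",
                               up_genes = NULL, down_genes = NULL) {
  universe <- unique(universe)
  if (length(universe) == 0) {
    abort("universe must be non-empty", class = "bmcscreen_validation_error")
  }
  deg_genes <- unique(deg_genes)
  if (!all(deg_genes %in% universe)) {
    abort("DEG set must be a subset of the universe",
          class = "bmcscreen_validation_error")
  }
  N <- length(universe)
  k <- length(deg_genes)
  rows <- purrr::imap(gene_sets, function(genes, id) {
    genes <- intersect(unique(genes), universe)
    m <- length(genes)
    ov <- length(intersect(deg_genes, genes))
    # P(X >= ov) for X ~ Hypergeom(m in-set, N - m out, k drawn)
    p <- phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    row <- tibble::tibble(
      set_id = id, overlap = ov, set_size = m,
      deg_size = k, universe_size = N, p_value = p
    )
    if (!is.null(up_genes)) row$overlap_up <- length(intersect(up_genes, genes))
    if (!is.null(down_genes)) {
      row$overlap_down <- length(intersect(down_genes, genes))
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = adjust)
  out$reported <- out$p_adjusted < p_cutoff
  dplyr::arrange(out, dplyr::desc(.data$overlap), .data$p_value)
}
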