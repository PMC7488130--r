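#' Attach drugs to a gene module
#'
#' The drug module of a gene module is the union, over member genes, of the
#' drugs associated with them in the gene-drug map; genes with no
#' association contribute nothing. An empty drug set is valid.
#'
#' @param genes Character vector of module member genes.
#' @param drug_map A [drug_gene_map()].
#' @return List with `drugs` (sorted unique drug names) and `gene_drugs`
#'   (tibble gene, drug restricted to module genes).
#' @export
attach_drugs <- function(genes, drug_map) {
  stopifnot(inherits(drug_map, "drug_gene_map") || is.data.frame(drug_map))
  hits <- drug_map[drug_map$gene %in% genes, c("gene", "drug"), drop = FALSE]
  list(drugs = sort(unique(hits$drug)), gene_drugs = tibble::as_tibble(hits))
}

activating_rules <- function(rules) rules$name[rules$sign == "activating"]
suppressing_rules <- function(rules) rules$name[rules$sign == "suppressing"]

#' Score one gene module for alteration and druggability
#'
#' Three summary scores per module:
#' \describe{
#'   \item{score_genes}{alteration density: mean of the binary rule matrix
#'     over module genes x applied rules, in \[0, 1\].}
#'   \item{score_drugs}{druggable fraction: proportion of module genes with
#'     at least one drug association, in \[0, 1\].}
#'   \item{s_score}{signed activation balance: mean of the activating
#'     per-rule sub-scores minus mean of the suppressing ones (each mean
#'     over the rule columns actually present), in \[-1, 1\]. Positive
#'     means predominantly activated (over-expression, copy gain,
#'     hypomethylation, mutation); negative means suppressed.}
#' }
#' Per-rule sub-scores (column means over module genes) are returned
#' alongside.
#'
#' @param genes Module member genes (non-empty, subset of the rule matrix).
#' @param rule_matrix A `rule_matrix` for the same patient.
#' @param drug_map A [drug_gene_map()].
#' @return Tibble with one row: `score_genes`, `score_drugs`, `s_score`,
#'   `n_genes`, `n_drugs`, plus one `sub_<rule>` column per applied rule.
#' @export
score_module <- function(genes, rule_matrix, drug_map) {
  stopifnot(inherits(rule_matrix, "rule_matrix"))
  if (length(genes) == 0) stop("module has no genes", call. = FALSE)
  missing <- setdiff(genes, rule_matrix$genes)
  if (length(missing)) {
    stop("module gene(s) absent from rule matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- colMeans(rule_matrix$values[genes, , drop = FALSE])
  score_genes <- mean(sub)  # == mean over all cells
  dm <- attach_drugs(genes, drug_map)
  druggable <- unique(dm$gene_drugs$gene)
  score_drugs <- length(druggable) / length(genes)
  act <- intersect(activating_rules(rule_matrix$rules), names(sub))
  sup <- intersect(suppressing_rules(rule_matrix$rules), names(sub))
  s_act <- if (length(act)) mean(sub[act]) else 0
  s_sup <- if (length(sup)) mean(sub[sup]) else 0
  s_score <- s_act - s_sup
  out <- tibble::tibble(score_genes = score_genes, score_drugs = score_drugs,
                        s_score = s_score, n_genes = length(genes),
                        n_drugs = length(dm$drugs))
  for (nm in names(sub)) out[[paste0("sub_", nm)]] <- unname(sub[nm])
  out
}

#' Score every module of every patient
#'
#' Builds the cohort-level result table: one row per (patient, module) with
#' member genes, attached drugs and all scores. For assignments produced by
#' the proximity strategy, rule matrices are computed from the same bundle
#' with the supplied rule set purely for scoring, so both strategies share
#' one scoring path. Clinical variables, when given, are joined by sample
#' id as trailing columns.
#'
#' @param assignments Named list of `module_assignment` (one per patient),
#'   as returned by [run_m1()] or [run_m2()].
#' @param bundle The [align_bundle()] result the assignments came from.
#' @param drug_map A [drug_gene_map()].
#' @param rules Rule set used for scoring (default [default_rules()]).
#' @param clinical Optional clinical tibble (first column `sample`).
#' @return Tibble of class `module_scores`, one row per patient x module:
#'   `patient`, `module`, `genes` (comma-joined), `drugs` (comma-joined or
#'   `NA`), `n_genes`, `n_drugs`, `score_genes`, `score_drugs`, `s_score`,
#'   `sub_*` columns, then clinical columns.
#' @export
score_all <- function(assignments, bundle, drug_map,
                      rules = default_rules(), clinical = NULL) {
  stopifnot(inherits(bundle, "omics_bundle"))
  rows <- purrr::map_dfr(names(assignments), function(patient) {
    asg <- assignments[[patient]]
    pm <- assemble_patient_matrix(bundle, patient)
    rm_ <- binarize_rules(pm, rules)
    purrr::map_dfr(sort(unique(asg$labels)), function(mod) {
      genes <- sort(names(asg$labels)[asg$labels == mod])
      sc <- score_module(genes, rm_, drug_map)
      dm <- attach_drugs(genes, drug_map)
      tibble::tibble(
        patient = patient, module = as.integer(mod),
        genes = paste(genes, collapse = ","),
        drugs = if (length(dm$drugs)) paste(dm$drugs, collapse = ",") else
          NA_character_
      ) |> dplyr::bind_cols(sc)
    })
  })
  if (!is.null(clinical)) {
    rows <- dplyr::left_join(rows, clinical,
                             by = c(patient = "sample"))
  }
  class(rows) <- c("module_scores", class(rows))
  rows
}

#' @export
print.module_scores <- function(x, ...) {
  cat(sprintf("<module_scores: %d patients, %d module rows>\n",
              dplyr::n_distinct(x$patient), nrow(x)))
  NextMethod()
}

#' One-row-per-patient summary of a score table
#'
#' @param x A `module_scores` tibble.
#' @param ... Unused.
#' @return Tibble with per-patient module count and score extremes.
#' @export
glance.module_scores <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$patient),
                   k = dplyr::n(),
                   max_s_score = max(.data$s_score),
                   min_s_score = min(.data$s_score),
                   n_druggable_modules = sum(.data$n_drugs > 0),
                   .groups = "drop")
}
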