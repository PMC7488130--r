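#' Run the full analysis from files to a result table
#'
#' End-to-end driver used by the command-line interface: reads the omics
#' layers, aligns them, restricts to the gene set (given directly or via
#' BED regions plus a gene annotation), clusters each patient with the
#' chosen strategy, scores every module against the gene-drug table,
#' merges clinical data and writes `results.tsv` into `out_dir`.
#'
#' @param expression,copy_number,methylation,mutation Paths to the layer
#'   TSVs; at least two layers must be given (`NULL` omits a layer).
#' @param drugs Path to the mandatory gene-drug association TSV.
#' @param genes Optional path to a one-gene-per-line list.
#' @param bed,annotation Optional paths: BED regions plus gene annotation,
#'   used instead of `genes`.
#' @param clinical Optional clinical TSV.
#' @param method `"m1"` or `"m2"`.
#' @param k Modules per patient: integer, or `"auto"` (m1 only).
#' @param rules Optional path to a rule TSV (default rules otherwise).
#' @param n_trees,n_init Strategy effort knobs.
#' @param seed Integer seed; all randomness derives from it.
#' @param out_dir Output directory (created if absent).
#' @return The `module_scores` tibble, invisibly; `results.tsv` is written
#'   to `out_dir`.
#' @export
run_analysis <- function(expression = NULL, copy_number = NULL,
                         methylation = NULL, mutation = NULL, drugs,
                         genes = NULL, bed = NULL, annotation = NULL,
                         clinical = NULL, method = c("m1", "m2"), k = "auto",
                         rules = NULL, n_trees = 500, n_init = 10, seed = 1,
                         out_dir = ".") {
  method <- match.arg(method)
  if (missing(drugs) || is.null(drugs)) {
    stop("the gene-drug association table is the mandatory input; ",
         "provide `drugs`", call. = FALSE)
  }
  if (!is.null(genes) && !is.null(bed)) {
    stop("provide either a gene list or BED regions, not both", call. = FALSE)
  }
  if (!is.null(bed) && is.null(annotation)) {
    stop("BED regions require a gene annotation table", call. = FALSE)
  }
  paths <- list(expression = expression, copy_number = copy_number,
                methylation = methylation, mutation = mutation)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (length(paths) < 2) {
    stop("at least two omics layers are required", call. = FALSE)
  }
  datasets <- purrr::imap(paths, function(p, kind)
    read_omics_table(p, kind))

  gene_set <- NULL
  if (!is.null(genes)) {
    gene_set <- unique(trimws(readLines(genes)))
    gene_set <- gene_set[nzchar(gene_set)]
    if (length(gene_set) == 0) stop("gene list is empty", call. = FALSE)
  } else if (!is.null(bed)) {
    gene_set <- map_regions_to_genes(read_bed(bed),
                                     read_gene_annotation(annotation))
  }

  bundle <- align_bundle(unname(datasets), genes = gene_set)
  drug_map <- read_drug_gene_map(drugs)
  rule_set <- if (is.null(rules)) default_rules() else read_rule_set(rules)
  clin <- if (is.null(clinical)) NULL else read_clinical_table(clinical)

  assignments <- if (method == "m1") {
    run_m1(bundle, k = k, n_trees = n_trees, seed = seed)
  } else {
    if (identical(k, "auto")) {
      stop("k must be an integer for the logic-rule strategy", call. = FALSE)
    }
    run_m2(bundle, k = as.integer(k), rules = rule_set, n_init = n_init,
           seed = seed)
  }
  scores <- score_all(assignments, bundle, drug_map, rules = rule_set,
                      clinical = clin)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_result_table(scores, file.path(out_dir, "results.tsv"))
  invisible(scores)
}
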