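#' Omics layer kinds understood by the pipeline
#'
#' @format Character vector of recognised layer kinds, in the canonical
#'   column order used when patient matrices are assembled.
#' @export
LAYER_KINDS <- c("expression", "copy_number", "methylation", "mutation", "other")

#' Construct an omics dataset (one layer, genes x samples)
#'
#' An omics dataset is a numeric matrix with genes on the rows and samples
#' on the columns, tagged with the kind of measurement it carries.
#' Layer-specific invariants are enforced: methylation beta values must lie
#' in \[0, 1\] and mutation values must be non-negative integers (0/1
#' indicators or counts).
#'
#' @param values Numeric matrix, rownames = gene symbols, colnames = sample
#'   ids. Gene and sample ids must be unique.
#' @param layer_kind One of `"expression"`, `"copy_number"`, `"methylation"`,
#'   `"mutation"`, `"other"`.
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(values, layer_kind) {
  layer_kind <- match.arg(layer_kind, LAYER_KINDS)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop("duplicate gene symbol: ", dup, call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    stop("duplicate sample id: ", dup, call. = FALSE)
  }
  finite <- values[is.finite(values)]
  if (layer_kind == "methylation" && length(finite) &&
      (min(finite) < 0 || max(finite) > 1)) {
    stop("methylation beta values must lie in [0, 1]", call. = FALSE)
  }
  if (layer_kind == "mutation" && length(finite) &&
      (min(finite) < 0 || any(finite != round(finite)))) {
    stop("mutation values must be non-negative integers", call. = FALSE)
  }
  structure(list(values = values, layer_kind = layer_kind),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("<omics_dataset: %s, %d genes x %d samples>\n",
              x$layer_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_dataset <- function(x) dim(x$values)

#' Read a tab-delimited omics matrix
#'
#' Expects a TSV whose first column (header `gene`) holds gene symbols and
#' whose remaining columns, one per sample, hold numeric values. Cells that
#' are empty or `NA` are imputed: 0 for mutation layers, the per-gene row
#' median otherwise (a message reports the count).
#'
#' @param path Path to the TSV file.
#' @param layer_kind Layer kind; see [omics_dataset()].
#' @return An [omics_dataset()].
#' @export
read_omics_table <- function(path, layer_kind) {
  layer_kind <- match.arg(layer_kind, LAYER_KINDS)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("NA", ""), quote = "")
  if (ncol(df) < 2) stop("omics table needs a gene column plus >=1 sample column",
                         call. = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbol: ", genes[duplicated(genes)][1], call. = FALSE)
  }
  samples <- colnames(df)[-1]
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value %s at gene '%s', sample '%s'",
                   dQuote(col[bad[1]]), genes[bad[1]], samples[j]),
           call. = FALSE)
    }
    vals[, j] <- num
  }
  n_missing <- sum(is.na(vals))
  if (n_missing > 0) {
    if (layer_kind == "mutation") {
      vals[is.na(vals)] <- 0
    } else {
      for (i in seq_len(nrow(vals))) {
        miss <- is.na(vals[i, ])
        if (any(miss)) {
          med <- stats::median(vals[i, !miss])
          vals[i, miss] <- if (is.na(med)) 0 else med
        }
      }
    }
    message(sprintf("imputed %d missing value(s) in %s layer", n_missing,
                    layer_kind))
  }
  omics_dataset(vals, layer_kind)
}

#' Write an omics dataset as a TSV
#'
#' Inverse of [read_omics_table()]: first column `gene`, one column per
#' sample.
#'
#' @param dataset An [omics_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omics_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "omics_dataset"))
  df <- data.frame(gene = rownames(dataset$values),
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align omics layers into a shared-gene, shared-sample bundle
#'
#' Restricts every layer to the intersection of gene symbols and sample ids
#' (optionally further restricted to a user gene set), orders both
#' lexicographically, and fixes the layer order to (expression, copy_number,
#' methylation, mutation, other) regardless of input order so downstream
#' patient matrices have a reproducible column order. Dropped genes and
#' samples are reported with a message. Matching is exact and
#' case-sensitive.
#'
#' @param datasets List of >= 2 [omics_dataset()] objects.
#' @param genes Optional character vector restricting the analysis gene set.
#' @return An object of class `omics_bundle` with elements `datasets`
#'   (named list), `genes`, `samples`.
#' @export
align_bundle <- function(datasets, genes = NULL) {
  if (!is.list(datasets) || length(datasets) < 2) {
    stop("at least two omics datasets are required", call. = FALSE)
  }
  ok <- vapply(datasets, inherits, logical(1), what = "omics_dataset")
  if (!all(ok)) stop("all elements must be omics_dataset objects", call. = FALSE)

  kinds <- vapply(datasets, function(d) d$layer_kind, character(1))
  ord <- order(match(kinds, LAYER_KINDS))
  datasets <- datasets[ord]
  kinds <- kinds[ord]
  if (anyDuplicated(kinds)) {
    stop("duplicate layer kind: ", kinds[duplicated(kinds)][1], call. = FALSE)
  }

  gene_sets <- lapply(datasets, function(d) rownames(d$values))
  shared_genes <- Reduce(intersect, gene_sets)
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, shared_genes)
    if (length(missing_genes)) {
      message(sprintf("%d gene(s) of the requested set absent from all layers",
                      length(missing_genes)))
    }
    shared_genes <- intersect(shared_genes, genes)
  }
  shared_genes <- sort(shared_genes)
  if (length(shared_genes) == 0) {
    stop("gene intersection across layers is empty", call. = FALSE)
  }
  dropped_genes <- length(unique(unlist(gene_sets))) - length(shared_genes)
  if (dropped_genes > 0 && is.null(genes)) {
    message(sprintf("dropped %d gene(s) not shared by every layer", dropped_genes))
  }

  sample_sets <- lapply(datasets, function(d) colnames(d$values))
  shared_samples <- sort(Reduce(intersect, sample_sets))
  if (length(shared_samples) == 0) {
    stop("sample intersection across layers is empty", call. = FALSE)
  }
  dropped_samples <- length(unique(unlist(sample_sets))) - length(shared_samples)
  if (dropped_samples > 0) {
    message(sprintf("dropped %d sample(s) not shared by every layer",
                    dropped_samples))
  }

  aligned <- lapply(datasets, function(d) {
    omics_dataset(d$values[shared_genes, shared_samples, drop = FALSE],
                  d$layer_kind)
  })
  names(aligned) <- kinds
  structure(list(datasets = aligned, genes = shared_genes,
                 samples = shared_samples),
            class = "omics_bundle")
}

#' @export
print.omics_bundle <- function(x, ...) {
  cat(sprintf("<omics_bundle: %d genes x %d samples, layers: %s>\n",
              length(x$genes), length(x$samples),
              paste(names(x$datasets), collapse = ", ")))
  invisible(x)
}

#' Read a gene-drug association table
#'
#' The association table is the one mandatory input of the pipeline: a
#' tab-delimited file whose first two columns (`gene`, `drug`) link gene
#' symbols to drug names. Additional columns are ignored; duplicate pairs
#' are collapsed. Gene symbol case is preserved and matching elsewhere is
#' case-sensitive.
#'
#' @param path Path to the TSV.
#' @return A tibble of class `drug_gene_map` with columns `gene`, `drug`.
#' @export
read_drug_gene_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  if (nrow(df) == 0) {
    stop("gene-drug table is empty; it is the mandatory input", call. = FALSE)
  }
  if (ncol(df) < 2) stop("gene-drug table needs columns gene, drug", call. = FALSE)
  drug_gene_map(tibble::tibble(gene = df[[1]], drug = df[[2]]))
}

#' Construct a gene-drug map from a data frame
#'
#' @param df Data frame with columns `gene` and `drug`.
#' @return Deduplicated tibble of class `drug_gene_map`.
#' @export
drug_gene_map <- function(df) {
  stopifnot(all(c("gene", "drug") %in% names(df)))
  out <- tibble::as_tibble(df[, c("gene", "drug")])
  out$gene <- as.character(out$gene)
  out$drug <- as.character(out$drug)
  if (any(!nzchar(out$gene))) stop("empty gene symbol in drug map", call. = FALSE)
  out <- dplyr::distinct(out)
  class(out) <- c("drug_gene_map", class(out))
  out
}

#' Read an optional clinical table
#'
#' Rows are samples (first column `sample`), columns are free clinical
#' variables. Clinical data is carried through to outputs by sample id only;
#' it never enters clustering.
#'
#' @param path Path to the TSV.
#' @return A tibble with first column `sample`.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "")
  names(df)[1] <- "sample"
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample id in clinical table", call. = FALSE)
  }
  tibble::as_tibble(df)
}
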