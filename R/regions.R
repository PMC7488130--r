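#' Read a BED file of genomic regions
#'
#' BED3+ with 0-based half-open coordinates. Only the first four columns
#' (chrom, start, end, optional name) are used.
#'
#' @param path Path to the BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) stop("BED file has no intervals", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    stop(sprintf("BED line %d has fewer than 3 columns",
                 which(n_fields < 3)[1]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer BED coordinate", call. = FALSE)
  }
  name <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_,
                 character(1))
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    stop(sprintf("invalid interval at BED line %d: end <= start", bad[1]),
         call. = FALSE)
  }
  tibble::tibble(chrom = chrom, start = start, end = end, name = name)
}

#' Read a gene annotation table
#'
#' A 4-column TSV (chrom, start, end, gene) with 0-based half-open
#' coordinates, the same convention as the BED input. Exports from 1-based
#' sources (e.g. RefSeq tables from a genome browser) must have 1 subtracted
#' from their start coordinate first.
#'
#' @param path Path to the annotation TSV (header row required).
#' @return A tibble with columns `chrom`, `start`, `end`, `gene`.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "")
  if (ncol(df) < 4) stop("annotation needs columns chrom, start, end, gene",
                         call. = FALSE)
  out <- tibble::tibble(chrom = as.character(df[[1]]),
                        start = as.integer(df[[2]]),
                        end = as.integer(df[[3]]),
                        gene = as.character(df[[4]]))
  if (any(!nzchar(out$gene))) stop("empty gene symbol in annotation", call. = FALSE)
  if (any(out$end <= out$start | out$start < 0)) {
    stop("invalid annotation interval: end <= start", call. = FALSE)
  }
  out
}

#' Map genomic regions to a gene set by interval overlap
#'
#' A gene is selected when its annotation interval overlaps any query region
#' by at least 1 bp under half-open semantics (`a.start < b.end` and
#' `b.start < a.end`); touching intervals do not overlap. Strand is ignored.
#'
#' @param regions Tibble of regions as returned by [read_bed()].
#' @param annotation Tibble as returned by [read_gene_annotation()].
#' @return Character vector of unique gene symbols, lexicographic order.
#' @export
map_regions_to_genes <- function(regions, annotation) {
  if (nrow(regions) == 0 || nrow(annotation) == 0) {
    stop("regions and annotation must be non-empty", call. = FALSE)
  }
  # half-open 0-based -> closed 1-based for IRanges
  reg <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  ann <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end))
  hits <- GenomicRanges::findOverlaps(ann, reg, minoverlap = 1L)
  genes <- sort(unique(annotation$gene[S4Vectors::queryHits(hits)]))
  if (length(genes) == 0) {
    stop("no annotated gene overlaps any region; provide a gene list instead",
         call. = FALSE)
  }
  genes
}
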