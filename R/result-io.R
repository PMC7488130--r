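fmt_num <- function(x) {
  # full-precision numeric formatting so written tables re-read exactly
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
}

#' Write the cohort result table as a wide TSV
#'
#' One row per sample; for each module j the columns
#' `module_j_genes` (comma-joined symbols), `module_j_drugs` (comma-joined
#' or `NA`), `module_j_score_genes`, `module_j_score_drugs`,
#' `module_j_s_score` and one `module_j_sub_<rule>` per applied rule.
#' Patients with fewer modules than the table-wide maximum leave the
#' surplus module cells `NA`. Clinical columns, when present in the score
#' table, trail the module columns. Re-reading with
#' [read_result_table()] reproduces the score table exactly.
#'
#' @param scores A `module_scores` tibble from [score_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(scores, path) {
  stopifnot(is.data.frame(scores))
  sub_cols <- grep("^sub_", names(scores), value = TRUE)
  core <- c("patient", "module", "genes", "drugs", "score_genes",
            "score_drugs", "s_score", "n_genes", "n_drugs", sub_cols)
  clin_cols <- setdiff(names(scores), core)
  patients <- unique(scores$patient)
  k_max <- max(scores$module)

  lines <- character(length(patients))
  header <- "sample"
  for (j in seq_len(k_max)) {
    header <- c(header,
                sprintf("module_%d_%s", j,
                        c("genes", "drugs", "score_genes", "score_drugs",
                          "s_score", sub("^sub_", "sub_", sub_cols))))
  }
  header <- c(header, clin_cols)

  for (i in seq_along(patients)) {
    mods <- scores[scores$patient == patients[i], , drop = FALSE]
    cells <- patients[i]
    for (j in seq_len(k_max)) {
      row <- mods[mods$module == j, , drop = FALSE]
      if (nrow(row) == 0) {
        cells <- c(cells, rep("NA", 5 + length(sub_cols)))
      } else {
        cells <- c(cells, row$genes,
                   ifelse(is.na(row$drugs), "NA", row$drugs),
                   fmt_num(row$score_genes), fmt_num(row$score_drugs),
                   fmt_num(row$s_score),
                   vapply(sub_cols, function(sc) fmt_num(row[[sc]]),
                          character(1)))
      }
    }
    for (cc in clin_cols) {
      v <- mods[[cc]][1]
      cells <- c(cells, if (is.na(v)) "NA" else as.character(v))
    }
    lines[i] <- paste(cells, collapse = "\t")
  }
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  invisible(path)
}

#' Read a cohort result table written by [write_result_table()]
#'
#' @param path Path to the TSV.
#' @return A `module_scores` tibble (long form, one row per
#'   patient x module), with any clinical columns re-attached.
#' @export
read_result_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", na.strings = NULL)
  if (names(df)[1] != "sample") stop("result table must start with 'sample'",
                                     call. = FALSE)
  mod_cols <- grep("^module_\\d+_", names(df), value = TRUE)
  if (length(mod_cols) == 0) stop("no module columns found", call. = FALSE)
  k_max <- max(as.integer(sub("^module_(\\d+)_.*$", "\\1", mod_cols)))
  sub_names <- unique(sub("^module_\\d+_sub_", "",
                          grep("^module_\\d+_sub_", mod_cols, value = TRUE)))
  clin_cols <- setdiff(names(df), c("sample", mod_cols))

  rows <- list()
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(k_max)) {
      genes <- df[[sprintf("module_%d_genes", j)]][i]
      if (is.na(genes) || genes == "NA") next
      drugs <- df[[sprintf("module_%d_drugs", j)]][i]
      n_drugs <- if (drugs == "NA") 0L else
        length(strsplit(drugs, ",", fixed = TRUE)[[1]])
      row <- tibble::tibble(
        patient = df$sample[i], module = j, genes = genes,
        drugs = ifelse(drugs == "NA", NA_character_, drugs),
        score_genes = as.numeric(df[[sprintf("module_%d_score_genes", j)]][i]),
        score_drugs = as.numeric(df[[sprintf("module_%d_score_drugs", j)]][i]),
        s_score = as.numeric(df[[sprintf("module_%d_s_score", j)]][i]),
        n_genes = length(strsplit(genes, ",", fixed = TRUE)[[1]]),
        n_drugs = n_drugs)
      for (sn in sub_names) {
        row[[paste0("sub_", sn)]] <-
          as.numeric(df[[sprintf("module_%d_sub_%s", j, sn)]][i])
      }
      for (cc in clin_cols) {
        v <- df[[cc]][i]
        row[[cc]] <- if (v == "NA") NA_character_ else v
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("module_scores", class(out))
  out
}
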