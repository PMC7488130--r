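html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

score_color <- function(v, signed = FALSE) {
  # white -> red for [0,1]; blue -> white -> red for [-1,1]
  if (is.na(v)) return("#f0f0f0")
  if (signed) {
    if (v >= 0) {
      w <- 1 - min(1, v)
      sprintf("#ff%02x%02x", round(w * 255), round(w * 255))
    } else {
      w <- 1 - min(1, -v)
      sprintf("#%02x%02xff", round(w * 255), round(w * 255))
    }
  } else {
    w <- 1 - min(1, max(0, v))
    sprintf("#ff%02x%02x", round(w * 255), round(w * 255))
  }
}

gene_link <- function(gene) {
  sprintf('<a href="https://www.ncbi.nlm.nih.gov/gene/?term=%s">%s</a>',
          utils::URLencode(gene, reserved = TRUE), html_escape(gene))
}

drug_link <- function(drug) {
  sprintf('<a href="https://dgidb.org/results?searchType=drug&searchTerms=%s">%s</a>',
          utils::URLencode(drug, reserved = TRUE), html_escape(drug))
}

heatmap_table <- function(scores, metric, signed) {
  patients <- unique(scores$patient)
  mods <- sort(unique(scores$module))
  rows <- vapply(patients, function(p) {
    cells <- vapply(mods, function(m) {
      v <- scores[[metric]][scores$patient == p & scores$module == m]
      v <- if (length(v)) v[1] else NA_real_
      sprintf('<td style="background:%s;text-align:center">%s</td>',
              score_color(v, signed), ifelse(is.na(v), "NA", sprintf("%.3f", v)))
    }, character(1))
    sprintf("<tr><td>%s</td>%s</tr>", html_escape(p),
            paste(cells, collapse = ""))
  }, character(1))
  sprintf(
    '<table class="heatmap" data-metric="%s"><tr><th>patient</th>%s</tr>%s</table>',
    metric,
    paste(sprintf("<th>module %d</th>", mods), collapse = ""),
    paste(rows, collapse = "\n"))
}

split_cell <- function(x) {
  if (is.na(x) || x == "NA") character(0) else
    strsplit(x, ",", fixed = TRUE)[[1]]
}

#' Render a static HTML report of the analysis
#'
#' A single self-contained HTML file with cohort-level score heatmaps
#' (signed activation score, alteration density, druggable fraction) drawn
#' as colour-coded tables, and per-patient sections listing each module's
#' genes and drugs with NCBI and DGIdb hyperlinks. When a selection table
#' is supplied its rows are shown in a cohort summary.
#'
#' @param scores A `module_scores` tibble (or path to a results TSV).
#' @param out_html Output path for the HTML file.
#' @param selection Optional `module_selection` tibble (or path to a
#'   selection TSV).
#' @return `out_html`, invisibly.
#' @export
report_html <- function(scores, out_html, selection = NULL) {
  if (is.character(scores)) scores <- read_result_table(scores)
  if (is.character(selection)) selection <- read_selection(selection)
  stopifnot(all(c("patient", "module", "s_score") %in% names(scores)))

  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Gene module report</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse;margin:1em 0}td,th{border:1px solid #ccc;padding:4px 8px}h2{margin-top:2em}</style>",
    "</head><body>",
    "<h1>Per-patient gene module report</h1>",
    sprintf("<p>%d patients, %d module rows.</p>",
            length(unique(scores$patient)), nrow(scores)),
    "<h2>Summary heatmaps</h2>",
    "<h3>Signed activation score (S-score)</h3>",
    heatmap_table(scores, "s_score", signed = TRUE),
    "<h3>Genomic alteration density</h3>",
    heatmap_table(scores, "score_genes", signed = FALSE),
    "<h3>Druggable fraction</h3>",
    heatmap_table(scores, "score_drugs", signed = FALSE))

  if (!is.null(selection)) {
    rows <- vapply(seq_len(nrow(selection)), function(i) {
      sprintf("<tr><td>%s</td><td>%.3f</td><td>%s</td><td>%s</td><td>%s</td></tr>",
              html_escape(selection$patient[i]), selection$s_score[i],
              html_escape(selection$genes[i]),
              ifelse(is.na(selection$drugs[i]), "NA",
                     html_escape(selection$drugs[i])),
              if ("category" %in% names(selection))
                html_escape(selection$category[i]) else "")
    }, character(1))
    parts <- c(parts, "<h2>Selected modules</h2>",
               "<table><tr><th>patient</th><th>score</th><th>genes</th><th>drugs</th><th>category</th></tr>",
               rows, "</table>")
  }

  for (p in unique(scores$patient)) {
    mods <- scores[scores$patient == p, , drop = FALSE]
    parts <- c(parts, sprintf('<h2 class="patient" id="patient-%s">Patient %s</h2>',
                              html_escape(p), html_escape(p)))
    rows <- vapply(seq_len(nrow(mods)), function(i) {
      genes <- split_cell(mods$genes[i])
      drugs <- split_cell(mods$drugs[i])
      sprintf("<tr><td>%d</td><td>%s</td><td>%s</td><td>%.3f</td><td>%.3f</td><td>%.3f</td></tr>",
              mods$module[i],
              paste(vapply(genes, gene_link, character(1)), collapse = ", "),
              if (length(drugs))
                paste(vapply(drugs, drug_link, character(1)), collapse = ", ")
              else "NA",
              mods$score_genes[i], mods$score_drugs[i], mods$s_score[i])
    }, character(1))
    parts <- c(parts,
               "<table><tr><th>module</th><th>genes</th><th>drugs</th><th>score genes</th><th>score drugs</th><th>S-score</th></tr>",
               rows, "</table>")
  }
  parts <- c(parts, "</body></html>")
  writeLines(parts, out_html)
  invisible(out_html)
}
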