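#' Automatically select the most active (or inactive) druggable module
#'
#' For each patient, among modules with at least `min_drugs` attached
#' drugs, the module with the extremal signed activation score is chosen:
#' maximal `s_score` for `direction = "active"`, minimal for
#' `"inactive"`. Ties break by larger `score_drugs`, then by smaller
#' module index. When no module meets the drug constraint the best-scoring
#' module overall is selected as a fallback.
#'
#' Categories: for the active direction the selection is `AOMD` (active
#' oncogenic module with drugs) when the drug constraint is met and
#' `s_score > 0`, otherwise `AOM`; for the inactive direction it is `IOMD`
#' when the constraint is met and `s_score < 0`, otherwise `none`.
#'
#' @param scores A `module_scores` tibble from [score_all()].
#' @param direction `"active"` or `"inactive"`.
#' @param min_drugs Minimum number of attached drugs (default 1).
#' @return Tibble of class `module_selection`, one row per patient:
#'   `patient`, `module`, `s_score`, `genes`, `drugs`, `n_drugs`,
#'   `category`.
#' @export
select_active <- function(scores, direction = c("active", "inactive"),
                          min_drugs = 1) {
  direction <- match.arg(direction)
  if (nrow(scores) == 0) {
    out <- tibble::tibble(patient = character(), module = integer(),
                          s_score = numeric(), genes = character(),
                          drugs = character(), n_drugs = integer(),
                          category = character())
    class(out) <- c("module_selection", class(out))
    return(out)
  }
  sgn <- if (direction == "active") 1 else -1
  out <- purrr::map_dfr(unique(scores$patient), function(p) {
    mods <- scores[scores$patient == p, , drop = FALSE]
    eligible <- mods[mods$n_drugs >= min_drugs, , drop = FALSE]
    constrained <- nrow(eligible) > 0
    pool <- if (constrained) eligible else mods
    ord <- order(-sgn * pool$s_score, -pool$score_drugs, pool$module)
    best <- pool[ord[1], , drop = FALSE]
    category <- if (direction == "active") {
      if (constrained && best$s_score > 0) "AOMD" else "AOM"
    } else {
      if (constrained && best$s_score < 0) "IOMD" else "none"
    }
    tibble::tibble(patient = p, module = best$module, s_score = best$s_score,
                   genes = best$genes, drugs = best$drugs,
                   n_drugs = best$n_drugs, category = category)
  })
  class(out) <- c("module_selection", class(out))
  out
}

#' Count selected-module categories across a cohort
#'
#' @param selections A `module_selection` tibble from [select_active()].
#' @return Tibble with one row: `AOMD`, `AOM`, `IOMD`, `none`,
#'   `AOM_with_drug` (AOM selections that still carry >= 1 drug).
#' @export
cohort_counts <- function(selections) {
  cat_n <- function(cat) sum(selections$category == cat)
  tibble::tibble(
    AOMD = cat_n("AOMD"),
    AOM = cat_n("AOM"),
    IOMD = cat_n("IOMD"),
    none = cat_n("none"),
    AOM_with_drug = sum(selections$category == "AOM" & selections$n_drugs >= 1)
  )
}

#' Write a module selection as a TSV
#'
#' Four columns — patient id, module score, member genes, drugs — plus the
#' selection category as a fifth column unless `category = FALSE`. Empty
#' drug sets are written as `NA`.
#'
#' @param selections A `module_selection` tibble.
#' @param path Output path.
#' @param category Include the category column (default TRUE).
#' @return `path`, invisibly.
#' @export
write_selection <- function(selections, path, category = TRUE) {
  df <- data.frame(patient_id = selections$patient,
                   score = selections$s_score,
                   genes = selections$genes,
                   drugs = ifelse(is.na(selections$drugs), "NA",
                                  selections$drugs),
                   stringsAsFactors = FALSE)
  if (category) df$category <- selections$category
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module selection TSV written by [write_selection()]
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `patient`, `s_score`, `genes`, `drugs`
#'   (`NA` for empty) and `category` when present.
#' @export
read_selection <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  out <- tibble::tibble(patient = df$patient_id,
                        s_score = as.numeric(df$score),
                        genes = df$genes,
                        drugs = ifelse(df$drugs == "NA", NA_character_,
                                       df$drugs))
  if ("category" %in% names(df)) out$category <- df$category
  out
}
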