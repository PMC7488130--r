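effect_delta <- function(effect) {
  switch(match.arg(effect, c("strong", "moderate", "weak")),
         strong = 3, moderate = 1.5, weak = 0.5)
}

rbeta_mean <- function(n, mean, concentration = 10) {
  stats::rbeta(n, shape1 = mean * concentration,
               shape2 = (1 - mean) * concentration)
}

#' Generate a synthetic multi-omics cohort with planted module structure
#'
#' Builds a four-layer cohort (expression, copy number, methylation,
#' mutation) in which genes are partitioned into modules with planted
#' states. Module 1 is activated, module 2 suppressed, any further modules
#' neutral; per layer the draws are:
#'
#' * activated: expression ~ N(+delta, 1); copy number ~ N(+0.6, 0.15);
#'   methylation ~ Beta(mean 0.2, concentration 10); mutation ~
#'   Bernoulli(0.3)
#' * suppressed: expression ~ N(-delta, 1); copy number ~ N(-0.6, 0.15);
#'   methylation ~ Beta(mean 0.8); mutation ~ Bernoulli(0.02) (mutation is
#'   an activation signal, so suppressed modules stay at background rate)
#' * neutral: expression ~ N(0, 1); copy number ~ N(0, 0.1); methylation ~
#'   Beta(mean 0.5); mutation ~ Bernoulli(0.02)
#'
#' with delta = 3 / 1.5 / 0.5 for strong / moderate / weak effects. A
#' `druggable_fraction` of genes receives 1-3 synthetic drug names. Module
#' composition is shared cohort-wide by default (each patient carries the
#' same gene partition); `per_patient_modules = TRUE` re-partitions genes
#' independently per patient.
#'
#' @param n_patients,n_genes,n_modules Cohort dimensions
#'   (`n_genes >= 3 * n_modules`).
#' @param effect `"strong"`, `"moderate"` or `"weak"`.
#' @param druggable_fraction Fraction of genes given drug associations.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param per_patient_modules Randomize module composition per patient.
#' @return List with `bundle` ([align_bundle()] result), `drug_map`
#'   ([drug_gene_map()]), `truth` (list: `labels` tibble patient, gene,
#'   module; `states` tibble module, state; `druggable_genes`).
#' @export
generate_cohort <- function(n_patients = 10, n_genes = 60, n_modules = 3,
                            effect = "strong", druggable_fraction = 0.3,
                            seed = 1, per_patient_modules = FALSE) {
  if (n_patients < 1 || n_genes < 1 || n_modules < 1) {
    stop("cohort dimensions must be positive", call. = FALSE)
  }
  if (n_genes < 3 * n_modules) {
    stop("need n_genes >= 3 * n_modules", call. = FALSE)
  }
  if (druggable_fraction < 0 || druggable_fraction > 1) {
    stop("druggable_fraction must lie in [0, 1]", call. = FALSE)
  }
  delta <- effect_delta(effect)
  set.seed(as.integer(seed))

  genes <- sprintf("GENE%03d", seq_len(n_genes))
  patients <- sprintf("P%03d", seq_len(n_patients))
  states <- rep(c("activated", "suppressed", rep("neutral", n_modules)),
                length.out = n_modules)

  partition_genes <- function() {
    lab <- rep(seq_len(n_modules), length.out = n_genes)
    sample(lab)
  }
  shared_labels <- partition_genes()

  layers <- list(
    expression = matrix(0, n_genes, n_patients,
                        dimnames = list(genes, patients)),
    copy_number = matrix(0, n_genes, n_patients,
                         dimnames = list(genes, patients)),
    methylation = matrix(0, n_genes, n_patients,
                         dimnames = list(genes, patients)),
    mutation = matrix(0, n_genes, n_patients,
                      dimnames = list(genes, patients)))

  truth_rows <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    labels <- if (per_patient_modules) partition_genes() else shared_labels
    truth_rows[[p]] <- tibble::tibble(patient = patients[p], gene = genes,
                                      module = labels)
    for (mod in seq_len(n_modules)) {
      idx <- which(labels == mod)
      n_m <- length(idx)
      st <- states[mod]
      if (st == "activated") {
        layers$expression[idx, p] <- stats::rnorm(n_m, delta, 1)
        layers$copy_number[idx, p] <- stats::rnorm(n_m, 0.6, 0.15)
        layers$methylation[idx, p] <- rbeta_mean(n_m, 0.2)
        layers$mutation[idx, p] <- stats::rbinom(n_m, 1, 0.3)
      } else if (st == "suppressed") {
        layers$expression[idx, p] <- stats::rnorm(n_m, -delta, 1)
        layers$copy_number[idx, p] <- stats::rnorm(n_m, -0.6, 0.15)
        layers$methylation[idx, p] <- rbeta_mean(n_m, 0.8)
        layers$mutation[idx, p] <- stats::rbinom(n_m, 1, 0.02)
      } else {
        layers$expression[idx, p] <- stats::rnorm(n_m, 0, 1)
        layers$copy_number[idx, p] <- stats::rnorm(n_m, 0, 0.1)
        layers$methylation[idx, p] <- rbeta_mean(n_m, 0.5)
        layers$mutation[idx, p] <- stats::rbinom(n_m, 1, 0.02)
      }
    }
  }

  n_druggable <- round(druggable_fraction * n_genes)
  druggable <- sort(sample(genes, n_druggable))
  assoc <- if (n_druggable > 0) {
    purrr::map_dfr(druggable, function(g) {
      nd <- sample(1:3, 1)
      tibble::tibble(gene = g,
                     drug = sprintf("drug_%s_%d", g, seq_len(nd)))
    })
  } else {
    tibble::tibble(gene = character(), drug = character())
  }

  datasets <- purrr::imap(layers, function(v, kind) omics_dataset(v, kind))
  bundle <- suppressMessages(align_bundle(unname(datasets)))
  truth <- list(labels = dplyr::bind_rows(truth_rows),
                states = tibble::tibble(module = seq_len(n_modules),
                                        state = states),
                druggable_genes = druggable)
  list(bundle = bundle,
       drug_map = if (nrow(assoc)) drug_gene_map(assoc) else {
         out <- assoc; class(out) <- c("drug_gene_map", class(out)); out
       },
       truth = truth)
}

#' Write a generated cohort to disk
#'
#' Writes the four omics TSVs, the drugs TSV and a truth JSON into a
#' directory, in the exact formats the readers expect.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (kind in names(cohort$bundle$datasets)) {
    write_omics_table(cohort$bundle$datasets[[kind]],
                      file.path(dir, paste0(kind, ".tsv")))
  }
  dm <- cohort$drug_map
  utils::write.table(data.frame(gene = dm$gene, drug = dm$drug),
                     file.path(dir, "drugs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(labels = cohort$truth$labels, states = cohort$truth$states,
         druggable_genes = cohort$truth$druggable_genes),
    file.path(dir, "truth.json"))
  invisible(dir)
}

truth_labels_for <- function(truth, patient, genes) {
  lab <- truth$labels[truth$labels$patient == patient, , drop = FALSE]
  stats::setNames(lab$module, lab$gene)[genes]
}

#' Module-recovery experiment on synthetic cohorts
#'
#' Runs the full pipeline (generate, cluster with the chosen strategy at
#' the true number of modules, score, select) on `n_reps` independently
#' seeded cohorts and reports the mean adjusted Rand index between
#' recovered and planted gene modules, plus the fraction of patients whose
#' planted activated module contains a druggable gene that are flagged
#' AOMD by the automatic selection.
#'
#' @param method `"m1"` (RF proximity + k-means) or `"m2"` (logic rules +
#'   k-modes).
#' @param effect Planted effect size passed to [generate_cohort()].
#' @param n_reps Number of replicate cohorts.
#' @param seed Integer base seed; replicate r uses `seed + 1000 * r`.
#' @param n_patients,n_genes,n_modules Cohort dimensions.
#' @param n_trees,n_init Strategy-specific effort knobs.
#' @return Tibble with one row: `method`, `effect`, `n_reps`, `mean_ari`,
#'   `aomd_detection_rate` (NA when no patient has a druggable planted
#'   activated module), `n_eligible` patients for that rate.
#' @export
recovery_experiment <- function(method = c("m1", "m2"), effect = "strong",
                                n_reps = 5, seed = 1, n_patients = 10,
                                n_genes = 60, n_modules = 3, n_trees = 500,
                                n_init = 10) {
  method <- match.arg(method)
  aris <- numeric(0)
  n_eligible <- 0L
  n_detected <- 0L
  for (r in seq_len(n_reps)) {
    rseed <- as.integer(seed) + 1000L * r
    cohort <- generate_cohort(n_patients = n_patients, n_genes = n_genes,
                              n_modules = n_modules, effect = effect,
                              seed = rseed)
    assignments <- if (method == "m1") {
      run_m1(cohort$bundle, k = n_modules, n_trees = n_trees, seed = rseed)
    } else {
      run_m2(cohort$bundle, k = n_modules, n_init = n_init, seed = rseed)
    }
    for (p in names(assignments)) {
      est <- assignments[[p]]$labels
      tru <- truth_labels_for(cohort$truth, p, names(est))
      aris <- c(aris, mclust::adjustedRandIndex(est, tru))
    }
    scores <- score_all(assignments, cohort$bundle, cohort$drug_map)
    sel <- select_active(scores, direction = "active", min_drugs = 1)
    act_mod <- cohort$truth$states$module[
      cohort$truth$states$state == "activated"]
    for (p in names(assignments)) {
      tru <- truth_labels_for(cohort$truth, p,
                              names(assignments[[p]]$labels))
      act_genes <- names(tru)[tru %in% act_mod]
      has_druggable <- length(intersect(act_genes,
                                        cohort$truth$druggable_genes)) > 0
      if (has_druggable) {
        n_eligible <- n_eligible + 1L
        if (sel$category[sel$patient == p] == "AOMD") {
          n_detected <- n_detected + 1L
        }
      }
    }
  }
  tibble::tibble(method = method, effect = effect, n_reps = n_reps,
                 mean_ari = mean(aris),
                 aomd_detection_rate = if (n_eligible > 0)
                   n_detected / n_eligible else NA_real_,
                 n_eligible = n_eligible)
}
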