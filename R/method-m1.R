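#' Assemble one patient's gene-by-layer feature matrix
#'
#' Extracts the patient's column from every layer, giving a G x m matrix
#' (genes by omics layers). Continuous columns are standardized to zero
#' mean, unit variance across genes (constant columns become all-zero);
#' binary 0/1 mutation columns are left on their original scale so tree
#' splits see them as indicators. Raw (unstandardized) values are retained
#' for rule evaluation against absolute thresholds.
#'
#' @param bundle An [align_bundle()] result.
#' @param patient Sample id present in the bundle.
#' @param standardize Standardize continuous columns (default TRUE).
#' @return Object of class `patient_matrix`: `patient`, `genes`, `layers`,
#'   `values` (standardized G x m), `raw` (unstandardized G x m).
#' @export
assemble_patient_matrix <- function(bundle, patient, standardize = TRUE) {
  stopifnot(inherits(bundle, "omics_bundle"))
  if (!patient %in% bundle$samples) {
    stop("patient '", patient, "' not present in the bundle", call. = FALSE)
  }
  raw <- vapply(bundle$datasets,
                function(d) d$values[bundle$genes, patient],
                numeric(length(bundle$genes)))
  raw <- matrix(raw, nrow = length(bundle$genes),
                dimnames = list(bundle$genes, names(bundle$datasets)))
  vals <- raw
  if (standardize) {
    for (j in seq_len(ncol(vals))) {
      col <- vals[, j]
      is_binary <- names(bundle$datasets)[j] == "mutation" &&
        all(col %in% c(0, 1))
      if (is_binary) next
      s <- stats::sd(col)
      vals[, j] <- if (is.na(s) || s == 0) 0 else (col - mean(col)) / s
    }
  }
  structure(list(patient = patient, genes = bundle$genes,
                 layers = names(bundle$datasets), values = vals, raw = raw),
            class = "patient_matrix")
}

#' Unsupervised random-forest proximity between genes
#'
#' Trains an unsupervised random forest on the patient matrix (real rows vs
#' a synthetic class built by independently permuting each column, the
#' Breiman product-of-marginals scheme as implemented in the randomForest
#' package) and returns the gene-gene proximity matrix: the proportion of
#' trees in which two genes land in the same terminal node, computed over
#' all trees so that identical rows have proximity exactly 1.
#'
#' @param pm A [assemble_patient_matrix()] result.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed; the forest is deterministic given the seed.
#' @param mtry Variables tried per split; default `max(1, floor(sqrt(m)))`.
#' @return Object of class `proximity_matrix`: `genes` plus a symmetric
#'   `values` matrix in \[0, 1\] with unit diagonal.
#' @export
rf_proximity <- function(pm, n_trees = 500, seed = 1,
                         mtry = max(1L, floor(sqrt(ncol(pm$values))))) {
  stopifnot(inherits(pm, "patient_matrix"))
  if (length(pm$genes) < 4) {
    stop("at least 4 genes are needed to grow a proximity forest; ",
         "provide a larger gene set", call. = FALSE)
  }
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = pm$values, ntree = n_trees,
                                   mtry = mtry, proximity = TRUE,
                                   oob.prox = FALSE)
  prox <- rf$proximity
  prox <- (prox + t(prox)) / 2
  diag(prox) <- 1
  prox[prox < 0] <- 0
  prox[prox > 1] <- 1
  dimnames(prox) <- list(pm$genes, pm$genes)
  structure(list(genes = pm$genes, values = prox, patient = pm$patient),
            class = "proximity_matrix")
}

#' Construct a proximity matrix object from a plain matrix
#'
#' Validates symmetry, unit diagonal and the \[0, 1\] range.
#'
#' @param values Square numeric matrix with gene dimnames.
#' @return A `proximity_matrix`.
#' @export
proximity_matrix <- function(values) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("g", seq_len(nrow(values)))
  }
  if (max(abs(values - t(values))) > 1e-8) {
    stop("proximity matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(values) - 1) > 1e-8)) {
    stop("proximity diagonal must be 1", call. = FALSE)
  }
  if (min(values) < -1e-8 || max(values) > 1 + 1e-8) {
    stop("proximity values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(genes = rownames(values), values = values, patient = NA),
            class = "proximity_matrix")
}

#' Cluster genes by k-means on proximity profiles
#'
#' Each gene is represented by its row of the proximity matrix (its
#' proximity profile to every gene) and genes are clustered with k-means
#' (Euclidean, multiple seeded restarts). Module labels are canonical:
#' module 1 is the module containing the lexicographically first gene, and
#' so on, making assignments comparable across runs.
#'
#' @param prox A `proximity_matrix`.
#' @param k Number of modules, `2 <= k <= n_genes`.
#' @param seed Integer seed.
#' @param n_restarts Number of k-means restarts (default 10).
#' @return Object of class `module_assignment`: `patient`, `labels` (named
#'   integer vector gene -> module in 1..k), `k`.
#' @export
cluster_proximity <- function(prox, k, seed = 1, n_restarts = 10) {
  stopifnot(inherits(prox, "proximity_matrix"))
  n <- length(prox$genes)
  if (k < 2 || k > n) {
    stop("k must satisfy 2 <= k <= number of genes", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_distinct <- sum(!duplicated(prox$values))
  if (k > n_distinct) {
    message(sprintf("only %d distinct proximity profiles: reducing k from %d",
                    n_distinct, k))
    k <- n_distinct
  }
  if (k == n) {
    labels <- seq_len(n)
  } else if (k == 1) {
    labels <- rep(1L, n)
  } else {
    fit <- suppressWarnings(
      stats::kmeans(prox$values, centers = k, nstart = n_restarts,
                    iter.max = 300))
    labels <- fit$cluster
  }
  names(labels) <- prox$genes
  module_assignment(labels, patient = prox$patient)
}

#' Construct a module assignment with canonical labels
#'
#' @param labels Named integer vector, gene -> raw cluster label.
#' @param patient Sample id (or NA).
#' @return A `module_assignment` with labels relabelled 1..k in order of
#'   each module's lexicographically first gene.
#' @export
module_assignment <- function(labels, patient = NA) {
  stopifnot(!is.null(names(labels)))
  genes <- names(labels)
  ord <- order(genes)
  first_seen <- labels[ord][!duplicated(labels[ord])]
  remap <- stats::setNames(seq_along(first_seen), first_seen)
  canon <- as.integer(remap[as.character(labels)])
  names(canon) <- genes
  structure(list(patient = patient, labels = canon, k = length(first_seen)),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment: patient %s, %d genes in %d modules>\n",
              x$patient, length(x$labels), x$k))
  invisible(x)
}

#' Tidy a module assignment into a gene-level tibble
#'
#' @param x A `module_assignment`.
#' @param ... Unused.
#' @return Tibble with columns `patient`, `gene`, `module`.
#' @importFrom generics tidy
#' @export
tidy.module_assignment <- function(x, ...) {
  tibble::tibble(patient = x$patient, gene = names(x$labels),
                 module = unname(x$labels))
}

#' One-row summary of a module assignment
#'
#' @param x A `module_assignment`.
#' @param ... Unused.
#' @return Tibble with `patient`, `k`, `n_genes`, `largest_module`.
#' @importFrom generics glance
#' @export
glance.module_assignment <- function(x, ...) {
  tibble::tibble(patient = x$patient, k = x$k, n_genes = length(x$labels),
                 largest_module = max(table(x$labels)))
}

#' Choose the number of modules by silhouette analysis
#'
#' Runs [cluster_proximity()] for each k in `[k_min, k_max]` and returns the
#' k maximizing the mean silhouette width (Euclidean distance on proximity
#' rows). Ties break toward the smaller k (parsimony).
#'
#' @param prox A `proximity_matrix`.
#' @param k_min,k_max Inclusive search range; `2 <= k_min <= k_max <= n - 1`.
#' @param seed Integer seed.
#' @param n_restarts Restarts per k.
#' @return The selected k (integer). The silhouette profile is attached as
#'   attribute `"silhouette"` (tibble k, mean_width).
#' @export
select_k_silhouette <- function(prox, k_min = 2,
                                k_max = min(10, length(prox$genes) - 1),
                                seed = 1, n_restarts = 10) {
  stopifnot(inherits(prox, "proximity_matrix"))
  n <- length(prox$genes)
  if (k_min < 2 || k_max > n - 1 || k_min > k_max) {
    stop("need 2 <= k_min <= k_max <= n_genes - 1", call. = FALSE)
  }
  d <- stats::dist(prox$values)
  ks <- seq.int(k_min, k_max)
  widths <- vapply(ks, function(k) {
    asg <- cluster_proximity(prox, k, seed = seed, n_restarts = n_restarts)
    if (length(unique(asg$labels)) < 2) return(-Inf)
    sil <- cluster::silhouette(asg$labels, d)
    mean(sil[, "sil_width"])
  }, numeric(1))
  best <- ks[which.max(widths)]  # which.max takes the first maximum: ties -> smaller k
  attr(best, "silhouette") <- tibble::tibble(k = ks, mean_width = widths)
  best
}

#' Run the random-forest proximity strategy over a cohort
#'
#' For every patient: assemble the G x m matrix, compute the unsupervised
#' RF proximity, optionally select k by silhouette, and k-means-cluster the
#' proximity rows into gene modules. Patients are processed independently
#' with per-patient seeds `seed + patient index`, so results do not depend
#' on processing order.
#'
#' @param bundle An [align_bundle()] result.
#' @param k Number of modules, or `"auto"` for silhouette selection.
#' @param n_trees Trees per forest.
#' @param seed Integer base seed.
#' @param standardize Standardize continuous columns (default TRUE).
#' @param n_restarts k-means restarts.
#' @return Named list of `module_assignment`, one per patient.
#' @export
run_m1 <- function(bundle, k = "auto", n_trees = 500, seed = 1,
                   standardize = TRUE, n_restarts = 10) {
  stopifnot(inherits(bundle, "omics_bundle"))
  out <- vector("list", length(bundle$samples))
  names(out) <- bundle$samples
  for (i in seq_along(bundle$samples)) {
    patient <- bundle$samples[i]
    pseed <- as.integer(seed) + i
    pm <- assemble_patient_matrix(bundle, patient, standardize = standardize)
    prox <- rf_proximity(pm, n_trees = n_trees, seed = pseed)
    kk <- if (identical(k, "auto")) {
      as.integer(select_k_silhouette(prox, seed = pseed,
                                     n_restarts = n_restarts))
    } else {
      as.integer(k)
    }
    out[[patient]] <- cluster_proximity(prox, kk, seed = pseed,
                                        n_restarts = n_restarts)
  }
  out
}
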