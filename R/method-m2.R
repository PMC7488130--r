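#' Default logic rules for binarizing a patient's genomic profile
#'
#' Seven crisp rules, one per common alteration signal. Expression rules
#' operate on the within-patient z-score across genes (scale-free), while
#' copy-number, methylation and mutation rules operate on raw values with
#' conventional absolute thresholds. Every threshold can be overridden.
#'
#' \describe{
#'   \item{over_expressed}{expression z-score > +1}
#'   \item{under_expressed}{expression z-score < -1}
#'   \item{cn_gain}{copy number > +0.3}
#'   \item{cn_loss}{copy number < -0.3}
#'   \item{hyper_methylated}{beta > 0.7}
#'   \item{hypo_methylated}{beta < 0.3}
#'   \item{mutated}{mutation value >= 1}
#' }
#'
#' @param overrides Named list/vector of numeric threshold overrides, e.g.
#'   `list(cn_gain = 0.5)`.
#' @return Tibble of class `rule_set` with columns `name`, `layer`,
#'   `direction` (`above`/`below`/`at_least`), `threshold`, `sign`
#'   (`activating`/`suppressing`), `on_standardized`.
#' @export
default_rules <- function(overrides = list()) {
  rules <- tibble::tibble(
    name = c("over_expressed", "under_expressed", "cn_gain", "cn_loss",
             "hyper_methylated", "hypo_methylated", "mutated"),
    layer = c("expression", "expression", "copy_number", "copy_number",
              "methylation", "methylation", "mutation"),
    direction = c("above", "below", "above", "below", "above", "below",
                  "at_least"),
    threshold = c(1, -1, 0.3, -0.3, 0.7, 0.3, 1),
    sign = c("activating", "suppressing", "activating", "suppressing",
             "suppressing", "activating", "activating"),
    on_standardized = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("threshold overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), rules$name)
    if (length(unknown)) {
      stop("unknown rule name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(overrides)) {
      val <- overrides[[nm]]
      if (!is.numeric(val) || length(val) != 1 || is.na(val)) {
        stop("threshold for rule '", nm, "' must be a single number",
             call. = FALSE)
      }
      rules$threshold[rules$name == nm] <- as.numeric(val)
    }
  }
  class(rules) <- c("rule_set", class(rules))
  rules
}

#' Read a custom rule set from a TSV
#'
#' Columns: name, layer, direction (above/below/at_least), threshold, and
#' optionally sign (activating/suppressing; defaults to activating for
#' above/at_least, suppressing for below) and on_standardized (0/1,
#' defaults to 1 for expression rules).
#'
#' @param path Path to the TSV.
#' @return A `rule_set` tibble.
#' @export
read_rule_set <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "")
  need <- c("name", "layer", "direction", "threshold")
  if (!all(need %in% names(df))) {
    stop("rule file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rules <- tibble::tibble(
    name = as.character(df$name),
    layer = as.character(df$layer),
    direction = as.character(df$direction),
    threshold = as.numeric(df$threshold),
    sign = if ("sign" %in% names(df)) as.character(df$sign) else
      ifelse(df$direction == "below", "suppressing", "activating"),
    on_standardized = if ("on_standardized" %in% names(df))
      as.logical(as.integer(df$on_standardized)) else
      df$layer == "expression"
  )
  if (anyDuplicated(rules$name)) stop("duplicate rule name", call. = FALSE)
  if (!all(rules$direction %in% c("above", "below", "at_least"))) {
    stop("rule direction must be above, below or at_least", call. = FALSE)
  }
  if (!all(rules$layer %in% LAYER_KINDS)) {
    stop("rule layer must be one of: ", paste(LAYER_KINDS, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(rules$threshold)) stop("non-numeric rule threshold", call. = FALSE)
  class(rules) <- c("rule_set", class(rules))
  rules
}

#' Binarize a patient matrix with logic rules
#'
#' Produces the g x r binary matrix: cell (gene, rule) is 1 when the gene's
#' value in the rule's layer satisfies the rule. Only rules whose layer is
#' present in the patient matrix are applied. Inequalities for
#' `above`/`below` are strict; `at_least` is `>=`.
#'
#' @param pm A [assemble_patient_matrix()] result.
#' @param rules A `rule_set` (default [default_rules()]).
#' @return Object of class `rule_matrix`: `patient`, `genes`, `rules`
#'   (applied subset of the rule set), `values` (binary g x r matrix).
#' @export
binarize_rules <- function(pm, rules = default_rules()) {
  stopifnot(inherits(pm, "patient_matrix"), inherits(rules, "rule_set"))
  applied <- rules[rules$layer %in% pm$layers, , drop = FALSE]
  if (nrow(applied) == 0) {
    stop("no rule matches any layer of the patient matrix", call. = FALSE)
  }
  vals <- matrix(0L, nrow = length(pm$genes), ncol = nrow(applied),
                 dimnames = list(pm$genes, applied$name))
  for (j in seq_len(nrow(applied))) {
    src <- if (applied$on_standardized[j]) pm$values else pm$raw
    x <- src[, applied$layer[j]]
    hit <- switch(applied$direction[j],
                  above = x > applied$threshold[j],
                  below = x < applied$threshold[j],
                  at_least = x >= applied$threshold[j])
    vals[, j] <- as.integer(hit)
  }
  structure(list(patient = pm$patient, genes = pm$genes, rules = applied,
                 values = vals),
            class = "rule_matrix")
}

#' @export
print.rule_matrix <- function(x, ...) {
  cat(sprintf("<rule_matrix: patient %s, %d genes x %d rules>\n",
              x$patient, nrow(x$values), ncol(x$values)))
  invisible(x)
}

hamming_to_centroids <- function(x, centroids) {
  # n x k matrix of Hamming distances from each row of x to each centroid
  d <- vapply(seq_len(nrow(centroids)), function(j) {
    rowSums(x != matrix(centroids[j, ], nrow(x), ncol(x), byrow = TRUE))
  }, numeric(nrow(x)))
  matrix(d, nrow = nrow(x), ncol = nrow(centroids))
}

column_modes <- function(x, prev = NULL) {
  # per-column mode of a binary matrix; ties -> previous centroid value,
  # else 0
  ones <- colSums(x)
  zeros <- nrow(x) - ones
  mode <- as.integer(ones > zeros)
  tie <- ones == zeros
  if (any(tie)) {
    mode[tie] <- if (is.null(prev)) 0L else as.integer(prev[tie])
  }
  mode
}

kmodes_once <- function(x, k, max_iter = 100) {
  n <- nrow(x)
  init_pool <- which(!duplicated(x))
  centroids <- x[sample(init_pool, k), , drop = FALSE]
  labels <- integer(n)
  cost_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d <- hamming_to_centroids(x, centroids)
    labels <- max.col(-d, ties.method = "first")
    # re-seed any empty cluster on the point farthest from its centroid:
    # the centroid jumps to that point, so its cost drops to 0 and the
    # per-iteration cost stays monotone non-increasing
    for (j in seq_len(k)) {
      if (!any(labels == j)) {
        far <- which.max(d[cbind(seq_len(n), labels)])
        centroids[j, ] <- x[far, ]
        labels[far] <- j
        d[, j] <- rowSums(x != matrix(centroids[j, ], n, ncol(x), byrow = TRUE))
      }
    }
    cost <- sum(d[cbind(seq_len(n), labels)])
    cost_trace <- c(cost_trace, cost)
    new_centroids <- centroids
    for (j in seq_len(k)) {
      members <- x[labels == j, , drop = FALSE]
      new_centroids[j, ] <- column_modes(members, prev = centroids[j, ])
    }
    if (all(new_centroids == centroids)) break
    centroids <- new_centroids
  }
  d <- hamming_to_centroids(x, centroids)
  labels <- max.col(-d, ties.method = "first")
  cost <- sum(d[cbind(seq_len(n), labels)])
  cost_trace <- c(cost_trace, cost)
  list(labels = labels, centroids = centroids, cost = cost,
       cost_trace = cost_trace)
}

#' Cluster a binary rule matrix with k-modes
#'
#' Huang's k-modes for categorical data: dissimilarity is the Hamming
#' distance (number of mismatching rule columns), centroids are per-column
#' modes, and assignment/update iterate to convergence. The best of
#' `n_init` seeded restarts (random distinct rows as initial centroids) by
#' total within-cluster dissimilarity is returned. When fewer than k
#' distinct rows exist the effective k is reduced (with a message) and
#' reported in the result. Labels are canonical as in
#' [cluster_proximity()].
#'
#' @param rm A `rule_matrix` (or plain binary matrix with gene rownames).
#' @param k Number of modules, `1 <= k <= n_genes`.
#' @param n_init Number of restarts (default 10).
#' @param seed Integer seed.
#' @return A `module_assignment` with extra fields `cost` (total
#'   within-cluster Hamming dissimilarity) and `cost_trace` of the winning
#'   restart.
#' @export
kmodes_cluster <- function(rm, k, n_init = 10, seed = 1) {
  x <- if (inherits(rm, "rule_matrix")) rm$values else rm
  patient <- if (inherits(rm, "rule_matrix")) rm$patient else NA
  stopifnot(is.matrix(x), all(x %in% c(0L, 1L)))
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= n_genes", call. = FALSE)
  n_distinct <- sum(!duplicated(x))
  if (k > n_distinct) {
    message(sprintf("only %d distinct rows: reducing k from %d", n_distinct, k))
    k <- n_distinct
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- kmodes_once(x, k)
    if (is.null(best) || fit$cost < best$cost) best <- fit
  }
  labels <- best$labels
  names(labels) <- rownames(x)
  asg <- module_assignment(labels, patient = patient)
  asg$cost <- best$cost
  asg$cost_trace <- best$cost_trace
  asg
}

#' Run the logic-rule strategy over a cohort
#'
#' For every patient: assemble the patient matrix, binarize it with the
#' rule set, and k-modes-cluster the g x r binary matrix into gene modules.
#' Per-patient seeds are `seed + patient index`, so patients are
#' independent of processing order.
#'
#' @param bundle An [align_bundle()] result.
#' @param k Number of modules.
#' @param rules A `rule_set` (default [default_rules()]).
#' @param n_init k-modes restarts per patient.
#' @param seed Integer base seed.
#' @return Named list of `module_assignment`, one per patient.
#' @export
run_m2 <- function(bundle, k, rules = default_rules(), n_init = 10, seed = 1) {
  stopifnot(inherits(bundle, "omics_bundle"))
  out <- vector("list", length(bundle$samples))
  names(out) <- bundle$samples
  for (i in seq_along(bundle$samples)) {
    patient <- bundle$samples[i]
    pseed <- as.integer(seed) + i
    pm <- assemble_patient_matrix(bundle, patient)
    rm_ <- binarize_rules(pm, rules)
    out[[patient]] <- kmodes_cluster(rm_, k, n_init = n_init, seed = pseed)
  }
  out
}
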