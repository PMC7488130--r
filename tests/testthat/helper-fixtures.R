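# Fixture builders and independent oracles shared across test files.

make_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

write_tsv_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# small aligned two-layer bundle over 3 genes x 2 samples
tiny_bundle <- function() {
  expr <- omics_dataset(make_matrix(c(1, 2, 0.5, 0.1, 3, 0), c("A", "B", "C"),
                                    c("s1", "s2")), "expression")
  cn <- omics_dataset(make_matrix(c(0.4, -0.4, 0, 0.1, -0.5, 0.5),
                                  c("A", "B", "C"), c("s1", "s2")),
                      "copy_number")
  suppressMessages(align_bundle(list(expr, cn)))
}

random_patient_matrix <- function(n_genes, seed, layers = c("expression",
                                                            "copy_number",
                                                            "methylation",
                                                            "mutation")) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  cols <- lapply(layers, function(l) switch(
    l,
    expression = rnorm(n_genes),
    copy_number = rnorm(n_genes, 0, 0.5),
    methylation = runif(n_genes),
    mutation = rbinom(n_genes, 1, 0.3),
    rnorm(n_genes)))
  raw <- do.call(cbind, cols)
  dimnames(raw) <- list(genes, layers)
  vals <- raw
  for (j in seq_along(layers)) {
    if (layers[j] == "mutation") next
    s <- sd(raw[, j])
    vals[, j] <- if (s == 0) 0 else (raw[, j] - mean(raw[, j])) / s
  }
  structure(list(patient = "px", genes = genes, layers = layers,
                 values = vals, raw = raw),
            class = "patient_matrix")
}

# random symmetric proximity matrix with unit diagonal, values in [0, 1]
random_proximity <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(sprintf("g%02d", seq_len(n)), sprintf("g%02d", seq_len(n)))
  proximity_matrix(m)
}

# block proximity: `sizes` blocks with given within/between proximity
block_proximity <- function(sizes, within = 0.95, between = 0.05) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  m <- matrix(between, n, n)
  for (b in seq_along(sizes)) {
    idx <- which(lab == b)
    m[idx, idx] <- within
  }
  diag(m) <- 1
  dimnames(m) <- list(sprintf("g%02d", seq_len(n)), sprintf("g%02d", seq_len(n)))
  proximity_matrix(m)
}

# --- independent oracles ------------------------------------------------

# all restricted-growth strings of length n with at most k distinct labels
# (i.e. every partition of n items into <= k blocks, canonically labelled)
rgs_partitions <- function(n, k) {
  out <- list()
  recurse <- function(prefix, max_used) {
    i <- length(prefix) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(min(max_used + 1, k))) {
      recurse(c(prefix, lab), max(max_used, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# total within-cluster Hamming cost of a labelling with mode centroids
kmodes_partition_cost <- function(x, labels) {
  cost <- 0
  for (j in unique(labels)) {
    rows <- x[labels == j, , drop = FALSE]
    ones <- colSums(rows)
    cost <- cost + sum(pmin(ones, nrow(rows) - ones))
  }
  cost
}

# exhaustive k-modes optimum over all partitions into <= k blocks
bf_kmodes_optimum <- function(x, k) {
  min(vapply(rgs_partitions(nrow(x), k), function(lab)
    kmodes_partition_cost(x, lab), numeric(1)))
}

# within-cluster sum of squares of a labelling with mean centroids
kmeans_partition_sse <- function(x, labels) {
  sse <- 0
  for (j in unique(labels)) {
    rows <- x[labels == j, , drop = FALSE]
    ctr <- colMeans(rows)
    sse <- sse + sum(sweep(rows, 2, ctr)^2)
  }
  sse
}

# exhaustive k-means optimum over all partitions into <= k non-empty blocks
bf_kmeans_optimum <- function(x, k) {
  min(vapply(rgs_partitions(nrow(x), k), function(lab)
    kmeans_partition_sse(x, lab), numeric(1)))
}

# all-pairs brute-force half-open interval overlap scan
bf_region_genes <- function(regions, annotation) {
  hits <- character(0)
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(annotation))) {
      if (regions$chrom[i] == annotation$chrom[j] &&
          regions$start[i] < annotation$end[j] &&
          annotation$start[j] < regions$end[i]) {
        hits <- c(hits, annotation$gene[j])
      }
    }
  }
  sort(unique(hits))
}

# mean silhouette width computed directly from its definition
bf_mean_silhouette <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  widths <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else NA_real_
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    if (is.na(a)) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(widths)
}

# exhaustive per-patient selection scan under the declared ordering
bf_select <- function(scores, direction, min_drugs) {
  sgn <- if (direction == "active") 1 else -1
  do.call(rbind, lapply(unique(scores$patient), function(p) {
    mods <- scores[scores$patient == p, , drop = FALSE]
    pool <- mods[mods$n_drugs >= min_drugs, , drop = FALSE]
    constrained <- nrow(pool) > 0
    if (!constrained) pool <- mods
    best <- NULL
    for (i in seq_len(nrow(pool))) {
      cand <- pool[i, ]
      if (is.null(best) ||
          sgn * cand$s_score > sgn * best$s_score ||
          (cand$s_score == best$s_score &&
           cand$score_drugs > best$score_drugs) ||
          (cand$s_score == best$s_score &&
           cand$score_drugs == best$score_drugs &&
           cand$module < best$module)) {
        best <- cand
      }
    }
    category <- if (direction == "active") {
      if (constrained && best$s_score > 0) "AOMD" else "AOM"
    } else {
      if (constrained && best$s_score < 0) "IOMD" else "none"
    }
    data.frame(patient = p, module = best$module, category = category,
               stringsAsFactors = FALSE)
  }))
}

# random scored table for selection tests
random_score_table <- function(n_patients, max_k, seed) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_patients), function(p) {
    k <- sample(2:max_k, 1)
    data.frame(patient = sprintf("p%02d", p), module = seq_len(k),
               genes = "G1", drugs = NA_character_,
               score_genes = round(runif(k), 2),
               score_drugs = round(runif(k), 1),
               s_score = round(runif(k, -1, 1), 1),
               n_genes = 1L, n_drugs = sample(0:3, k, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  out <- tibble::as_tibble(rows)
  class(out) <- c("module_scores", class(out))
  out
}
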