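test_that("patient matrices extract the right columns and standardize", {
  b <- tiny_bundle()
  pm <- assemble_patient_matrix(b, "s1", standardize = FALSE)
  expect_equal(unname(pm$raw[, "expression"]),
               unname(b$datasets$expression$values[, "s1"]))
  expect_equal(unname(pm$raw[, "copy_number"]),
               unname(b$datasets$copy_number$values[, "s1"]))
  expect_equal(pm$genes, b$genes)

  pmz <- assemble_patient_matrix(b, "s1")
  for (j in seq_len(ncol(pmz$values))) {
    expect_lt(abs(mean(pmz$values[, j])), 1e-9)
    expect_lt(abs(stats::var(pmz$values[, j]) - 1), 1e-9)
  }
  expect_error(assemble_patient_matrix(b, "nope"), "not present")
})

test_that("constant columns standardize to all-zero", {
  expr <- omics_dataset(make_matrix(rep(5, 4), paste0("G", 1:4), "s1"),
                        "expression")
  cn <- omics_dataset(make_matrix(c(1, 2, 3, 4), paste0("G", 1:4), "s1"),
                      "copy_number")
  b <- align_bundle(list(expr, cn))
  pm <- assemble_patient_matrix(b, "s1")
  expect_equal(unname(pm$values[, "expression"]), rep(0, 4))
})

test_that("binary mutation columns are left unstandardized", {
  expr <- omics_dataset(make_matrix(rnorm(6), paste0("G", 1:6), "s1"),
                        "expression")
  mut <- omics_dataset(make_matrix(c(0, 1, 0, 0, 1, 0), paste0("G", 1:6), "s1"),
                       "mutation")
  b <- align_bundle(list(expr, mut))
  pm <- assemble_patient_matrix(b, "s1")
  expect_equal(unname(pm$values[, "mutation"]), c(0, 1, 0, 0, 1, 0))
})

test_that("RF proximity satisfies its invariants and pins duplicate rows", {
  for (seed in c(2, 7)) {
    pm <- random_patient_matrix(12, seed)
    pm$values[2, ] <- pm$values[1, ]  # duplicated gene profile
    prox <- rf_proximity(pm, n_trees = 200, seed = seed)
    v <- prox$values
    expect_equal(v, t(v))
    expect_equal(unname(diag(v)), rep(1, 12))
    expect_true(min(v) >= 0 && max(v) <= 1)
    expect_identical(v[1, 2], 1)
  }
})

test_that("RF proximity separates well-separated blocks", {
  set.seed(31)
  genes <- sprintf("g%02d", 1:20)
  vals <- rbind(matrix(rnorm(30, +3, 0.1), 10, 3),
                matrix(rnorm(30, -3, 0.1), 10, 3))
  dimnames(vals) <- list(genes, c("expression", "copy_number", "other"))
  pm <- structure(list(patient = "px", genes = genes,
                       layers = colnames(vals), values = scale(vals),
                       raw = vals), class = "patient_matrix")
  prox <- rf_proximity(pm, n_trees = 500, seed = 31)
  v <- prox$values
  within <- c(v[1:10, 1:10][upper.tri(v[1:10, 1:10])],
              v[11:20, 11:20][upper.tri(v[11:20, 11:20])])
  between <- v[1:10, 11:20]
  expect_gt(mean(within), mean(between))
})

test_that("proximity forest refuses tiny gene sets", {
  pm <- random_patient_matrix(3, 1)
  expect_error(rf_proximity(pm), "larger gene set")
})

test_that("k-means on block-diagonal proximity recovers the blocks", {
  prox <- block_proximity(c(4, 4), within = 1, between = 0)
  asg <- cluster_proximity(prox, k = 2, seed = 1)
  expect_equal(unname(asg$labels), rep(c(1L, 2L), each = 4))
  expect_equal(asg$k, 2L)
  # canonical labels: module 1 holds the lexicographically first gene
  expect_equal(unname(asg$labels[sort(prox$genes)[1]]), 1L)
})

test_that("k = n gives every gene its own module; k out of range errors", {
  prox <- random_proximity(6, 3)
  asg <- cluster_proximity(prox, k = 6, seed = 1)
  expect_equal(sort(unname(asg$labels)), 1:6)
  expect_error(cluster_proximity(prox, k = 1, seed = 1), "k must")
  expect_error(cluster_proximity(prox, k = 7, seed = 1), "k must")
})

test_that("silhouette selection finds planted block counts", {
  prox <- block_proximity(c(8, 8, 8))
  k <- select_k_silhouette(prox, 2, 6, seed = 4)
  expect_equal(as.integer(k), 3L)
  # the attached profile agrees with a direct-formula recomputation
  profile <- attr(k, "silhouette")
  for (i in seq_len(nrow(profile))) {
    asg <- cluster_proximity(prox, profile$k[i], seed = 4)
    expect_equal(profile$mean_width[i],
                 bf_mean_silhouette(prox$values, asg$labels),
                 tolerance = 1e-9)
  }

  perfect <- block_proximity(c(5, 5), within = 1, between = 0)
  k2 <- select_k_silhouette(perfect, 2, 4, seed = 4)
  expect_equal(as.integer(k2), 2L)
  prof <- attr(k2, "silhouette")
  expect_gt(prof$mean_width[prof$k == 2], 0.9)

  expect_equal(as.integer(select_k_silhouette(prox, 4, 4, seed = 1)), 4L)
})

test_that("the cohort-level m1 run is deterministic and order-independent", {
  co <- generate_cohort(n_patients = 3, n_genes = 18, n_modules = 2, seed = 8)
  a <- run_m1(co$bundle, k = 2, n_trees = 100, seed = 8)
  b <- run_m1(co$bundle, k = 2, n_trees = 100, seed = 8)
  expect_identical(a, b)
  expect_length(a, 3)
  # each patient's result depends only on its own data and derived seed
  pm <- assemble_patient_matrix(co$bundle, co$bundle$samples[2])
  prox <- rf_proximity(pm, n_trees = 100, seed = 8 + 2)
  expect_identical(a[[2]], cluster_proximity(prox, 2, seed = 8 + 2))
})
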