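test_that("default rules carry the documented thresholds and overrides work", {
  rules <- default_rules()
  expect_equal(nrow(rules), 7)
  expect_setequal(rules$name, c("over_expressed", "under_expressed",
                                "cn_gain", "cn_loss", "hyper_methylated",
                                "hypo_methylated", "mutated"))
  expect_equal(rules$threshold[rules$name == "cn_gain"], 0.3)
  expect_equal(rules$threshold[rules$name == "hyper_methylated"], 0.7)

  over <- default_rules(list(cn_gain = 0.5))
  expect_equal(over$threshold[over$name == "cn_gain"], 0.5)
  expect_error(default_rules(list(cn_gain = "high")), "single number")
  expect_error(default_rules(list(nonsense = 1)), "unknown rule")
})

test_that("rule binarization applies strict thresholds per layer", {
  genes <- paste0("G", 1:4)
  raw <- cbind(expression = c(5, -5, 0, 1),
               copy_number = c(0, 0.4, -0.4, 0.3))
  rownames(raw) <- genes
  vals <- raw
  vals[, 1] <- (raw[, 1] - mean(raw[, 1])) / sd(raw[, 1])
  pm <- structure(list(patient = "p", genes = genes,
                       layers = colnames(raw), values = vals, raw = raw),
                  class = "patient_matrix")
  rm_ <- binarize_rules(pm)
  expect_setequal(colnames(rm_$values),
                  c("over_expressed", "under_expressed", "cn_gain", "cn_loss"))
  expect_equal(unname(rm_$values["G1", c("over_expressed", "under_expressed",
                                         "cn_gain", "cn_loss")]),
               c(1L, 0L, 0L, 0L))
  # boundary: cn exactly at +0.3 is NOT a gain (strict inequality)
  expect_equal(unname(rm_$values["G4", "cn_gain"]), 0L)
})

test_that("only rules matching the provided layers are applied", {
  pm <- random_patient_matrix(10, 3, layers = c("expression", "mutation"))
  rm_ <- binarize_rules(pm)
  expect_setequal(colnames(rm_$values),
                  c("over_expressed", "under_expressed", "mutated"))

  # adding a layer only adds columns; removing removes exactly its rules
  pm4 <- random_patient_matrix(10, 3)
  rm4 <- binarize_rules(pm4)
  expect_true(all(colnames(rm_$values) %in% colnames(rm4$values)))
  expect_setequal(setdiff(colnames(rm4$values), colnames(rm_$values)),
                  c("cn_gain", "cn_loss", "hyper_methylated",
                    "hypo_methylated"))

  pm_none <- random_patient_matrix(6, 1, layers = c("other"))
  expect_error(binarize_rules(pm_none), "no rule")
})

test_that("binarization equals a naive per-cell oracle on random inputs", {
  rules <- default_rules()
  for (seed in 1:20) {
    pm <- random_patient_matrix(20, seed)
    rm_ <- binarize_rules(pm, rules)
    for (g in pm$genes) {
      for (j in seq_len(nrow(rules))) {
        r <- rules[j, ]
        if (!r$layer %in% pm$layers) next
        x <- if (r$on_standardized) pm$values[g, r$layer] else pm$raw[g, r$layer]
        expected <- switch(r$direction,
                           above = x > r$threshold,
                           below = x < r$threshold,
                           at_least = x >= r$threshold)
        expect_identical(rm_$values[g, r$name], as.integer(expected))
      }
    }
    expect_true(all(rm_$values %in% c(0L, 1L)))
  }
})

test_that("k-modes separates perfectly separable binary rows at zero cost", {
  x <- rbind(matrix(rep(c(1, 0, 0), 3), 3, byrow = TRUE),
             matrix(rep(c(0, 1, 1), 3), 3, byrow = TRUE))
  rownames(x) <- paste0("g", 1:6)
  asg <- kmodes_cluster(x, k = 2, n_init = 5, seed = 1)
  expect_equal(unname(asg$labels), rep(c(1L, 2L), each = 3))
  expect_equal(asg$cost, 0)
})

test_that("k-modes on identical rows collapses to one cluster", {
  x <- matrix(1, 6, 3, dimnames = list(paste0("g", 1:6), NULL))
  asg1 <- kmodes_cluster(x, k = 1, seed = 1)
  expect_equal(asg1$k, 1L)
  expect_equal(asg1$cost, 0)
  expect_message(asg2 <- kmodes_cluster(x, k = 3, seed = 1), "distinct rows")
  expect_equal(asg2$k, 1L)
})

test_that("k-modes cost is monotone non-increasing across iterations", {
  for (seed in 1:25) {
    set.seed(seed)
    x <- matrix(rbinom(10 * 5, 1, 0.5), 10, 5,
                dimnames = list(sprintf("g%02d", 1:10), NULL))
    asg <- kmodes_cluster(x, k = 3, n_init = 3, seed = seed)
    expect_true(all(diff(asg$cost_trace) <= 0))
  }
})

test_that("k-modes with many restarts attains the exhaustive optimum", {
  for (seed in 1:10) {
    set.seed(seed)
    g <- sample(5:8, 1)
    r <- sample(3:4, 1)
    x <- matrix(rbinom(g * r, 1, 0.5), g, r,
                dimnames = list(sprintf("g%02d", seq_len(g)), NULL))
    asg <- kmodes_cluster(x, k = 2, n_init = 50, seed = seed)
    expect_equal(asg$cost, bf_kmodes_optimum(x, 2))
  }
})

test_that("the cohort-level m2 run is deterministic and per-patient", {
  co <- generate_cohort(n_patients = 3, n_genes = 15, n_modules = 2, seed = 6)
  a <- run_m2(co$bundle, k = 2, seed = 6)
  b <- run_m2(co$bundle, k = 2, seed = 6)
  expect_identical(a, b)
  expect_length(a, 3)
  pm <- assemble_patient_matrix(co$bundle, co$bundle$samples[3])
  rm_ <- binarize_rules(pm)
  expect_identical(a[[3]], kmodes_cluster(rm_, 2, n_init = 10, seed = 6 + 3))
})
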