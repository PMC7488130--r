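test_that("omics tables round-trip through read/write with values intact", {
  path <- write_tsv_text(c("gene\ts1\ts2", "A\t1.0\t2.0", "B\t0.5\t0.1",
                           "C\t3.0\t0.0"))
  ds <- read_omics_table(path, "expression")
  expect_s3_class(ds, "omics_dataset")
  expect_equal(dim(ds), c(3L, 2L))
  expect_equal(ds$values, make_matrix(c(1, 2, 0.5, 0.1, 3, 0),
                                      c("A", "B", "C"), c("s1", "s2")))
  out <- tempfile()
  write_omics_table(ds, out)
  expect_equal(read_omics_table(out, "expression")$values, ds$values)
})

test_that("invalid omics tables are rejected with informative errors", {
  dup <- write_tsv_text(c("gene\ts1", "TP53\t1", "TP53\t2"))
  expect_error(read_omics_table(dup, "expression"), "TP53")

  meth <- write_tsv_text(c("gene\ts1", "A\t0.4", "B\t1.3"))
  expect_error(read_omics_table(meth, "methylation"), "\\[0, 1\\]")

  bad <- write_tsv_text(c("gene\ts1\ts2", "A\t1\tx", "B\t2\t3"))
  expect_error(read_omics_table(bad, "expression"), "A.*s2")

  frac_mut <- write_tsv_text(c("gene\ts1", "A\t0.5"))
  expect_error(read_omics_table(frac_mut, "mutation"), "integer")
})

test_that("missing cells are imputed per layer policy", {
  mut <- write_tsv_text(c("gene\ts1\ts2", "A\tNA\t1"))
  expect_message(ds <- read_omics_table(mut, "mutation"), "imputed")
  expect_equal(unname(ds$values["A", ]), c(0, 1))

  expr <- write_tsv_text(c("gene\ts1\ts2\ts3", "A\t1\t\t3"))
  expect_message(ds <- read_omics_table(expr, "expression"), "imputed")
  expect_equal(unname(ds$values["A", "s2"]), 2)  # row median
})

test_that("align_bundle intersects genes and samples deterministically", {
  d1 <- omics_dataset(make_matrix(1:6, c("A", "B", "C"), c("s1", "s2")),
                      "expression")
  d2 <- omics_dataset(make_matrix(1:6, c("B", "C", "D"), c("s2", "s1")),
                      "copy_number")
  b <- suppressMessages(align_bundle(list(d2, d1)))
  expect_equal(b$genes, c("B", "C"))
  expect_equal(b$samples, c("s1", "s2"))
  # canonical layer order regardless of argument order
  expect_equal(names(b$datasets), c("expression", "copy_number"))

  d3 <- omics_dataset(make_matrix((1:6) / 10, c("B", "C", "D"),
                                  c("s3", "s4")), "methylation")
  expect_error(suppressMessages(align_bundle(list(d1, d3))), "sample")
  expect_error(align_bundle(list(d1)), "two")
})

test_that("aligning three identical layers keeps all genes and samples", {
  genes <- paste0("G", 1:5)
  samples <- paste0("s", 1:4)
  mk <- function(kind) omics_dataset(
    make_matrix(seq_len(20), genes, samples), kind)
  b <- align_bundle(list(mk("expression"), mk("copy_number"), mk("other")))
  expect_length(b$genes, 5)
  expect_length(b$samples, 4)
  expect_length(b$datasets, 3)
})

test_that("align_bundle is idempotent on already-aligned layers", {
  b <- tiny_bundle()
  b2 <- align_bundle(b$datasets)
  expect_equal(b2$genes, b$genes)
  expect_equal(b2$samples, b$samples)
  expect_equal(lapply(b2$datasets, `[[`, "values"),
               lapply(b$datasets, `[[`, "values"))
})

test_that("drug-gene map reads, deduplicates and rejects empty files", {
  path <- write_tsv_text(c("gene\tdrug", "ERCC6\tcisplatin", "ATR\tolaparib",
                           "ATR\ttemozolomide"))
  dm <- read_drug_gene_map(path)
  expect_equal(nrow(dm), 3)
  expect_equal(sort(unique(dm$gene)), c("ATR", "ERCC6"))

  dup <- write_tsv_text(c("gene\tdrug", "ATR\tolaparib", "ATR\tolaparib"))
  expect_equal(nrow(read_drug_gene_map(dup)), 1)

  empty <- write_tsv_text("gene\tdrug")
  expect_error(read_drug_gene_map(empty), "mandatory")
})

test_that("result tables round-trip and partition the gene set", {
  co <- generate_cohort(n_patients = 3, n_genes = 15, n_modules = 3,
                        seed = 42)
  scores <- score_all(run_m2(co$bundle, k = 3, seed = 42), co$bundle,
                      co$drug_map)
  path <- tempfile()
  write_result_table(scores, path)
  back <- read_result_table(path)
  expect_equal(as.data.frame(back), as.data.frame(scores))

  # every gene appears in exactly one module per patient
  for (p in unique(scores$patient)) {
    genes <- unlist(strsplit(scores$genes[scores$patient == p], ","))
    expect_setequal(genes, co$bundle$genes)
    expect_equal(anyDuplicated(genes), 0L)
  }
})

test_that("modules without drugs serialize as NA", {
  co <- generate_cohort(n_patients = 2, n_genes = 12, n_modules = 2,
                        druggable_fraction = 0, seed = 5)
  expect_equal(nrow(co$drug_map), 0)
  scores <- score_all(run_m2(co$bundle, k = 2, seed = 5), co$bundle,
                      co$drug_map)
  expect_true(all(is.na(scores$drugs)))
  path <- tempfile()
  write_result_table(scores, path)
  raw <- readLines(path)
  expect_true(grepl("\tNA\t", raw[2]))
})

test_that("clinical variables are carried through by sample id only", {
  co <- generate_cohort(n_patients = 3, n_genes = 12, n_modules = 2, seed = 9)
  clin <- tibble::tibble(sample = c("P001", "P002", "P003"),
                         stage = c("II", "III", "I"))
  scores <- score_all(run_m2(co$bundle, k = 2, seed = 9), co$bundle,
                      co$drug_map, clinical = clin)
  expect_true("stage" %in% names(scores))
  expect_equal(unique(scores$stage[scores$patient == "P002"]), "III")
  path <- tempfile()
  write_result_table(scores, path)
  back <- read_result_table(path)
  expect_equal(back$stage, scores$stage)
})
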