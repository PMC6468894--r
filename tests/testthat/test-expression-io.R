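test_that("expression matrix ingestion parses, validates, and log-transforms", {
  dir <- withr::local_tempdir()
  mat_path <- write_tsv_fixture(
    data.frame(probeset = c("p1", "p2", "p3"),
               s1 = c(5.2, 7.1, 6.6), s2 = c(4.9, 8.0, 6.1)),
    file.path(dir, "expr.tsv"))
  ann_path <- write_tsv_fixture(
    data.frame(sample_id = c("s1", "s2"), group = c("SHH", "cerebellum")),
    file.path(dir, "ann.tsv"))

  ds <- read_expression_matrix(mat_path, ann_path, "d1", "mouse")
  expect_s3_class(ds, "expr_dataset")
  expect_equal(dim(ds), c(3L, 2L))
  expect_equal(unname(ds$sample_groups), c("SHH", "cerebellum"))
  expect_equal(ds$matrix["p2", "s2"], 8.0)

  # linear-looking values get log2(x + 1); detection is idempotent
  lin_path <- write_tsv_fixture(
    data.frame(probeset = c("p1", "p2"), s1 = c(12000, 300), s2 = c(40, 7)),
    file.path(dir, "lin.tsv"))
  expect_message(
    ds_lin <- read_expression_matrix(lin_path, ann_path, "d2", "human"),
    "log2")
  expect_equal(max(ds_lin$matrix), log2(12001), tolerance = 1e-12)
  ds_round <- expression_dataset(ds_lin$matrix, c(s1 = "SHH", s2 = "cerebellum"),
                                 "human", "d2b", feature_level = "probeset")
  expect_true(max(ds_round$matrix) < 50)  # would not re-trigger

  # annotation missing a sample names the offender
  bad_ann <- write_tsv_fixture(data.frame(sample_id = "s1", group = "SHH"),
                               file.path(dir, "bad_ann.tsv"))
  expect_error(read_expression_matrix(mat_path, bad_ann, "d3", "human"), "s2")

  # duplicate feature ids are a hard error
  dup_path <- write_tsv_fixture(
    data.frame(probeset = c("p1", "p1"), s1 = c(1, 2), s2 = c(3, 4)),
    file.path(dir, "dup.tsv"))
  expect_error(read_expression_matrix(dup_path, ann_path, "d4", "human"),
               "duplicate feature")
})

test_that("rows with missing values are dropped and counted", {
  m <- matrix(c(1, NA, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expect_message(
    ds <- expression_dataset(m, c(s1 = "A", s2 = "B"), "human", "na",
                             feature_level = "gene"),
    "1 row")
  expect_equal(nrow(ds$matrix), 2L)
  expect_equal(ds$n_dropped_na, 1L)
})

test_that("expression dataset round-trips through disk", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset(values = rnorm(20, 7, 2))
  write_expression_matrix(ds, file.path(dir, "m.tsv"), file.path(dir, "a.tsv"))
  back <- read_expression_matrix(file.path(dir, "m.tsv"),
                                 file.path(dir, "a.tsv"), ds$dataset_id,
                                 ds$species, feature_level = "gene")
  expect_equal(back$matrix, ds$matrix, tolerance = 1e-6)
  expect_identical(back$sample_groups, ds$sample_groups)
})

test_that("GMT parsing uppercases, deduplicates, errors on bad lines", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("SETA\tdesc\tGli1\tPTCH1",
               "SETB\tdesc\tA\tA\tB"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets$name, c("SETA", "SETB"))
  expect_equal(sets$genes[[1]], c("GLI1", "PTCH1"))
  expect_equal(sort(sets$genes[[2]]), c("A", "B"))

  writeLines(c("S1\td\tX", "S1\td\tY"), gmt)
  expect_error(read_gmt(gmt), "duplicate")
  writeLines(c("S1\td\tX", "ONLY\tTWO"), gmt)
  expect_error(read_gmt(gmt), "line 2")

  # write/read round-trip
  good <- tibble::tibble(name = c("A", "B"), description = c("x", "y"),
                         genes = list(c("G1", "G2"), c("G3", "G4", "G5")))
  write_gmt(good, gmt)
  expect_equal(read_gmt(gmt), good)
})

test_that("homolog map resolves case-convention pairs and ambiguities", {
  dir <- withr::local_tempdir()
  path <- write_tsv_fixture(
    data.frame(mouse = c("Gpr153", "Shisa2"), human = c("GPR153", "SHISA2")),
    file.path(dir, "hom.tsv"))
  hm <- read_homolog_map(path)
  expect_equal(nrow(hm), 2L)
  expect_equal(hm$human[hm$mouse == "Gpr153"], "GPR153")

  amb <- write_tsv_fixture(data.frame(mouse = c("A", "A"), human = c("X", "Y")),
                           file.path(dir, "amb.tsv"))
  expect_message(hm2 <- read_homolog_map(amb), "2 ambiguous")
  expect_equal(nrow(hm2), 0L)
  expect_equal(attr(hm2, "n_ambiguous"), 2L)

  hm3 <- read_homolog_map(mouse_genes = c("Gli1", "Mouseonly"),
                          human_genes = c("GLI1", "HUMANONLY"))
  expect_equal(hm3, tibble::tibble(mouse = "Gli1", human = "GLI1"),
               ignore_attr = TRUE)
})

test_that("result tables are written with documented deterministic order", {
  dir <- withr::local_tempdir()
  gsea_like <- tibble::tibble(set_name = c("a", "b", "c"),
                              nes = c(1.2, -2.5, 2.0),
                              fwer_p = c(0.5, 0.01, 0.01))
  out <- write_results(gsea_like, file.path(dir, "g.tsv"))
  expect_equal(out$set_name, c("b", "c", "a"))  # fwer asc, |nes| desc

  diff_like <- tibble::tibble(gene = c("X", "Y"), diff = c(-0.2, 0.9))
  out2 <- write_results(diff_like, file.path(dir, "d.tsv"))
  expect_equal(out2$gene, c("Y", "X"))

  expect_error(write_results(tibble::tibble(), file.path(dir, "e.tsv")),
               "non-empty")
})
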