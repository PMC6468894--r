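make_median_tbl <- function(values, groups, features = NULL, species = "human",
                            id = "d1") {
  m <- matrix(values, ncol = length(groups), byrow = TRUE)
  if (is.null(features)) features <- sprintf("GENE%02d", seq_len(nrow(m)))
  out <- dplyr::bind_cols(tibble::tibble(feature = features),
                          tibble::as_tibble(`colnames<-`(m, groups)))
  attr(out, "dataset_id") <- id
  attr(out, "species") <- species
  attr(out, "feature_level") <- "gene"
  out
}

test_that("row-centering produces overexpression values summing to zero", {
  tbl <- make_median_tbl(c(2, 4, 6,
                           5, 5, 5,
                           1, 2, 10), c("SHH", "Group3", "Group4"))
  ct <- center_rows(tbl)
  expect_equal(unlist(ct[1, -1]), c(SHH = -2, Group3 = 0, Group4 = 2))
  expect_equal(unlist(ct[2, -1]), c(SHH = 0, Group3 = 0, Group4 = 0))
  expect_equal(unlist(ct[3, -1]),
               c(SHH = 1 - 13 / 3, Group3 = 2 - 13 / 3, Group4 = 10 - 13 / 3),
               tolerance = 1e-12)
  expect_equal(attr(ct, "mode"), "row_centered")
  expect_error(center_rows(make_median_tbl(1:3, "SHH")), ">= 2")

  # conservation holds for arbitrary random tables
  withr::local_seed(21)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    tbl <- make_median_tbl(rnorm(40 * k), paste0("G", seq_len(k)))
    sums <- rowSums(as.matrix(center_rows(tbl)[, -1]))
    expect_lt(max(abs(sums)), 1e-9 * k)
  }
})

test_that("cerebellum normalization zeroes the control column", {
  tbl <- make_median_tbl(c(7.0, 5.5,
                           3.0, 3.0), c("Shh", "cerebellum"),
                         species = "mouse")
  cn <- cerebellum_normalize(tbl, "cerebellum")
  expect_equal(cn$cerebellum, c(0, 0))
  expect_equal(cn$Shh, c(1.5, 0))
  expect_equal(attr(cn, "mode"), "cerebellum_normalized")
  expect_error(cerebellum_normalize(tbl, "missing"), "missing")

  # identical columns give all zeros
  same <- make_median_tbl(rep(rnorm(5), each = 2), c("Shh", "cerebellum"))
  expect_true(all(as.matrix(cerebellum_normalize(same, "cerebellum")[, -1]) == 0))
})

test_that("quantile ranks span [0,1] with average-rank ties", {
  tbl <- make_median_tbl(c(0.1, 0, 0.5, 0, 0.9, 0), c("SHH", "Group3"),
                         features = c("A", "B", "C"))
  rv <- quantile_rank(tbl, "SHH")
  expect_equal(setNames(rv$qrank, rv$gene), c(A = 0, B = 0.5, C = 1))

  tied <- make_median_tbl(c(1, 0, 1, 0, 2, 0), c("SHH", "Group3"),
                          features = c("A", "B", "C"))
  rv2 <- quantile_rank(tied, "SHH")
  expect_equal(setNames(rv2$qrank, rv2$gene), c(A = 0.25, B = 0.25, C = 1))

  # n untied values rank exactly {0, 1/(n-1), ..., 1}; uniform ECDF
  withr::local_seed(22)
  big <- make_median_tbl(as.vector(rbind(rnorm(1000), 0)), c("SHH", "Group3"),
                         features = sprintf("G%04d", 1:1000))
  rv3 <- quantile_rank(big, "SHH")
  expect_equal(sort(rv3$qrank), seq(0, 1, length.out = 1000))
  expect_gt(suppressWarnings(ks.test(rv3$qrank, "punif"))$p.value, 0.01)

  # invariance under strictly monotone transforms of the scores
  mono <- big
  mono$SHH <- exp(2 * mono$SHH + 1)
  expect_equal(quantile_rank(mono, "SHH")$qrank, rv3$qrank)

  # case-insensitive target group finds the mouse-cased column
  mtbl <- make_median_tbl(c(1, 0, 2, 0), c("Shh", "cerebellum"),
                          species = "mouse", features = c("Ga", "Gb"))
  expect_equal(quantile_rank(mtbl, "SHH")$qrank, c(0, 1))
  expect_error(quantile_rank(tbl, "Group9"), "Group9")
})

test_that("species rank averaging uses partial means over homolog pairs", {
  hm <- tibble::tibble(mouse = c("Gli1", "Ptch1"), human = c("GLI1", "PTCH1"))
  rv <- function(genes, ranks, species, id) {
    out <- tibble::tibble(gene = genes, qrank = ranks)
    attr(out, "species") <- species
    attr(out, "dataset_id") <- id
    out
  }
  h <- average_ranks_by_species(
    list(rv(c("GLI1", "PTCH1"), c(0.2, 0.9), "human", "h1"),
         rv("GLI1", 0.4, "human", "h2"),
         rv(c("Gli1", "Ptch1"), c(1, 1), "mouse", "m1")),
    "human", hm)
  expect_equal(h$mean_rank[h$gene == "GLI1"], 0.3)
  expect_equal(h$n_datasets[h$gene == "GLI1"], 2L)
  expect_equal(h$mean_rank[h$gene == "PTCH1"], 0.9)
  expect_equal(h$n_datasets[h$gene == "PTCH1"], 1L)

  m <- average_ranks_by_species(
    list(rv(c("Gli1", "Unmapped1"), c(0.8, 0.5), "mouse", "m1")), "mouse", hm)
  expect_equal(m$gene, "GLI1")  # unmapped mouse symbols dropped
  expect_error(average_ranks_by_species(list(), "mouse", hm), "mouse")
})

test_that("rank differences carry specificity labels and are antisymmetric", {
  h <- tibble::tibble(gene = c("A", "B", "C", "D"),
                      mean_rank = c(0.9, 0.95, 0.1, 0.5),
                      n_datasets = 3L)
  m <- tibble::tibble(gene = c("A", "B", "C", "D"),
                      mean_rank = c(0.1, 0.97, 0.85, 0.5),
                      n_datasets = 3L)
  rd <- rank_difference(h, m)
  expect_equal(rd$diff[rd$gene == "A"], 0.8)
  expect_equal(rd$label[rd$gene == "A"], "human_specific")
  expect_equal(rd$label[rd$gene == "B"], "shared")
  expect_equal(rd$label[rd$gene == "C"], "mouse_specific")
  expect_equal(rd$label[rd$gene == "D"], "neither")
  expect_equal(rd$gene, rd$gene[order(-rd$diff)])  # sorted descending

  swapped <- rank_difference(m, h)
  expect_equal(
    setNames(swapped$diff, swapped$gene)[rd$gene],
    -setNames(rd$diff, rd$gene))
  expect_error(rank_difference(h, tibble::tibble(gene = "Z", mean_rank = 1,
                                                 n_datasets = 1L)),
               "both species")
})

test_that("correlogram is symmetric with unit diagonal and exact extremes", {
  hm <- tibble::tibble(mouse = paste0("Mg", 1:20),
                       human = toupper(paste0("Mg", 1:20)))
  tbl <- make_median_tbl(as.vector(rbind(rnorm(20), 0)), c("SHH", "Group3"),
                         features = toupper(paste0("Mg", 1:20)), id = "h1")
  tbl2 <- tbl
  attr(tbl2, "dataset_id") <- "h2"
  cg <- dataset_correlogram(list(tbl, tbl2), hm)
  expect_equal(diag(cg$r), c(h1 = 1, h2 = 1))
  expect_equal(cg$r["h1", "h2"], 1)           # identical tables
  expect_equal(cg$r, t(cg$r))
  expect_equal(cg$n["h1", "h2"], 20L)

  td <- tidy(cg)
  expect_equal(nrow(td), 1L)
  expect_equal(td$comparison, "within_human")

  few <- make_median_tbl(c(1, 0, 2, 0), c("SHH", "Group3"),
                         features = c("MG1", "ZZZ"), id = "h3")
  expect_error(dataset_correlogram(list(tbl, few), hm), "fewer than 3")
  expect_error(dataset_correlogram(list(tbl), hm), ">= 2")
})

test_that("rank concordance regression recovers exact and null relations", {
  r <- setNames(seq(0, 1, length.out = 50), sprintf("G%02d", 1:50))
  # lm warns about the degenerate exact fits; the fit itself is the point
  self <- suppressWarnings(rank_concordance(r, r))
  expect_equal(self$r_squared, 1)
  expect_equal(self$slope, 1)
  expect_equal(self$n, 50L)

  anti <- suppressWarnings(rank_concordance(r, 1 - r))
  expect_equal(anti$r_squared, 1)
  expect_equal(anti$slope, -1)

  withr::local_seed(23)
  n <- 2000
  a <- setNames(runif(n), sprintf("G%04d", 1:n))
  b <- setNames(runif(n), sprintf("G%04d", 1:n))
  null <- rank_concordance(a, b)
  expect_lt(null$r_squared, 0.05)

  expect_error(rank_concordance(r[1:2], r[1:2]), "3 shared")
  expect_s3_class(glance(self), "tbl_df")
  expect_equal(suppressWarnings(tidy(self))$estimate[2], 1)
})
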