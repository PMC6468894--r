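test_that("enrichment score handles single-gene boundary sets exactly", {
  rl <- ranked_list(c(g1 = 3, g2 = 2, g3 = 1, g4 = 0.5))
  top <- enrichment_score(rl, "g1")
  expect_equal(top$es, 1)
  expect_equal(top$leading_edge, "G1")
  bottom <- enrichment_score(rl, "g4")
  expect_equal(bottom$es, -1)
  expect_equal(bottom$leading_edge, "G4")

  expect_error(enrichment_score(rl, "absent"), "no gene")
  expect_error(enrichment_score(rl, c("g1", "g2", "g3", "g4")), "every")
  expect_error(ranked_list(c(a = 1, A = 2)), "duplicate")
})

test_that("enrichment score matches brute-force running-sum and KS oracles", {
  withr::local_seed(31)
  for (i in 1:200) {
    n <- sample(50:400, 1)
    scores <- rnorm(n)
    names(scores) <- sprintf("G%04d", sample.int(9999, n))
    rl <- ranked_list(scores)
    k <- sample(3:min(40, n - 1), 1)
    set <- sample(names(rl), k)
    w <- sample(c(0, 1, 1.5), 1)
    mine <- enrichment_score(rl, set, weight = w)$es
    hit <- names(rl) %in% set
    expect_equal(mine, oracle_es(unname(rl), hit, w), tolerance = 1e-12)
    if (w == 0) {
      expect_equal(mine, oracle_ks_signed(n, which(hit)), tolerance = 1e-12)
    }
  }
})

test_that("weight-1 enrichment score agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  withr::local_seed(32)
  for (i in 1:100) {
    n <- sample(100:500, 1)
    scores <- sort(rnorm(n), decreasing = TRUE) + seq(n, 1) * 1e-9
    names(scores) <- sprintf("G%04d", seq_len(n))
    rl <- ranked_list(scores)
    set <- sample(names(rl), sample(5:50, 1))
    mine <- enrichment_score(rl, set, weight = 1)$es
    ref <- fgsea::calcGseaStat(unname(rl), sort(match(set, names(rl))),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("reversing the ranked list negates every enrichment score", {
  withr::local_seed(33)
  scores <- rnorm(300)
  names(scores) <- sprintf("G%03d", 1:300)
  rl <- ranked_list(scores)
  rl_rev <- ranked_list(-scores)
  for (i in 1:20) {
    set <- sample(names(scores), 15)
    expect_equal(enrichment_score(rl_rev, set)$es,
                 -enrichment_score(rl, set)$es, tolerance = 1e-12)
  }
})

test_that("permutation null is seeded, centered, and validated", {
  withr::local_seed(34)
  scores <- rnorm(400)
  names(scores) <- sprintf("G%03d", 1:400)
  rl <- ranked_list(scores)
  a <- permutation_null(rl, 25, 500, seed = 9)
  b <- permutation_null(rl, 25, 500, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, permutation_null(rl, 25, 500, seed = 10)))

  null <- permutation_null(rl, 25, 2000, seed = 1)
  expect_lt(abs(mean(null)), 0.05)  # symmetric scores -> centered null

  expect_error(permutation_null(rl, 0, 500, 1), "set_size")
  expect_error(permutation_null(rl, 400, 500, 1), "set_size")
  expect_error(permutation_null(rl, 25, 50, 1), "n_perm")
})

test_that("NES/FWER bookkeeping honors boundary and single-set families", {
  observed <- tibble::tibble(set_name = "s1", es = 0.5, set_size_used = 5L,
                             leading_edge = list("G1"))
  nulls <- matrix(c(0.5, 0.25, -0.25, 0.5, 0.25, -0.4, 0.5, 0.1, -0.1, 0.25),
                  ncol = 1)
  res <- normalize_and_fwer(observed, nulls)
  # family of one: FWER equals nominal p computed on the NES scale
  expect_equal(res$fwer_p, res$nominal_p)
  # observed equal to the max same-sign null in every permutation -> both 1
  # when ES equals every positive null
  nulls2 <- matrix(rep(0.5, 200), ncol = 1)
  res2 <- normalize_and_fwer(observed, nulls2)
  expect_equal(res2$fwer_p, 1)
  expect_equal(res2$nominal_p, 1)
  expect_equal(res2$nes, 1)  # ES / mean(same-sign nulls)
})

test_that("nominal p-values are uniform for random sets under a null list", {
  withr::local_seed(35)
  scores <- rnorm(1000)
  names(scores) <- sprintf("G%04d", 1:1000)
  rl <- ranked_list(scores)
  sets <- tibble::tibble(
    name = sprintf("R%03d", 1:200),
    description = "random",
    genes = lapply(1:200, function(i) sample(names(scores), 30)))
  res <- run_gsea(rl, sets, min_size = 5, max_size = 500, n_perm = 500,
                  seed = 41)
  ks <- suppressWarnings(ks.test(res$nominal_p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # type-I error near the nominal level
  expect_lt(abs(mean(res$nominal_p < 0.05) - 0.05), 0.05)
})

test_that("run_gsea filters by size, sorts deterministically, swaps on reversal", {
  withr::local_seed(36)
  scores <- c(seq(3, 0.5, length.out = 60), seq(-0.5, -3, length.out = 60))
  names(scores) <- sprintf("G%03d", seq_along(scores))
  top_set <- names(scores)[1:20]
  bottom_set <- names(scores)[101:120]
  sets <- tibble::tibble(
    name = c("TOP", "BOTTOM", "TINY"),
    description = "",
    genes = list(top_set, bottom_set, names(scores)[1:3]))

  expect_message(
    res <- run_gsea(ranked_list(scores), sets, min_size = 15, n_perm = 200,
                    seed = 5),
    "skipped")
  expect_setequal(res$set_name, c("TOP", "BOTTOM"))  # TINY filtered out
  expect_equal(res$direction[res$set_name == "TOP"], "positive")
  expect_equal(res$direction[res$set_name == "BOTTOM"], "negative")

  rev_res <- run_gsea(ranked_list(-scores), sets, min_size = 15, n_perm = 200,
                      seed = 5)
  expect_equal(rev_res$es[match(c("TOP", "BOTTOM"), rev_res$set_name)],
               -res$es[match(c("TOP", "BOTTOM"), res$set_name)])

  expect_error(run_gsea(ranked_list(scores), sets[3, ], min_size = 15,
                        n_perm = 200, seed = 5),
               "no gene set")
})
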