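test_that("TF-protein correlations match the covariance formula", {
  withr::with_seed(81, {
    A <- matrix(rnorm(30), 3, 10,
                dimnames = list(paste0("TF", 1:3), paste0("c", 1:10)))
    P <- matrix(rnorm(20), 10, 2,
                dimnames = list(paste0("c", 1:10), paste0("p", 1:2)))
  })
  r <- tf_protein_correlation(A, P)
  # brute-force pairwise computation
  for (q in 1:3) for (s in 1:2) {
    x <- A[q, ]; y <- P[, s]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r[q, s], oracle, tolerance = 1e-12)
  }
  # perfect and anti-perfect alignment
  A2 <- rbind(P[, 1], -P[, 2])
  dimnames(A2) <- list(c("TFa", "TFb"), paste0("c", 1:10))
  r2 <- tf_protein_correlation(A2, P)
  expect_equal(r2["TFa", "p1"], 1)
  expect_equal(r2["TFb", "p2"], -1)
  expect_error(tf_protein_correlation(A[, 1:2], P[1:2, ]), ">= 3")
})

test_that("pathway co-occurrence honours membership and ADT aliases", {
  pw <- list(PATH1 = c("STAT1", "PDCD1"), PATH2 = c("FOSL2", "CD27"))
  cooc <- pathway_cooccurrence(pw, tfs = c("STAT1", "FOSL2", "MYC"),
                               proteins = c("CD279", "CD27"),
                               alias = data.frame(adt_name = "CD279",
                                                  gene_symbol = "PDCD1"))
  expect_identical(cooc["STAT1", "CD279"], 1L)   # via alias to PDCD1
  expect_identical(cooc["FOSL2", "CD27"], 1L)
  expect_identical(cooc["MYC", "CD279"], 0L)
  expect_identical(cooc["STAT1", "CD27"], 0L)
})

test_that("enrichment p equals the closed-form hypergeometric anchors", {
  # 10 correlated pairs all sharing a pathway, 10 uncorrelated sharing none
  corr <- matrix(c(rep(0.9, 10), rep(0.05, 10)), 4, 5)
  cooc <- matrix(c(rep(1, 10), rep(0, 10)), 4, 5)
  res <- enrichment_test(corr, cooc)
  expect_identical(unname(res$table[1, ]), c(10L, 0L))
  expect_identical(unname(res$table[2, ]), c(0L, 10L))
  expect_equal(res$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  # all pairs share a pathway: no discrimination, p = 1
  expect_equal(enrichment_test(corr, cooc * 0 + 1)$p_value, 1)
  # degenerate correlation margins are errors
  expect_error(enrichment_test(corr * 0, cooc), "no correlated")
  expect_error(enrichment_test(corr * 0 + 0.9, cooc), "no uncorrelated")
})

test_that("the intermediate correlation band is excluded from the table", {
  corr <- matrix(c(0.9, 0.3, 0.25, 0.05, 0.5, -0.1), 2, 3)
  cooc <- matrix(c(1, 1, 0, 0, 0, 1), 2, 3)
  res <- enrichment_test(corr, cooc, r_hi = 0.4, r_lo = 0.2)
  expect_identical(res$n_pairs_used, 4L)          # 0.3, 0.25 dropped
})

test_that("hypergeometric p equals Fisher's one-sided exact p", {
  withr::with_seed(9, {
    for (i in 1:20) {
      n <- 200
      corr <- matrix(runif(n, -1, 1), 20, 10)
      cooc <- matrix(rbinom(n, 1, 0.5), 20, 10)
      res <- enrichment_test(corr, cooc)
      fp <- fisher.test(res$table, alternative = "greater")$p.value
      expect_equal(res$p_value, fp, tolerance = 1e-12)
    }
  })
})

test_that("enrichment p-values are near-uniform under independence", {
  withr::with_seed(9, {
    ps <- replicate(1000, {
      corr <- matrix(runif(200, -1, 1), 20, 10)
      cooc <- matrix(rbinom(200, 1, 0.5), 20, 10)
      enrichment_test(corr, cooc)$p_value
    })
  })
  ks <- suppressWarnings(ks.test(ps, "punif")$statistic)
  expect_lt(unname(ks), 0.1)
})

test_that("planted two-cluster protein data refines to two marked clusters", {
  P <- planted_blobs(M = 30, S = 40, nplant = 3, shift = 4, seed = 13)
  ca <- cluster_cells_by_protein(P, init_groups = 10)
  expect_identical(ca$k, 2L)
  expect_lte(ca$iterations, 9L)                   # init_groups - 1
  for (cl in 1:2) {
    nsig <- sum(ca$diff_proteins$q[ca$diff_proteins$cluster == cl] < 0.05)
    expect_gte(nsig, 3)
  }
  truth <- rep(1:2, each = 15)
  agree <- max(mean((ca$clusters == 1) == (truth == 1)),
               mean((ca$clusters == 1) == (truth == 2)))
  expect_gte(agree, 0.9)
})

test_that("cluster partition is invariant to cell input order", {
  P <- planted_blobs(seed = 13)
  ca <- cluster_cells_by_protein(P, init_groups = 10)
  perm <- withr::with_seed(82, sample(nrow(P)))
  ca2 <- cluster_cells_by_protein(P[perm, ], init_groups = 10)
  ord <- sort(names(ca$clusters))
  expect_identical(ca$clusters[ord], ca2$clusters[ord])
})

test_that("structureless cells collapse to the minimum cut with a warning", {
  P <- matrix(1, 20, 4,
              dimnames = list(paste0("c", 1:20), paste0("p", 1:4)))
  expect_warning(ca <- cluster_cells_by_protein(P, init_groups = 10),
                 "no cut")
  expect_identical(ca$k, 2L)
  expect_false(ca$all_qualified)
})

test_that("lineage-marker proteins can be excluded before clustering", {
  P <- planted_blobs(seed = 13)
  ca <- suppressWarnings(
    cluster_cells_by_protein(P, exclude = colnames(P)[1:3],
                             init_groups = 10))
  # the planted signal lives in the excluded proteins: no structure remains
  expect_false(all(c("ADT01", "ADT02", "ADT03") %in%
                   unique(ca$diff_proteins$protein)))
})

test_that("differential activity ranks a planted TF first with tiny q", {
  withr::with_seed(17, {
    A <- matrix(rnorm(15 * 100), 15, 100,
                dimnames = list(paste0("TF", 1:15), paste0("c", 1:100)))
  })
  cl <- setNames(rep(c(1L, 2L), c(30, 70)), colnames(A))
  A["TF1", cl == 1] <- A["TF1", cl == 1] + 3
  da <- differential_activity(A, cl)
  top1 <- da[da$cluster == 1, ][1, ]
  expect_identical(top1$tf, "TF1")
  expect_lt(top1$q, 1e-5)
  # constant TF: effect 0, p = 1
  A2 <- rbind(A, const = 1)
  da2 <- differential_activity(A2, cl)
  expect_equal(da2$p[da2$tf == "const"], c(1, 1))
  expect_equal(da2$effect[da2$tf == "const"], c(0, 0))
})

test_that("permuting cluster labels destroys differential significance", {
  withr::with_seed(17, {
    A <- matrix(rnorm(10 * 60), 10, 60,
                dimnames = list(paste0("TF", 1:10), paste0("c", 1:60)))
    cl <- setNames(rep(c(1L, 2L), 30), colnames(A))
    minq <- replicate(100, {
      clp <- setNames(sample(cl), names(cl))
      min(differential_activity(A, clp)$q)
    })
  })
  expect_gte(mean(minq > 0.05), 0.9)
})

test_that("top_differential reports the union of per-cluster top TFs", {
  withr::with_seed(83, {
    A <- matrix(rnorm(8 * 40), 8, 40,
                dimnames = list(paste0("TF", 1:8), paste0("c", 1:40)))
  })
  cl <- setNames(rep(1:2, each = 20), colnames(A))
  da <- differential_activity(A, cl)
  top <- top_differential(da, top_k = 2)
  expect_lte(length(unique(top$tf)), 4)
  expect_gte(length(unique(top$tf)), 2)
})
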