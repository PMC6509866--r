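test_that("BH adjustment matches the hand-computed step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(50)
  expect_equal(bh_adjust(p), bh_by_hand(p))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])  # order equivariance
})

test_that("differential expression recovers a planted 2-log2 shift", {
  set.seed(9)
  base <- rnorm(20, 5, 0.1)
  fx <- two_class_fixture(c(hit = 0, null = 0), n_per_class = 20L,
                          sd = 0.1, seed = 9)
  m <- fx$matrix
  m["hit", fx$labels == "TP"] <- m["hit", fx$labels == "TP"] + 2
  tab <- dea_expression(m, fx$labels)
  hit <- tab[tab$feature_id == "hit", ]
  expect_equal(hit$log2_fc, 2, tolerance = 0.1)
  expect_true(hit$selected)
  # closed-form Welch p for the same row
  ref <- t.test(m["hit", fx$labels == "TP"], m["hit", fx$labels == "NT"])
  expect_equal(hit$p_value, ref$p.value, tolerance = 1e-12)
  expect_false(tab[tab$feature_id == "null", "selected"])
})

test_that("zero-variance and boundary genes follow the stated conventions", {
  m <- expression_matrix(rbind(flat = rep(5, 8),
                               edge = rep(c(2, 3, 1, 2), each = 2)),
                         sample_ids = sprintf("s%d", 1:8))
  lab <- sample_labels(colnames(m), rep(c("TP", "NT"), each = 4))
  tab <- dea_expression(m, lab)
  flat <- tab[tab$feature_id == "flat", ]
  expect_true(flat$zero_variance)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$log2_fc, 0)
  expect_false(flat$selected)
  # |log2_fc| exactly 1 (exact binary values) is selected: inclusive boundary
  edge <- tab[tab$feature_id == "edge", ]
  expect_identical(edge$log2_fc, 1)
  expect_true(edge$selected || edge$fdr > 0.01)
})

test_that("selection is monotone in the thresholds", {
  fx <- two_class_fixture(setNames(seq(0, 3, length.out = 30),
                                   sprintf("g%02d", 1:30)),
                          n_per_class = 15L, seed = 5)
  base <- dea_expression(fx$matrix, fx$labels, logfc_cut = 1, fdr_cut = 0.01)
  looser_fdr <- dea_expression(fx$matrix, fx$labels, 1, 0.10)
  looser_fc <- dea_expression(fx$matrix, fx$labels, 0.5, 0.01)
  sel <- function(t) t$feature_id[t$selected]
  expect_true(all(sel(base) %in% sel(looser_fdr)))
  expect_true(all(sel(base) %in% sel(looser_fc)))
})

test_that("methylation screen selects a planted beta difference", {
  set.seed(21)
  n <- 15L
  vals <- rbind(hit = c(rnorm(n, 0.9, 0.03), rnorm(n, 0.4, 0.03)),
                null = rnorm(2 * n, 0.5, 0.03))
  vals <- pmin(pmax(vals, 0), 1)
  m <- expression_matrix(vals, sample_ids = sprintf("s%02d", 1:(2 * n)))
  lab <- sample_labels(colnames(m), rep(c("TP", "NT"), each = n))
  tab <- dea_methylation(m, lab)
  expect_equal(tab[tab$feature_id == "hit", "diff_mean"], 0.5,
               tolerance = 0.05)
  expect_true(tab[tab$feature_id == "hit", "selected"])
  expect_false(tab[tab$feature_id == "null", "selected"])
  expect_error(dea_methylation(m * 2, lab), "\\[0, 1\\]")
})

test_that("methylation boundary |diff_mean| = 0.35 is inclusive", {
  n <- 10L
  vals <- rbind(edge = c(rep(c(0.70, 0.80), n / 2),
                         rep(c(0.35, 0.45), n / 2)))
  m <- expression_matrix(vals, sample_ids = sprintf("s%02d", 1:(2 * n / 1)))
  dimnames(m) <- list("edge", sprintf("s%02d", 1:(2 * n)))
  lab <- sample_labels(colnames(m), rep(c("TP", "NT"), each = n))
  tab <- dea_methylation(m, lab)
  expect_identical(tab$diff_mean, 0.35)
  expect_true(tab$selected)
})

test_that("miRNA target-degree filter is strict and matches brute force", {
  edges <- typed_edges(
    c("m1", "m2", "m3", "m1", "m2", "m9"),
    c("tA", "tA", "tA", "tB", "tB", "tB"),
    rep("mirna_target", 6))
  demir <- c("m1", "m2", "m3")
  expect_identical(mirna_target_genes(demir, edges, 2), "tA")  # 3 > 2
  expect_identical(mirna_target_genes(demir, edges, 1),
                   c("tA", "tB"))                              # tB has 2 > 1
  expect_identical(mirna_target_genes(character(), edges, 2), character())

  set.seed(13)
  mirnas <- sprintf("m%02d", 1:50)
  genes <- sprintf("t%03d", 1:200)
  grid <- expand.grid(m = mirnas, g = genes, stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < 0.03, ]
  e <- typed_edges(grid$m, grid$g, rep("mirna_target", nrow(grid)))
  demir <- sample(mirnas, 20)
  got <- mirna_target_genes(demir, e, 2)
  counts <- vapply(genes, function(g)
    sum(e$gene_a %in% demir & e$gene_b == g), 0L)
  expect_identical(got, sort(genes[counts > 2]))
})

test_that("diff-gene union tracks provenance and partitions exactly", {
  u <- union_diff_genes(c("A", "B"), c("B", "C"), character())
  expect_identical(u$diff_genes, c("A", "B", "C"))
  b <- u$provenance[u$provenance$gene == "B", ]
  expect_true(b$deg && b$dmet && !b$mirna)
  u2 <- union_diff_genes(c("x1", "x2", "x3"), c("y1", "y2"), "z1")
  expect_length(u2$diff_genes, 6L)
  expect_equal(unname(u2$intersections[c("deg_dmet", "deg_mirna",
                                         "dmet_mirna", "all_three")]),
               rep(0L, 4L))
  set.seed(17)
  pool <- sprintf("G%03d", 1:80)
  a <- sample(pool, 30); b <- sample(pool, 25); c <- sample(pool, 10)
  u3 <- union_diff_genes(a, b, c)
  expect_identical(u3$diff_genes, sort(unique(c(a, b, c))))
  expect_identical(u3$provenance$gene[u3$provenance$deg], sort(unique(a)))
  expect_identical(u3$provenance$gene[u3$provenance$dmet], sort(unique(b)))
  expect_identical(u3$provenance$gene[u3$provenance$mirna], sort(unique(c)))
  expect_equal(sum(u3$intersections), length(u3$diff_genes))
})
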