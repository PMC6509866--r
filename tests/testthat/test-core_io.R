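test_that("expression matrix TSV round-trips at full float precision", {
  set.seed(7)
  m <- expression_matrix(matrix(rnorm(100), 10, 10,
                                dimnames = list(sprintf("g%02d", 1:10),
                                                sprintf("s%02d", 1:10))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  back <- read_expression(path)
  expect_identical(dim(back), dim(m))
  expect_identical(unname(back), unname(m))   # bitwise, not approximate
  expect_identical(dimnames(back), dimnames(m))
})

test_that("small matrix values and orientation are preserved", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3", "gA\t1\t2\t3", "gB\t4\t5\t6"), path)
  m <- read_expression(path)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(m["gA", ]), c(1, 2, 3))
  expect_equal(unname(m["gB", ]), c(4, 5, 6))
})

test_that("reader surfaces duplicate ids and non-numeric cells by name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "EGFR\t1\t2", "EGFR\t3\t4"), path)
  expect_error(read_expression(path), "EGFR")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\toops", "gB\t3\t4"), path)
  expect_error(read_expression(path), "gA.*s2|s2.*gA")
})

test_that("labels must cover exactly the matrix samples", {
  mpath <- withr::local_tempfile(fileext = ".tsv")
  lpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2"), mpath)
  writeLines(c("sample_id\tclass", "s1\tTP", "s9\tNT"), lpath)
  expect_error(read_expression(mpath, lpath), "s2|s9")
  writeLines(c("sample_id\tclass", "s2\tNT", "s1\tTP"), lpath)
  m <- read_expression(mpath, lpath)
  expect_identical(as.character(attr(m, "labels")), c("TP", "NT"))
})

test_that("undirected edges canonicalise and self-edges are dropped with count", {
  e <- typed_edges(c("B", "A"), c("A", "B"), c("physical", "physical"))
  expect_equal(nrow(e), 1L)
  expect_equal(e$gene_a, "A")
  expect_warning(
    e2 <- typed_edges(c("A", "A"), c("A", "B"), c("colocation", "physical")),
    "self-edge")
  expect_equal(nrow(e2), 1L)
  expect_equal(attr(e2, "n_self_dropped"), 1L)
  expect_error(typed_edges("A", "B", "friendship"), "unknown interaction")
})

test_that("parallel typed edges on one pair are distinct edges", {
  e <- typed_edges(rep("A", 3), rep("B", 3),
                   c("colocation", "physical", "shared_domain"))
  expect_equal(nrow(e), 3L)
  net <- build_network(c("A", "B"), e)
  expect_equal(unname(net$degree["A"]), 3L)
})

test_that("edge list TSV round-trips", {
  e <- typed_edges(c("A", "B", "C"), c("B", "C", "D"),
                   c("physical", "colocation", "mirna_target"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(e, path)
  back <- read_edge_list(path)
  expect_equal(as.data.frame(back), as.data.frame(e))
})

test_that("causal network TSV round-trips, including the empty network", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_causal_network(causal_network(), path)
  expect_length(readLines(path), 1L)      # header only
  expect_equal(nrow(read_causal_network(path)), 0L)

  set.seed(11)
  n <- 20L
  net <- causal_network(data.frame(
    source = sprintf("g%02d", sample(50, n)),
    target = sprintf("h%02d", sample(50, n)),
    interaction_type = sample(c("colocation", "physical", "shared_domain"),
                              n, TRUE),
    pearson_r = runif(n, -1, 1), pearson_p = runif(n),
    cointegration_p = ifelse(runif(n) < 0.3, NA, runif(n)),
    granger_p_forward = runif(n), granger_p_reverse = runif(n),
    lag_used = sample(1:3, n, TRUE), stringsAsFactors = FALSE))
  write_causal_network(net, path)
  expect_length(readLines(path), n + 1L)
  back <- read_causal_network(path)
  expect_identical(as.data.frame(back), as.data.frame(net))
})

test_that("time-series matrices enforce ordering and minimum length", {
  vals <- matrix(rnorm(20), 2, 10, dimnames = list(c("a", "b"), NULL))
  expect_error(timeseries_matrix(vals, time_points = c(1:9, 9)),
               "strictly increasing")
  expect_error(timeseries_matrix(vals[, 1:7, drop = FALSE],
                                 time_points = 1:7), "8 time points")
  m <- timeseries_matrix(vals, time_points = c(0, 0.5, 1, 2, 3, 4, 5, 6, 7, 8))
  expect_equal(attr(m, "time_points")[2], 0.5)
})
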