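test_that("pearson test matches the closed-form t transform", {
  x <- 1:20
  p1 <- pearson_test(x, 2 * x + 1)
  expect_equal(p1$r, 1)
  expect_lt(p1$p, 1e-12)
  expect_equal(pearson_test(x, -x)$r, -1)
  set.seed(31)
  n <- 26
  x <- rnorm(n); y <- 0.5 * x + rnorm(n, 0, sqrt(0.75))
  got <- pearson_test(x, y)
  expect_lt(abs(got$r - 0.5), 0.3)
  tstat <- got$r * sqrt((n - 2) / (1 - got$r^2))
  expect_equal(got$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
  expect_false(pearson_test(rep(1, 10), rnorm(10))$ok)
})

test_that("unit root test separates stationary AR(1) from random walks", {
  n_rep <- 40L
  orders_ar <- orders_rw <- integer(n_rep)
  for (i in seq_len(n_rep)) {
    set.seed(100 + i)
    ar <- as.numeric(arima.sim(list(ar = 0.3), 200))
    rw <- cumsum(rnorm(200))
    orders_ar[i] <- unit_root_test(ar)$order
    orders_rw[i] <- unit_root_test(rw)$order
  }
  expect_gte(mean(orders_ar == 0L), 0.95)
  expect_gte(mean(orders_rw == 1L, na.rm = TRUE), 0.90)
  expect_true(is.na(unit_root_test(rep(2, 50))$order))
})

test_that("cointegration test has power on built pairs and near-nominal size", {
  n_rep <- 40L
  p_coint <- p_indep <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    set.seed(200 + i)
    x <- cumsum(rnorm(200))
    y <- x + rnorm(200, 0, 0.5)
    p_coint[i] <- cointegration_test(x, y, orders = c(1L, 1L))$p
    y2 <- cumsum(rnorm(200))
    p_indep[i] <- cointegration_test(x, y2, orders = c(1L, 1L))$p
  }
  expect_gte(mean(p_coint < 0.05), 0.90)
  expect_lte(mean(p_indep < 0.05), 0.15)
  x <- cumsum(rnorm(100))
  expect_equal(cointegration_test(x, x, orders = c(1L, 1L))$p, 0)
  expect_error(cointegration_test(rnorm(50), rnorm(50), orders = c(0L, 0L)),
               "order 1")
})

test_that("granger F-test detects planted lag-1 influence, not its reverse", {
  n_rep <- 30L
  p_fwd <- p_rev <- p_null <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    set.seed(300 + i)
    n <- 200
    x <- rnorm(n)
    y <- 0.9 * c(0, x[-n]) + rnorm(n)
    p_fwd[i] <- granger_test(x, y, 1)$p
    p_rev[i] <- granger_test(y, x, 1)$p
    p_null[i] <- granger_test(rnorm(n), rnorm(n), 1)$p
  }
  expect_gte(mean(p_fwd < 0.01), 0.95)
  expect_lte(mean(p_rev < 0.05), 0.15)
  expect_lte(mean(p_null < 0.05), 0.15)
})

test_that("granger F-test agrees with an independent nested-regression oracle", {
  skip_if_not_installed("lmtest")
  set.seed(37)
  n <- 100
  x <- rnorm(n)
  y <- 0.5 * c(0, x[-n]) + rnorm(n)
  for (lag in 1:3) {
    got <- granger_test(x, y, lag)
    ref <- lmtest::grangertest(y ~ x, order = lag)
    expect_equal(got$F, ref$F[2], tolerance = 1e-8)
    expect_equal(got$p, ref$`Pr(>F)`[2], tolerance = 1e-8)
  }
})

test_that("the cascade gates in order and never skips ahead", {
  set.seed(41)
  ts <- timeseries_matrix(rbind(a = rnorm(50), b = rnorm(50)),
                          time_points = 0:49)
  res <- direct_edge("a", "b", ts)
  # independent white noise: overwhelmingly not correlated, and then no
  # downstream diagnostics may be filled in
  if (res$verdict == "not_correlated") {
    expect_true(is.na(res$granger_p_ab))
    expect_true(is.na(res$order_a))
  }
  expect_error(direct_edge("a", "zz", ts), "zz")
})

test_that("direct_edge verdicts mirror under argument swap", {
  for (i in 1:5) {
    spec <- synthetic_spec(n_genes = 2, n_timepoints = 150, n_planted = 1,
                           targets_per_source = 1, causal_coef = 0.9,
                           seed = 400 + i)
    ts <- simulate_var_timeseries(spec)$matrix
    ab <- direct_edge("G01", "G02", ts)
    ba <- direct_edge("G02", "G01", ts)
    mirror <- c(a_causes_b = "b_causes_a", b_causes_a = "a_causes_b",
                bidirectional = "bidirectional", none = "none",
                not_correlated = "not_correlated",
                not_testable = "not_testable")
    expect_identical(ba$verdict, unname(mirror[ab$verdict]))
    expect_equal(ab$granger_p_ab, ba$granger_p_ba)
    expect_equal(ab$pearson_p, ba$pearson_p)
  }
})

test_that("a planted coupling is directed and a symmetric one is not", {
  spec <- synthetic_spec(n_genes = 2, n_timepoints = 200, n_planted = 1,
                         targets_per_source = 1, causal_coef = 0.9, seed = 5)
  ts <- simulate_var_timeseries(spec)$matrix
  expect_identical(direct_edge("G01", "G02", ts)$verdict, "a_causes_b")

  # two-way coupling: neither direction may win
  set.seed(6)
  n <- 220
  x <- y <- numeric(n)
  for (t in 2:n) {
    x[t] <- 0.3 * x[t - 1] + 0.5 * y[t - 1] + rnorm(1)
    y[t] <- 0.3 * y[t - 1] + 0.5 * x[t - 1] + rnorm(1)
  }
  ts2 <- timeseries_matrix(rbind(a = x[-(1:20)], b = y[-(1:20)]),
                           time_points = seq_len(n - 20) - 1)
  expect_identical(direct_edge("a", "b", ts2)$verdict, "bidirectional")
})

test_that("directing a 20-gene network recovers most planted relations", {
  spec <- synthetic_spec(n_genes = 20, n_planted = 5, targets_per_source = 2,
                         causal_coef = 0.9, n_timepoints = 150,
                         edge_density = 0.15, seed = 2L)
  ts <- simulate_var_timeseries(spec)$matrix
  net <- build_network(spec$genes, simulate_interactions(spec))
  res <- direct_network(net, ts)
  arcs <- unique(res$network[, c("source", "target")])
  truth_key <- paste(spec$planted_causal_edges$source,
                     spec$planted_causal_edges$target)
  got_key <- paste(arcs$source, arcs$target)
  expect_gte(sum(truth_key %in% got_key), 7L)
  expect_lte(sum(!got_key %in% truth_key), 3L)
})

test_that("direct_network restricts to interacting pairs and summarises types", {
  spec <- synthetic_spec(n_genes = 8, n_timepoints = 150, n_planted = 2,
                         targets_per_source = 1, causal_coef = 0.9,
                         edge_density = 0.3, seed = 43)
  ts <- simulate_var_timeseries(spec)$matrix
  inter <- simulate_interactions(spec)
  net <- build_network(spec$genes, inter)
  res <- direct_network(net, ts)
  expect_s3_class(res$network, "causal_network")
  expect_equal(length(res$pair_results), nrow(network_pairs(net)))
  # per-type causal counts partition the causal edge set
  expect_equal(sum(res$type_summary$n_causal), nrow(res$network))
  expect_equal(sum(res$type_summary$n_tested),
               nrow(net$edges))
  # every directed edge's unordered pair is an input edge
  if (nrow(res$network)) {
    key_in <- paste(net$edges$gene_a, net$edges$gene_b)
    key_out <- paste(pmin(res$network$source, res$network$target),
                     pmax(res$network$source, res$network$target))
    expect_true(all(key_out %in% key_in))
  }
  # genes absent from the time series are skipped, not errors
  ts_small <- ts[-1, , drop = FALSE]
  res2 <- direct_network(net, timeseries_matrix(ts_small, rownames(ts_small),
                                                attr(ts, "time_points")))
  expect_gt(res2$n_skipped_pairs, 0L)
  # empty feature network gives an empty causal network
  empty <- build_network(spec$genes,
                         typed_edges(character(), character(), character()))
  expect_equal(nrow(direct_network(empty, ts)$network), 0L)
})
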