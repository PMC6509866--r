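# Dickey-Fuller machinery -----------------------------------------------
#
# Asymptotic quantiles of the Dickey-Fuller tau distribution (Fuller 1976)
# for the regression with a constant ("drift") and without ("none"), and of
# the Engle-Granger residual distribution for two variables with a constant
# in the cointegrating regression (MacKinnon 1991). P-values are obtained by
# monotone interpolation of the test statistic against the normal quantile
# of the tabulated probabilities, with linear extrapolation at the ends and
# clamping; gate decisions only need accuracy near conventional levels.

.DF_TAB <- list(
  drift = data.frame(
    p = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
    q = c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)),
  none = data.frame(
    p = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
    q = c(-2.58, -2.23, -1.95, -1.62, 0.89, 1.28, 1.62, 2.00)),
  eg2 = data.frame(
    p = c(0.01, 0.025, 0.05, 0.10),
    q = c(-3.90, -3.59, -3.34, -3.04)))

.df_pvalue <- function(stat, table) {
  q <- table$q
  z <- qnorm(table$p)
  k <- length(q)
  if (stat <= q[1L]) {
    zz <- z[1L] + (stat - q[1L]) * (z[2L] - z[1L]) / (q[2L] - q[1L])
  } else if (stat >= q[k]) {
    zz <- z[k] + (stat - q[k]) * (z[k] - z[k - 1L]) / (q[k] - q[k - 1L])
  } else {
    zz <- approx(q, z, xout = stat)$y
  }
  min(max(pnorm(zz), 1e-4), 0.9999)
}

# ADF regression: diff(x)_t on x_{t-1}, `lags` lagged differences and an
# optional constant; tau = t-ratio of the x_{t-1} coefficient.
.adf_stat <- function(x, lags = 1L, type = c("drift", "none")) {
  type <- match.arg(type)
  n <- length(x)
  if (n < lags + 8L) return(NA_real_)
  dx <- diff(x)
  idx <- (lags + 1L):(n - 1L)            # rows of the regression
  y <- dx[idx]
  X <- x[idx]                            # level lag
  if (lags > 0L)
    X <- cbind(X, sapply(seq_len(lags), function(j) dx[idx - j]))
  X <- as.matrix(X)
  if (type == "drift") X <- cbind(X, 1)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  dfree <- length(y) - ncol(X)
  if (dfree <= 0 || rss <= 0) return(NA_real_)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / dfree * XtXinv[1L, 1L])
  unname(fit$coefficients[1L] / se)
}

#' Augmented Dickey-Fuller test
#'
#' Tests the null of a unit root against stationarity. The regression
#' includes `lags` lagged differences and (for `type = "drift"`) a constant;
#' the p-value comes from interpolated asymptotic tau tables.
#'
#' @param x numeric series (length >= lags + 8).
#' @param lags number of augmenting difference lags (default 1).
#' @param type `"drift"` (constant, the usual case for expression levels) or
#'   `"none"` (used on cointegration residuals, which have mean zero).
#' @return list with `stat` and `p` (`NA` if the series is too short or
#'   constant).
#' @export
adf_test <- function(x, lags = 1L, type = c("drift", "none")) {
  type <- match.arg(type)
  if (sd(x) == 0) return(list(stat = NA_real_, p = NA_real_))
  stat <- .adf_stat(x, lags, type)
  if (is.na(stat)) return(list(stat = NA_real_, p = NA_real_))
  list(stat = stat, p = .df_pvalue(stat, .DF_TAB[[type]]))
}

#' Integration order of a series
#'
#' Runs the ADF test on levels; if the unit root is not rejected at
#' `alpha`, tests the first differences. Integration order 0 means the
#' levels are stationary, 1 means only the differences are; anything else is
#' not testable (order `NA`), as is a constant series.
#'
#' @param x numeric series (length >= 10).
#' @param alpha rejection level for the unit-root null (default 0.05).
#' @param lags augmenting lags passed to [adf_test()].
#' @return list with `order` (0, 1 or NA), `stat`, `p` (levels test) and
#'   `stat_diff`, `p_diff` (differences test, NA when not needed).
#' @export
unit_root_test <- function(x, alpha = 0.05, lags = 1L) {
  if (length(x) < 10L) stop("unit_root_test needs at least 10 observations")
  lev <- adf_test(x, lags, "drift")
  if (is.na(lev$p))
    return(list(order = NA_integer_, stat = lev$stat, p = lev$p,
                stat_diff = NA_real_, p_diff = NA_real_))
  if (lev$p < alpha)
    return(list(order = 0L, stat = lev$stat, p = lev$p,
                stat_diff = NA_real_, p_diff = NA_real_))
  dif <- adf_test(diff(x), lags, "drift")
  order <- if (!is.na(dif$p) && dif$p < alpha) 1L else NA_integer_
  list(order = order, stat = lev$stat, p = lev$p,
       stat_diff = dif$stat, p_diff = dif$p)
}

#' Engle-Granger cointegration test
#'
#' Two-step residual-based test for a pair of I(1) series: regress one level
#' series on the other (with constant), then ADF (no constant) on the
#' residuals against the Engle-Granger N = 2 critical values. The regression
#' is run in both orientations and the smaller p-value is returned, so the
#' test is symmetric in its arguments. A numerically exact linear relation
#' (residuals ~ 0) returns p = 0.
#'
#' @param x,y numeric series, both integrated of order 1.
#' @param orders optional integer vector `c(order_x, order_y)`; computed via
#'   [unit_root_test()] when omitted. Both must equal 1, otherwise the test
#'   is a misuse and errors.
#' @param lags augmenting lags for the residual ADF.
#' @param alpha level used only when `orders` is computed internally.
#' @return list with `stat` and `p`.
#' @export
cointegration_test <- function(x, y, orders = NULL, lags = 1L, alpha = 0.05) {
  if (is.null(orders))
    orders <- c(unit_root_test(x, alpha, lags)$order,
                unit_root_test(y, alpha, lags)$order)
  if (anyNA(orders) || !all(orders == 1L))
    stop("cointegration test requires two series integrated of order 1")
  one_way <- function(a, b) {
    res <- residuals(stats::lm.fit(cbind(1, a), b))
    if (sd(res) < 1e-10 * max(sd(b), 1)) return(list(stat = -Inf, p = 0))
    r <- adf_test(res, lags, "none")
    r$p <- .df_pvalue(r$stat, .DF_TAB$eg2)   # EG residual distribution
    r
  }
  f <- one_way(x, y); b <- one_way(y, x)
  if (is.na(f$p) && is.na(b$p)) return(list(stat = NA_real_, p = NA_real_))
  if (is.na(b$p) || (!is.na(f$p) && f$p <= b$p)) f else b
}

#' Pearson correlation test
#'
#' Two-sided test of zero correlation. A zero-variance input makes the pair
#' untestable (`ok = FALSE`) rather than erroring, so the cascade can record
#' the verdict.
#'
#' @param x,y numeric series of equal length >= 3.
#' @return list with `ok`, `r`, `p`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("pearson_test needs two equal-length series of length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(ok = FALSE, r = NA_real_, p = NA_real_))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(ok = TRUE, r = unname(ct$estimate), p = ct$p.value)
}

#' Granger causality F-test
#'
#' Tests whether past values of `x` improve the prediction of `y` beyond
#' `y`'s own past: an F-test of the restricted autoregression
#' `y_t ~ y_{t-1..lag}` against the unrestricted regression adding
#' `x_{t-1..lag}` (both with constant), estimated by nested OLS on the same
#' sample.
#'
#' @param x candidate cause series.
#' @param y effect series.
#' @param lag positive lag order.
#' @return list with `F`, `p`, `df1`, `df2` (`p = NA` when the sample is too
#'   short for the unrestricted regression).
#' @export
granger_test <- function(x, y, lag = 1L) {
  stopifnot(lag >= 1L, length(x) == length(y))
  n <- length(y)
  nobs <- n - lag
  df2 <- nobs - (2L * lag + 1L)
  if (df2 < 2L) return(list(F = NA_real_, p = NA_real_, df1 = lag, df2 = df2))
  t_idx <- (lag + 1L):n
  Y <- y[t_idx]
  ylags <- sapply(seq_len(lag), function(j) y[t_idx - j])
  xlags <- sapply(seq_len(lag), function(j) x[t_idx - j])
  Xr <- cbind(1, ylags)
  Xu <- cbind(Xr, xlags)
  rss_r <- sum(stats::lm.fit(Xr, Y)$residuals^2)
  rss_u <- sum(stats::lm.fit(Xu, Y)$residuals^2)
  if (rss_u <= 0) return(list(F = Inf, p = 0, df1 = lag, df2 = df2))
  F <- ((rss_r - rss_u) / lag) / (rss_u / df2)
  list(F = F, p = pf(F, lag, df2, lower.tail = FALSE), df1 = lag, df2 = df2)
}

#' Configuration of the causality cascade
#'
#' @param alpha_pearson significance gate for the Pearson correlation test
#'   (default 0.01).
#' @param alpha_tests shared level for the unit-root, cointegration and
#'   Granger tests (default 0.05).
#' @param max_lag largest lag considered when `lag_selection` is
#'   `"information_criterion"` (default 3; short expression time courses do
#'   not support large lags).
#' @param lag_selection `"fixed"` (use `fixed_lag`, the default) or
#'   `"information_criterion"` (AIC over 1..max_lag on the bivariate
#'   regressions).
#' @param fixed_lag the lag used under fixed selection (default 1).
#' @param adf_lags augmenting lags of the ADF regressions (default 1).
#' @param on_nonstationary what to do with pairs that are not both
#'   stationary and not cointegrated: `"not_testable"` (default; the
#'   cascade treats cointegration as a gate) or `"difference"` (difference
#'   integrated series and test on the stationary transforms).
#' @param bidirectional_as_feedback if `TRUE`, pairs significant in both
#'   directions emit a 2-cycle instead of no edge (default `FALSE`).
#' @export
causality_config <- function(alpha_pearson = 0.01, alpha_tests = 0.05,
                             max_lag = 3L,
                             lag_selection = c("fixed",
                                               "information_criterion"),
                             fixed_lag = 1L, adf_lags = 1L,
                             on_nonstationary = c("not_testable",
                                                  "difference"),
                             bidirectional_as_feedback = FALSE) {
  stopifnot(alpha_pearson > 0, alpha_pearson < 1,
            alpha_tests > 0, alpha_tests < 1,
            max_lag >= 1L, fixed_lag >= 1L)
  structure(list(alpha_pearson = alpha_pearson, alpha_tests = alpha_tests,
                 max_lag = as.integer(max_lag),
                 lag_selection = match.arg(lag_selection),
                 fixed_lag = as.integer(fixed_lag),
                 adf_lags = as.integer(adf_lags),
                 on_nonstationary = match.arg(on_nonstationary),
                 bidirectional_as_feedback = bidirectional_as_feedback),
            class = "causality_config")
}

# AIC-based common lag for the pair: sum of the AICs of both unrestricted
# equations, on the common sample implied by max_lag.
.choose_lag <- function(x, y, cfg) {
  if (cfg$lag_selection == "fixed") return(cfg$fixed_lag)
  n <- length(x)
  best <- 1L; best_aic <- Inf
  for (lag in seq_len(cfg$max_lag)) {
    t_idx <- (cfg$max_lag + 1L):n       # common sample across lags
    nobs <- length(t_idx)
    if (nobs - (2L * lag + 1L) < 2L) break
    aic_eq <- function(a, b) {
      B <- b[t_idx]
      X <- cbind(1, sapply(seq_len(lag), function(j) b[t_idx - j]),
                 sapply(seq_len(lag), function(j) a[t_idx - j]))
      rss <- sum(stats::lm.fit(X, B)$residuals^2)
      nobs * log(rss / nobs) + 2 * ncol(X)
    }
    aic <- aic_eq(x, y) + aic_eq(y, x)
    if (aic < best_aic) { best_aic <- aic; best <- lag }
  }
  best
}

#' Direct a single interacting gene pair
#'
#' Runs the gated cascade on one pair of time series: Pearson correlation
#' (gate at `alpha_pearson`), unit-root testing of both series,
#' cointegration when both are I(1), then Granger F-tests in both
#' directions. The pair is directed `a_causes_b` only when the forward test
#' is significant *and* the reverse is not (the defining two conditions of
#' Granger causality); both-significant pairs are recorded as
#' `bidirectional`, neither as `none`. Pairs failing an earlier gate never
#' reach a later test.
#'
#' @param gene_a,gene_b gene identifiers present in `ts`.
#' @param ts time-series matrix ([timeseries_matrix()]).
#' @param cfg a [causality_config()].
#' @return a `pair_test` list: identifiers, diagnostics (`pearson_r`,
#'   `pearson_p`, `order_a`, `order_b`, `coint_p`, `granger_p_ab`,
#'   `granger_p_ba`, `lag_used`) and `verdict` in `a_causes_b`,
#'   `b_causes_a`, `bidirectional`, `none`, `not_correlated`,
#'   `not_testable`.
#' @export
direct_edge <- function(gene_a, gene_b, ts, cfg = causality_config()) {
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(ts)) stop("gene not in time series: ", g)
  x <- as.numeric(ts[gene_a, ]); y <- as.numeric(ts[gene_b, ])
  out <- list(gene_a = gene_a, gene_b = gene_b, pearson_r = NA_real_,
              pearson_p = NA_real_, order_a = NA_integer_,
              order_b = NA_integer_, coint_p = NA_real_,
              granger_p_ab = NA_real_, granger_p_ba = NA_real_,
              lag_used = NA_integer_, verdict = "not_testable")
  class(out) <- "pair_test"
  pe <- pearson_test(x, y)
  if (!pe$ok) return(out)
  out$pearson_r <- pe$r; out$pearson_p <- pe$p
  if (pe$p >= cfg$alpha_pearson) { out$verdict <- "not_correlated"; return(out) }

  ua <- unit_root_test(x, cfg$alpha_tests, cfg$adf_lags)
  ub <- unit_root_test(y, cfg$alpha_tests, cfg$adf_lags)
  out$order_a <- ua$order; out$order_b <- ub$order
  if (is.na(ua$order) || is.na(ub$order)) return(out)

  if (ua$order == 0L && ub$order == 0L) {
    tx <- x; ty <- y
  } else if (ua$order == 1L && ub$order == 1L) {
    co <- cointegration_test(x, y, orders = c(1L, 1L), lags = cfg$adf_lags)
    out$coint_p <- co$p
    if (!is.na(co$p) && co$p < cfg$alpha_tests) {
      tx <- x; ty <- y                    # cointegrated: test on levels
    } else if (cfg$on_nonstationary == "difference") {
      tx <- diff(x); ty <- diff(y)
    } else return(out)
  } else {                                # mixed integration orders
    if (cfg$on_nonstationary == "difference") {
      tx <- if (ua$order == 1L) diff(x) else x[-1L]
      ty <- if (ub$order == 1L) diff(y) else y[-1L]
    } else return(out)
  }

  lag <- .choose_lag(tx, ty, cfg)
  out$lag_used <- lag
  g_ab <- granger_test(tx, ty, lag)
  g_ba <- granger_test(ty, tx, lag)
  out$granger_p_ab <- g_ab$p; out$granger_p_ba <- g_ba$p
  if (is.na(g_ab$p) || is.na(g_ba$p)) return(out)
  sig_ab <- g_ab$p < cfg$alpha_tests
  sig_ba <- g_ba$p < cfg$alpha_tests
  out$verdict <- if (sig_ab && sig_ba) "bidirectional"
    else if (sig_ab) "a_causes_b"
    else if (sig_ba) "b_causes_a"
    else "none"
  out
}

#' Direct every interacting pair of a feature-gene network
#'
#' Applies [direct_edge()] to each unique unordered pair linked in the
#' multi-interaction network (pairs only, never all gene couples), and
#' assembles the directed causal network. Each directed edge carries the
#' interaction types of its underlying undirected edge, one row per type.
#' Pairs with a gene missing from the time series are skipped and counted.
#'
#' @param feature_net a `multi_network` restricted to feature genes.
#' @param ts time-series matrix.
#' @param cfg a [causality_config()].
#' @return list of class `granger_directing`: `network` (a
#'   [causal_network()]), `pair_results` (all `pair_test`s), `type_summary`
#'   (per interaction type: undirected edges tested vs causal edges found)
#'   and `n_skipped_pairs`.
#' @export
direct_network <- function(feature_net, ts, cfg = causality_config()) {
  pairs <- network_pairs(feature_net)
  results <- list()
  rows <- list()
  n_skip <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    if (!(a %in% rownames(ts)) || !(b %in% rownames(ts))) {
      n_skip <- n_skip + 1L
      next
    }
    res <- direct_edge(a, b, ts, cfg)
    results[[length(results) + 1L]] <- res
    dir <- switch(res$verdict,
                  a_causes_b = list(c(a, b)),
                  b_causes_a = list(c(b, a)),
                  bidirectional = if (cfg$bidirectional_as_feedback)
                    list(c(a, b), c(b, a)) else list(),
                  list())
    for (st in dir) {
      fwd <- identical(st[1L], a)
      for (type in strsplit(pairs$types[i], ",", fixed = TRUE)[[1L]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          source = st[1L], target = st[2L], interaction_type = type,
          pearson_r = res$pearson_r, pearson_p = res$pearson_p,
          cointegration_p = res$coint_p,
          granger_p_forward = if (fwd) res$granger_p_ab else res$granger_p_ba,
          granger_p_reverse = if (fwd) res$granger_p_ba else res$granger_p_ab,
          lag_used = res$lag_used, stringsAsFactors = FALSE)
      }
    }
  }
  net <- if (length(rows)) causal_network(do.call(rbind, rows))
         else causal_network()
  tested_types <- unlist(strsplit(pairs$types, ",", fixed = TRUE))
  type_summary <- data.frame(
    interaction_type = UNDIRECTED_TYPES,
    n_tested = as.integer(table(factor(tested_types,
                                       levels = UNDIRECTED_TYPES))),
    n_causal = as.integer(table(factor(net$interaction_type,
                                       levels = UNDIRECTED_TYPES))),
    stringsAsFactors = FALSE)
  type_summary$fraction_causal <-
    ifelse(type_summary$n_tested > 0,
           type_summary$n_causal / type_summary$n_tested, NA_real_)
  structure(list(network = net, pair_results = results,
                 type_summary = type_summary, n_skipped_pairs = n_skip,
                 nodes = feature_net$nodes),
            class = "granger_directing")
}

#' @export
print.granger_directing <- function(x, ...) {
  verdicts <- vapply(x$pair_results, `[[`, "", "verdict")
  cat(sprintf("Granger directing: %d pairs tested, %d directed edges (%d skipped)\n",
              length(x$pair_results), nrow(x$network), x$n_skipped_pairs))
  if (length(verdicts)) print(table(verdicts))
  invisible(x)
}
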