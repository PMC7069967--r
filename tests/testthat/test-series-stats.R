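test_that("alignment deletes missing rows first and then applies the lag", {
  y <- c(10, 11, 12, 13, 14, 15)
  x <- c(1, 2, NA, 4, 5, 6)
  p0 <- align_and_clean(y, x, lag = 0)
  expect_equal(p0$n, 5)
  expect_equal(p0$response, c(10, 11, 13, 14, 15))
  p1 <- align_and_clean(y, x, lag = 1)
  expect_equal(p1$n, 4)
  expect_equal(p1$response, c(11, 13, 14, 15))
  expect_equal(p1$predictor, c(1, 2, 4, 5))
  ## lag-1 pairs y_t with the immediately preceding predictor value
  p <- align_and_clean(1:5, 101:105, lag = 1)
  expect_equal(p$response, 2:5)
  expect_equal(p$predictor, 101:104)
  expect_error(align_and_clean(y[1:4], x[1:4], lag = 1), ">= 4")
})

test_that("trend tests agree with closed-form OLS and handle degenerate input", {
  s <- c(2.3, 2.9, 2.1, 3.4, 3.9, 3.2, 4.4, 4.1)
  tt <- trend_tests(s)
  t_idx <- seq_along(s)
  b <- sum((t_idx - mean(t_idx)) * (s - mean(s))) / sum((t_idx - mean(t_idx))^2)
  a <- mean(s) - b * mean(t_idx)
  res <- s - a - b * t_idx
  se <- sqrt(sum(res^2) / (length(s) - 2) / sum((t_idx - mean(t_idx))^2))
  expect_equal(tt$ols_slope, b)
  expect_equal(tt$ols_p, 2 * pt(abs(b / se), df = length(s) - 2, lower.tail = FALSE))
  expect_equal(trend_tests(1:10)$spearman_rho, 1)
  cons <- trend_tests(rep(4, 6))
  expect_equal(cons$ols_slope, 0)
  expect_gte(cons$ols_p, 0.05)
})

test_that("autocorrelation diagnostics compute acf and Durbin-Watson from their definitions", {
  set.seed(2)
  e <- rnorm(40)
  d <- autocorr_diagnostics(e)
  expect_equal(d$acf[1], 1)
  expect_equal(d$durbin_watson, sum(diff(e)^2) / sum(e^2))
  expect_true(d$durbin_watson >= 0 && d$durbin_watson <= 4)
  expect_equal(autocorr_diagnostics(c(1, -1, 1, -1))$durbin_watson, 3)
  expect_error(autocorr_diagnostics(rep(1, 6)), "zero-variance")
})

test_that("generalized differencing removes trend and lag-1 autocorrelation", {
  r <- c(0.3, -0.2, 0.5, -0.4, 0.1, -0.3, 0.2, -0.2)
  gd <- generalized_difference(r)
  expect_length(gd, length(r) - 1)
  ## exactly linear series -> zero residuals -> zero output
  lin <- 2 + 0.7 * (1:10)
  expect_equal(as.numeric(generalized_difference(lin)), rep(0, 9))
  ## rho = 0 -> output equals residuals r_2..r_n
  alt <- rep(c(1, -1), 5)  # lag-1 acf of OLS residuals is negative, not zero
  res <- residuals(lm(alt ~ seq_along(alt)))
  rho <- sum(res[-1] * res[-10]) / sum(res^2)
  expect_equal(as.numeric(generalized_difference(alt)),
               as.numeric(res[-1] - rho * res[-10]))
  ## strong AR(1) residuals come out nearly uncorrelated
  set.seed(31)
  ar1 <- as.numeric(arima.sim(list(ar = 0.7), 500))
  out <- generalized_difference(ar1)
  expect_lt(abs(acf(out, plot = FALSE)$acf[2]), 0.1)
})

test_that("ndiffs distinguishes white noise from integrated series and honours the cap", {
  set.seed(5)
  wn <- rnorm(200)
  expect_equal(ndiffs(wn), 0)
  set.seed(6)
  rw <- cumsum(rnorm(200))
  expect_equal(ndiffs(rw), 1)
  ## doubly integrated
  set.seed(7)
  expect_gte(ndiffs(cumsum(cumsum(rnorm(200)))), 2)
  expect_lte(ndiffs(rw, max_d = 5), 5)
  expect_lte(ndiffs(seq(1, 40) + rep(c(0, 1e6), 20), max_d = 5), 5)
})

test_that("stationarity tests reject and accept on the textbook cases", {
  set.seed(8)
  wn <- rnorm(300)
  rw <- cumsum(rnorm(300))
  expect_false(kpss_test(wn)$reject)
  expect_true(kpss_test(rw)$reject)
  expect_true(adf_test(wn)$reject)
  expect_false(adf_test(rw)$reject)
})

test_that("auto_arima recovers simple generating orders", {
  set.seed(42)
  wn <- rnorm(300)
  expect_equal(unname(auto_arima(wn)$order), c(0, 0, 0))
  set.seed(43)
  ar1 <- as.numeric(arima.sim(list(ar = 0.8), 300))
  f <- auto_arima(ar1)
  expect_gte(f$order[["p"]], 1)
  expect_equal(f$ar[1], 0.8, tolerance = 0.15 / 0.8)
  expect_error(auto_arima(rnorm(5)), "at least 8")
})

test_that("ARMA correlation matrices are symmetric positive definite over coefficient draws", {
  set.seed(12)
  for (i in 1:20) {
    p <- sample(0:2, 1); q <- sample(0:2, 1)
    if (p + q == 0) q <- 1
    repeat {  # draw until stationary/invertible
      ar <- if (p) runif(p, -0.6, 0.6) else numeric()
      ma <- if (q) runif(q, -0.6, 0.6) else numeric()
      ok_ar <- !length(ar) || all(Mod(polyroot(c(1, -ar))) > 1.02)
      ok_ma <- !length(ma) || all(Mod(polyroot(c(1, ma))) > 1.02)
      if (ok_ar && ok_ma) break
    }
    m <- arma_correlation_matrix(ar, ma, n = 12)
    expect_equal(m, t(m))
    expect_true(all(eigen(m, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("gls with order (0,0) reproduces ordinary least squares", {
  pr <- list(response = c(0, 1, 2), predictor = c(0, 1, 2))
  f <- gls_arma(pr, order = c(0, 0))
  expect_equal(f$slope, 1)
  expect_equal(f$residual_std_error, 0)
  f2 <- gls_arma(list(response = c(1, 2, 4), predictor = c(0, 1, 2)),
                 order = c(0, 0))
  expect_equal(f2$slope, 1.5)
  expect_error(gls_arma(list(response = 1:4, predictor = rep(2, 4)), c(0, 0)),
               "singular")
})

test_that("gls with a vanishing fixed AR coefficient matches the uncorrelated fit", {
  set.seed(9)
  pr <- list(response = rnorm(20, 1:20 * 0.1), predictor = 1:20 * 0.3 + rnorm(20))
  f0 <- gls_arma(pr, order = c(0, 0))
  f1 <- gls_arma(pr, order = c(1, 0), coef_init = 1e-8, fixed = TRUE)
  expect_equal(f1$slope, f0$slope, tolerance = 1e-6)
  expect_equal(f1$slope_p, f0$slope_p, tolerance = 1e-6)
  expect_equal(f1$residual_std_error, f0$residual_std_error, tolerance = 1e-6)
})

test_that("the pipeline decision path is deterministic and lag-aware", {
  inp <- pipeline_inputs(seed = 303L)
  r1 <- run_correlation_pipeline(inp$size, inp$d18O, lag = 0)
  r2 <- run_correlation_pipeline(inp$size, inp$d18O, lag = 0)
  expect_identical(r1, r2)
  expect_true(all(c("group", "lag", "p", "d", "q", "p_value", "correlation",
                    "residual_std_error", "differenced", "n") %in% names(r1)))
  expect_true(r1$p_value >= 0 && r1$p_value <= 1)
})

test_that("lag-1 alignment wins when the response is a one-step-delayed copy of the predictor", {
  set.seed(14)
  x <- as.numeric(arima.sim(list(ar = 0.8), 40))
  y <- c(0, x[-40]) + rnorm(40, 0, 0.05)  # y_t responds to x_{t-1}
  t_of <- function(lag) {
    f <- gls_arma(align_and_clean(y, x, lag), order = c(0, 0))
    abs(f$slope / f$slope_se)
  }
  expect_gt(t_of(1), t_of(0))
})

test_that("constant inputs raise a staged trend-test error", {
  expect_error(run_correlation_pipeline(rep(1, 10), rep(2, 10)),
               "\\[trend_tests\\]")
})
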