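test_that("information criteria identities hold, including worked examples", {
  ic <- information_criteria(361.1643, 3, 50)
  expect_equal(ic$aic, 367.1643)
  expect_equal(ic$bic, 361.1643 + 3 * log(50))
  expect_equal(ic$bic, 372.9003, tolerance = 1e-4)
  expect_equal(round(ic$hqic, 4), 369.3486)
  # AICc-style corrected criterion
  ic2 <- information_criteria(492.5518, 3, 50)
  expect_equal(ic2$caic, 499.0736, tolerance = 1e-4)
  expect_equal(ic2$caic, ic2$aic + 24 / 46)
  ic3 <- information_criteria(0, 0, 10)
  expect_equal(unlist(ic3[c("aic", "bic", "hqic")]), c(aic = 0, bic = 0, hqic = 0))
  expect_equal(as.numeric(ic3$caic), 0)
  ic4 <- information_criteria(10, 5, 6)
  expect_true(is.na(ic4$caic))
})

test_that("K-S statistic and p-value behave at analytic anchors", {
  m <- t2gwe(1, 1, 1)
  n <- 10
  # u at symmetric plotting positions gives D = 1/(2n)
  x <- qt2gwg((2 * (1:n) - 1) / (2 * n), m)
  ks <- ks_test_fitted(x, function(z) pt2gwg(z, m))
  expect_equal(ks$statistic, 1 / (2 * n), tolerance = 1e-12)
  expect_equal(t2gwg:::.kolmogorov_pvalue(0), 1)
  # oracle: agreement with stats::ks.test asymptotic p-value
  xr <- withr::with_seed(3, rt2gwg(60, m))
  mine <- ks_test_fitted(xr, function(z) pt2gwg(z, m))
  ref <- suppressWarnings(stats::ks.test(xr, function(z) pt2gwg(z, m),
                                         exact = FALSE))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$pvalue, ref$p.value, tolerance = 1e-3)
})

test_that("fitted-model K-S p-values are roughly uniform under the null", {
  m <- t2gwe(1.5, 1, 1)
  pv <- vapply(1:200, function(s) {
    x <- withr::with_seed(s, rt2gwg(100, m))
    ks_test_fitted(x, function(z) pt2gwg(z, m))$pvalue
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("W* and A* match naive reference loops and analytic anchors", {
  m <- t2gwe(1, 1, 1)
  n <- 8
  x <- qt2gwg((2 * (1:n) - 1) / (2 * n), m)
  expect_equal(as.numeric(cvm_stat(x, function(z) pt2gwg(z, m))),
               1 / (12 * n), tolerance = 1e-12)
  x1 <- qt2gwg(0.5, m)
  expect_equal(as.numeric(ad_stat(x1, function(z) pt2gwg(z, m))),
               -1 - 2 * log(0.5), tolerance = 1e-9)
  w_naive <- function(u) {
    n <- length(u); total <- 1 / (12 * n)
    for (i in 1:n) total <- total + (u[i] - (2 * i - 1) / (2 * n))^2
    total
  }
  a_naive <- function(u) {
    n <- length(u); s <- 0
    for (i in 1:n) s <- s + (2 * i - 1) * (log(u[i]) + log(1 - u[n + 1 - i]))
    -n - s / n
  }
  xr <- withr::with_seed(9, rt2gwg(40, m))
  u <- sort(pt2gwg(sort(xr), m))
  expect_equal(as.numeric(cvm_stat(xr, function(z) pt2gwg(z, m))),
               w_naive(u), tolerance = 1e-12)
  expect_equal(as.numeric(ad_stat(xr, function(z) pt2gwg(z, m))),
               a_naive(u), tolerance = 1e-12)
})

test_that("distance statistics are invariant under monotone reparameterization", {
  # transform data and model consistently: y = exp(x), cdf_y = cdf_x(log y)
  m <- t2gwe(1.3, 0.9, 1)
  x <- withr::with_seed(15, rt2gwg(50, m))
  cdf_x <- function(z) pt2gwg(z, m)
  cdf_y <- function(z) pt2gwg(log(z), m)
  expect_equal(ks_test_fitted(x, cdf_x)$statistic,
               ks_test_fitted(exp(x), cdf_y)$statistic, tolerance = 1e-12)
  expect_equal(as.numeric(cvm_stat(x, cdf_x)),
               as.numeric(cvm_stat(exp(x), cdf_y)), tolerance = 1e-12)
  expect_equal(as.numeric(ad_stat(x, cdf_x)),
               as.numeric(ad_stat(exp(x), cdf_y)), tolerance = 1e-12)
})

test_that("scaled TTT transform matches hand computation and endpoints", {
  tt <- ttt_scaled(c(1, 2, 3))
  expect_equal(tt$p, c(0, 1 / 3, 2 / 3, 1))
  expect_equal(tt$G, c(0, 0.5, 5 / 6, 1))
  ttc <- ttt_scaled(rep(4, 6))
  expect_true(all(ttc$G[-1] == 1))
  expect_error(ttt_scaled(c(1, -2, 3)), "positive")
  expect_error(ttt_scaled(3), "two")
  # exponential samples: the TTT curve tends to the diagonal
  dev <- vapply(1:10, function(s) {
    tt <- ttt_scaled(withr::with_seed(s, rexp(1e4)))
    max(abs(tt$G - tt$p))
  }, numeric(1))
  expect_gte(sum(dev < 0.05), 9)
})

test_that("Kaplan-Meier equals one minus the ECDF without censoring", {
  x <- c(1, 2, 3)
  km <- km_curve(x); ec <- ecdf_points(x)
  expect_equal(km$time, ec$time)
  expect_equal(km$surv, 1 - ec$ecdf, tolerance = 1e-12)
  expect_equal(ec$ecdf[ec$time == 2], 2 / 3)
  xr <- withr::with_seed(21, rt2gwg(60, t2gwe(1, 1, 1)))
  km2 <- km_curve(xr); ec2 <- ecdf_points(xr)
  expect_equal(km2$surv, 1 - ec2$ecdf, tolerance = 1e-12)
  expect_equal(km2$time, sort(unique(xr)))
  expect_equal(stats::ecdf(xr)(min(xr) - 1), 0)
})

test_that("gof_report assembles consistent statistics for a fitted model", {
  x <- withr::with_seed(25, rt2gwg(120, t2gwe(2, 1, 1)))
  ft <- fit(x, "t2gwe", "mle", standard_errors = FALSE)
  g <- gof_report(ft, x)
  expect_equal(g$neg2logl, 2 * nll(ft$estimates, x), tolerance = 1e-8)
  expect_equal(g$aic, g$neg2logl + 6, tolerance = 1e-10)
  expect_equal(g$caic, g$aic + 24 / (120 - 4), tolerance = 1e-10)
  expect_true(g$ks_pvalue >= 0 && g$ks_pvalue <= 1)
})

test_that("model comparison ranks the generating family first on its own data", {
  wins <- sum(vapply(1:20, function(s) {
    x <- withr::with_seed(s + 4000, rweibull(500, 1.7, 3))
    tab <- compare_models(x, c("weibull", "gamma", "t2g"),
                          standard_errors = FALSE, n_restarts = 2)
    tab$family[1] == "weibull"
  }, logical(1)))
  expect_gte(wins, 19)
})

test_that("comparison keeps non-converging families with a failure flag", {
  x <- withr::with_seed(26, rt2gwg(80, t2gwe(1, 1, 1)))
  tab <- compare_models(x, c("t2gwe", "weibull"), standard_errors = FALSE)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("aic", "bic", "caic", "hqic", "w_star", "a_star",
                    "ks", "ks_pvalue", "converged") %in% names(tab)))
  expect_true(all(tab$converged))
  expect_true(!is.unsorted(tab$aic))
})
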