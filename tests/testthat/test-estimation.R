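test_that("single-observation likelihood anchors are exact", {
  x <- log(2)
  expect_equal(nll(c(1, 1, 1), x), 1 - log(2), tolerance = 1e-12)
  s <- score(c(1, 1, 1), x)
  expect_equal(unname(s[["alpha"]]), 0, tolerance = 1e-12)
})

test_that("distance objectives take their hand-computed values", {
  # LS with a single observation where F(x_1) = 0.75
  # solve F = 0.75 for the unit model: x = qt2gwg(0.75)
  m <- t2gwe(1, 1, 1)
  x1 <- qt2gwg(0.75, m)
  expect_equal(ls_objective(c(1, 1, 1), x1), 0.0625, tolerance = 1e-10)
  # WLS weight at n = 1 is (n+1)^2 (n+2) / (i (n-i+1)) = 12
  expect_equal(wls_objective(c(1, 1, 1), x1), 0.75, tolerance = 1e-9)
  # CVM at n = 1: 1/12 + (0.75 - 0.5)^2
  expect_equal(cvm_objective(c(1, 1, 1), x1), 1 / 12 + 0.0625,
               tolerance = 1e-10)
  # CVM perfect fit leaves only the 1/(12 n^2) term
  n <- 5
  xs <- qt2gwg((2 * (1:n) - 1) / (2 * n), m)
  expect_equal(cvm_objective(c(1, 1, 1), xs), 1 / 300, tolerance = 1e-10)
  # LS perfect fit at plotting positions i/(n+1) is zero
  xs2 <- qt2gwg((1:n) / (n + 1), m)
  expect_equal(ls_objective(c(1, 1, 1), xs2), 0, tolerance = 1e-12)
  # AD at n = 1 with F(x_1) = 0.5
  xm <- qt2gwg(0.5, m)
  expect_equal(ad_objective(c(1, 1, 1), xm),
               -1 - (log(0.5) + log(0.5)), tolerance = 1e-9)
})

test_that("MPS spacings telescope to one and hit the equal-spacing bound", {
  m <- t2gwe(1, 1, 1)
  x2 <- qt2gwg(c(1 / 3, 2 / 3), m)
  # three equal spacings: W = log(1/3), objective = -W
  expect_equal(mps_objective(c(1, 1, 1), x2), -log(1 / 3), tolerance = 1e-9)
  for (par in draw_params(5, seed = 2)) {
    x <- withr::with_seed(8, rt2gwg(40, m))
    sp <- spacings(unname(par), x)
    expect_equal(sum(sp$D), 1, tolerance = 1e-12)
    expect_true(all(sp$D >= 0))
    # Jensen bound: mean log spacing never exceeds log(1/(n+1))
    expect_gte(mps_objective(unname(par), x), log(length(x) + 1))
  }
  # grid-search oracle at n = 2: the best achievable objective is log(3)
  best <- Inf
  grid <- (1:19) / 20
  for (p1 in grid[grid <= 0.85]) for (p2 in grid[grid >= p1 + 0.049 & grid <= 0.95]) {
    D <- c(p1, p2 - p1, 1 - p2)
    best <- min(best, -mean(log(D)))
  }
  expect_gte(best, log(3) - 1e-9)
})

test_that("exact ties fall back to the density convention, never -Inf", {
  x <- c(0.4, 0.7, 0.7, 1.1)
  v <- mps_objective(c(1.2, 0.9, 1), x)
  expect_true(is.finite(v))
})

test_that("AD objective equals a naive two-loop reference on random inputs", {
  ad_naive <- function(par, x) {
    xs <- sort(x); n <- length(xs)
    m <- t2gwe(par[1], par[2], par[3])
    total <- 0
    clamp <- function(u) pmin(pmax(u, 1e-300), 1 - 1e-16)
    for (i in 1:n) {
      Fi <- clamp(pt2gwg(xs[i], m))
      Fhi <- clamp(pt2gwg(xs[n + 1 - i], m))
      total <- total + (2 * i - 1) * (log(Fi) + log(1 - Fhi))
    }
    -n - total / n
  }
  for (par in draw_params(5, seed = 12)) {
    x <- withr::with_seed(77, rt2gwg(30, t2gwe(2, 1, 1)))
    expect_equal(ad_objective(unname(par), x), ad_naive(unname(par), x),
                 tolerance = 1e-12)
  }
})

test_that("analytic gradients of all six criteria match finite differences", {
  objectives <- list(
    mle = function(p, x, g = FALSE) {
      if (!g) return(nll(p, x))
      v <- nll(p, x); attr(v, "gradient") <- -unname(score(p, x)); v
    },
    ls = function(p, x, g = FALSE) ls_objective(p, x, gradient = g),
    wls = function(p, x, g = FALSE) wls_objective(p, x, gradient = g),
    mps = function(p, x, g = FALSE) mps_objective(p, x, gradient = g),
    cvm = function(p, x, g = FALSE) cvm_objective(p, x, gradient = g),
    ad = function(p, x, g = FALSE) ad_objective(p, x, gradient = g))
  pts <- draw_params(120, seed = 5)
  x <- withr::with_seed(100, rt2gwg(40, t2gwe(2.5, 0.8, 1.3)))
  # keep draws in the smooth interior: no probability clamping in effect
  # and no near-degenerate spacings (finite differences of log-spacings
  # are meaningless when adjacent fitted probabilities collide at 1e-14)
  pts <- Filter(function(par) {
    Fv <- pt2gwg(sort(x), t2gwe(par[["alpha"]], par[["beta"]], par[["gamma"]]))
    min(Fv) > 1e-12 && max(Fv) < 1 - 1e-12 &&
      all(diff(c(0, Fv, 1)) > 1e-7)
  }, pts)
  expect_gte(length(pts), 50)
  for (nm in names(objectives)) {
    fo <- objectives[[nm]]
    worst <- 0
    for (par in pts) {
      p <- unname(par)
      g <- attr(fo(p, x, TRUE), "gradient")
      fd <- pracma::grad(function(q) fo(q, x), p)
      worst <- max(worst, max(abs(g - fd)) / max(abs(fd), 1e-6))
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("fitting recovers parameters and never beats the truth's objective", {
  x <- withr::with_seed(302, rt2gwg(1000, t2gwe(2.5, 0.8, 1.3)))
  truth <- c(2.5, 0.8, 1.3)
  for (m in method_names()) {
    ft <- fit(x, "t2gwe", m, init = truth, n_restarts = 0,
              standard_errors = FALSE)
    expect_true(ft$converged)
    # published large-sample RMSEs: ~0.34 (alpha), 0.06 (beta), 0.16 (gamma)
    expect_lt(abs(ft$estimates[["alpha"]] - 2.5), 3 * 0.34)
    expect_lt(abs(ft$estimates[["beta"]] - 0.8), 3 * 0.06)
    expect_lt(abs(ft$estimates[["gamma"]] - 1.3), 3 * 0.16)
    obj_truth <- switch(m,
      mle = nll(truth, x), ls = ls_objective(truth, x),
      wls = wls_objective(truth, x), mps = mps_objective(truth, x),
      cvm = cvm_objective(truth, x), ad = ad_objective(truth, x))
    expect_lte(ft$objective, obj_truth + 1e-8)
  }
})

test_that("the MLE score vanishes at the fitted optimum", {
  x <- withr::with_seed(303, rt2gwg(500, t2gwe(2.5, 0.8, 1.3)))
  ft <- fit(x, "t2gwe", "mle", standard_errors = FALSE)
  s <- score(ft$estimates, x)
  # gradient w.r.t. log-parameters (the optimization scale)
  expect_lt(max(abs(s * ft$estimates)), 1e-3 * length(x))
})

test_that("objective_at_optimum is consistent with re-evaluation", {
  x <- withr::with_seed(304, rt2gwg(200, t2gwe(2, 1, 1)))
  ft <- fit(x, "t2gwe", "cvm", standard_errors = FALSE)
  expect_equal(ft$objective, cvm_objective(ft$estimates, x),
               tolerance = 1e-8)
})

test_that("MLE is equivariant under data rescaling (exponential baseline)", {
  x <- withr::with_seed(305, rt2gwg(400, t2gwe(2.5, 0.8, 1.3)))
  f1 <- fit(x, "t2gwe", "mle", standard_errors = FALSE)
  f2 <- fit(3 * x, "t2gwe", "mle", standard_errors = FALSE)
  expect_equal(f1$estimates[["alpha"]], f2$estimates[["alpha"]],
               tolerance = 1e-5)
  expect_equal(f1$estimates[["beta"]], f2$estimates[["beta"]],
               tolerance = 1e-5)
  expect_equal(f1$estimates[["gamma"]] / 3, f2$estimates[["gamma"]],
               tolerance = 1e-5)
})

test_that("uniform-baseline fits keep gamma above the sample maximum", {
  x <- withr::with_seed(306, rt2gwg(150, t2gwu(0.65, 0.31, 90)))
  ft <- fit(x, "t2gwu", "mle", standard_errors = FALSE)
  expect_true(ft$converged)
  expect_gt(ft$estimates[["gamma"]], max(x))
})

test_that("standard errors come from the observed information and are positive", {
  x <- withr::with_seed(307, rt2gwg(800, t2gwe(2.5, 0.8, 1.3)))
  ft <- fit(x, "t2gwe", "mle")
  expect_false(is.null(ft$std_errors))
  expect_true(all(ft$std_errors > 0))
  # large-sample sanity: SEs in the ballpark of the published sqrt(MSE)
  expect_lt(ft$std_errors[["beta"]], 0.2)
  ft2 <- fit(x, "t2gwe", "cvm")
  expect_null(ft2$std_errors)
})

test_that("degenerate input yields a diagnosed non-fit, not a crash", {
  x <- rep(2, 12)
  ft <- tryCatch(fit(x, "t2gwe", "mle", standard_errors = FALSE),
                 error = function(e) NULL)
  expect_false(is.null(ft))    # no uncaught crash
  expect_true(is.null(ft$estimates) || !anyNA(ft$estimates))
})

test_that("competitor families fit synthetic data from their own model", {
  x <- withr::with_seed(308, rweibull(400, 1.4, 2))
  fw <- fit(x, "weibull", "mle", standard_errors = FALSE)
  expect_equal(fw$estimates[["k"]], 1.4, tolerance = 0.15)
  expect_equal(fw$estimates[["lambda"]], 2, tolerance = 0.15)
  xg <- withr::with_seed(309, rgamma(400, shape = 2, rate = 1.5))
  fg <- fit(xg, "gamma", "mle", standard_errors = FALSE)
  expect_equal(fg$estimates[["alpha"]], 2, tolerance = 0.3)
})
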