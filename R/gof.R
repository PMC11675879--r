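#' Information criteria from a -2 log-likelihood
#'
#' Standard penalized-likelihood criteria for a model with `k` estimated
#' parameters fitted to `n` observations:
#' AIC = -2logL + 2k; BIC = -2logL + k log n;
#' HQIC = -2logL + 2k log(log n); CAIC = AIC + 2k(k+1)/(n-k-1)
#' (the small-sample corrected AIC).
#'
#' @param neg2logl -2 times the maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return named list `aic`, `bic`, `caic`, `hqic`; `caic` is `NA` with a
#'   `caic_undefined` attribute when `n <= k + 1`.
#' @examples
#' information_criteria(361.1643, 3, 50)
#' @export
information_criteria <- function(neg2logl, k, n) {
  stopifnot(k >= 0, n >= 1)
  aic <- neg2logl + 2 * k
  caic <- if (n > k + 1) aic + 2 * k * (k + 1) / (n - k - 1) else
    structure(NA_real_, caic_undefined = TRUE)
  list(aic = aic,
       bic = neg2logl + k * log(n),
       caic = caic,
       hqic = neg2logl + 2 * k * log(log(n)))
}

#' One-sample Kolmogorov-Smirnov test against a fitted cdf
#'
#' The statistic is the supremum distance
#' `D = max_i max(i/n - u_(i), u_(i) - (i-1)/n)` with `u_(i)` the fitted
#' cdf at the sorted sample; the p-value comes from the asymptotic
#' Kolmogorov series for `sqrt(n) * D` (no correction for estimated
#' parameters, matching common practice in lifetime-model comparisons).
#'
#' @param data numeric sample.
#' @param fitted_cdf vectorized cdf function.
#' @return list with `statistic` and `pvalue`.
#' @export
ks_test_fitted <- function(data, fitted_cdf) {
  n <- length(data)
  u <- sort(fitted_cdf(sort(data)))
  i <- seq_len(n)
  D <- max(pmax(i / n - u, u - (i - 1) / n))
  list(statistic = D, pvalue = .kolmogorov_pvalue(sqrt(n) * D))
}

# P(K > t) for the Kolmogorov distribution, by the alternating series
.kolmogorov_pvalue <- function(t) {
  if (t <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Cramer-von Mises and Anderson-Darling goodness-of-fit statistics
#'
#' With `u_(i)` the fitted cdf at the sorted sample,
#' `W = 1/(12n) + sum_i (u_(i) - (2i-1)/(2n))^2` and
#' `A = -n - (1/n) sum_i (2i-1) [log u_(i) + log(1 - u_(n+1-i))]`.
#' The values are reported raw (no small-sample factor); the
#' `(1 + 0.5/n)`-modified versions are attached as attribute
#' `"modified"` for reference.
#'
#' @inheritParams ks_test_fitted
#' @return numeric statistic with attribute `"modified"`.
#' @export
cvm_stat <- function(data, fitted_cdf) {
  n <- length(data)
  u <- sort(fitted_cdf(sort(data)))
  W <- 1 / (12 * n) + sum((u - (2 * seq_len(n) - 1) / (2 * n))^2)
  structure(W, modified = W * (1 + 0.5 / n))
}

#' @rdname cvm_stat
#' @export
ad_stat <- function(data, fitted_cdf) {
  n <- length(data)
  u <- .clampF(sort(fitted_cdf(sort(data))))
  i <- seq_len(n)
  A <- -n - sum((2 * i - 1) * (log(u[i]) + log1p(-u[n + 1 - i]))) / n
  structure(A, modified = A * (1 + 0.75 / n + 2.25 / n^2))
}

#' Scaled total time on test transform
#'
#' `G(i/n) = [sum_{j<=i} x_(j) + (n-i) x_(i)] / sum_j x_j`.  The shape of
#' the polyline (i/n, G(i/n)) diagnoses the hazard: concave for increasing
#' hazard, convex for decreasing, convex-then-concave for a bathtub.
#'
#' @param data positive numeric sample, n >= 2.
#' @return data.frame with columns `p = i/n` and `G`, including the
#'   origin (0, 0).
#' @examples
#' ttt_scaled(c(1, 2, 3))
#' @export
ttt_scaled <- function(data) {
  if (length(data) < 2) stop("need at least two observations", call. = FALSE)
  if (any(!is.finite(data) | data <= 0))
    stop("all data must be positive and finite", call. = FALSE)
  xs <- sort(data)
  n <- length(xs)
  i <- seq_len(n)
  G <- (cumsum(xs) + (n - i) * xs) / sum(xs)
  data.frame(p = c(0, i / n), G = c(0, G))
}

#' Kaplan-Meier survival curve and empirical cdf for uncensored data
#'
#' `km_curve` evaluates the Kaplan-Meier estimator (via
#' [survival::survfit()]); with no censoring it equals `1 - ecdf` at every
#' step.  `ecdf_points` returns the empirical cdf evaluated at the sorted
#' unique data values.
#'
#' @param data positive numeric sample (assumed fully observed).
#' @return data.frame with columns `time` and `surv` (`km_curve`) or
#'   `time` and `ecdf` (`ecdf_points`).
#' @export
km_curve <- function(data) {
  sf <- survival::survfit(survival::Surv(data, rep(1, length(data))) ~ 1)
  data.frame(time = sf$time, surv = sf$surv)
}

#' @rdname km_curve
#' @export
ecdf_points <- function(data) {
  t <- sort(unique(data))
  data.frame(time = t, ecdf = stats::ecdf(data)(t))
}

#' Goodness-of-fit report for one fitted model
#'
#' @param fit_obj a converged [fit()] result (method `"mle"` for
#'   likelihood-based criteria).
#' @param data the data the model was fitted to.
#' @return list of class `"t2gwg_gof"`: `neg2logl`, `aic`, `bic`, `caic`,
#'   `hqic`, `w_star`, `a_star`, `ks_stat`, `ks_pvalue`, `n`, `k_params`.
#' @export
gof_report <- function(fit_obj, data) {
  stopifnot(inherits(fit_obj, "t2gwg_fit"), !is.null(fit_obj$estimates))
  fam <- .fit_family(fit_obj$family, data)
  par <- fit_obj$estimates
  n2l <- 2 * sum(-fam$logpdf(data, par))
  ic <- information_criteria(n2l, fam$npar, length(data))
  cdf <- function(x) fam$cdf(x, par)
  ks <- ks_test_fitted(data, cdf)
  out <- c(list(family = fit_obj$family, neg2logl = n2l), ic,
           list(w_star = as.numeric(cvm_stat(data, cdf)),
                a_star = as.numeric(ad_stat(data, cdf)),
                ks_stat = ks$statistic, ks_pvalue = ks$pvalue,
                n = length(data), k_params = fam$npar))
  class(out) <- "t2gwg_gof"
  out
}

#' Fit and rank several families on one dataset
#'
#' Fits each family by the same criterion, assembles the goodness-of-fit
#' statistics and ranks the table (by AIC by default).  Families that fail
#' to converge stay in the table with `converged = FALSE`.
#'
#' @param data positive numeric sample.
#' @param families character vector of [family_names()] entries (>= 2).
#' @param method estimation criterion, see [method_names()].
#' @param rank_by column to sort by (`"aic"` default).
#' @param ... further arguments passed to [fit()].
#' @return data.frame of class `"t2gwg_comparison"` with one row per
#'   family: estimates (flattened, `par1..par4` + names), `neg2logl`,
#'   `aic`, `caic`, `bic`, `hqic`, `w_star`, `a_star`, `ks`, `ks_pvalue`,
#'   `converged`; fitted objects attached as attribute `"fits"`.
#' @export
compare_models <- function(data, families, method = "mle",
                           rank_by = "aic", ...) {
  stopifnot(length(families) >= 2)
  fits <- lapply(families, function(f)
    tryCatch(fit(data, f, method, ...), error = function(e)
      structure(list(method = method, family = f, estimates = NULL,
                     converged = FALSE, message = conditionMessage(e)),
                class = "t2gwg_fit")))
  rows <- lapply(fits, function(ft) {
    base <- data.frame(family = ft$family, converged = isTRUE(ft$converged),
                       stringsAsFactors = FALSE)
    if (is.null(ft$estimates)) {
      cbind(base, data.frame(params = NA_character_, neg2logl = NA_real_,
                             aic = NA_real_, caic = NA_real_,
                             bic = NA_real_, hqic = NA_real_,
                             w_star = NA_real_, a_star = NA_real_,
                             ks = NA_real_, ks_pvalue = NA_real_))
    } else {
      g <- gof_report(ft, data)
      cbind(base, data.frame(
        params = paste(names(ft$estimates),
                       formatC(ft$estimates, format = "f", digits = 4),
                       sep = "=", collapse = ", "),
        neg2logl = g$neg2logl, aic = g$aic, caic = as.numeric(g$caic),
        bic = g$bic, hqic = g$hqic, w_star = g$w_star, a_star = g$a_star,
        ks = g$ks_stat, ks_pvalue = g$ks_pvalue))
    }
  })
  tab <- do.call(rbind, rows)
  ord <- order(is.na(tab[[rank_by]]), tab[[rank_by]])
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  class(tab) <- c("t2gwg_comparison", "data.frame")
  tab
}

#' @export
print.t2gwg_comparison <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, right = FALSE)
  invisible(x)
}
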