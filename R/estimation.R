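#' @title Estimation criteria
#'
#' @description
#' Six estimation criteria are provided for T2GWG models: maximum
#' likelihood (`nll`), ordinary and weighted least squares on the cdf at
#' plotting positions i/(n+1) (`ls_objective`, `wls_objective`), maximum
#' product spacing (`mps_objective`, negated mean log spacing), and the
#' Cramer-von Mises and Anderson-Darling minimum-distance criteria
#' (`cvm_objective`, `ad_objective`).  All are minimized; all carry
#' analytic gradients for the T2GWG special-case families.
#'
#' @name estimation
NULL

# clamping bounds for log-based objectives (AD, MPS)
.F_EPS_LO <- 1e-300
.F_EPS_HI <- 1 - 1e-16

.clampF <- function(F) pmin(pmax(F, .F_EPS_LO), .F_EPS_HI)

# soft rejection: objectives return +Inf when a datum falls off the support
# or the parameters are invalid, so the optimizer retreats
.finite_or_inf <- function(v) if (is.finite(v)) v else Inf

#' Negative log-likelihood and score for a T2GWG model
#'
#' `nll` evaluates minus the log-likelihood
#' \deqn{\ell = n\log\alpha + n\log\beta + \sum\log h
#'   - (\beta+1)\sum\log H + (\beta-1)\sum\log\bar H
#'   - \alpha\sum (H/\bar H)^{-\beta},}
#' and `score` its analytic gradient with respect to
#' `(alpha, beta, psi...)`.
#'
#' @param par named parameter vector in family order (e.g.
#'   `(alpha, beta, gamma)` for `"t2gwe"`).
#' @param data positive numeric vector of lifetimes.
#' @param family one of `"t2gwe"`, `"t2gwu"`, `"t2gwp"`.
#' @return `nll`: scalar (`Inf` when a datum is off the support);
#'   `score`: gradient vector of the *log-likelihood* (not of the nll).
#' @export
nll <- function(par, data, family = "t2gwe") {
  fam <- .fit_family(family, data)
  lp <- fam$logpdf(data, par)
  .finite_or_inf(-sum(lp))
}

#' @rdname nll
#' @export
score <- function(par, data, family = "t2gwe") {
  fam <- .fit_family(family, data)
  if (!isTRUE(fam$is_t2gwg))
    stop("analytic score available only for T2GWG families", call. = FALSE)
  fg <- .t2gwg_F_and_grad(data, par, fam)
  n <- length(data)
  a <- par[1]; b <- par[2]
  lodds <- fg$lo$log_odds
  dla <- n / a - sum(fg$u)
  dlb <- n / b - sum(lodds) + a * sum(fg$u * lodds)
  H <- exp(fg$lo$logH); SF <- exp(fg$lo$logSF)
  h <- baseline_pdf(data, fam$model(par)$baseline)
  kern <- a * b * exp(-(b + 1) * fg$lo$logH + (b - 1) * fg$lo$logSF)
  dpsi <- colSums(fg$grad_base$dh / h - (b + 1) * fg$grad_base$dH / H -
                    (b - 1) * fg$grad_base$dH / SF +
                    kern * fg$grad_base$dH)
  out <- c(dla, dlb, dpsi)
  names(out) <- fam$par_names
  out
}

# shared machinery: sorted data, fitted F at order statistics, and (when a
# gradient is requested) dF; returns NULL on invalid evaluation
.sorted_F <- function(par, data, fam, grad = FALSE) {
  xs <- sort(data)
  if (grad && fam$is_t2gwg) {
    fg <- tryCatch(.t2gwg_F_and_grad(xs, par, fam), error = function(e) NULL)
    if (is.null(fg) || any(!is.finite(fg$F))) return(NULL)
    list(xs = xs, F = fg$F, dF = fg$dF)
  } else {
    F <- tryCatch(fam$cdf(xs, par), error = function(e) NULL)
    if (is.null(F) || any(!is.finite(F))) return(NULL)
    list(xs = xs, F = F, dF = NULL)
  }
}

#' Least-squares and weighted least-squares criteria
#'
#' `ls_objective` is \eqn{\sum_i [F(x_{(i)}) - i/(n+1)]^2};
#' `wls_objective` weights each term by
#' \eqn{(n+1)^2 (n+2) / [i (n-i+1)]} (the inverse variance of the i-th
#' uniform order statistic).
#'
#' @inheritParams nll
#' @param gradient logical; also return the analytic gradient (T2GWG
#'   families only) as attribute `"gradient"`.
#' @return scalar objective value (smaller is better).
#' @export
ls_objective <- function(par, data, family = "t2gwe", gradient = FALSE) {
  fam <- .fit_family(family, data)
  sf <- .sorted_F(par, data, fam, grad = gradient)
  if (is.null(sf)) return(Inf)
  n <- length(sf$xs)
  r <- sf$F - seq_len(n) / (n + 1)
  val <- sum(r^2)
  if (gradient && !is.null(sf$dF))
    attr(val, "gradient") <- as.numeric(2 * crossprod(sf$dF, r))
  val
}

#' @rdname ls_objective
#' @export
wls_objective <- function(par, data, family = "t2gwe", gradient = FALSE) {
  fam <- .fit_family(family, data)
  sf <- .sorted_F(par, data, fam, grad = gradient)
  if (is.null(sf)) return(Inf)
  n <- length(sf$xs)
  i <- seq_len(n)
  w <- (n + 1)^2 * (n + 2) / (i * (n - i + 1))
  r <- sf$F - i / (n + 1)
  val <- sum(w * r^2)
  if (gradient && !is.null(sf$dF))
    attr(val, "gradient") <- as.numeric(2 * crossprod(sf$dF, w * r))
  val
}

#' Maximum product spacing criterion (negated)
#'
#' Returns minus the mean log spacing
#' \eqn{-W = -\frac{1}{n+1}\sum_{i=1}^{n+1} \log D_i}, where the spacings
#' are consecutive differences of the fitted cdf at the sorted sample with
#' \eqn{D_1 = F(x_{(1)})} and \eqn{D_{n+1} = 1 - F(x_{(n)})}.  Exact ties
#' produce zero spacings, which are replaced by the fitted density at the
#' tied point (Cheng-Amin convention) so the criterion never returns
#' `-Inf` from ties alone.
#'
#' @inheritParams ls_objective
#' @param spacings `"full"` (default): all n+1 spacings including both tail
#'   gaps `F(x_(1))` and `1 - F(x_(n))`, the canonical geometric-mean
#'   criterion; `"left"`: the left-anchored set `D_1, ..., D_n` that omits
#'   the upper tail gap, a convention also found in applied Monte Carlo
#'   work (see the methods vignette).
#' @return scalar: minus the mean log spacing (minimize).
#' @export
mps_objective <- function(par, data, family = "t2gwe", gradient = FALSE,
                          spacings = c("full", "left")) {
  spacings <- match.arg(spacings)
  fam <- .fit_family(family, data)
  sf <- .sorted_F(par, data, fam, grad = gradient)
  if (is.null(sf)) return(Inf)
  n <- length(sf$xs)
  D <- if (spacings == "full") diff(c(0, sf$F, 1)) else diff(c(0, sf$F))
  tied <- diff(sf$xs) == 0                   # D_{i+1} from a tied pair
  if (spacings == "full") tied <- c(tied, FALSE)
  if (any(tied)) {
    dens <- exp(fam$logpdf(sf$xs[which(tied)], par))
    D[which(tied) + 1L] <- dens
  }
  if (any(D <= 0)) return(Inf)
  val <- -mean(log(D))
  if (gradient && !is.null(sf$dF) && !any(tied)) {
    dD <- if (spacings == "full")
      rbind(sf$dF, 0) - rbind(0, sf$dF)      # d D_i / d par, (n+1) x p
    else sf$dF - rbind(0, sf$dF[-n, , drop = FALSE])
    attr(val, "gradient") <- as.numeric(-colSums(dD / D) / length(D))
  }
  val
}

#' Spacings of a fitted cdf at sorted data
#'
#' @inheritParams nll
#' @return list with `x` (sorted data), `D` (the n+1 spacings, summing to
#'   1) and `F` (fitted cdf at the sorted data).
#' @export
spacings <- function(par, data, family = "t2gwe") {
  fam <- .fit_family(family, data)
  xs <- sort(data)
  F <- fam$cdf(xs, par)
  list(x = xs, D = diff(c(0, F, 1)), F = F)
}

#' Cramer-von Mises estimation criterion
#'
#' `S = 1/(12 n^2) + (1/n) * sum_i [F(x_(i)) - (2i-1)/(2n)]^2`, the form
#' the minimum-distance estimator minimizes over the sorted sample.
#'
#' @inheritParams ls_objective
#' @return scalar objective value.
#' @export
cvm_objective <- function(par, data, family = "t2gwe", gradient = FALSE) {
  fam <- .fit_family(family, data)
  sf <- .sorted_F(par, data, fam, grad = gradient)
  if (is.null(sf)) return(Inf)
  n <- length(sf$xs)
  r <- sf$F - (2 * seq_len(n) - 1) / (2 * n)
  val <- 1 / (12 * n^2) + sum(r^2) / n
  if (gradient && !is.null(sf$dF))
    attr(val, "gradient") <- as.numeric(2 * crossprod(sf$dF, r) / n)
  val
}

#' Anderson-Darling estimation criterion
#'
#' \deqn{AD = -n - \frac{1}{n}\sum_{i=1}^n (2i-1)
#'   [\log F(x_{(i)}) - \log \bar F(x_{(n+1-i)})].}
#' Fitted probabilities are clamped to `[1e-300, 1 - 1e-16]` before the
#' logarithms.
#'
#' @inheritParams ls_objective
#' @return scalar objective value.
#' @export
ad_objective <- function(par, data, family = "t2gwe", gradient = FALSE) {
  fam <- .fit_family(family, data)
  sf <- .sorted_F(par, data, fam, grad = gradient)
  if (is.null(sf)) return(Inf)
  n <- length(sf$xs)
  i <- seq_len(n)
  Fl <- .clampF(sf$F)
  val <- -n - sum((2 * i - 1) *
                    (log(Fl[i]) + log1p(-Fl[n + 1 - i]))) / n
  if (!is.finite(val)) return(Inf)
  if (gradient && !is.null(sf$dF)) {
    # d/dpar: -(1/n) sum (2i-1) [ dF_i/F_i + dF_{n+1-i}/(1-F_{n+1-i}) * (-1)... ]
    w1 <- (2 * i - 1) / Fl[i]
    w2 <- (2 * i - 1) / (1 - Fl[n + 1 - i])
    g <- -(crossprod(sf$dF[i, , drop = FALSE], w1) -
             crossprod(sf$dF[n + 1 - i, , drop = FALSE], w2)) / n
    attr(val, "gradient") <- as.numeric(g)
  }
  val
}

.objective_fns <- list(
  mle = function(par, data, fam, gradient = FALSE) {
    lp <- tryCatch(fam$logpdf(data, par), error = function(e) NULL)
    if (is.null(lp) || any(!is.finite(lp))) return(Inf)
    val <- -sum(lp)
    if (gradient && fam$is_t2gwg)
      attr(val, "gradient") <- -unname(score(par, data, fam$name))
    val
  },
  ls = function(par, data, fam, gradient = FALSE)
    ls_objective(par, data, fam$name, gradient),
  wls = function(par, data, fam, gradient = FALSE)
    wls_objective(par, data, fam$name, gradient),
  mps = function(par, data, fam, gradient = FALSE, spacings = "full")
    mps_objective(par, data, fam$name, gradient, spacings),
  cvm = function(par, data, fam, gradient = FALSE)
    cvm_objective(par, data, fam$name, gradient),
  ad = function(par, data, fam, gradient = FALSE)
    ad_objective(par, data, fam$name, gradient)
)

#' Estimation method labels
#' @return character vector of the six method identifiers.
#' @export
method_names <- function() names(.objective_fns)

#' Fit a lifetime family to data
#'
#' Minimizes the chosen criterion on an unconstrained transform of the
#' parameter space (log scale for positive parameters; range-linked
#' transforms keep the uniform baseline's upper bound above the sample
#' maximum and the Pareto scale below the minimum).  Optimization uses
#' L-BFGS-B with analytic gradients where available, a Nelder-Mead
#' fallback, and a deterministic seed-derived multistart design.
#'
#' @param data positive numeric vector (n >= 3 recommended).
#' @param family one of [family_names()].
#' @param method one of [method_names()].
#' @param init optional named initial parameter vector (natural scale).
#' @param n_restarts number of additional jittered starts (>= 0).
#' @param seed integer seed controlling the restart design.
#' @param tol relative convergence tolerance on the objective.
#' @param standard_errors logical; compute inverse observed-information
#'   standard errors (method `"mle"` only).
#' @param mps_spacings spacing convention for method `"mps"`; see
#'   [mps_objective()].
#' @return object of class `"t2gwg_fit"`: a list with `method`, `family`,
#'   `estimates`, `std_errors` (or `NULL`), `objective`, `n_obs`,
#'   `converged`, `n_restarts_used`, `seed`, and `loglik` (MLE only).
#' @examples
#' set.seed(1)
#' x <- rt2gwg(200, t2gwe(2.5, 0.8, 1.3))
#' fit(x, "t2gwe", "mle")
#' @export
fit <- function(data, family = "t2gwe", method = "mle", init = NULL,
                n_restarts = 5L, seed = 1L, tol = 1e-10,
                standard_errors = (method == "mle"),
                mps_spacings = c("full", "left")) {
  stopifnot(is.numeric(data), length(data) >= 1, all(is.finite(data)))
  family <- match.arg(family, family_names())
  method <- match.arg(method, method_names())
  mps_spacings <- match.arg(mps_spacings)
  fam <- .fit_family(family, data)
  objfn <- if (method == "mps")
    function(par, data, fam, gradient = FALSE)
      mps_objective(par, data, fam$name, gradient, mps_spacings)
  else .objective_fns[[method]]

  starts <- list(if (is.null(init)) fam$init(data) else unname(init))
  if (n_restarts > 0) {
    rs <- .with_seed(seed, lapply(seq_len(n_restarts), function(i)
      starts[[1]] * exp(stats::rnorm(fam$npar, 0, 0.5))))
    starts <- c(starts, rs)
  }

  eta_obj <- function(eta) {
    par <- fam$transform$from(eta)
    as.numeric(objfn(par, data, fam, gradient = FALSE))
  }
  eta_grad <- if (fam$is_t2gwg) function(eta) {
    par <- fam$transform$from(eta)
    v <- objfn(par, data, fam, gradient = TRUE)
    g <- attr(v, "gradient")
    if (is.null(g))
      g <- tryCatch(pracma::grad(function(p) objfn(p, data, fam), par),
                    error = function(e) rep(NA_real_, fam$npar))
    # chain rule through the transform: d par / d eta
    dpar <- .transform_jacobian_diag(fam, eta)
    g * dpar
  } else NULL

  best <- NULL; used <- 0L
  for (s in starts) {
    eta0 <- fam$transform$to(s)
    if (any(!is.finite(eta0)) || !is.finite(eta_obj(eta0))) next
    res <- tryCatch(
      stats::optim(eta0, eta_obj, gr = eta_grad, method = "L-BFGS-B",
                   control = list(maxit = 500L, factr = tol / 1e-15)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value))
      res <- tryCatch(
        stats::optim(eta0, eta_obj, method = "Nelder-Mead",
                     control = list(maxit = 2000L, reltol = tol)),
        error = function(e) NULL)
    else {
      # polish with Nelder-Mead if L-BFGS-B stopped abnormally
      if (res$convergence != 0) {
        res2 <- tryCatch(
          stats::optim(res$par, eta_obj, method = "Nelder-Mead",
                       control = list(maxit = 2000L, reltol = tol)),
          error = function(e) NULL)
        if (!is.null(res2) && is.finite(res2$value) &&
            res2$value <= res$value) res <- res2
      }
    }
    used <- used + 1L
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value)) best <- res
  }

  if (is.null(best)) {
    out <- list(method = method, family = family, estimates = NULL,
                std_errors = NULL, objective = NA_real_,
                n_obs = length(data), converged = FALSE,
                n_restarts_used = used, seed = seed,
                message = "no start converged")
    class(out) <- "t2gwg_fit"
    return(out)
  }

  est <- fam$transform$from(best$par)
  names(est) <- fam$par_names
  se <- NULL
  if (standard_errors && method == "mle") {
    Hn <- tryCatch(
      pracma::hessian(function(p) {
        v <- .objective_fns$mle(p, data, fam)
        if (!is.finite(v)) 1e10 else v
      }, est),
      error = function(e) NULL)
    if (!is.null(Hn)) {
      cv <- tryCatch(solve(Hn), error = function(e) NULL)
      if (!is.null(cv)) {
        d <- diag(cv)
        se <- ifelse(d > 0, sqrt(d), NA_real_)
        names(se) <- fam$par_names
      }
    }
  }
  out <- list(method = method, family = family, estimates = est,
              std_errors = se, objective = best$value,
              n_obs = length(data),
              converged = best$convergence %in% c(0L, 52L) ||
                is.finite(best$value),
              n_restarts_used = used, seed = seed)
  if (method == "mle") out$loglik <- -best$value
  class(out) <- "t2gwg_fit"
  out
}

# diagonal of d par / d eta for the (elementwise) transforms in use
.transform_jacobian_diag <- function(fam, eta) {
  par <- fam$transform$from(eta)
  switch(fam$name,
         t2gwu = c(par[1:2], par[3] - par[3] / (1 + exp(eta[3]))),
         t2gwp = {
           p3 <- stats::plogis(eta[3])
           c(par[1:2], par[3] * (1 - p3), par[4])
         },
         par)    # pure log transforms: d exp(eta) / d eta = par
}

#' @export
print.t2gwg_fit <- function(x, ...) {
  cat("T2GWG fit: family = ", x$family, ", method = ", x$method, "\n",
      sep = "")
  if (is.null(x$estimates)) {
    cat("  NOT CONVERGED: ", x$message, "\n", sep = "")
    return(invisible(x))
  }
  est <- signif(x$estimates, 6)
  if (!is.null(x$std_errors)) {
    cat("  estimates (SE):\n")
    for (i in seq_along(est))
      cat("    ", names(est)[i], " = ", est[i],
          " (", signif(x$std_errors[i], 4), ")\n", sep = "")
  } else {
    cat("  estimates: ",
        paste(names(est), est, sep = " = ", collapse = ", "), "\n",
        sep = "")
  }
  cat("  objective at optimum: ", signif(x$objective, 8),
      "  (n = ", x$n_obs, ", converged = ", x$converged, ")\n", sep = "")
  invisible(x)
}

# run code under a temporary RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
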