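#' @title Fit-target families
#'
#' @description
#' [fit()] and [compare_models()] operate on *fit families*: lightweight
#' descriptions of a parametric lifetime family (parameter names, support,
#' cdf/log-density as functions of the parameter vector, initial-value
#' heuristic and a bijection between the natural and an unconstrained
#' optimization scale).  The three T2GWG special cases carry analytic
#' cdf-gradients and likelihood scores; the comparison families (EGT, WGE,
#' LGT, Type 2 Gumbel, Weibull, gamma) are fitted with numerical
#' derivatives.
#'
#' @name families
NULL

#' Available fit-family names
#' @return character vector of family identifiers accepted by [fit()].
#' @export
family_names <- function()
  c("t2gwe", "t2gwu", "t2gwp", "egt", "wge", "lgt", "t2g", "weibull", "gamma")

# Build the internal family object. `data` is needed by the families whose
# parameter space depends on the sample range (t2gwu, t2gwp).
.fit_family <- function(name, data) {
  name <- match.arg(name, family_names())
  n <- length(data)
  xmin <- min(data); xmax <- max(data)
  log_eta <- list(to = function(par, ...) log(par),
                  from = function(eta, ...) exp(eta))
  fam <- switch(
    name,
    t2gwe = list(
      par_names = c("alpha", "beta", "gamma"),
      model = function(par) t2gwe(par[[1]], par[[2]], par[[3]]),
      init = function(x) c(alpha = 1, beta = 1, gamma = 1 / mean(x)),
      transform = log_eta),
    t2gwu = list(
      par_names = c("alpha", "beta", "gamma"),
      model = function(par) t2gwu(par[[1]], par[[2]], par[[3]]),
      init = function(x) c(alpha = 1, beta = 1, gamma = 1.05 * max(x)),
      # gamma must exceed max(data): gamma = xmax * (1 + exp(eta3))
      transform = list(
        to = function(par) c(log(par[1:2]),
                             log(pmax(par[3] / xmax - 1, 1e-9))),
        from = function(eta) c(exp(eta[1:2]),
                               xmax * (1 + exp(eta[3]))))),
    t2gwp = list(
      par_names = c("alpha", "beta", "theta", "k"),
      model = function(par) t2gwp(par[[1]], par[[2]], par[[3]], par[[4]]),
      init = function(x) c(alpha = 1, beta = 1, theta = 0.9 * min(x), k = 1),
      # theta must stay below min(data): theta = xmin * plogis(eta3)
      transform = list(
        to = function(par) c(log(par[1:2]),
                             stats::qlogis(pmin(par[3] / xmin, 1 - 1e-12)),
                             log(par[4])),
        from = function(eta) c(exp(eta[1:2]),
                               xmin * stats::plogis(eta[3]),
                               exp(eta[4])))),
    egt = list(
      # exponentiated Gumbel type-2: F = 1 - (1 - exp(-theta x^-phi))^alpha
      par_names = c("alpha", "phi", "theta"),
      cdf = function(x, par) {
        G <- -expm1(-par[3] * x^(-par[2]))
        -expm1(par[1] * log(G))
      },
      logpdf = function(x, par) {
        a <- par[1]; ph <- par[2]; th <- par[3]
        u <- th * x^(-ph)
        log(a) + log(ph) + log(th) - (ph + 1) * log(x) - u +
          (a - 1) * log(-expm1(-u))
      },
      init = function(x) c(alpha = 1, phi = 1, theta = stats::median(x)),
      transform = log_eta),
    wge = list(
      # Weibull generalized exponential: F = 1 - exp(-a (e^(g x) - 1)^t)
      par_names = c("alpha", "theta", "gamma"),
      cdf = function(x, par) {
        -expm1(-par[1] * expm1(par[3] * x)^par[2])
      },
      logpdf = function(x, par) {
        a <- par[1]; t <- par[2]; g <- par[3]
        u <- expm1(g * x)
        log(a) + log(t) + log(g) + g * x + (t - 1) * log(u) - a * u^t
      },
      init = function(x) c(alpha = 1, theta = 1, gamma = 1 / mean(x)),
      transform = log_eta),
    lgt = list(
      # Lomax Gumbel type-2: Lomax outer on the odds of G = exp(-theta x^-k)
      par_names = c("alpha", "beta", "theta", "k"),
      cdf = function(x, par) {
        lG <- -par[3] * x^(-par[4])
        odds <- exp(lG - log(-expm1(lG)))
        -expm1(-par[1] * log1p(odds / par[2]))
      },
      logpdf = function(x, par) {
        a <- par[1]; b <- par[2]; th <- par[3]; k <- par[4]
        lG <- -th * x^(-k)
        lodds <- lG - log(-expm1(lG))
        # d odds/dx = g' / (1-G)^2, g' = G * th * k * x^(-k-1)
        log(a) + log(th) + log(k) - (k + 1) * log(x) + lG -
          2 * log(-expm1(lG)) - log(b) -
          (a + 1) * log1p(exp(lodds) / b)
      },
      init = function(x) c(alpha = 1, beta = 1, theta = stats::median(x),
                           k = 1),
      transform = log_eta),
    t2g = list(
      # Type 2 Gumbel: F = exp(-alpha x^-nu)
      par_names = c("alpha", "nu"),
      cdf = function(x, par) exp(-par[1] * x^(-par[2])),
      logpdf = function(x, par)
        log(par[1]) + log(par[2]) - (par[2] + 1) * log(x) -
        par[1] * x^(-par[2]),
      init = function(x) c(alpha = stats::median(x), nu = 1),
      transform = log_eta),
    weibull = list(
      par_names = c("k", "lambda"),
      cdf = function(x, par) stats::pweibull(x, par[1], par[2]),
      logpdf = function(x, par) stats::dweibull(x, par[1], par[2], log = TRUE),
      init = function(x) c(k = 1, lambda = mean(x)),
      transform = log_eta),
    gamma = list(
      par_names = c("alpha", "beta"),
      cdf = function(x, par) stats::pgamma(x, shape = par[1], rate = par[2]),
      logpdf = function(x, par) stats::dgamma(x, shape = par[1],
                                              rate = par[2], log = TRUE),
      init = function(x) {
        m <- mean(x); v <- stats::var(x)
        c(alpha = m^2 / v, beta = m / v)
      },
      transform = log_eta)
  )
  fam$name <- name
  fam$npar <- length(fam$par_names)
  fam$is_t2gwg <- name %in% c("t2gwe", "t2gwu", "t2gwp")
  if (fam$is_t2gwg) {
    fam$cdf <- function(x, par) pt2gwg(x, fam$model(par))
    fam$logpdf <- function(x, par) dt2gwg(x, fam$model(par), log = TRUE)
  }
  fam
}

# cdf F and its gradient dF (n x npar) w.r.t. the natural parameters, for
# the three T2GWG families; used by the distance-objective gradients.
.t2gwg_F_and_grad <- function(x, par, fam) {
  model <- fam$model(par)
  a <- model$alpha; b <- model$beta
  spec <- model$baseline
  lo <- .log_odds(x, spec)
  u <- exp(-b * lo$log_odds)                 # (H/Hbar)^(-beta)
  F <- exp(-a * u)
  g <- baseline_param_grad(x, spec)
  # dF/dpsi = alpha*beta*F*H^(-b-1)*Hbar^(b-1) * dH/dpsi
  kern <- a * b * F * exp(-(b + 1) * lo$logH + (b - 1) * lo$logSF)
  dF <- cbind(alpha = -u * F,
              beta = a * lo$log_odds * u * F,
              kern * g$dH)
  colnames(dF) <- fam$par_names
  list(F = F, dF = dF, model = model, lo = lo, u = u, grad_base = g)
}
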