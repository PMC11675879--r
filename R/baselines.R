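#' @title Baseline distributions for the exponentiated odds-ratio generator
#'
#' @description
#' The T2GWG machinery is baseline-agnostic: any continuous lifetime
#' distribution H(x, psi) with a density h, a closed-form survival function
#' and a quantile function can act as the "inner driver".  A baseline is
#' represented as an object of class `"t2gwg_baseline"` carrying closed-form
#' cdf, pdf, log-survival, quantile and parameter-gradient functions.  Three
#' baselines ship with the package (exponential, uniform, Pareto); further
#' baselines can be registered at run time with [register_baseline()].
#'
#' All baseline parameters must be strictly positive.  The survival function
#' is always evaluated from its own closed form (e.g. exp(-gamma*x) for the
#' exponential), never as 1 - cdf, so that log-survival stays accurate deep
#' in the tail.
#'
#' @name baselines
NULL

# registry of baseline factories, keyed by name
.baseline_registry <- new.env(parent = emptyenv())

#' Register a baseline distribution factory
#'
#' @param name character key (e.g. `"exponential"`).
#' @param factory function(psi) returning a list with elements
#'   `psi` (named numeric), `support` (length-2 numeric), and functions
#'   `cdf(x)`, `pdf(x)`, `logsf(x)`, `logcdf(x)`, `logpdf(x)`, `quantile(p)`,
#'   `grad_cdf(x)` and `grad_pdf(x)` (each gradient an n x length(psi)
#'   matrix of derivatives with respect to the baseline parameters).
#' @return `name`, invisibly.
#' @export
register_baseline <- function(name, factory) {
  stopifnot(is.character(name), length(name) == 1L, is.function(factory))
  assign(name, factory, envir = .baseline_registry)
  invisible(name)
}

#' List registered baseline names
#' @return character vector of registered baseline names.
#' @export
baseline_names <- function() sort(ls(.baseline_registry))

#' Construct a baseline specification
#'
#' @param name one of [baseline_names()]; `"exponential"` (rate `gamma`),
#'   `"uniform"` (upper bound `gamma`, support (0, gamma)) or `"pareto"`
#'   (scale `theta`, shape `k`, support (theta, Inf)).
#' @param ... named positive parameters for the chosen baseline.
#' @return an object of class `"t2gwg_baseline"`.
#' @examples
#' b <- baseline("exponential", gamma = 1.3)
#' baseline_cdf(1, b)
#' @export
baseline <- function(name, ...) {
  name <- match.arg(name, baseline_names())
  psi <- c(...)
  if (length(psi) && (is.null(names(psi)) || any(!nzchar(names(psi)))))
    stop("baseline parameters must be named", call. = FALSE)
  factory <- get(name, envir = .baseline_registry)
  spec <- factory(psi)
  if (any(!is.finite(spec$psi)) || any(spec$psi <= 0))
    stop("all baseline parameters must be strictly positive and finite",
         call. = FALSE)
  spec$name <- name
  class(spec) <- "t2gwg_baseline"
  spec
}

#' @export
print.t2gwg_baseline <- function(x, ...) {
  cat("Baseline distribution: ", x$name, "\n", sep = "")
  cat("  parameters: ",
      paste(names(x$psi), signif(x$psi, 6), sep = " = ", collapse = ", "),
      "\n", sep = "")
  cat("  support: (", x$support[1], ", ", x$support[2], ")\n", sep = "")
  invisible(x)
}

#' Evaluate a baseline distribution
#'
#' `baseline_cdf`, `baseline_pdf`, `baseline_logsf` and `baseline_quantile`
#' evaluate H, h, log(1 - H) and the inverse of H.  `baseline_param_grad`
#' returns the derivatives of H and h with respect to the baseline
#' parameters, which every estimation gradient needs.
#'
#' @param x numeric vector of evaluation points.
#' @param p numeric vector of probabilities in (0, 1).
#' @param spec a [baseline()] object.
#' @return `baseline_cdf`: probabilities (0 below the support, 1 above);
#'   `baseline_pdf`: densities (0 off the support); `baseline_logsf`:
#'   log-survival values; `baseline_quantile`: quantiles;
#'   `baseline_param_grad`: a list with matrices `dH` and `dh`
#'   (rows = observations, columns = parameters).
#' @export
baseline_cdf <- function(x, spec) {
  stopifnot(inherits(spec, "t2gwg_baseline"))
  out <- numeric(length(x))
  lo <- x <= spec$support[1]
  hi <- x >= spec$support[2]
  mid <- !lo & !hi
  out[hi] <- 1
  if (any(mid)) out[mid] <- spec$cdf(x[mid])
  out
}

#' @rdname baseline_cdf
#' @export
baseline_pdf <- function(x, spec) {
  stopifnot(inherits(spec, "t2gwg_baseline"))
  out <- numeric(length(x))
  mid <- x > spec$support[1] & x < spec$support[2]
  if (any(mid)) out[mid] <- spec$pdf(x[mid])
  out
}

#' @rdname baseline_cdf
#' @export
baseline_logsf <- function(x, spec) {
  stopifnot(inherits(spec, "t2gwg_baseline"))
  out <- numeric(length(x))            # log(1) = 0 below support
  hi <- x >= spec$support[2]
  mid <- x > spec$support[1] & !hi
  out[hi] <- -Inf
  if (any(mid)) out[mid] <- spec$logsf(x[mid])
  out
}

#' @rdname baseline_cdf
#' @export
baseline_quantile <- function(p, spec) {
  stopifnot(inherits(spec, "t2gwg_baseline"))
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  spec$quantile(p)
}

#' @rdname baseline_cdf
#' @export
baseline_param_grad <- function(x, spec) {
  stopifnot(inherits(spec, "t2gwg_baseline"))
  np <- length(spec$psi)
  dH <- matrix(0, length(x), np, dimnames = list(NULL, names(spec$psi)))
  dh <- dH
  mid <- x > spec$support[1] & x < spec$support[2]
  if (any(mid)) {
    g <- spec$grad(x[mid])
    dH[mid, ] <- g$dH
    dh[mid, ] <- g$dh
  }
  list(dH = dH, dh = dh)
}

# --- built-in baselines ------------------------------------------------------

# Exponential, rate gamma: H = 1 - exp(-gamma x) on (0, Inf)
.baseline_exponential <- function(psi) {
  if (!setequal(names(psi), "gamma"))
    stop("exponential baseline takes a single parameter 'gamma'", call. = FALSE)
  g <- unname(psi[["gamma"]])
  list(
    psi = c(gamma = g),
    support = c(0, Inf),
    cdf = function(x) -expm1(-g * x),
    pdf = function(x) g * exp(-g * x),
    logsf = function(x) -g * x,
    logcdf = function(x) log(-expm1(-g * x)),
    logpdf = function(x) log(g) - g * x,
    quantile = function(p) -log1p(-p) / g,
    quantile_sf = function(s) -log(s) / g,
    grad = function(x) {
      e <- exp(-g * x)
      list(dH = cbind(gamma = x * e),
           dh = cbind(gamma = e * (1 - g * x)))
    })
}

# Uniform on (0, gamma): H = x/gamma; survival hits exactly 0 at x = gamma
.baseline_uniform <- function(psi) {
  if (!setequal(names(psi), "gamma"))
    stop("uniform baseline takes a single parameter 'gamma'", call. = FALSE)
  g <- unname(psi[["gamma"]])
  list(
    psi = c(gamma = g),
    support = c(0, g),
    cdf = function(x) x / g,
    pdf = function(x) rep_len(1 / g, length(x)),
    logsf = function(x) log(g - x) - log(g),
    logcdf = function(x) log(x) - log(g),
    logpdf = function(x) rep_len(-log(g), length(x)),
    quantile = function(p) g * p,
    quantile_sf = function(s) g * (1 - s),
    grad = function(x) {
      list(dH = cbind(gamma = -x / g^2),
           dh = cbind(gamma = rep_len(-1 / g^2, length(x))))
    })
}

# Pareto with scale theta, shape k: H = 1 - (theta/x)^k on (theta, Inf)
.baseline_pareto <- function(psi) {
  if (!setequal(names(psi), c("theta", "k")))
    stop("pareto baseline takes parameters 'theta' and 'k'", call. = FALSE)
  th <- unname(psi[["theta"]]); k <- unname(psi[["k"]])
  list(
    psi = c(theta = th, k = k),
    support = c(th, Inf),
    cdf = function(x) -expm1(k * (log(th) - log(x))),
    pdf = function(x) k * th^k / x^(k + 1),
    logsf = function(x) k * (log(th) - log(x)),
    logcdf = function(x) log(-expm1(k * (log(th) - log(x)))),
    logpdf = function(x) log(k) + k * log(th) - (k + 1) * log(x),
    quantile = function(p) th * (1 - p)^(-1 / k),
    quantile_sf = function(s) th * s^(-1 / k),
    grad = function(x) {
      s <- exp(k * (log(th) - log(x)))     # survival (theta/x)^k
      lr <- log(th) - log(x)
      list(dH = cbind(theta = -s * k / th, k = -s * lr),
           dh = cbind(theta = k^2 * th^(k - 1) / x^(k + 1),
                      k = (th^k / x^(k + 1)) * (1 + k * lr)))
    })
}

register_baseline("exponential", .baseline_exponential)
register_baseline("uniform", .baseline_uniform)
register_baseline("pareto", .baseline_pareto)
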