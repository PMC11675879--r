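# shared fixtures: models, random parameter draws, numerical helpers

unit_t2gwe <- function() t2gwe(1, 1, 1)

# deterministic set of random-but-reasonable parameter draws
draw_params <- function(n, seed = 421) {
  withr::with_seed(seed, replicate(n, c(
    alpha = exp(runif(1, -1, 1.2)),
    beta = exp(runif(1, -1, 1)),
    gamma = exp(runif(1, -1, 1))), simplify = FALSE))
}

all_baselines <- function() list(
  exponential = baseline("exponential", gamma = 1.3),
  uniform = baseline("uniform", gamma = 2),
  pareto = baseline("pareto", theta = 1, k = 2))

# interior grid of a baseline support (probability-side spacing)
support_grid <- function(spec, n = 1000, eps = 1e-6) {
  spec$quantile(seq(eps, 1 - eps, length.out = n))
}

central_diff <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
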