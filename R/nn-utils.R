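# Internal numerical helpers shared by the two networks: a local-seed guard,
# fan-in-scaled initialization, activations, and a plain Adam optimizer over
# named lists of parameter arrays.

# Evaluate `expr` under `seed` and restore the caller's RNG state afterwards,
# so every generator/trainer is a pure function of its arguments.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Uniform(-1/sqrt(fan_in), 1/sqrt(fan_in)) weight initialization.
init_uniform <- function(nrow, ncol = NULL, fan_in = nrow) {
  lim <- 1 / sqrt(fan_in)
  if (is.null(ncol)) stats::runif(nrow, -lim, lim)
  else matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

relu <- function(x) (x > 0) * x

# Numerically stable log(1 + exp(x)).
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam update over a named list of arrays; `grads` must mirror `params`.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Largest absolute eigenvalue of a square matrix.
spectral_radius <- function(A) {
  if (all(A == 0)) return(0)
  max(Mod(eigen(A, only.values = TRUE)$values))
}
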