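# Gated generative modules, swap samples, discriminator, losses, training.

toy_series <- function(v = 4, t = 60, seed = 1) {
  net <- sample_directed_graph(v, 0.4, seed = seed)
  suppressWarnings(simulate_nonlinear_var(
    net, simulation_config(v, t, noise_sd = 0.2, nonlinearity = "identity",
                           seed = seed)))
}

test_that("initialization pins the gate diagonal and is fully seeded", {
  cfg <- bcen_config(seed = 5)
  net <- init_bcen(6, cfg)
  expect_true(all(diag(net$gates$gates) == 0))
  for (i in 1:6) expect_identical(net$modules[[i]]$gate_column[i], 0)
  again <- init_bcen(6, cfg)
  expect_identical(net, again)  # bitwise determinism
  expect_false(identical(net$gates, init_bcen(6, bcen_config(seed = 6))$gates))
  expect_error(init_bcen(1, cfg), class = "bcenet_invalid_argument")

  big <- init_bcen(116, cfg)
  free <- sum(row(big$gates$gates) != col(big$gates$gates))
  expect_identical(free, 116L * 115L)
  expect_true(all(big$gates$gates[row(big$gates$gates) !=
                                    col(big$gates$gates)] != 0))
})

test_that("a zero gate column annihilates the input", {
  net <- init_bcen(4, bcen_config(seed = 2))
  m <- net$modules[[2]]
  m$gate_column <- rep(0, 4)
  X <- toy_series(4, 30, seed = 2)
  xhat <- predict_region(m, X, lag = 1)
  expect_identical(xhat[1], unname(X$values[1, 2]))  # copied prefix
  expect_equal(diff(xhat[-1]), rep(0, 28))       # constant: only biases remain
})

test_that("prediction equals the closed-form tanh composition on a toy", {
  # 2 regions, 3 time points, hidden width 2, hand-set weights, lag = 0
  m <- bcenet:::new_generator_module(
    region_index = 1,
    gate_column = c(0, 0.5),
    W1 = matrix(c(1, -1, 2, 0.5), 2, 2),
    b1 = c(0.1, -0.2),
    w2 = c(1.5, -0.5),
    b2 = 0.25)
  X <- matrix(c(0.3, -0.1, 0.7, 0.4, 0.2, -0.6), 3, 2)
  got <- predict_region(m, roi_timeseries(X), lag = 0)
  for (tau in 1:3) {
    u <- c(0, 0.5) * X[tau, ]
    h <- tanh(c(u %*% matrix(c(1, -1, 2, 0.5), 2, 2)) + c(0.1, -0.2))
    expect_equal(got[tau], sum(h * c(1.5, -0.5)) + 0.25, tolerance = 1e-12)
  }
  # lagged variant shifts the input row back by one
  got_lag <- predict_region(m, roi_timeseries(X), lag = 1)
  expect_identical(got_lag[1], X[1, 1])
  expect_equal(got_lag[2:3], got[1:2], tolerance = 1e-12)
})

test_that("swap samples replace exactly one column", {
  X <- toy_series(4, 25, seed = 3)
  same <- assemble_swap_sample(X, X$values[, 2], 2)
  expect_identical(same$values, X$values)

  xhat <- rnorm(25)
  sw <- assemble_swap_sample(X, xhat, 3)
  expect_identical(sw$values[, 3], xhat)
  expect_identical(sw$values[, -3], X$values[, -3])
  expect_error(assemble_swap_sample(X, xhat, 9),
               class = "bcenet_invalid_argument")
  expect_error(assemble_swap_sample(X, xhat[-1], 2),
               class = "bcenet_invalid_argument")

  # one-to-one substitution yields v distinct samples
  net <- init_bcen(4, bcen_config(seed = 4))
  swaps <- lapply(1:4, function(i)
    assemble_swap_sample(X, predict_region(net$modules[[i]], X, 1), i)$values)
  for (a in 1:3) for (b in (a + 1):4)
    expect_false(identical(swaps[[a]], swaps[[b]]))
})

test_that("the KL estimate is zero for a silent discriminator", {
  net <- init_bcen(3, bcen_config(seed = 1))
  disc <- net$discriminator
  disc$w3 <- rep(0, length(disc$w3)); disc$b3 <- 0
  real <- matrix(rnorm(300), 100, 3)
  expect_identical(estimate_kl(disc, real, real + 1), 0)
  expect_error(estimate_kl(disc, real, matrix(0, 10, 2)),
               class = "bcenet_invalid_argument")
  expect_error(estimate_kl(disc, real[0, ], real),
               class = "bcenet_invalid_argument")
})

test_that("the trained KL estimate grows with the distribution shift", {
  set.seed(8)
  real <- matrix(rnorm(3000 * 2), 3000, 2)
  kl_at_shift <- function(delta) {
    disc <- init_bcen(2, bcen_config(seed = 3))$discriminator
    synth <- real + delta
    st <- NULL
    for (step in 1:150) {
      upd <- discriminator_step(disc, real, list(synth), st,
                                learning_rate = 0.01)
      disc <- upd$discriminator; st <- upd$opt_state
    }
    estimate_kl(disc, real, synth)
  }
  k_small <- kl_at_shift(0.5)
  k_large <- kl_at_shift(2)
  expect_gt(k_large, k_small)
  expect_gt(k_small, 0)
  # closed-form Gaussian KL for a mean shift: delta^2 * d / 2
  expect_lt(abs(k_small - 0.25), 0.2)
})

test_that("generator loss reduces to the squared reconstruction error", {
  X <- toy_series(3, 40, seed = 5)
  net <- init_bcen(3, bcen_config(seed = 5))
  cfg0 <- bcen_config(sparsity_weight = 0, adversarial_weight = 0, seed = 5)
  got <- generator_loss(X, net$modules, net$gates, net$discriminator, cfg0)
  xhats <- vapply(1:3, function(i)
    predict_region(net$modules[[i]], X, lag = 1), numeric(40))
  expect_equal(got$total, sum((xhats - X$values)^2), tolerance = 1e-12)
  expect_identical(got$components$sparsity, 0)
})

test_that("generator loss equals the hand-computed three-term sum", {
  X <- toy_series(3, 20, seed = 6)
  net <- init_bcen(3, bcen_config(seed = 6))
  cfg <- bcen_config(sparsity_weight = 0.3, adversarial_weight = 2, seed = 6)
  got <- generator_loss(X, net$modules, net$gates, net$discriminator, cfg)
  xhats <- vapply(1:3, function(i)
    predict_region(net$modules[[i]], X, lag = 1), numeric(20))
  recon <- sum((xhats - X$values)^2)
  spars <- 0.3 * sum(abs(net$gates$gates)) / 3
  kl <- sum(vapply(1:3, function(i)
    estimate_kl(net$discriminator, X$values,
                assemble_swap_sample(X, xhats[, i], i)$values), numeric(1)))
  expect_equal(got$total, recon + spars + 2 * kl, tolerance = 1e-10)
  expect_equal(got$components$reconstruction, recon)
  expect_equal(got$components$kl, kl)
})

test_that("discriminator training behaves like a logistic classifier", {
  set.seed(10)
  net <- init_bcen(2, bcen_config(seed = 2))
  disc <- net$discriminator
  real <- matrix(rnorm(400), 200, 2)
  # identical distributions: loss stays near log 2 and is non-negative
  st <- NULL
  for (step in 1:50) {
    upd <- discriminator_step(disc, real, list(real), st, 0.005)
    disc <- upd$discriminator; st <- upd$opt_state
    expect_gte(upd$loss, 0)
  }
  expect_lt(abs(upd$loss - log(2)), 0.05 * log(2))

  # linearly separable classes: loss is driven toward zero
  disc2 <- init_bcen(2, bcen_config(seed = 2))$discriminator
  synth <- real + 8
  st2 <- NULL
  for (step in 1:400) {
    upd2 <- discriminator_step(disc2, real, list(synth), st2, 0.01)
    disc2 <- upd2$discriminator; st2 <- upd2$opt_state
  }
  expect_lt(upd2$loss, 0.05)
  expect_error(discriminator_step(disc2, real, list()),
               class = "bcenet_invalid_argument")
})

test_that("training produces the declared trace and conserves the mask", {
  X <- toy_series(4, 50, seed = 7)
  cfg <- bcen_config(generator_epochs = 30, discriminator_epochs = 10,
                     seed = 7)
  fit <- train_bcen(X, cfg)
  expect_identical(nrow(fit$trace), 30L)
  expect_identical(sum(!is.na(fit$trace$d_loss)), 10L)
  expect_true(all(diag(fit$gates$gates) == 0))
  expect_true(all(is.finite(fit$trace$g_loss)))

  # seeded determinism of the whole procedure
  fit2 <- train_bcen(X, cfg)
  expect_identical(fit$gates, fit2$gates)

  bad <- X$values; bad[3, 2] <- Inf
  expect_error(train_bcen(bad, cfg), class = "bcenet_invalid_argument")
})

test_that("reconstruction error decreases over training", {
  for (seed in 1:3) {
    X <- toy_series(4, 80, seed = seed)
    fit <- train_bcen(X, bcen_config(generator_epochs = 120,
                                     discriminator_epochs = 40, seed = seed))
    expect_lt(tail(fit$trace$recon, 1), fit$trace$recon[1])
  }
})

test_that("connectome extraction maps gates by mode", {
  X <- toy_series(3, 40, seed = 9)
  fit <- train_bcen(X, bcen_config(generator_epochs = 10,
                                   discriminator_epochs = 5, seed = 9))
  signed <- extract_connectome(fit, "signed")
  absolute <- extract_connectome(fit)
  expect_identical(signed$weights, fit$gates$gates)
  expect_identical(absolute$weights, abs(fit$gates$gates))
  expect_true(all(absolute$weights >= 0))
  expect_true(all(diag(absolute$weights) == 0))
  expect_identical(absolute$method_tag, "bcen")
})
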