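# Graph convolution, TopK pooling, readouts and the full classifier.

dense_normalize_oracle <- function(A) {
  At <- (abs(A) + t(abs(A))) / 2 + diag(nrow(A))
  D <- diag(1 / sqrt(rowSums(At)))
  D %*% At %*% D
}

test_that("adjacency normalization matches hand-computed cases", {
  expect_equal(normalize_adjacency(matrix(0, 3, 3)), diag(3))

  A <- matrix(c(0, 1, 1, 0), 2, 2)  # single undirected unit edge
  got <- normalize_adjacency(A)
  expect_equal(got, matrix(0.5, 2, 2))

  set.seed(2)
  for (trial in 1:20) {
    v <- sample(2:10, 1)
    A <- matrix(rnorm(v * v), v, v)
    got <- normalize_adjacency(A)
    expect_equal(got, dense_normalize_oracle(A), tolerance = 1e-12)
    expect_equal(got, t(got))
  }
  expect_error(normalize_adjacency(matrix(c(0, NA, 1, 0), 2, 2)),
               class = "bcenet_invalid_argument")
})

test_that("graph convolution equals the brute-force dense product", {
  set.seed(4)
  for (trial in 1:20) {
    v <- sample(2:10, 1); d <- sample(2:6, 1); dout <- sample(2:6, 1)
    A <- matrix(rnorm(v * v), v, v)
    N <- matrix(rnorm(v * d), v, d)
    W <- matrix(rnorm(d * dout), d, dout)
    st <- layer_state(A, N)
    got <- gcn_layer(st, W)
    oracle <- pmax(dense_normalize_oracle(A) %*% N %*% W, 0)
    expect_equal(got, oracle, tolerance = 1e-6)
  }
  # isolated node with identity weights passes features through
  st1 <- layer_state(matrix(0, 1, 1), matrix(c(2, -3), 1, 2))
  expect_equal(gcn_layer(st1, diag(2), activation = identity),
               matrix(c(2, -3), 1, 2))
  expect_error(gcn_layer(layer_state(matrix(0, 2, 2), matrix(0, 2, 3)),
                         matrix(0, 2, 2)),
               class = "bcenet_invalid_argument")
})

test_that("node scores are normalized projections", {
  N <- matrix(c(1, 0, 0, 0, 1, 0), 3, 2)
  expect_equal(node_scores(N, c(1, 0)), N[, 1])      # unit-basis projection
  expect_equal(node_scores(N, c(5, 0)), N[, 1])      # scale invariance
  set.seed(6)
  N <- matrix(rnorm(15), 5, 3)
  p <- rnorm(3)
  expect_equal(node_scores(N, p), drop(N %*% p) / sqrt(sum(p^2)),
               tolerance = 1e-9)
  expect_error(node_scores(N, c(0, 0, 0)), class = "bcenet_invalid_argument")
})

topk_oracle_idx <- function(scores, k) {
  # full sort with explicit lowest-index tie-break
  ord <- order(scores, -seq_along(scores), decreasing = TRUE)
  sort(ord[seq_len(k)])
}

test_that("topk pooling matches the full-sort oracle incl. exhaustive ties", {
  st0 <- function(v) layer_state(matrix(1, v, v) - diag(v),
                                 matrix(seq_len(v * 2), v, 2))
  st <- st0(3)
  pooled <- topk_pool(st, c(0.9, 0.1, 0.5), keep = 2)
  expect_identical(pooled$retained, c(1L, 3L))

  tied <- topk_pool(st0(4), rep(0.3, 4), keep = 2)
  expect_identical(tied$retained, c(1L, 2L))

  # every score configuration from a small value alphabet, v <= 8
  set.seed(9)
  vals <- c(-1, 0, 0, 0.5, 0.5, 1, 2, 2)
  for (trial in 1:50) {
    v <- sample(2:8, 1)
    scores <- sample(vals, v, replace = TRUE)
    k <- sample(v, 1)
    pooled <- topk_pool(st0(v), scores, keep = k)
    expect_identical(pooled$retained, topk_oracle_idx(scores, k))
    expect_equal(pooled$features,
                 st0(v)$features[pooled$retained, , drop = FALSE] *
                   tanh(scores[pooled$retained]),
                 ignore_attr = TRUE)
    expect_equal(pooled$adjacency,
                 st0(v)$adjacency[pooled$retained, pooled$retained,
                                  drop = FALSE])
  }

  # ratio resolution and clamping
  byratio <- topk_pool(st0(5), 1:5, keep = 0.5)
  expect_identical(length(byratio$retained), 3L)  # ceiling(0.5 * 5)
  expect_warning(clamped <- topk_pool(st0(3), 1:3, keep = 10), "clamping")
  expect_identical(clamped$retained, 1:3)
  expect_error(topk_pool(st0(3), 1:3, keep = 0),
               class = "bcenet_invalid_argument")
})

test_that("readout is a per-column absolute sum", {
  expect_equal(readout(matrix(c(1, 3, -2, 0), 2, 2)), c(4, 2))
  expect_equal(readout(matrix(0, 3, 4)), rep(0, 4))
  N <- matrix(rnorm(12), 3, 4)
  expect_equal(readout(rbind(N, N)), 2 * readout(N))
  expect_error(readout(matrix(numeric(0), 0, 2)),
               class = "bcenet_invalid_argument")
})

test_that("forward pass yields proper probabilities of the declared width", {
  set.seed(11)
  cfg <- hrgnn_config(conv_widths = c(8, 8, 8), pool_keep = 0.6,
                      mlp_widths = c(16, 8), epochs = 1, seed = 2)
  ds <- small_group_dataset(2, v = 9, seed = 3)
  fit <- train_hrgnn(ds, cfg)
  p <- hrgnn_forward(ds[[1]], fit$params, cfg)
  expect_length(p, 2L)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  # Gr length = sum of conv widths feeds the MLP input
  expect_identical(nrow(fit$params$M[[1]]), 24L)
})

test_that("the forward pass is invariant to node permutation", {
  set.seed(13)
  cfg <- hrgnn_config(conv_widths = c(6, 6, 6), pool_keep = 0.5,
                      mlp_widths = c(8, 4), epochs = 2, seed = 5)
  ds <- small_group_dataset(2, v = 8, seed = 5)
  fit <- train_hrgnn(ds, cfg)
  g <- ds[[3]]
  for (trial in 1:5) {
    perm <- sample(g$v)
    gp <- brain_graph(g$adjacency[perm, perm],
                      g$node_features[perm, , drop = FALSE],
                      label = g$label)
    p1 <- hrgnn_forward(g, fit$params, cfg)
    p2 <- hrgnn_forward(gp, fit$params, cfg)
    expect_equal(p1, p2, tolerance = 1e-5)
  }
})

test_that("node counts are non-increasing across pooling stages", {
  cfg <- hrgnn_config(conv_widths = c(4, 4, 4), pool_keep = 0.5,
                      mlp_widths = c(8, 4), epochs = 1, seed = 1)
  ds <- small_group_dataset(1, v = 10, seed = 7)
  fit <- train_hrgnn(ds, cfg)
  fc <- bcenet:::hrgnn_forward_cache(ds[[1]]$adjacency,
                                     ds[[1]]$node_features,
                                     fit$params, cfg)
  sizes <- vapply(fc$layers, function(l) length(l$idx), integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(vapply(seq_along(fc$layers), function(k)
    all(fc$layers[[k]]$retained %in%
          if (k == 1) 1:10 else fc$layers[[k - 1]]$retained), logical(1))))
})

test_that("training reduces the loss, is seeded, and records every epoch", {
  ds <- small_group_dataset(6, v = 10, seed = 4)
  cfg <- hrgnn_config(conv_widths = c(8, 8, 8), pool_keep = 6,
                      mlp_widths = c(16, 8), epochs = 40, seed = 3)
  for (seed in 1:3) {
    cfg$seed <- seed
    fit <- train_hrgnn(ds, cfg)
    expect_length(fit$loss_trace, 40L)
    expect_lt(fit$loss_trace[40], fit$loss_trace[1])
  }
  fit_a <- train_hrgnn(ds, cfg)
  fit_b <- train_hrgnn(ds, cfg)
  expect_identical(fit_a$params, fit_b$params)

  single <- lapply(ds[1:4], function(g) { g$label <- 1L; g })
  expect_error(train_hrgnn(single, cfg), class = "bcenet_invalid_argument")
})

test_that("pool-keep sweep shares one fold split across keep values", {
  ds <- small_group_dataset(10, v = 8, seed = 6)
  cfg <- hrgnn_config(conv_widths = c(6, 6, 6), mlp_widths = c(8, 4),
                      epochs = 5, seed = 2)
  tab <- sweep_pool_keep(ds, cfg, keep_values = c(4, 8), k = 5)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$keep, c(4, 8))
  expect_true(all(tab$acc >= 0 & tab$acc <= 100))
  expect_length(attr(tab, "folds"), length(ds))

  one <- sweep_pool_keep(ds, cfg, keep_values = 6, k = 5)
  expect_identical(nrow(one), 1L)
  expect_error(sweep_pool_keep(ds, cfg, numeric(0)),
               class = "bcenet_invalid_argument")
})
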