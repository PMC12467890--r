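# Hierarchical-representation graph classifier: three graph-convolution
# layers interleaved with three TopK pooling layers; each pooling stage emits
# a fixed-length L1 readout, the three readouts are concatenated and fed to a
# two-layer MLP with a softmax head, trained with cross-entropy.
#
# The forward and backward passes are explicit matrix algebra. Gradients do
# not flow through the discrete node selection (standard TopK behaviour);
# they do flow through the tanh(score) gating, which is what trains the
# projection vectors.

#' Layer state of the hierarchical graph network
#'
#' Bundles the current (sub)graph adjacency, the current node features, and
#' the retained node indices relative to the original graph.
#'
#' @param adjacency Current `v_k x v_k` raw adjacency.
#' @param features Current `v_k x d` node-feature matrix.
#' @param retained Integer indices of the surviving nodes in the original
#'   graph (defaults to all nodes).
#' @param k Layer index (1-based).
#' @return A `layer_state` list.
#' @export
layer_state <- function(adjacency, features, retained = seq_len(nrow(adjacency)),
                        k = 1L) {
  adjacency <- as.matrix(adjacency)
  features <- as.matrix(features)
  if (nrow(adjacency) != ncol(adjacency) || nrow(features) != nrow(adjacency))
    stop_invalid("adjacency must be square and match the feature rows")
  structure(list(adjacency = adjacency, features = features,
                 retained = as.integer(retained), k = as.integer(k)),
            class = "layer_state")
}

#' Symmetric degree normalization of an adjacency matrix
#'
#' Computes `D^{-1/2} %*% Atilde %*% D^{-1/2}` where
#' `Atilde = (|A| + |A|^T) / 2 + I` (symmetrized absolute weights plus
#' self-loops) and `D` is `Atilde`'s row-sum diagonal. Directed or signed
#' input is therefore admissible; the self-loop guarantees every degree is
#' at least 1, so no division by zero can occur.
#'
#' @param A Numeric `v x v` matrix.
#' @return A symmetric `v x v` matrix.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (!all(is.finite(A))) stop_invalid("adjacency must be finite")
  if (nrow(A) != ncol(A)) stop_invalid("adjacency must be square")
  At <- (abs(A) + t(abs(A))) / 2
  diag(At) <- diag(At) + 1
  d <- 1 / sqrt(rowSums(At))
  At * outer(d, d)
}

#' One graph-convolution layer
#'
#' Computes `N' = activation(normalize_adjacency(G_k) %*% N_k %*% W_k)`.
#'
#' @param state A [layer_state].
#' @param W_k Numeric `d x d'` weight matrix.
#' @param activation Elementwise activation function (default ReLU).
#' @return The `v_k x d'` output feature matrix.
#' @export
gcn_layer <- function(state, W_k, activation = relu) {
  if (!inherits(state, "layer_state")) stop_invalid("`state` must be a layer_state")
  W_k <- as.matrix(W_k)
  if (ncol(state$features) != nrow(W_k))
    stop_invalid("W_k has ", nrow(W_k), " input dims but features have ",
                 ncol(state$features))
  activation(normalize_adjacency(state$adjacency) %*% state$features %*% W_k)
}

#' Node-importance scores for TopK pooling
#'
#' Projects each node's feature row onto a learnable direction:
#' `score_j = <N_j, p> / ||p||_2`. Scores are invariant to the scale of the
#' projection vector.
#'
#' @param N_k Numeric `v x d` feature matrix.
#' @param projection Non-zero numeric `d`-vector.
#' @return A numeric `v`-vector of scores.
#' @export
node_scores <- function(N_k, projection) {
  N_k <- as.matrix(N_k)
  if (length(projection) != ncol(N_k))
    stop_invalid("projection length must equal the feature dimension")
  nrm <- sqrt(sum(projection^2))
  if (nrm == 0) stop_invalid("projection vector must be non-zero")
  drop(N_k %*% (projection / nrm))
}

resolve_keep <- function(keep, v_current, warn = TRUE) {
  if (length(keep) != 1L || !is.finite(keep) || keep <= 0)
    stop_invalid("`keep` must be a positive count or a ratio in (0, 1)")
  k <- if (keep < 1) max(1L, as.integer(ceiling(keep * v_current)))
       else as.integer(keep)
  if (k > v_current) {
    if (warn)
      warning("pool size ", k, " exceeds the current ", v_current,
              " nodes; clamping", call. = FALSE)
    k <- v_current
  }
  k
}

#' TopK graph pooling
#'
#' Keeps the `keep` highest-scoring nodes (ties broken in favour of the
#' lower original index), restricts the adjacency to the selected
#' rows-and-columns submatrix, multiplies the surviving feature rows by
#' `tanh(score)` (so the projection vector receives gradient), and updates
#' the retained-index bookkeeping. A ratio `r` in (0, 1) resolves to
#' `max(1, ceiling(r * v))`; an absolute count larger than the current node
#' count is clamped with a warning.
#'
#' @param state A [layer_state].
#' @param scores Numeric score vector, one per current node.
#' @param keep Node count (>= 1) or ratio in (0, 1).
#' @return The pooled [layer_state] with `k` incremented.
#' @export
topk_pool <- function(state, scores, keep) {
  if (!inherits(state, "layer_state")) stop_invalid("`state` must be a layer_state")
  v_cur <- nrow(state$adjacency)
  if (length(scores) != v_cur)
    stop_invalid("need one score per current node")
  k <- resolve_keep(keep, v_cur)
  idx <- sort(order(-scores, seq_along(scores))[seq_len(k)])
  layer_state(
    adjacency = state$adjacency[idx, idx, drop = FALSE],
    features = state$features[idx, , drop = FALSE] * tanh(scores[idx]),
    retained = state$retained[idx],
    k = state$k + 1L
  )
}

#' Fixed-length L1 readout of a feature matrix
#'
#' Aggregates a node-feature matrix into a `d`-vector of per-feature-column
#' absolute sums, a permutation-invariant representation whose length does
#' not depend on how many nodes survived pooling.
#'
#' @param N_k Numeric `v x d` feature matrix with at least one row.
#' @return A numeric `d`-vector.
#' @export
readout <- function(N_k) {
  N_k <- as.matrix(N_k)
  if (nrow(N_k) == 0L) stop_invalid("readout needs at least one node")
  colSums(abs(N_k))
}

init_hrgnn_params <- function(d_in, n_classes, cfg) {
  with_local_seed(cfg$seed, {
    widths <- cfg$conv_widths
    W <- list(); p <- list()
    d <- d_in
    for (k in seq_len(cfg$n_layers)) {
      W[[k]] <- init_uniform(d, widths[k])
      p[[k]] <- init_uniform(widths[k], fan_in = widths[k])
      d <- widths[k]
    }
    gr_len <- sum(widths)
    m_in <- gr_len
    M <- list(); mb <- list()
    for (j in seq_along(cfg$mlp_widths)) {
      M[[j]] <- init_uniform(m_in, cfg$mlp_widths[j])
      mb[[j]] <- init_uniform(cfg$mlp_widths[j], fan_in = m_in)
      m_in <- cfg$mlp_widths[j]
    }
    Wo <- init_uniform(m_in, n_classes)
    bo <- init_uniform(n_classes, fan_in = m_in)
    list(W = W, p = p, M = M, mb = mb, Wo = Wo, bo = bo,
         d_in = d_in, n_classes = n_classes)
  })
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Full forward pass with caches for backprop. `Ahat1` optionally supplies
# the (input-fixed) normalized adjacency of layer 1; when pooling keeps all
# nodes the previous layer's normalization is reused unchanged.
hrgnn_forward_cache <- function(adjacency, features, params, cfg,
                                Ahat1 = NULL) {
  n_layers <- cfg$n_layers
  layers <- vector("list", n_layers)
  st <- layer_state(adjacency, features)
  readouts <- vector("list", n_layers)
  Ahat_prev <- NULL
  kept_all <- FALSE
  for (k in seq_len(n_layers)) {
    Ahat <- if (k == 1L && !is.null(Ahat1)) Ahat1
            else if (kept_all) Ahat_prev
            else normalize_adjacency(st$adjacency)
    AN <- Ahat %*% st$features
    Z <- AN %*% params$W[[k]]
    H <- relu(Z)
    s <- node_scores(H, params$p[[k]])
    kk <- resolve_keep(cfg$pool_keep, nrow(H), warn = FALSE)
    idx <- sort(order(-s, seq_along(s))[seq_len(kk)])
    gate <- tanh(s[idx])
    P <- H[idx, , drop = FALSE] * gate
    layers[[k]] <- list(Ahat = Ahat, AN = AN, Z = Z, H = H, s = s,
                        idx = idx, gate = gate, P = P,
                        n_in = nrow(H), retained = st$retained[idx])
    readouts[[k]] <- colSums(abs(P))
    kept_all <- length(idx) == nrow(H)
    Ahat_prev <- Ahat
    st <- layer_state(st$adjacency[idx, idx, drop = FALSE], P,
                      retained = st$retained[idx], k = k + 1L)
  }
  Gr <- unlist(readouts)
  a <- Gr
  mlp <- vector("list", length(params$M))
  for (j in seq_along(params$M)) {
    zj <- drop(a %*% params$M[[j]]) + params$mb[[j]]
    hj <- relu(zj)
    mlp[[j]] <- list(input = a, z = zj, h = hj)
    a <- hj
  }
  logits <- drop(a %*% params$Wo) + params$bo
  probs <- softmax(logits)
  list(layers = layers, readouts = readouts, Gr = Gr, mlp = mlp,
       logits = logits, probs = probs)
}

#' Forward pass of the hierarchical graph classifier
#'
#' Runs three (by default) convolution + pooling stages, concatenates the
#' per-stage L1 readouts into the graph representation `Gr = r1 || r2 || r3`,
#' and maps it through the MLP and softmax head.
#'
#' @param g A [brain_graph].
#' @param params Parameters from [train_hrgnn] (element `params`) or
#'   an initializer.
#' @param cfg The [hrgnn_config] used to build `params`.
#' @return A named vector of class probabilities summing to 1.
#' @export
hrgnn_forward <- function(g, params, cfg) {
  if (!inherits(g, "brain_graph")) stop_invalid("`g` must be a brain_graph")
  if (g$v < 1L) stop_invalid("graph must have at least one node")
  if (ncol(g$node_features) != params$d_in)
    stop_invalid("graph features have ", ncol(g$node_features),
                 " dims but the model expects ", params$d_in)
  fc <- hrgnn_forward_cache(g$adjacency, g$node_features, params, cfg)
  probs <- fc$probs
  names(probs) <- attr(params, "class_levels") %||% as.character(seq_along(probs) - 1L)
  probs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Backward pass for one graph; returns gradients mirroring `params` plus the
# cross-entropy loss.
hrgnn_backward <- function(fc, y_index, params, cfg) {
  n_layers <- cfg$n_layers
  loss <- -log(max(fc$probs[y_index], 1e-12))
  dlogits <- fc$probs
  dlogits[y_index] <- dlogits[y_index] - 1

  last_h <- if (length(fc$mlp)) fc$mlp[[length(fc$mlp)]]$h else fc$Gr
  gWo <- outer(last_h, dlogits)
  gbo <- dlogits
  da <- drop(params$Wo %*% dlogits)
  gM <- vector("list", length(params$M))
  gmb <- vector("list", length(params$M))
  for (j in rev(seq_along(params$M))) {
    cache <- fc$mlp[[j]]
    dz <- da * (cache$z > 0)
    gM[[j]] <- outer(cache$input, dz)
    gmb[[j]] <- dz
    da <- drop(params$M[[j]] %*% dz)
  }
  dGr <- da

  widths <- cfg$conv_widths
  offs <- c(0L, cumsum(widths))
  gW <- vector("list", n_layers)
  gp <- vector("list", n_layers)
  dN_next <- NULL  # gradient wrt the pooled features feeding layer k+1
  for (k in rev(seq_len(n_layers))) {
    ly <- fc$layers[[k]]
    dr <- dGr[(offs[k] + 1L):offs[k + 1L]]
    # readout: d colSums(|P|) / dP = sign(P)
    dP <- sign(ly$P) * rep(dr, each = nrow(ly$P))
    if (!is.null(dN_next)) dP <- dP + dN_next
    Hsel <- ly$H[ly$idx, , drop = FALSE]
    dHsel <- dP * ly$gate
    dgate <- rowSums(dP * Hsel)
    ds_sel <- dgate * (1 - ly$gate^2)
    u <- params$p[[k]] / sqrt(sum(params$p[[k]]^2))
    dH <- matrix(0, ly$n_in, ncol(ly$H))
    dH[ly$idx, ] <- dHsel + outer(ds_sel, u)
    du <- drop(crossprod(Hsel, ds_sel))
    nrm <- sqrt(sum(params$p[[k]]^2))
    gp[[k]] <- (du - u * sum(u * du)) / nrm
    dZ <- dH * (ly$Z > 0)
    gW[[k]] <- crossprod(ly$AN, dZ)
    dN <- ly$Ahat %*% (dZ %*% t(params$W[[k]]))  # Ahat is symmetric
    dN_next <- dN
  }
  list(loss = loss, grads = list(W = gW, p = gp, M = gM, mb = gmb,
                                 Wo = gWo, bo = gbo))
}

flatten_hrgnn <- function(x) {
  out <- list()
  for (k in seq_along(x$W)) out[[paste0("W", k)]] <- x$W[[k]]
  for (k in seq_along(x$p)) out[[paste0("p", k)]] <- x$p[[k]]
  for (j in seq_along(x$M)) { out[[paste0("M", j)]] <- x$M[[j]]
                              out[[paste0("mb", j)]] <- x$mb[[j]] }
  out$Wo <- x$Wo; out$bo <- x$bo
  out
}

unflatten_hrgnn <- function(flat, params) {
  for (k in seq_along(params$W)) params$W[[k]] <- flat[[paste0("W", k)]]
  for (k in seq_along(params$p)) params$p[[k]] <- flat[[paste0("p", k)]]
  for (j in seq_along(params$M)) { params$M[[j]] <- flat[[paste0("M", j)]]
                                   params$mb[[j]] <- flat[[paste0("mb", j)]] }
  params$Wo <- flat$Wo; params$bo <- flat$bo
  params
}

#' Train the hierarchical graph classifier
#'
#' Full-batch Adam training of the convolution weights, pooling projections
#' and MLP head under the mean cross-entropy loss, for `cfg$epochs` epochs.
#' Reproducible under `cfg$seed`.
#'
#' @param dataset Non-empty list of labeled [brain_graph] objects with at
#'   least two classes.
#' @param cfg An [hrgnn_config].
#' @return An `hrgnn_fit` list: `params`, `loss_trace` (one mean
#'   cross-entropy value per epoch), `class_levels`, `config`.
#' @export
train_hrgnn <- function(dataset, cfg = hrgnn_config()) {
  labels <- dataset_labels(dataset)
  class_levels <- sort(unique(labels))
  if (length(class_levels) < 2L)
    stop_invalid("training needs at least two classes, found ",
                 length(class_levels))
  y <- match(labels, class_levels)
  d_in <- ncol(dataset[[1]]$node_features)
  vmin <- min(vapply(dataset, function(g) g$v, integer(1)))
  if (cfg$pool_keep >= 1 && cfg$pool_keep > vmin)
    warning("pool_keep ", cfg$pool_keep, " exceeds the smallest graph (",
            vmin, " nodes) and will be clamped", call. = FALSE)
  params <- init_hrgnn_params(d_in, length(class_levels), cfg)
  attr(params, "class_levels") <- as.character(class_levels)
  flat <- flatten_hrgnn(params)
  state <- adam_init(flat)
  n <- length(dataset)
  loss_trace <- numeric(cfg$epochs)

  Ahat1 <- lapply(dataset, function(g) normalize_adjacency(g$adjacency))
  for (epoch in seq_len(cfg$epochs)) {
    total <- 0
    acc <- lapply(flat, function(x) x * 0)
    for (s in seq_len(n)) {
      g <- dataset[[s]]
      fc <- hrgnn_forward_cache(g$adjacency, g$node_features, params, cfg,
                                Ahat1 = Ahat1[[s]])
      bw <- hrgnn_backward(fc, y[s], params, cfg)
      total <- total + bw$loss
      gf <- flatten_hrgnn(bw$grads)
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + gf[[nm]]
    }
    for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / n
    upd <- adam_step(flat, acc, state, lr = cfg$learning_rate)
    flat <- upd$params
    state <- upd$state
    params <- unflatten_hrgnn(flat, params)
    loss_trace[epoch] <- total / n
    if (cfg$verbose && epoch %% 100L == 0L)
      message(sprintf("epoch %d: mean cross-entropy %.5f", epoch,
                      loss_trace[epoch]))
  }
  structure(list(params = params, loss_trace = loss_trace,
                 class_levels = class_levels, config = cfg),
            class = "hrgnn_fit")
}

#' @export
print.hrgnn_fit <- function(x, ...) {
  cat("<hrgnn_fit> ", length(x$class_levels), " classes, ",
      length(x$loss_trace), " epochs, final loss ",
      signif(x$loss_trace[length(x$loss_trace)], 5), "\n", sep = "")
  invisible(x)
}

#' Predict classes for brain graphs
#'
#' @param object An `hrgnn_fit`.
#' @param graphs A list of [brain_graph] objects (or a single graph).
#' @param type `"class"` (default) for predicted labels, `"prob"` for the
#'   probability matrix.
#' @param ... Unused.
#' @return A vector of predicted labels or a probability matrix.
#' @export
predict.hrgnn_fit <- function(object, graphs, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(graphs, "brain_graph")) graphs <- list(graphs)
  probs <- t(vapply(graphs, function(g)
    hrgnn_forward(g, object$params, object$config),
    numeric(length(object$class_levels))))
  colnames(probs) <- as.character(object$class_levels)
  if (type == "prob") return(probs)
  object$class_levels[max.col(probs, ties.method = "first")]
}

#' Ablation sweep of the pooling parameter
#'
#' Runs stratified 10-fold cross-validation of the classifier once per value
#' of the pooling parameter, with a single fold split shared across all
#' values, and tabulates the pooled classification metrics.
#'
#' @param dataset Labeled list of [brain_graph] objects.
#' @param cfg Base [hrgnn_config]; its `pool_keep` is overridden per row.
#' @param keep_values Non-empty vector of pooling parameters to try.
#' @param k Number of folds (default 10).
#' @param seed Seed for the shared fold split (default `cfg$seed`).
#' @return A data frame with columns `keep`, `acc`, `sen`, `spe`, `f1`
#'   (percent), one row per keep value, plus attribute `folds`.
#' @export
sweep_pool_keep <- function(dataset, cfg, keep_values, k = 10L,
                            seed = cfg$seed) {
  if (length(keep_values) == 0L) stop_invalid("`keep_values` must be non-empty")
  labels <- dataset_labels(dataset)
  folds <- make_stratified_folds(labels, k, seed)
  rows <- lapply(keep_values, function(kv) {
    cfg_kv <- cfg
    cfg_kv$pool_keep <- as.numeric(kv)
    cv <- kfold_cross_validate(dataset, hrgnn_model_factory(cfg_kv),
                               k = k, seed = seed, folds = folds)
    data.frame(keep = kv, acc = cv$pooled$acc, sen = cv$pooled$sen,
               spe = cv$pooled$spe, f1 = cv$pooled$f1)
  })
  out <- do.call(rbind, rows)
  attr(out, "folds") <- folds
  out
}

#' Model factory for cross-validating the graph classifier
#'
#' Returns a function suitable for [kfold_cross_validate]: it trains the
#' classifier on a training set and returns a prediction function.
#'
#' @param cfg An [hrgnn_config].
#' @return A function `(train_set) -> (test_set -> labels)`.
#' @export
hrgnn_model_factory <- function(cfg) {
  function(train_set) {
    fit <- suppressWarnings(train_hrgnn(train_set, cfg))
    function(test_set) suppressWarnings(predict(fit, test_set))
  }
}
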