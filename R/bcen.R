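# Gated adversarial estimation of directed connectivity.
#
# One generative module per region predicts that region's (optionally lagged)
# signal from all other regions through a learnable causal gate; replacing a
# region's observed column with its prediction yields one synthetic sample
# per region, and a shared discriminator separates real from synthetic
# time-point rows, providing both a KL-divergence estimate and an adversarial
# training signal. The trained gate magnitudes are the directed connectome.
#
# All forward/backward passes and the Adam updates are explicit matrix
# algebra; no autodiff framework is involved.

new_generator_module <- function(region_index, gate_column, W1, b1, w2, b2) {
  structure(list(region_index = region_index, gate_column = gate_column,
                 W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                 hidden_activation = "tanh"),
            class = "generator_module")
}

#' Initialize the connectivity estimation network
#'
#' Creates `v` generative modules (one hidden layer of `cfg$hidden_width`
#' tanh units each), the shared two-hidden-layer ReLU discriminator, and the
#' `v x v` causal-gate matrix. Gates are drawn i.i.d. Uniform(-0.5, 0.5) and
#' the diagonal is pinned to exactly 0 (a region's own signal never enters
#' its module); network weights use fan-in-scaled uniform initialization.
#' Fully reproducible under `cfg$seed`.
#'
#' @param v Number of regions (>= 2).
#' @param cfg A [bcen_config].
#' @return A list with elements `modules` (list of `v` generator modules),
#'   `discriminator`, and `gates` (a [causal_gates]).
#' @export
init_bcen <- function(v, cfg = bcen_config()) {
  v <- check_count(v, "v", min = 2L)
  h <- cfg$hidden_width
  with_local_seed(cfg$seed, {
    # Gates start small and sign-symmetric: the gate is the model's edge
    # score, so its initial magnitude is ranking noise that the optimizer
    # must undo; a tight initialization keeps the learned selection signal,
    # not the draw, in charge of the ranking. Hidden input rows are
    # unit-normalized so the gate carries each source's path strength from
    # the start (see the weight-normalization step in train_bcen).
    G <- matrix(stats::runif(v * v, -0.1, 0.1), v, v)
    diag(G) <- 0
    modules <- lapply(seq_len(v), function(i) {
      W1_i <- init_uniform(v, h)
      W1_i <- W1_i / sqrt(rowSums(W1_i * W1_i))
      new_generator_module(
        region_index = i,
        gate_column = G[, i],
        W1 = W1_i,
        b1 = init_uniform(h, fan_in = v),
        w2 = init_uniform(h, fan_in = h),
        b2 = init_uniform(1L, fan_in = h)
      )
    })
    disc <- structure(list(
      W1 = init_uniform(v, h), b1 = init_uniform(h, fan_in = v),
      W2 = init_uniform(h, h), b2 = init_uniform(h, fan_in = h),
      w3 = init_uniform(h, fan_in = h), b3 = init_uniform(1L, fan_in = h)
    ), class = "bcen_discriminator")
    list(modules = modules, discriminator = disc, gates = causal_gates(G))
  })
}

# Forward pass of one generative module on pre-gated input rows is shared by
# the public predictor and the training loop.
module_forward <- function(module, rows) {
  U <- rows * rep(module$gate_column, each = nrow(rows))
  Z1 <- U %*% module$W1
  Z1 <- Z1 + rep(module$b1, each = nrow(Z1))
  H <- tanh(Z1)
  xhat <- drop(H %*% module$w2) + module$b2
  list(U = U, H = H, xhat = xhat)
}

#' Predict one region's signal from all others
#'
#' For each time index `tau >= lag`, the row `X[tau - lag, ]` is multiplied
#' elementwise by the module's gate column (which zeroes the region's own
#' signal), passed through the tanh hidden layer and the linear output to
#' give the predicted value at `tau`. The first `lag` predictions copy the
#' observed values (unpredictable prefix); `lag = 0` uses instantaneous
#' inputs.
#'
#' @param module_i A generator module from [init_bcen] or a trained fit.
#' @param X An [roi_timeseries] (or numeric matrix) with `v` columns.
#' @param lag Non-negative integer lag (default 1).
#' @return A numeric vector of length `t` of predicted values for the
#'   module's region.
#' @export
predict_region <- function(module_i, X, lag = 1L) {
  if (!inherits(module_i, "generator_module"))
    stop_invalid("`module_i` must be a generator_module")
  Xm <- as_ts_matrix(X)
  lag <- check_count(lag, "lag", min = 0L)
  if (ncol(Xm) != length(module_i$gate_column))
    stop_invalid("module expects ", length(module_i$gate_column),
                 " regions but X has ", ncol(Xm))
  tt <- nrow(Xm)
  if (lag >= tt) stop_invalid("`lag` must be smaller than the series length")
  i <- module_i$region_index
  if (lag == 0L) return(module_forward(module_i, Xm)$xhat)
  xhat <- numeric(tt)
  xhat[seq_len(lag)] <- Xm[seq_len(lag), i]
  xhat[(lag + 1L):tt] <- module_forward(module_i, Xm[1:(tt - lag), , drop = FALSE])$xhat
  xhat
}

#' Form a synthetic sample by one-to-one substitution
#'
#' Returns a copy of `X` whose column `i` is replaced by the predicted
#' signal `xhat_i`; all other columns are untouched. Each subject yields `v`
#' such synthetic samples, one per region.
#'
#' @param X An [roi_timeseries].
#' @param xhat_i Numeric vector of length `X$t`.
#' @param i Region index in `1..v`.
#' @return An [roi_timeseries] identical to `X` except in column `i`.
#' @export
assemble_swap_sample <- function(X, xhat_i, i) {
  Xm <- as_ts_matrix(X)
  if (length(xhat_i) != nrow(Xm))
    stop_invalid("`xhat_i` must have length t = ", nrow(Xm))
  if (length(i) != 1L || i < 1L || i > ncol(Xm) || i != round(i))
    stop_invalid("region index `i` out of range 1..", ncol(Xm))
  Xm[, i] <- xhat_i
  roi_timeseries(Xm, colnames(Xm))
}

disc_forward <- function(disc, rows) {
  n <- nrow(rows)
  Z1 <- rows %*% disc$W1 + rep(disc$b1, each = n)
  H1 <- relu(Z1)
  Z2 <- H1 %*% disc$W2 + rep(disc$b2, each = n)
  H2 <- relu(Z2)
  logit <- drop(H2 %*% disc$w3) + disc$b3
  list(logit = logit, H1 = H1, H2 = H2)
}

# Gradient of the discriminator logit with respect to its input rows.
disc_input_grad <- function(disc, fwd) {
  dZ2 <- (fwd$H2 > 0) * rep(disc$w3, each = nrow(fwd$H2))
  dZ1 <- (fwd$H1 > 0) * (dZ2 %*% t(disc$W2))
  dZ1 %*% t(disc$W1)
}

# Gradients of a weighted sum of logits: `dlogit` holds the weight each row's
# logit carries in the objective.
disc_param_grad <- function(disc, rows, fwd, dlogit) {
  dH2 <- outer(dlogit, disc$w3)
  dZ2 <- dH2 * (fwd$H2 > 0)
  dH1 <- dZ2 %*% t(disc$W2)
  dZ1 <- dH1 * (fwd$H1 > 0)
  list(W1 = crossprod(rows, dZ1), b1 = colSums(dZ1),
       W2 = crossprod(fwd$H1, dZ2), b2 = colSums(dZ2),
       w3 = drop(crossprod(fwd$H2, dlogit)), b3 = sum(dlogit))
}

#' Density-ratio estimate of the KL divergence
#'
#' Estimates `KL(P_real || P_synth)` as the mean discriminator logit over the
#' real rows. When the discriminator has been trained to convergence on the
#' balanced logistic real-vs-synthetic objective, its logit approximates the
#' log density ratio `log p_real(x) / p_synth(x)`, whose expectation under
#' the real distribution is the KL divergence. The estimate may be negative
#' for an undertrained discriminator; no clamping is applied.
#'
#' @param disc A discriminator (from [init_bcen] or a trained fit).
#' @param real_rows Numeric `n x v` matrix of real time-point rows.
#' @param synth_rows Numeric `m x v` matrix of synthetic rows (used for
#'   width validation; the estimator itself averages over the real rows).
#' @return A single numeric KL estimate (nats).
#' @export
estimate_kl <- function(disc, real_rows, synth_rows) {
  real_rows <- as_ts_matrix(real_rows); synth_rows <- as_ts_matrix(synth_rows)
  if (nrow(real_rows) == 0L || nrow(synth_rows) == 0L)
    stop_invalid("both row sets must be non-empty")
  if (ncol(real_rows) != ncol(synth_rows))
    stop_invalid("real and synthetic rows must have the same width")
  mean(disc_forward(disc, real_rows)$logit)
}

#' Generator loss and its components
#'
#' Computes the generator objective: the squared reconstruction error
#' `||Xhat - X||_2^2` summed over all entries (predictions assembled
#' column-wise from all `v` modules), plus the L1 gate penalty
#' `lambda * (1/v) * sum |gates|`, plus the adversarial term
#' `beta * sum_i KL(X || Xtilde_i)` estimated from the shared
#' discriminator's logits.
#'
#' @param X An [roi_timeseries].
#' @param modules List of `v` generator modules.
#' @param gates A [causal_gates] (or `v x v` matrix).
#' @param disc The shared discriminator.
#' @param cfg A [bcen_config] supplying `lag`, `sparsity_weight` and
#'   `adversarial_weight`.
#' @return A list with `total` and `components`
#'   (`reconstruction`, `sparsity`, `kl` = the summed KL estimate).
#' @export
generator_loss <- function(X, modules, gates, disc, cfg = bcen_config()) {
  Xm <- as_ts_matrix(X)
  G <- if (inherits(gates, "causal_gates")) gates$gates else as.matrix(gates)
  v <- ncol(Xm)
  if (length(modules) != v || nrow(G) != v)
    stop_invalid("modules/gates dimensions must match X")
  xhats <- vapply(modules, function(m) predict_region(m, Xm, lag = cfg$lag),
                  numeric(nrow(Xm)))
  recon <- sum((xhats - Xm)^2)
  sparsity <- cfg$sparsity_weight * sum(abs(G)) / v
  kl_each <- vapply(seq_len(v), function(i) {
    Si <- Xm; Si[, i] <- xhats[, i]
    estimate_kl(disc, Xm, Si)
  }, numeric(1))
  kl <- sum(kl_each)
  list(total = recon + sparsity + cfg$adversarial_weight * kl,
       components = list(reconstruction = recon, sparsity = sparsity, kl = kl))
}

disc_loss_value <- function(disc, real_rows, synth_rows) {
  d_real <- disc_forward(disc, real_rows)$logit
  d_synth <- disc_forward(disc, synth_rows)$logit
  0.5 * mean(softplus(-d_real)) + 0.5 * mean(softplus(d_synth))
}

#' One optimizer step of the shared discriminator
#'
#' Performs a single Adam step on the balanced logistic real-vs-synthetic
#' objective over time-point rows pooled across all substituted samples, and
#' returns the post-step loss. At the chance-level optimum (identical
#' distributions) the loss converges to `log 2`.
#'
#' @param disc The discriminator to update.
#' @param X An [roi_timeseries] (or matrix) of real rows.
#' @param synth_samples Non-empty list of synthetic samples
#'   ([roi_timeseries] or matrices) as built by [assemble_swap_sample].
#' @param opt_state Adam state from a previous call, or `NULL` to start.
#' @param learning_rate Adam learning rate (default 0.001).
#' @return A list with `discriminator` (updated), `opt_state`, and `loss`
#'   (post-step balanced logistic loss).
#' @export
discriminator_step <- function(disc, X, synth_samples, opt_state = NULL,
                               learning_rate = 0.001) {
  if (!is.list(synth_samples) || length(synth_samples) == 0L)
    stop_invalid("`synth_samples` must be a non-empty list")
  real <- as_ts_matrix(X)
  synth <- do.call(rbind, lapply(synth_samples, as_ts_matrix))
  if (ncol(synth) != ncol(real))
    stop_invalid("synthetic rows must match the width of the real rows")
  fwd_r <- disc_forward(disc, real)
  fwd_s <- disc_forward(disc, synth)
  # d/d logit of 0.5*mean softplus(-d_real) + 0.5*mean softplus(d_synth)
  w_r <- -0.5 * sigmoid(-fwd_r$logit) / nrow(real)
  w_s <- 0.5 * sigmoid(fwd_s$logit) / nrow(synth)
  g_r <- disc_param_grad(disc, real, fwd_r, w_r)
  g_s <- disc_param_grad(disc, synth, fwd_s, w_s)
  grads <- Map(`+`, g_r, g_s)
  params <- unclass(disc)[names(grads)]
  if (is.null(opt_state)) opt_state <- adam_init(params)
  upd <- adam_step(params, grads, opt_state, lr = learning_rate)
  disc[names(upd$params)] <- upd$params
  list(discriminator = disc, opt_state = upd$state,
       loss = disc_loss_value(disc, real, synth))
}

#' Train the connectivity estimation network
#'
#' Runs `cfg$generator_epochs` full-batch Adam updates of all `v` generative
#' modules and their gates; discriminator updates are interleaved evenly so
#' that they total exactly `cfg$discriminator_epochs` (with the default
#' 3000/1000 epochs this is one discriminator step after every third
#' generator epoch). The gate diagonal is structurally masked at every step.
#' Inputs are z-scored per region when `cfg$standardize` is `TRUE`.
#'
#' The adversarial term reported in the trace is the density-ratio KL
#' estimate of [estimate_kl]; the generator's adversarial gradient uses the
#' standard non-saturating surrogate (raising the discriminator's logit on
#' the synthetic rows), which shares its optimum with the KL term while
#' providing a usable gradient.
#'
#' @param X An [roi_timeseries] (or numeric `t x v` matrix).
#' @param cfg A [bcen_config].
#' @return A `bcen_fit` list: `gates` ([causal_gates]), `trace` (data frame
#'   with one row per generator epoch: `epoch`, `g_loss`, `d_loss` (`NA` on
#'   epochs without a discriminator update), `recon`, `sparsity`, `kl`;
#'   with `adversarial_weight = 0` the KL estimate is evaluated only on
#'   discriminator epochs and is `NA` elsewhere),
#'   `modules`, `discriminator`, `config`, and the standardization
#'   `center`/`scale`.
#' @examples
#' net <- sample_directed_graph(4, 0.3, seed = 1)
#' ts <- simulate_nonlinear_var(net, simulation_config(4, 80, seed = 1))
#' fit <- train_bcen(ts, bcen_config(generator_epochs = 30,
#'                                   discriminator_epochs = 10))
#' extract_connectome(fit)
#' @export
train_bcen <- function(X, cfg = bcen_config()) {
  if (!inherits(X, "roi_timeseries")) X <- roi_timeseries(X)
  if (!all(is.finite(X$values))) stop_invalid("X contains non-finite values")
  v <- X$v; tt <- X$t; lag <- cfg$lag; h <- cfg$hidden_width
  if (tt <= lag) stop_invalid("series length t must exceed the lag")

  center <- rep(0, v); scale <- rep(1, v)
  Xs <- X$values
  if (cfg$standardize) {
    center <- colMeans(Xs)
    scale <- apply(Xs, 2, stats::sd)
    if (any(scale == 0))
      stop_invalid("region(s) with zero variance cannot be standardized: ",
                   paste(X$region_names[scale == 0], collapse = ", "))
    Xs <- sweep(sweep(Xs, 2, center), 2, scale, "/")
  }

  net <- init_bcen(v, cfg)
  modules <- net$modules
  disc <- net$discriminator
  G <- net$gates$gates

  pred_rows <- if (lag == 0L) seq_len(tt) else (lag + 1L):tt
  Xin <- if (lag == 0L) Xs else Xs[1:(tt - lag), , drop = FALSE]
  Xtar <- Xs[pred_rows, , drop = FALSE]
  n <- nrow(Xin)
  lambda <- cfg$sparsity_weight
  beta <- cfg$adversarial_weight
  GE <- cfg$generator_epochs
  DE <- cfg$discriminator_epochs

  params <- list()
  for (i in seq_len(v)) {
    m <- modules[[i]]
    params[[paste0("m", i, "_g")]] <- G[, i]
    params[[paste0("m", i, "_W1")]] <- m$W1
    params[[paste0("m", i, "_b1")]] <- m$b1
    params[[paste0("m", i, "_w2")]] <- m$w2
    params[[paste0("m", i, "_b2")]] <- m$b2
  }
  gen_state <- adam_init(params)
  disc_state <- NULL

  trace <- data.frame(epoch = seq_len(GE), g_loss = NA_real_, d_loss = NA_real_,
                      recon = NA_real_, sparsity = NA_real_, kl = NA_real_)

  for (epoch in seq_len(GE)) {
    # ---- generator forward ----
    fwd <- vector("list", v)
    xhat_pred <- matrix(0, n, v)
    for (i in seq_len(v)) {
      mod <- new_generator_module(i, params[[paste0("m", i, "_g")]],
                                  params[[paste0("m", i, "_W1")]],
                                  params[[paste0("m", i, "_b1")]],
                                  params[[paste0("m", i, "_w2")]],
                                  params[[paste0("m", i, "_b2")]])
      fwd[[i]] <- module_forward(mod, Xin)
      xhat_pred[, i] <- fwd[[i]]$xhat
    }
    recon_val <- sum((xhat_pred - Xtar)^2)
    gate_abs <- sum(vapply(seq_len(v), function(i)
      sum(abs(params[[paste0("m", i, "_g")]])), numeric(1)))
    sparsity_val <- lambda * gate_abs / v

    # ---- synthetic samples (full length: unpredictable prefix is real),
    # built only when the adversary or the scheduled discriminator step
    # consumes them ----
    disc_epoch <- floor(epoch * DE / GE) > floor((epoch - 1) * DE / GE)
    synth_full <- NULL
    if (beta > 0 || disc_epoch) {
      synth_full <- matrix(0, v * tt, v)
      for (i in seq_len(v)) {
        Si <- Xs
        Si[pred_rows, i] <- xhat_pred[, i]
        synth_full[((i - 1L) * tt + 1L):(i * tt), ] <- Si
      }
    }
    # KL estimate for the trace: evaluated whenever the adversary is active,
    # otherwise only on discriminator epochs (with beta = 0 it does not
    # enter the objective).
    kl_val <- if (beta > 0 || disc_epoch)
      v * mean(disc_forward(disc, Xs)$logit) else NA_real_

    g_loss <- recon_val + sparsity_val +
      if (beta > 0) beta * kl_val else 0
    if (!is.finite(g_loss))
      stop("bcen training diverged at epoch ", epoch, " (non-finite loss)",
           call. = FALSE)

    # ---- adversarial gradient (non-saturating surrogate) ----
    adv_grad <- NULL
    if (beta > 0) {
      sf <- disc_forward(disc, synth_full)
      igrad <- disc_input_grad(disc, sf)
      adv_grad <- matrix(0, n, v)
      for (i in seq_len(v))
        adv_grad[, i] <- -igrad[((i - 1L) * tt + 1L):(i * tt), i][pred_rows] / tt
    }

    # ---- generator backward ----
    # Optimization uses per-time-point units (mean over rows for the data
    # term, mean logit for the KL term), so the penalty weights lambda and
    # beta are commensurate with the data term independently of t. The
    # trace reports the summed squared error.
    grads <- params
    for (i in seq_len(v)) {
      dxhat <- (2 / n) * (xhat_pred[, i] - Xtar[, i])
      if (beta > 0) dxhat <- dxhat + beta * adv_grad[, i]
      H <- fwd[[i]]$H
      w2 <- params[[paste0("m", i, "_w2")]]
      dH <- outer(dxhat, w2)
      dZ1 <- dH * (1 - H * H)
      dU <- dZ1 %*% t(params[[paste0("m", i, "_W1")]])
      g_i <- params[[paste0("m", i, "_g")]]
      dg <- colSums(dU * Xin) + (lambda / v) * sign(g_i)
      dg[i] <- 0  # structural mask: no self-loop gradient
      grads[[paste0("m", i, "_g")]] <- dg
      grads[[paste0("m", i, "_W1")]] <- crossprod(fwd[[i]]$U, dZ1)
      grads[[paste0("m", i, "_b1")]] <- colSums(dZ1)
      grads[[paste0("m", i, "_w2")]] <- drop(crossprod(H, dxhat))
      grads[[paste0("m", i, "_b2")]] <- sum(dxhat)
    }
    upd <- adam_step(params, grads, gen_state, lr = cfg$learning_rate)
    params <- upd$params
    gen_state <- upd$state
    for (i in seq_len(v)) {
      params[[paste0("m", i, "_g")]][i] <- 0
      # Gate-carrying weight normalization: fold each source's hidden-weight
      # row norm into its gate, so the gate is the unique carrier of that
      # source's path strength (otherwise the L1 penalty drains true-edge
      # gates into W1 and gate magnitudes stop meaning edge strength).
      # The represented function is unchanged.
      W1 <- params[[paste0("m", i, "_W1")]]
      rn <- sqrt(rowSums(W1 * W1))
      rn[rn == 0] <- 1
      params[[paste0("m", i, "_g")]] <- params[[paste0("m", i, "_g")]] * rn
      params[[paste0("m", i, "_W1")]] <- W1 / rn
    }

    # ---- discriminator step on the even interleaving schedule ----
    d_loss <- NA_real_
    if (disc_epoch) {
      step <- discriminator_step(disc, Xs, list(synth_full),
                                 opt_state = disc_state,
                                 learning_rate = cfg$learning_rate)
      disc <- step$discriminator
      disc_state <- step$opt_state
      d_loss <- step$loss
    }

    trace[epoch, c("g_loss", "d_loss", "recon", "sparsity", "kl")] <-
      c(g_loss, d_loss, recon_val, sparsity_val, kl_val)
    if (cfg$verbose && epoch %% 100L == 0L)
      message(sprintf("epoch %d: g_loss %.4f recon %.4f sparsity %.4f kl %.4f",
                      epoch, g_loss, recon_val, sparsity_val, kl_val))
  }

  for (i in seq_len(v)) {
    G[, i] <- params[[paste0("m", i, "_g")]]
    modules[[i]] <- new_generator_module(i, G[, i],
                                         params[[paste0("m", i, "_W1")]],
                                         params[[paste0("m", i, "_b1")]],
                                         params[[paste0("m", i, "_w2")]],
                                         params[[paste0("m", i, "_b2")]])
  }
  structure(list(gates = causal_gates(G, X$region_names), trace = trace,
                 modules = modules, discriminator = disc, config = cfg,
                 center = center, scale = scale,
                 region_names = X$region_names),
            class = "bcen_fit")
}

#' @export
print.bcen_fit <- function(x, ...) {
  tr <- x$trace
  cat("<bcen_fit> ", length(x$region_names), " regions, ",
      nrow(tr), " generator epochs, ", sum(!is.na(tr$d_loss)),
      " discriminator epochs\n  final recon ", signif(tr$recon[nrow(tr)], 5),
      ", mean |gate| ", signif(mean(abs(x$gates$gates)), 4), "\n", sep = "")
  invisible(x)
}

#' Extract the directed connectome from trained gates
#'
#' Entry `(m, i)` of the connectome is the trained gate of region `m` inside
#' region `i`'s module — the directional influence `m -> i` — either signed
#' or in absolute value (default). No thresholding is applied; the
#' continuous weighted directed graph is returned.
#'
#' @param gates A [causal_gates] or a `bcen_fit`.
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return A [directed_connectome] with `method_tag = "bcen"`.
#' @export
extract_connectome <- function(gates, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (inherits(gates, "bcen_fit")) gates <- gates$gates
  if (!inherits(gates, "causal_gates"))
    stop_invalid("`gates` must be a causal_gates or bcen_fit")
  W <- if (mode == "absolute") abs(gates$gates) else gates$gates
  directed_connectome(W, gates$region_names, directed = TRUE,
                      method_tag = "bcen")
}
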