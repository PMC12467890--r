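check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_invalid("`", name, "` must be a single integer >= ", min)
  as.integer(x)
}

check_scalar <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (length(x) != 1L || !is.finite(x))
    stop_invalid("`", name, "` must be a single finite number")
  if (x < min || x > max || (strict_min && x == min))
    stop_invalid("`", name, "` must be in [", min, ", ", max, "]",
                 if (strict_min) " (exclusive lower bound)")
  as.numeric(x)
}

#' Simulation configuration
#'
#' Settings for the nonlinear vector-autoregressive simulator. The default
#' series length of 135 time points matches the number of retained fMRI
#' volumes in typical resting-state acquisitions after dummy-scan removal.
#'
#' @param n_regions Number of regions `v` (>= 2).
#' @param n_timepoints Series length `t` (default 135); must exceed `lag`.
#' @param edge_density Probability in `[0, 1]` of each directed edge.
#' @param coupling_scale Positive scale of the edge weights.
#' @param noise_sd Innovation standard deviation (>= 0).
#' @param nonlinearity Coupling nonlinearity, `"tanh"` (default) or
#'   `"identity"`.
#' @param lag Positive temporal lag of the coupling (default 1).
#' @param seed Integer seed; the simulator is a pure function of its seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_regions, n_timepoints = 135L,
                              edge_density = 0.2, coupling_scale = 1,
                              noise_sd = 0.1,
                              nonlinearity = c("tanh", "identity"),
                              lag = 1L, seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  cfg <- list(
    n_regions = check_count(n_regions, "n_regions", min = 2L),
    n_timepoints = check_count(n_timepoints, "n_timepoints", min = 2L),
    edge_density = check_scalar(edge_density, "edge_density", 0, 1),
    coupling_scale = check_scalar(coupling_scale, "coupling_scale", 0, strict_min = TRUE),
    noise_sd = check_scalar(noise_sd, "noise_sd", 0),
    nonlinearity = nonlinearity,
    lag = check_count(lag, "lag", min = 1L),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (cfg$n_timepoints <= cfg$lag)
    stop_invalid("`n_timepoints` must exceed `lag`")
  structure(cfg, class = "simulation_config")
}

#' Connectivity-estimation network configuration
#'
#' Training settings for the gated adversarial connectivity estimator.
#' Defaults follow the reference training recipe: one-hidden-layer
#' generative modules with 100 tanh units, a two-hidden-layer 100-unit ReLU
#' discriminator, Adam at learning rate 0.001, 3000 generator epochs and
#' 1000 discriminator epochs.
#'
#' @param hidden_width Hidden units per generative module (default 100).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param generator_epochs Generator training epochs (default 3000).
#' @param discriminator_epochs Discriminator training epochs (default 1000);
#'   must not exceed `generator_epochs`.
#' @param sparsity_weight Weight `lambda` of the L1 gate penalty
#'   (default 0.1).
#' @param adversarial_weight Weight `beta` of the adversarial
#'   (KL-divergence) term (default 1); `beta = 0` reduces training to plain
#'   gated regression.
#' @param lag Temporal lag of the generative modules (default 1); `lag = 0`
#'   uses instantaneous inputs.
#' @param seed Integer seed governing initialization.
#' @param standardize Z-score each region's series before training
#'   (default `TRUE`) so gate magnitudes are comparable across regions.
#' @param verbose Emit a progress message every 100 epochs (default `FALSE`).
#' @return A `bcen_config` list.
#' @export
bcen_config <- function(hidden_width = 100L, learning_rate = 0.001,
                        generator_epochs = 3000L, discriminator_epochs = 1000L,
                        sparsity_weight = 0.1, adversarial_weight = 1,
                        lag = 1L, seed = 1L, standardize = TRUE,
                        verbose = FALSE) {
  cfg <- list(
    hidden_width = check_count(hidden_width, "hidden_width"),
    learning_rate = check_scalar(learning_rate, "learning_rate", 0, strict_min = TRUE),
    generator_epochs = check_count(generator_epochs, "generator_epochs"),
    discriminator_epochs = check_count(discriminator_epochs, "discriminator_epochs"),
    sparsity_weight = check_scalar(sparsity_weight, "sparsity_weight", 0),
    adversarial_weight = check_scalar(adversarial_weight, "adversarial_weight", 0),
    lag = check_count(lag, "lag", min = 0L),
    seed = check_count(seed, "seed", min = -.Machine$integer.max),
    standardize = isTRUE(standardize),
    verbose = isTRUE(verbose)
  )
  if (cfg$generator_epochs < cfg$discriminator_epochs)
    stop_invalid("`generator_epochs` must be >= `discriminator_epochs`")
  structure(cfg, class = "bcen_config")
}

#' Hierarchical graph network configuration
#'
#' Settings for the hierarchical-representation graph classifier: three
#' graph-convolution layers, three TopK pooling layers and a two-layer MLP
#' head. Defaults follow the reference recipe: 64-unit convolutions,
#' a 64/32-unit MLP, Adam at learning rate 0.001, 1000 epochs, and a pooling
#' parameter of 40 nodes per stage.
#'
#' @param conv_widths Integer vector of per-layer convolution output widths
#'   (length = number of layers; default `c(64, 64, 64)`).
#' @param pool_keep Pooling parameter `p`: either an absolute node count
#'   (default 40) or a ratio in `(0, 1)` of the current node count. Counts
#'   exceeding the current node count are clamped with a warning.
#' @param mlp_widths Integer vector of MLP hidden widths (default
#'   `c(64, 32)`).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Training epochs (default 1000).
#' @param seed Integer seed governing initialization.
#' @param verbose Emit a progress message every 100 epochs (default `FALSE`).
#' @return An `hrgnn_config` list.
#' @export
hrgnn_config <- function(conv_widths = c(64L, 64L, 64L), pool_keep = 40L,
                         mlp_widths = c(64L, 32L), learning_rate = 0.001,
                         epochs = 1000L, seed = 1L, verbose = FALSE) {
  if (length(conv_widths) < 1L)
    stop_invalid("`conv_widths` needs at least one layer")
  conv_widths <- vapply(seq_along(conv_widths), function(i)
    check_count(conv_widths[i], "conv_widths"), integer(1))
  mlp_widths <- vapply(seq_along(mlp_widths), function(i)
    check_count(mlp_widths[i], "mlp_widths"), integer(1))
  if (length(pool_keep) != 1L || !is.finite(pool_keep) || pool_keep <= 0)
    stop_invalid("`pool_keep` must be a positive count or a ratio in (0, 1)")
  if (pool_keep >= 1 && pool_keep != round(pool_keep))
    stop_invalid("`pool_keep` >= 1 must be an integer node count")
  structure(list(
    n_layers = length(conv_widths),
    conv_widths = conv_widths,
    pool_keep = as.numeric(pool_keep),
    mlp_widths = mlp_widths,
    learning_rate = check_scalar(learning_rate, "learning_rate", 0, strict_min = TRUE),
    epochs = check_count(epochs, "epochs"),
    seed = check_count(seed, "seed", min = -.Machine$integer.max),
    verbose = isTRUE(verbose)
  ), class = "hrgnn_config")
}
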