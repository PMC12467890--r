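# Synthetic-data generators: sparse directed ground-truth graphs, a nonlinear
# lag-1 (configurable) VAR simulator, and labeled two-class graph populations.
# These make structure recovery and graph classification testable end to end
# with known ground truth and no external dataset.

#' Sample a sparse directed ground-truth graph
#'
#' Each ordered off-diagonal pair `(m, i)` carries a directed edge `m -> i`
#' independently with probability `density`. Edge weights are drawn uniformly
#' from `±[0.5, 1] * coupling_scale`: magnitudes are bounded away from zero so
#' that true edges remain identifiable from short simulated series.
#'
#' @param v Number of regions (>= 2).
#' @param density Edge probability in `[0, 1]`.
#' @param coupling_scale Positive weight scale.
#' @param seed Integer seed; identical arguments give identical graphs.
#' @return A [ground_truth_network].
#' @examples
#' net <- sample_directed_graph(10, density = 0.2, seed = 1)
#' sum(net$adjacency != 0)
#' @export
sample_directed_graph <- function(v, density, coupling_scale = 1, seed = 1L) {
  v <- check_count(v, "v", min = 2L)
  density <- check_scalar(density, "density", 0, 1)
  coupling_scale <- check_scalar(coupling_scale, "coupling_scale", 0, strict_min = TRUE)
  with_local_seed(seed, {
    present <- matrix(stats::runif(v * v) < density, v, v)
    magnitude <- matrix(stats::runif(v * v, 0.5, 1), v, v) * coupling_scale
    sign <- matrix(sample(c(-1, 1), v * v, replace = TRUE), v, v)
    A <- present * magnitude * sign
    diag(A) <- 0
    ground_truth_network(A)
  })
}

#' Simulate a nonlinear VAR time series from a directed graph
#'
#' Generates `X[tau, i] = f(sum_m A[m, i] * X[tau - lag, m]) + eps` with
#' `eps ~ Normal(0, noise_sd^2)` and nonlinearity `f` either the identity or
#' `tanh`; the initial `lag` rows are standard normal (or supplied via
#' `init_rows`). Under the identity nonlinearity the linear dynamics can
#' diverge, so if the adjacency's spectral radius exceeds 0.95 the weights are
#' rescaled to spectral radius 0.95 and a warning is issued (stationarity
#' guard); the `tanh` coupling is bounded and needs no guard.
#'
#' @param net A [ground_truth_network].
#' @param cfg A [simulation_config] whose `n_regions` matches `net`.
#' @param init_rows Optional `lag x v` matrix of initial values (testing
#'   hook); default standard-normal rows.
#' @return An [roi_timeseries] of shape `n_timepoints x v`.
#' @examples
#' net <- sample_directed_graph(5, 0.3, seed = 2)
#' ts <- simulate_nonlinear_var(net, simulation_config(5, 135, seed = 2))
#' @export
simulate_nonlinear_var <- function(net, cfg, init_rows = NULL) {
  if (!inherits(net, "ground_truth_network"))
    stop_invalid("`net` must be a ground_truth_network")
  if (!inherits(cfg, "simulation_config"))
    stop_invalid("`cfg` must be a simulation_config")
  v <- net$v
  if (cfg$n_regions != v)
    stop_invalid("config declares ", cfg$n_regions, " regions but the network has ", v)
  A <- net$adjacency
  if (cfg$nonlinearity == "identity") {
    sr <- spectral_radius(A)
    if (sr > 0.95) {
      warning("adjacency spectral radius ", signif(sr, 4),
              " exceeds 0.95; rescaling to 0.95 for stationarity", call. = FALSE)
      A <- A * (0.95 / sr)
    }
  }
  lag <- cfg$lag
  tt <- cfg$n_timepoints
  f <- if (cfg$nonlinearity == "tanh") tanh else identity
  if (!is.null(init_rows)) {
    init_rows <- as.matrix(init_rows)
    if (nrow(init_rows) != lag || ncol(init_rows) != v)
      stop_invalid("`init_rows` must be a ", lag, " x ", v, " matrix")
  }
  with_local_seed(cfg$seed, {
    X <- matrix(0, tt, v)
    X[seq_len(lag), ] <- if (is.null(init_rows)) stats::rnorm(lag * v) else init_rows
    noise <- matrix(stats::rnorm((tt - lag) * v, sd = cfg$noise_sd), tt - lag, v)
    for (tau in (lag + 1L):tt)
      X[tau, ] <- f(X[tau - lag, ] %*% A) + noise[tau - lag, ]
    roi_timeseries(X, net$region_names)
  })
}

#' Build a labeled two-class population of brain graphs
#'
#' Draws one template directed network, then gives every subject the template
#' plus independent `Normal(0, noise_sd^2)` edge noise; class-1 subjects
#' additionally have `n_perturbed_edges` fixed, randomly chosen edge slots
#' shifted by `±effect_size` (one fixed sign per slot). Node features follow
#' the package convention (rows of the symmetrized absolute connectome), so
#' the graphs are directly consumable by the graph classifier.
#'
#' @param n_per_class Subjects per class.
#' @param v Regions per graph.
#' @param n_perturbed_edges Number of perturbed off-diagonal edge slots
#'   (<= `v * (v - 1)`).
#' @param effect_size Absolute shift applied to perturbed slots in class 1.
#' @param noise_sd Between-subject edge-noise standard deviation.
#' @param seed Integer seed.
#' @param edge_density Template edge density (default 0.2).
#' @param coupling_scale Template weight scale (default 1).
#' @return A list of `2 * n_per_class` [brain_graph] objects with labels 0
#'   (first half) and 1 (second half); the template network and the perturbed
#'   slots are attached as attributes `template` and `perturbed_edges`.
#' @export
make_group_dataset <- function(n_per_class, v, n_perturbed_edges, effect_size,
                               noise_sd, seed = 1L, edge_density = 0.2,
                               coupling_scale = 1) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  v <- check_count(v, "v", min = 2L)
  n_perturbed_edges <- check_count(n_perturbed_edges, "n_perturbed_edges", min = 0L)
  effect_size <- check_scalar(effect_size, "effect_size")
  noise_sd <- check_scalar(noise_sd, "noise_sd", 0)
  n_slots <- v * (v - 1L)
  if (n_perturbed_edges > n_slots)
    stop_invalid("`n_perturbed_edges` (", n_perturbed_edges,
                 ") exceeds the ", n_slots, " off-diagonal edge slots")
  with_local_seed(seed, {
    template <- sample_directed_graph(v, edge_density, coupling_scale,
                                      seed = sample.int(1e6, 1))
    offdiag <- which(row(template$adjacency) != col(template$adjacency))
    slots <- sort(sample(offdiag, n_perturbed_edges))
    signs <- sample(c(-1, 1), n_perturbed_edges, replace = TRUE)
    shift <- matrix(0, v, v)
    shift[slots] <- signs * effect_size
    make_subject <- function(label) {
      noise <- matrix(stats::rnorm(v * v, sd = noise_sd), v, v)
      A <- template$adjacency + noise + if (label == 1L) shift else 0
      diag(A) <- 0
      brain_graph(A, label = label, region_names = template$region_names)
    }
    graphs <- c(lapply(seq_len(n_per_class), function(s) make_subject(0L)),
                lapply(seq_len(n_per_class), function(s) make_subject(1L)))
    attr(graphs, "template") <- template
    attr(graphs, "perturbed_edges") <- data.frame(
      source = row(template$adjacency)[slots],
      target = col(template$adjacency)[slots],
      shift = signs * effect_size
    )
    graphs
  })
}

#' Labels of a brain-graph dataset
#'
#' @param dataset A list of [brain_graph] objects.
#' @return A vector of labels (error if any graph is unlabeled).
#' @export
dataset_labels <- function(dataset) {
  labs <- lapply(dataset, `[[`, "label")
  if (any(vapply(labs, is.null, logical(1))))
    stop_invalid("every graph in the dataset must carry a label")
  unlist(labs)
}
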