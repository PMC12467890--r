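#' @keywords internal
stop_invalid <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("bcenet_invalid_argument", "error")))
}

default_region_names <- function(v) sprintf("R%d", seq_len(v))

check_region_names <- function(region_names, v) {
  if (is.null(region_names)) return(default_region_names(v))
  region_names <- as.character(region_names)
  if (length(region_names) != v)
    stop_invalid("`region_names` must have length ", v, ", got ", length(region_names))
  if (anyDuplicated(region_names))
    stop_invalid("`region_names` must be unique")
  region_names
}

#' Multivariate ROI time series
#'
#' Container for a `t x v` matrix of per-region signals (one column per brain
#' region, one row per time point), the unit of input to the connectivity
#' estimators.
#'
#' @param values Numeric `t x v` matrix; all entries must be finite.
#' @param region_names Optional character vector of `v` unique region
#'   identifiers. Defaults to `R1..Rv` (or the matrix column names).
#' @return An object of class `roi_timeseries` with elements `values`,
#'   `region_names`, `t` (time points) and `v` (regions).
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(40), 10, 4))
#' ts$t; ts$v
#' @export
roi_timeseries <- function(values, region_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop_invalid("time-series values must all be finite")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop_invalid("a time series needs t >= 2 time points and v >= 2 regions, got ",
                 nrow(values), " x ", ncol(values))
  if (is.null(region_names) && !is.null(colnames(values)))
    region_names <- colnames(values)
  region_names <- check_region_names(region_names, ncol(values))
  colnames(values) <- region_names
  structure(
    list(values = values, region_names = region_names,
         t = nrow(values), v = ncol(values)),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("<roi_timeseries> ", x$t, " time points x ", x$v, " regions\n", sep = "")
  invisible(x)
}

as_ts_matrix <- function(X) {
  if (inherits(X, "roi_timeseries")) return(X$values)
  if (is.matrix(X)) return(X)
  stop_invalid("expected an `roi_timeseries` or a numeric matrix")
}

#' Ground-truth directed network
#'
#' A known weighted directed graph used by the simulator and by the
#' structure-recovery scores. Entry `(m, i)` of `adjacency` is the weight of
#' the directed edge from region `m` to region `i`.
#'
#' @param adjacency Numeric `v x v` matrix with an all-zero diagonal
#'   (no self-loops).
#' @param region_names Optional character vector of `v` unique identifiers.
#' @return An object of class `ground_truth_network`.
#' @export
ground_truth_network <- function(adjacency, region_names = NULL) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  v <- nrow(adjacency)
  if (v < 2L || ncol(adjacency) != v)
    stop_invalid("adjacency must be square with v >= 2")
  if (any(diag(adjacency) != 0))
    stop_invalid("adjacency diagonal must be exactly 0 (no self-loops)")
  region_names <- check_region_names(region_names, v)
  dimnames(adjacency) <- list(region_names, region_names)
  structure(list(adjacency = adjacency, region_names = region_names, v = v),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat("<ground_truth_network> ", x$v, " regions, ",
      sum(x$adjacency != 0), " directed edges\n", sep = "")
  invisible(x)
}

#' Weighted directed connectome
#'
#' The output container shared by the gate extractor and the baseline
#' estimators. Entry `(m, i)` is the estimated influence of region `m` on
#' region `i`; the diagonal is structurally zero.
#'
#' @param weights Numeric `v x v` matrix with zero diagonal.
#' @param region_names Optional character vector of `v` unique identifiers.
#' @param directed Logical; `FALSE` for symmetric (correlation-type) networks.
#' @param method_tag Character provenance tag, e.g. `"bcen"` or `"pearson"`.
#' @return An object of class `directed_connectome`.
#' @export
directed_connectome <- function(weights, region_names = NULL,
                                directed = TRUE, method_tag = "unknown") {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  v <- nrow(weights)
  if (ncol(weights) != v)
    stop_invalid("connectome weight matrix must be square")
  if (any(diag(weights) != 0))
    stop_invalid("connectome diagonal must be zero")
  if (!directed && !isTRUE(all.equal(weights, t(weights), tolerance = 1e-12)))
    stop_invalid("an undirected connectome must have a symmetric weight matrix")
  region_names <- check_region_names(region_names, v)
  dimnames(weights) <- list(region_names, region_names)
  structure(list(weights = weights, region_names = region_names, v = v,
                 directed = isTRUE(directed), method_tag = method_tag),
            class = "directed_connectome")
}

#' @export
print.directed_connectome <- function(x, ...) {
  cat("<directed_connectome> ", x$v, " regions, method = ", x$method_tag,
      ", directed = ", x$directed, "\n", sep = "")
  invisible(x)
}

#' Brain graph (connectome + node features + optional label)
#'
#' The unit of graph classification: a weighted adjacency matrix (possibly
#' directed/signed, as produced by the gate extractor), a node-feature matrix
#' and an optional class label.
#'
#' @param adjacency Numeric `v x v` matrix (directed and signed entries are
#'   allowed).
#' @param node_features Numeric `v x d` matrix, one feature row per region.
#'   Defaults to the rows of the symmetrized absolute adjacency
#'   (`d = v`), the package's node-feature convention.
#' @param label Optional class label (kept as given; compared by equality).
#' @param region_names Optional character vector of `v` unique identifiers.
#' @return An object of class `brain_graph`.
#' @export
brain_graph <- function(adjacency, node_features = NULL, label = NULL,
                        region_names = NULL) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  v <- nrow(adjacency)
  if (ncol(adjacency) != v)
    stop_invalid("brain-graph adjacency must be square")
  if (!all(is.finite(adjacency)))
    stop_invalid("brain-graph adjacency must be finite")
  if (is.null(node_features))
    node_features <- connectome_node_features(adjacency)
  node_features <- as.matrix(node_features)
  storage.mode(node_features) <- "double"
  if (nrow(node_features) != v)
    stop_invalid("node_features must have one row per region (", v, ")")
  if (!all(is.finite(node_features)))
    stop_invalid("node_features must be finite")
  region_names <- check_region_names(region_names, v)
  dimnames(adjacency) <- list(region_names, region_names)
  rownames(node_features) <- region_names
  structure(list(adjacency = adjacency, node_features = node_features,
                 label = label, region_names = region_names, v = v),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat("<brain_graph> ", x$v, " nodes, d = ", ncol(x$node_features),
      if (!is.null(x$label)) paste0(", label = ", x$label) else "", "\n", sep = "")
  invisible(x)
}

#' Node features from a connectome
#'
#' The package's node-feature convention: node `i`'s feature vector is row
#' `i` of the symmetrized absolute connectome, `(|A| + |A|^T) / 2`, so
#' `d = v` and the features are self-contained in the graph.
#'
#' @param adjacency Numeric `v x v` matrix.
#' @return A `v x v` numeric feature matrix.
#' @export
connectome_node_features <- function(adjacency) {
  A <- abs(as.matrix(adjacency))
  (A + t(A)) / 2
}

#' Causal gate matrix
#'
#' The `v x v` matrix of directional-influence gates learned by the
#' connectivity estimation network. Entry `(m, i)` is the gate that scales
#' region `m`'s signal at the input of region `i`'s generative module; the
#' diagonal is a structural zero (a region never predicts itself).
#'
#' @param gates Numeric `v x v` matrix with zero diagonal.
#' @param region_names Optional character vector of `v` unique identifiers.
#' @return An object of class `causal_gates`.
#' @export
causal_gates <- function(gates, region_names = NULL) {
  gates <- as.matrix(gates)
  storage.mode(gates) <- "double"
  v <- nrow(gates)
  if (ncol(gates) != v)
    stop_invalid("gate matrix must be square")
  if (any(diag(gates) != 0))
    stop_invalid("gate diagonal must be exactly 0 (structural mask)")
  region_names <- check_region_names(region_names, v)
  dimnames(gates) <- list(region_names, region_names)
  structure(list(gates = gates, region_names = region_names, v = v),
            class = "causal_gates")
}

#' @export
print.causal_gates <- function(x, ...) {
  cat("<causal_gates> ", x$v, " x ", x$v,
      " (mean |gate| = ", signif(mean(abs(x$gates)), 4), ")\n", sep = "")
  invisible(x)
}
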