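# Classification metrics, stratified k-fold cross-validation,
# structure-recovery scores against a ground-truth graph, and the Welch
# two-sample t-test used for method comparison.

#' Confusion-matrix classification metrics
#'
#' Computes ACC = (tp + tn) / n, SEN = tp / (tp + fn),
#' SPE = tn / (tn + fp) and F1 = 2 tp / (2 tp + fp + fn), all reported as
#' percentages. A ratio with a zero denominator is reported as `NaN` with a
#' warning, never silently as 0.
#'
#' @param y_true Vector of true labels.
#' @param y_pred Vector of predicted labels (same length).
#' @param positive_class The label treated as positive for SEN/SPE/F1.
#' @return A `classification_metrics` list with `acc`, `sen`, `spe`, `f1`
#'   (percent) and the counts `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0), positive_class = 1)
#' @export
confusion_metrics <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred))
    stop_invalid("`y_true` and `y_pred` must have equal length")
  pos_t <- y_true == positive_class
  pos_p <- y_pred == positive_class
  tp <- sum(pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  tn <- sum(!pos_t & !pos_p); fp <- sum(!pos_t & pos_p)
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting NaN",
              call. = FALSE)
      return(NaN)
    }
    num / den
  }
  structure(list(
    acc = 100 * safe_ratio(tp + tn, tp + tn + fp + fn, "ACC"),
    sen = 100 * safe_ratio(tp, tp + fn, "SEN"),
    spe = 100 * safe_ratio(tn, tn + fp, "SPE"),
    f1 = 100 * safe_ratio(2 * tp, 2 * tp + fp + fn, "F1"),
    tp = tp, fp = fp, tn = tn, fn = fn
  ), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("ACC %.2f  SEN %.2f  SPE %.2f  F1 %.2f  (tp %d fp %d tn %d fn %d)\n",
              x$acc, x$sen, x$spe, x$f1, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Deterministic, seeded, stratified partition: within each class the
#' (shuffled) samples are dealt to folds round-robin, so per-fold class
#' ratios stay within one sample of the global ratio.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return An integer vector of fold ids in `1..k`, one per sample.
#' @export
make_stratified_folds <- function(labels, k = 10L, seed = 1L) {
  k <- check_count(k, "k")
  n <- length(labels)
  if (n < k) stop_invalid("need at least k = ", k, " samples, got ", n)
  folds <- integer(n)
  with_local_seed(seed, {
    start <- 0L
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # continue the round-robin across classes so fold sizes stay balanced
      folds[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
  })
  folds
}

#' Stratified k-fold cross-validation
#'
#' Each sample is tested exactly once; aggregate metrics are computed from
#' the confusion counts pooled over all folds (micro aggregation), alongside
#' per-fold metrics.
#'
#' @param dataset List of labeled samples (e.g. [brain_graph] objects); each
#'   element must carry a `label`.
#' @param model_factory Function taking a training subset of `dataset` and
#'   returning a prediction function (test subset -> predicted labels); see
#'   [hrgnn_model_factory].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param positive_class Label treated as positive (default: the larger of
#'   the two class labels, i.e. the later-stage group).
#' @param folds Optional precomputed fold assignment (integer vector in
#'   `1..k`), e.g. to share one split across configurations.
#' @return A list with `pooled` ([confusion_metrics] on pooled counts),
#'   `per_fold` (data frame), `folds`, `predictions` (one per sample).
#' @export
kfold_cross_validate <- function(dataset, model_factory, k = 10L, seed = 1L,
                                 positive_class = NULL, folds = NULL) {
  labels <- dataset_labels(dataset)
  n <- length(dataset)
  k <- check_count(k, "k")
  if (n < k) stop_invalid("need at least k = ", k, " samples, got ", n)
  if (is.null(folds)) folds <- make_stratified_folds(labels, k, seed)
  if (length(folds) != n || !all(folds %in% seq_len(k)))
    stop_invalid("`folds` must assign every sample to a fold in 1..k")
  if (is.null(positive_class)) positive_class <- max(labels)
  preds <- rep(labels[1], n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    if (length(unique(labels[train_idx])) < 2L)
      stop_invalid("fold ", f, " leaves a single-class training split")
    predictor <- model_factory(dataset[train_idx])
    pr <- predictor(dataset[test_idx])
    preds[test_idx] <- pr
    m <- suppressWarnings(
      confusion_metrics(labels[test_idx], pr, positive_class))
    per_fold[[f]] <- data.frame(fold = f, acc = m$acc, sen = m$sen,
                                spe = m$spe, f1 = m$f1, n = length(test_idx))
  }
  pooled <- confusion_metrics(labels, preds, positive_class)
  list(pooled = pooled, per_fold = do.call(rbind, per_fold),
       folds = folds, predictions = preds)
}

# Rank-based AUROC with ties averaged (equivalent to the Mann-Whitney
# statistic).
auroc_rank <- function(scores, labels) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Non-interpolated average precision over distinct thresholds, ties grouped.
auprc_rank <- function(scores, labels) {
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  ends <- cumsum(rle(s)$lengths)  # last position of each tie group
  tp_cum <- cumsum(as.numeric(l))[ends]
  n_cum <- ends
  prec <- tp_cum / n_cum
  rec <- tp_cum / sum(l)
  sum(diff(c(0, rec)) * prec)
}

#' Structure-recovery scores against a ground-truth network
#'
#' Treats the absolute off-diagonal entries of the estimate as edge scores
#' and the nonzero pattern of the ground truth as labels, and computes the
#' areas under the ROC and precision-recall curves by rank statistics
#' (ties averaged).
#'
#' @param estimate A [directed_connectome] (or `v x v` matrix).
#' @param truth A [ground_truth_network] (or `v x v` matrix) with at least
#'   one edge and one non-edge off the diagonal.
#' @return A list with `auroc` and `auprc`.
#' @export
recovery_scores <- function(estimate, truth) {
  E <- if (inherits(estimate, "directed_connectome")) estimate$weights
       else as.matrix(estimate)
  A <- if (inherits(truth, "ground_truth_network")) truth$adjacency
       else as.matrix(truth)
  if (!all(dim(E) == dim(A)))
    stop_invalid("estimate and truth dimensions differ")
  off <- row(A) != col(A)
  scores <- abs(E[off])
  labels <- A[off] != 0
  if (all(labels) || !any(labels))
    stop_invalid("truth must contain at least one edge and one non-edge")
  list(auroc = auroc_rank(scores, labels), auprc = auprc_rank(scores, labels))
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance (Welch) t-test, the package's method-comparison
#' test.
#'
#' @param a,b Numeric vectors of length >= 2.
#' @return A list with `statistic`, `p_value` and `df`.
#' @export
two_sample_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_invalid("both samples need at least 2 values")
  if (stats::var(a) + stats::var(b) == 0)
    stop_invalid("degenerate (zero) variance in both samples")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
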