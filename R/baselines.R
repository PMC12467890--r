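# Reference connectivity estimators: Pearson-correlation networks and
# pairwise (bivariate) Granger causality via nested least-squares F-tests.

#' Pearson-correlation connectome
#'
#' Entry `(m, i)` is the sample Pearson correlation of regions `m` and `i`;
#' the diagonal is set to 0 and the matrix is symmetric (the network is
#' undirected).
#'
#' @param X An [roi_timeseries] (or numeric `t x v` matrix).
#' @return A [directed_connectome] with `directed = FALSE` and
#'   `method_tag = "pearson"`.
#' @export
pearson_connectome <- function(X) {
  if (!inherits(X, "roi_timeseries")) X <- roi_timeseries(X)
  sds <- apply(X$values, 2, stats::sd)
  if (any(sds == 0))
    stop_invalid("zero-variance region(s): ",
                 paste(X$region_names[sds == 0], collapse = ", "))
  C <- stats::cor(X$values)
  diag(C) <- 0
  directed_connectome(C, X$region_names, directed = FALSE,
                      method_tag = "pearson")
}

# Residual sum of squares of least squares y ~ design (design includes the
# intercept column).
ols_sse <- function(design, y) {
  fit <- stats::lm.fit(design, y)
  sum(fit$residuals^2)
}

#' Bivariate Granger causality over all region pairs
#'
#' For each ordered pair `(m, i)`, compares the restricted model (region
#' `i`'s own `lag` past values plus an intercept) against the full model
#' (additionally the past values of region `m`) with the standard nested
#' least-squares F-test. A large F for `(m, i)` indicates that `m`'s history
#' improves the prediction of `i` — `m` Granger-causes `i`.
#'
#' @param X An [roi_timeseries] (or numeric `t x v` matrix).
#' @param lag Positive autoregressive order (default 1).
#' @return A list with `f` (`v x v` F-statistics, diagonal 0), `p`
#'   (`v x v` two-model F-test p-values, diagonal `NA`), and `connectome`
#'   (a [directed_connectome] of the F-statistics,
#'   `method_tag = "granger"`).
#' @export
bivariate_granger <- function(X, lag = 1L) {
  if (!inherits(X, "roi_timeseries")) X <- roi_timeseries(X)
  lag <- check_count(lag, "lag")
  tt <- X$t; v <- X$v
  if (tt <= 3L * lag + 3L)
    stop_invalid("series too short for lag ", lag, ": need t > ", 3L * lag + 3L)
  Xm <- X$values
  n <- tt - lag
  rows_y <- (lag + 1L):tt
  # lag matrix for each region: columns x[t-1], ..., x[t-lag]
  lag_cols <- lapply(seq_len(v), function(j)
    vapply(seq_len(lag), function(l) Xm[rows_y - l, j], numeric(n)))
  intercept <- rep(1, n)
  fmat <- matrix(0, v, v, dimnames = list(X$region_names, X$region_names))
  pmat <- matrix(NA_real_, v, v, dimnames = dimnames(fmat))
  df2 <- n - 2L * lag - 1L
  for (i in seq_len(v)) {
    y <- Xm[rows_y, i]
    design_r <- cbind(intercept, lag_cols[[i]])
    sse_r <- ols_sse(design_r, y)
    for (m in seq_len(v)) {
      if (m == i) next
      design_f <- cbind(design_r, lag_cols[[m]])
      sse_f <- ols_sse(design_f, y)
      f <- max(0, ((sse_r - sse_f) / lag) / (sse_f / df2))
      fmat[m, i] <- f
      pmat[m, i] <- stats::pf(f, lag, df2, lower.tail = FALSE)
    }
  }
  list(f = fmat, p = pmat,
       connectome = directed_connectome(fmat, X$region_names,
                                        directed = TRUE,
                                        method_tag = "granger"))
}
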