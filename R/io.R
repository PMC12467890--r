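# Readers and writers for the package's artifacts. Everything is
# tab-delimited UTF-8 text with a header row, '.' decimal separator and
# full-precision ("%.17g") floats, so write -> read round-trips are
# bit-exact. Connectomes travel either as a square matrix (header = region
# names) or as a 3-column edge list (source, target, weight; direction is
# source -> target, matching gate entry (m, i) = influence of m on i).

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv_matrix <- function(M, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(M), collapse = "\t"), con)
  body <- apply(M, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Write an ROI time series as TSV
#'
#' Header row = region names; `t` data rows; tab-delimited, full-precision
#' decimal serialization.
#'
#' @param ts An [roi_timeseries].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  if (!inherits(ts, "roi_timeseries")) stop_invalid("`ts` must be an roi_timeseries")
  write_tsv_matrix(ts$values, path)
}

parse_error <- function(path, line, ...) {
  stop(errorCondition(
    paste0(basename(path), ", line ", line, ": ", paste0(...)),
    class = c("bcenet_parse_error", "error")))
}

read_tsv_table <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) && lines[length(lines)] == "")
    lines <- lines[-length(lines)]
  if (length(lines) < 1L) parse_error(path, 1, "empty file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  v <- length(header)
  for (r in seq_along(fields)[-1]) {
    if (length(fields[[r]]) != v)
      parse_error(path, r, "expected ", v, " fields, found ", length(fields[[r]]))
  }
  list(header = header, fields = fields[-1], path = path)
}

numeric_cell <- function(cell, path, line, col) {
  x <- suppressWarnings(as.numeric(cell))
  if (is.na(x))
    parse_error(path, line, "non-numeric value '", cell, "' in column ", col)
  x
}

tsv_numeric_matrix <- function(tab) {
  v <- length(tab$header)
  n <- length(tab$fields)
  M <- matrix(0, n, v)
  for (r in seq_len(n)) {
    row <- suppressWarnings(as.numeric(tab$fields[[r]]))
    if (anyNA(row)) {
      j <- which(is.na(row))[1]
      parse_error(tab$path, r + 1L, "non-numeric value '",
                  tab$fields[[r]][j], "' in column ", j)
    }
    M[r, ] <- row
  }
  colnames(M) <- tab$header
  M
}

#' Read an ROI time series from TSV
#'
#' Parses a header-bearing TSV written by [write_timeseries]; validates
#' rectangular shape, numeric finite cells and unique region names, and
#' reports parse errors with the offending line number.
#'
#' @param path Input file path.
#' @param verbose Log the parsed dimensions (default `FALSE`).
#' @return An [roi_timeseries].
#' @export
read_timeseries <- function(path, verbose = FALSE) {
  tab <- read_tsv_table(path)
  M <- tsv_numeric_matrix(tab)
  if (verbose)
    message("read ", nrow(M), " time points x ", ncol(M),
            " regions from ", path)
  roi_timeseries(M, tab$header)
}

#' Write a connectome (or any square network) as TSV
#'
#' @param x A [directed_connectome], [causal_gates], [ground_truth_network]
#'   or square numeric matrix.
#' @param path Output file path.
#' @param format `"matrix"` (square TSV, header = region names) or
#'   `"edgelist"` (columns `source`, `target`, `weight`; only nonzero
#'   entries are written).
#' @return The path, invisibly.
#' @export
write_connectome <- function(x, path, format = c("matrix", "edgelist")) {
  format <- match.arg(format)
  W <- if (inherits(x, "directed_connectome")) x$weights
       else if (inherits(x, "causal_gates")) x$gates
       else if (inherits(x, "ground_truth_network")) x$adjacency
       else as.matrix(x)
  if (is.null(colnames(W))) colnames(W) <- default_region_names(ncol(W))
  if (format == "matrix") return(write_tsv_matrix(W, path))
  nz <- which(t(W) != 0)  # row-major order: by source, then target
  src <- ((nz - 1L) %/% ncol(W)) + 1L
  tgt <- ((nz - 1L) %% ncol(W)) + 1L
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("source\ttarget\tweight", con)
  if (length(nz))
    writeLines(paste(colnames(W)[src], colnames(W)[tgt],
                     fmt_num(W[cbind(src, tgt)]), sep = "\t"), con)
  invisible(path)
}

#' Read a connectome from TSV (matrix or edge-list dialect)
#'
#' The dialect is auto-detected from the header: a header of exactly
#' `source`, `target`, `weight` is read as an edge list (absent edges are
#' zero); anything else is read as a square matrix whose header names the
#' regions. Both dialects load to the same in-memory object.
#'
#' @param path Input file path.
#' @param region_names Optional declared node set (required to recover
#'   isolated nodes from an edge list; must cover all names in the file).
#' @return A [directed_connectome] (`directed = FALSE` if the loaded matrix
#'   is exactly symmetric).
#' @export
read_connectome <- function(path, region_names = NULL) {
  tab <- read_tsv_table(path)
  if (identical(tab$header, c("source", "target", "weight"))) {
    src <- vapply(tab$fields, `[[`, character(1), 1L)
    tgt <- vapply(tab$fields, `[[`, character(1), 2L)
    w <- vapply(seq_along(tab$fields), function(r)
      numeric_cell(tab$fields[[r]][3L], path, r + 1L, 3L), numeric(1))
    nodes <- region_names %||% unique(c(src, tgt))
    if (length(nodes) < 2L)
      stop_invalid("edge list needs a declared node set of >= 2 regions ",
                   "(pass `region_names`)")
    unknown <- setdiff(c(src, tgt), nodes)
    if (length(unknown))
      stop_invalid("edge list names regions outside `region_names`: ",
                   paste(unique(unknown), collapse = ", "))
    W <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    W[cbind(match(src, nodes), match(tgt, nodes))] <- w
  } else {
    W <- tsv_numeric_matrix(tab)
    if (nrow(W) != ncol(W))
      parse_error(path, length(tab$fields) + 1L,
                  "square matrix expected: ", nrow(W), " rows for ",
                  ncol(W), " columns")
    rownames(W) <- colnames(W)
  }
  diag_zero <- all(diag(W) == 0)
  if (!diag_zero) diag(W) <- 0
  directed_connectome(W, colnames(W),
                      directed = !isSymmetric(unname(W)),
                      method_tag = "file")
}

#' Write a training trace as TSV
#'
#' @param trace Data frame (e.g. the `trace` element of a `bcen_fit`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(trace), collapse = "\t"), con)
  body <- apply(trace, 1, function(r) paste(
    ifelse(is.na(r), "NA", fmt_num(as.numeric(r))), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a labels table (columns `sample_id`, `label`)
#'
#' @param path Input TSV path.
#' @return A data frame with character `sample_id` and `label`.
#' @export
read_labels <- function(path) {
  tab <- read_tsv_table(path)
  if (!all(c("sample_id", "label") %in% tab$header))
    parse_error(path, 1, "expected columns sample_id and label")
  si <- match("sample_id", tab$header); li <- match("label", tab$header)
  data.frame(
    sample_id = vapply(tab$fields, `[[`, character(1), si),
    label = vapply(tab$fields, `[[`, character(1), li),
    stringsAsFactors = FALSE)
}
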