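# Delimited-text interfaces. Expression matrices are stored genes x time
# with a "gene" identifier column and t1..tK headers; networks as dense
# matrices or signed edge lists. TSV is the default; .csv paths switch to
# commas.

sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix
#'
#' Expects a delimited file with header \code{gene, t1, ..., tK}: one row
#' per gene, one column per time point. Returns the transposed (time x
#' gene) matrix the filters consume. Malformed cells are reported with
#' their row and column.
#'
#' @param path input file (TSV; \code{.csv} files are comma-separated).
#' @return A list: \code{measurements} (K x n numeric matrix), \code{genes}
#'   (character vector of identifiers).
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression file needs a gene column and >= 1 time point")
  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (length(bad) > 0)
    stop(sprintf("cannot parse cell at gene row %d, time column %d ('%s')",
                 bad[1, 1], bad[1, 2], vals[bad[1, 1], bad[1, 2]]))
  if (anyNA(num))
    stop("expression matrix contains missing values")
  list(measurements = t(num), genes = genes)
}

#' Write an expression matrix
#'
#' @param path output file.
#' @param measurements K x n matrix (time x gene), as produced by
#'   \code{\link{simulate_trajectory}}.
#' @param genes optional gene identifiers (default \code{g1..gn}).
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(path, measurements, genes = NULL) {
  measurements <- as.matrix(measurements)
  n <- ncol(measurements)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  df <- data.frame(gene = genes, t(measurements), check.names = FALSE)
  colnames(df) <- c("gene", paste0("t", seq_len(nrow(measurements))))
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a network as a dense matrix
#'
#' @param path output file.
#' @param A n x n coefficient (or 0/1 adjacency) matrix.
#' @param genes optional identifiers used as row/column names.
#' @return The path, invisibly.
#' @export
write_network <- function(path, A, genes = NULL) {
  A <- as.matrix(A)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(A)))
  df <- data.frame(gene = genes, A, check.names = FALSE)
  colnames(df) <- c("gene", genes)
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a dense network matrix
#'
#' @param path file written by \code{\link{write_network}} (or any dense
#'   matrix with a leading identifier column).
#' @return A list: \code{A} (numeric matrix), \code{genes}.
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          check.names = FALSE)
  genes <- as.character(df[[1]])
  A <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(A) != ncol(A)) stop("network matrix is not square")
  storage.mode(A) <- "double"
  dimnames(A) <- NULL
  list(A = A, genes = genes)
}

#' Write a signed edge list
#'
#' One row per entry with \code{|a_ij| > tau}: \code{source} (regulator
#' gene j), \code{target} (regulated gene i), signed \code{weight}.
#'
#' @param path output file.
#' @param A n x n coefficient matrix.
#' @param tau magnitude threshold for inclusion (default 0: all nonzeros).
#' @param genes optional identifiers.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(path, A, tau = 0, genes = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  idx <- which(abs(A) > tau, arr.ind = TRUE)
  df <- data.frame(source = genes[idx[, 2]], target = genes[idx[, 1]],
                   weight = A[idx])
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a prior indicator / strength matrix
#'
#' Dense n x n nonnegative matrix; entry \code{e_ij > 0} marks "gene j
#' unlikely to regulate gene i", larger values a stronger prior.
#'
#' @param path dense matrix file (with or without a leading gene column).
#' @return Numeric n x n matrix.
#' @export
read_prior_indicator <- function(path) {
  first <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                             check.names = FALSE, nrows = 1)
  has_gene_col <- is.character(first[[1]]) || is.factor(first[[1]])
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          check.names = FALSE)
  E <- as.matrix(if (has_gene_col) df[, -1, drop = FALSE] else df)
  storage.mode(E) <- "double"
  dimnames(E) <- NULL
  if (nrow(E) != ncol(E)) stop("prior matrix is not square")
  if (any(E < 0)) stop("prior matrix must be nonnegative")
  E
}

# component-name convention for bounds files: x<i>, a<i>_<j>, mu<i>
component_names <- function(n) {
  c(paste0("x", seq_len(n)),
    paste0("a", rep(seq_len(n), each = n), "_", rep(seq_len(n), n)),
    paste0("mu", seq_len(n)))
}

#' Read per-component range bounds
#'
#' TSV with columns \code{component}, \code{lower}, \code{upper}.
#' Component names follow \code{x<i>} (expression), \code{a<i>_<j>}
#' (coefficient of gene j acting on gene i), \code{mu<i>} (steepness).
#' Components without a row stay unbounded.
#'
#' @param path bounds file.
#' @param n gene count (fixes the augmented layout).
#' @return A \code{\link{range_constraint}} of dimension \code{n^2 + 2n}.
#' @export
read_bounds <- function(path, n) {
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          check.names = FALSE)
  need <- c("component", "lower", "upper")
  if (!all(need %in% colnames(df)))
    stop("bounds file must have columns component, lower, upper")
  nm <- component_names(n)
  lower <- rep(-Inf, length(nm)); upper <- rep(Inf, length(nm))
  for (r in seq_len(nrow(df))) {
    i <- match(as.character(df$component[r]), nm)
    if (is.na(i))
      stop(sprintf("unknown component '%s' at line %d",
                   df$component[r], r + 1L))
    lower[i] <- as.numeric(df$lower[r])
    upper[i] <- as.numeric(df$upper[r])
  }
  range_constraint(lower, upper)
}

#' Write a benchmark report
#'
#' Emits the min/max/avg summary as TSV (one row per filter and metric)
#' and, when the \pkg{jsonlite} package is available, a machine-readable
#' JSON twin next to it (same path with extension \code{.json}).
#'
#' @param path output TSV path.
#' @param bench a \code{grn_benchmark}.
#' @return The TSV path, invisibly.
#' @export
write_benchmark_report <- function(path, bench) {
  stopifnot(inherits(bench, "grn_benchmark"))
  utils::write.table(bench$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jpath <- sub("\\.[^.]*$", "", path)
    jsonlite::write_json(
      list(summary = bench$summary, per_run = bench$per_run,
           config = list(runs = bench$config$runs, K = bench$config$K,
                         filters = bench$config$filters,
                         tau = bench$config$tau,
                         base_seed = bench$config$base_seed)),
      paste0(jpath, ".json"), dataframe = "rows", auto_unbox = TRUE,
      digits = NA)
  }
  invisible(path)
}
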