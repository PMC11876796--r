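#' Incomplete spatiotemporal series
#'
#' Bundles a multivariate time-series matrix `X` (rows = sensors/genes,
#' columns = time steps), the sensor-network adjacency `A` and the binary
#' observation mask `M` (1 = observed, 0 = missing) into a single validated
#' object.  Masked-out cells of `X` are stored as 0; the model never reads
#' them (the input projection substitutes a learned missing-token embedding),
#' so the sentinel cannot leak into predictions.
#'
#' @param X Numeric N x T matrix of observed values.
#' @param A Nonnegative N x N adjacency matrix; `A[i, j] != 0` makes series
#'   `j` a neighbour (attention key) of series `i`.
#' @param M Binary N x T observation mask.  Defaults to "all observed" except
#'   where `X` is `NA` (those cells become missing).
#' @param node_ids Character labels for the N series.
#' @param time_index Labels for the T steps (integers or timestamps).
#' @return An object of class `st_series`.
#' @seealso [validate_series()], [build_adjacency()], [read_series_csv()]
#' @export
st_series <- function(X, A, M = NULL, node_ids = NULL, time_index = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(M)) {
    M <- matrix(1, nrow(X), ncol(X))
    M[is.na(X)] <- 0
  }
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  X[M == 0 | is.na(X)] <- 0   # sentinel; never consumed by the model
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  node_ids <- as.character(node_ids %||% rownames(X) %||% paste0("s", seq_len(nrow(X))))
  time_index <- time_index %||% colnames(X) %||% (seq_len(ncol(X)) - 1L)
  s <- structure(
    list(X = unname(X), A = unname(A), M = unname(M),
         node_ids = node_ids, time_index = time_index),
    class = "st_series")
  v <- validate_series(s)
  if (length(v) > 0) stopf("invalid st_series: %s", paste(v, collapse = "; "))
  s
}

#' Validate a spatiotemporal series
#'
#' Checks the structural invariants of an [st_series()] and reports every
#' violation rather than stopping at the first, naming the invariant and the
#' offending indices.
#'
#' @param s An `st_series` (or a bare list with the same fields).
#' @return Character vector of violations; empty when the object is valid.
#' @export
validate_series <- function(s) {
  out <- character()
  N <- length(s$node_ids); TT <- length(s$time_index)
  if (!all(dim(s$X) == c(N, TT)))
    out <- c(out, sprintf("shape: X is %dx%d, expected %dx%d", nrow(s$X), ncol(s$X), N, TT))
  if (!all(dim(s$M) == c(N, TT)))
    out <- c(out, sprintf("shape: M is %dx%d, expected %dx%d", nrow(s$M), ncol(s$M), N, TT))
  if (!all(dim(s$A) == c(N, N)))
    out <- c(out, sprintf("shape: A is %dx%d, expected %dx%d", nrow(s$A), ncol(s$A), N, N))
  bad <- which(!(s$M %in% c(0, 1)))
  if (length(bad) > 0)
    out <- c(out, sprintf("M-binarity: %d entries outside {0,1} (first at index %d)",
                          length(bad), bad[1]))
  neg <- which(s$A < 0)
  if (length(neg) > 0)
    out <- c(out, sprintf("A-nonnegativity: %d negative weights (first at index %d)",
                          length(neg), neg[1]))
  if (anyNA(s$X)) out <- c(out, "X contains NA after masking")
  out
}

#' @export
print.st_series <- function(x, ...) {
  cat(sprintf("<st_series> %d series x %d steps; %.1f%% observed; %d graph edges\n",
              nrow(x$X), ncol(x$X), 100 * mean(x$M),
              sum(x$A != 0) - sum(diag(x$A) != 0)))
  invisible(x)
}

#' Read a series (and optional mask/adjacency) from delimited text
#'
#' Layout: rows = series, columns = time steps, first column = series IDs,
#' header row = time labels.  Empty or `NA` cells are recorded as missing in
#' the mask.  Non-numeric tokens are reported with their row/column location.
#'
#' @param path Path to the series CSV/TSV.
#' @param adjacency Either a path to a dense N x N CSV, a path to a 3-column
#'   edge-list TSV (src, dst, weight), an N x N matrix, or `NULL` for the
#'   identity graph.
#' @param mask Optional path to a 0/1 CSV laid out like the series file; by
#'   default missingness is inferred from empty cells.
#' @param sep Field separator (`","` or `"\t"`; guessed from the extension).
#' @return An [st_series()].
#' @export
read_series_csv <- function(path, adjacency = NULL, mask = NULL, sep = NULL) {
  tab <- read_grid(path, sep)
  node_ids <- tab$row_ids
  X <- tab$values
  M <- matrix(as.numeric(!is.na(X)), nrow(X))
  if (!is.null(mask)) {
    mt <- read_grid(mask, sep)
    if (!all(dim(mt$values) == dim(X)))
      stopf("mask file %s is %dx%d but series is %dx%d", mask,
            nrow(mt$values), ncol(mt$values), nrow(X), ncol(X))
    M <- M * mt$values
  }
  A <- read_adjacency(adjacency, node_ids)
  st_series(X, A, M, node_ids = node_ids, time_index = tab$col_ids)
}

read_grid <- function(path, sep = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- sep %||% if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  row_ids <- as.character(raw[[1]])
  cells <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow(cells)))
  bad <- which(is.na(vals) & !is.na(cells) & nzchar(trimws(cells)) &
                 toupper(trimws(cells)) != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-numeric cell '%s' at row %s, column %s of %s",
          cells[bad[1, 1], bad[1, 2]], row_ids[bad[1, 1]],
          colnames(cells)[bad[1, 2]], path)
  list(values = vals, row_ids = row_ids, col_ids = colnames(cells))
}

#' Read an adjacency from dense CSV, edge-list TSV, or matrix
#'
#' @param adjacency See [read_series_csv()].
#' @param node_ids Node labels used to size and index an edge-list graph.
#' @return Dense N x N matrix.
#' @export
read_adjacency <- function(adjacency, node_ids) {
  N <- length(node_ids)
  if (is.null(adjacency)) return(diag(1, N))
  if (is.matrix(adjacency)) return(adjacency)
  if (grepl("\\.tsv$", adjacency)) {
    ed <- utils::read.table(adjacency, sep = "\t", header = FALSE,
                            col.names = c("src", "dst", "weight"))
    A <- diag(1, N)
    si <- match(as.character(ed$src), node_ids)
    di <- match(as.character(ed$dst), node_ids)
    if (anyNA(si) || anyNA(di))
      stopf("edge list refers to unknown node id '%s'",
            c(as.character(ed$src)[is.na(si)], as.character(ed$dst)[is.na(di)])[1])
    A[cbind(di, si)] <- as.numeric(ed$weight)  # key src is neighbour of query dst
    return(A)
  }
  g <- read_grid(adjacency)
  if (!all(dim(g$values) == c(N, N)))
    stopf("adjacency %s is %dx%d, expected %dx%d", adjacency,
          nrow(g$values), ncol(g$values), N, N)
  g$values
}

#' Write a series to CSV (values + mask, optional adjacency)
#'
#' Observed values round-trip bit-exactly; missing cells are written empty.
#'
#' @param s An [st_series()].
#' @param path Output path for the values; the mask goes to
#'   `<path>.mask.csv` and the adjacency to `<path>.adj.csv` when requested.
#' @param write_mask,write_adjacency Logical switches.
#' @return Invisibly, the paths written.
#' @export
write_series_csv <- function(s, path, write_mask = TRUE, write_adjacency = FALSE) {
  Xc <- matrix(format_cell(s$X), nrow(s$X))
  Xc[s$M == 0] <- ""
  df <- data.frame(id = s$node_ids, Xc, check.names = FALSE)
  colnames(df) <- c("id", as.character(s$time_index))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  paths <- path
  if (write_mask) {
    mp <- paste0(path, ".mask.csv")
    dfm <- data.frame(id = s$node_ids, s$M, check.names = FALSE)
    colnames(dfm) <- colnames(df)
    utils::write.table(dfm, mp, sep = ",", row.names = FALSE, quote = FALSE)
    paths <- c(paths, mp)
  }
  if (write_adjacency) {
    ap <- paste0(path, ".adj.csv")
    dfa <- data.frame(id = s$node_ids, format_cell(s$A), check.names = FALSE)
    colnames(dfa) <- c("id", s$node_ids)
    utils::write.table(dfa, ap, sep = ",", row.names = FALSE, quote = FALSE)
    paths <- c(paths, ap)
  }
  invisible(paths)
}

format_cell <- function(x) formatC(x, format = "g", digits = 17)
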