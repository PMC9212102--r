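# Functional connectivity estimation and matrix/edge-vector plumbing.
#
# A connectivity matrix is a plain numeric matrix carrying attributes:
# subject_id, scale ("r" or "z"); row/colnames are the region labels. The
# diagonal is fixed at 0 throughout (self-connectivity is not a feature and
# keeps KNN distances finite). The canonical edge ordering everywhere in the
# package is the ROW-MAJOR strict upper triangle: (1,2), (1,3), ..., (1,a),
# (2,3), ...

new_conn_matrix <- function(mat, subject_id = NULL, scale = c("r", "z")) {
  scale <- match.arg(scale)
  attr(mat, "subject_id") <- subject_id
  attr(mat, "scale") <- scale
  class(mat) <- c("conn_matrix", class(mat))
  mat
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("conn_matrix [%s]: %d x %d regions, subject %s\n",
              attr(x, "scale"), nrow(x), ncol(x),
              attr(x, "subject_id") %||% "<unnamed>"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson functional connectivity from an ROI time series
#'
#' @param ts Timepoints x regions numeric matrix (>= 3 timepoints).
#' @param subject_id Optional subject identifier stored on the result.
#' @return A `conn_matrix` of raw Pearson correlations, symmetric with a
#'   zero diagonal.
#' @export
pearson_connectivity <- function(ts, subject_id = NULL) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("at least 3 timepoints are required", call. = FALSE)
  if (ncol(ts) < 2L) stop("at least 2 regions are required", call. = FALSE)
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1L]
    nm <- colnames(ts)[bad] %||% as.character(bad)
    stop(sprintf("degenerate region: column %s has zero variance", nm),
         call. = FALSE)
  }
  r <- stats::cor(ts)
  diag(r) <- 0
  if (is.null(colnames(ts))) dimnames(r) <- rep(list(region_labels(ncol(ts))), 2)
  new_conn_matrix(r, subject_id = subject_id, scale = "r")
}

#' Fisher r-to-z transform of a connectivity matrix
#'
#' Applies `z = atanh(r)` elementwise off-diagonal after clipping `r` to
#' +/- (1 - 1e-7); the diagonal stays 0. Applying it to a matrix already on
#' the z scale is an error.
#'
#' @param cm A raw-r `conn_matrix`.
#' @return A `conn_matrix` on the z scale.
#' @export
fisher_z <- function(cm) {
  if (!identical(attr(cm, "scale"), "r")) {
    stop("state error: matrix is already Fisher-z transformed", call. = FALSE)
  }
  lim <- 1 - 1e-7
  z <- atanh(pmin(pmax(unclass(cm), -lim), lim))
  diag(z) <- 0
  new_conn_matrix(z, subject_id = attr(cm, "subject_id"), scale = "z")
}

#' Row-major strict-upper-triangle edge indices
#'
#' @param a Number of regions.
#' @return Data frame with columns `i`, `j` (i < j) in canonical edge order.
#' @export
edge_index <- function(a) {
  i <- rep.int(seq_len(a - 1L), times = (a - 1L):1L)
  j <- unlist(lapply(seq_len(a - 1L), function(k) (k + 1L):a), use.names = FALSE)
  data.frame(i = i, j = j)
}

#' Canonical edge names (`edge_i_j`, row-major upper triangle)
#' @param a Number of regions.
#' @export
edge_names <- function(a) {
  ei <- edge_index(a)
  sprintf("edge_%03d_%03d", ei$i, ei$j)
}

#' Vectorize the strict upper triangle (row-major)
#'
#' @param m Square symmetric matrix.
#' @return Numeric vector of length `a*(a-1)/2` in canonical edge order.
#' @export
vectorize_upper <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("shape error: matrix must be square", call. = FALSE)
  # row-major upper triangle == column-major lower triangle of the transpose
  v <- t(m)[lower.tri(m)]
  names(v) <- edge_names(nrow(m))
  v
}

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#'
#' Exact inverse of [vectorize_upper()].
#'
#' @param v Edge vector of length `a*(a-1)/2`.
#' @param a Number of regions.
#' @param labels Optional region labels for dimnames.
#' @export
devectorize_upper <- function(v, a, labels = NULL) {
  if (length(v) != a * (a - 1L) / 2L) {
    stop(sprintf("shape error: expected %d edges for a=%d, got %d",
                 a * (a - 1L) / 2L, a, length(v)), call. = FALSE)
  }
  mt <- matrix(0, a, a)
  mt[lower.tri(mt)] <- v    # fills row-major upper triangle of t(mt)
  m <- t(mt)
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' Write a connectivity matrix as TSV (header row = region labels)
#' @param cm Connectivity matrix.
#' @param path Output file.
#' @export
write_conn_matrix <- function(cm, path) {
  utils::write.table(format(unclass(cm), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a connectivity matrix TSV written by [write_conn_matrix()]
#'
#' Validates squareness, numeric content and finiteness; parse failures name
#' the offending line, invalid values name the cell.
#'
#' @param path TSV file.
#' @param scale Declared scale of the stored values ("z" default).
#' @param subject_id Optional subject id to attach.
#' @export
read_conn_matrix <- function(path, scale = "z", subject_id = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("parse error: file has no data rows", call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  a <- length(header)
  rows <- vector("list", length(lines) - 1L)
  for (k in 2:length(lines)) {
    fields <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != a) {
      stop(sprintf("parse error at line %d: expected %d fields, found %d",
                   k, a, length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    bad <- which(is.na(vals) & !(toupper(fields) %in% c("NA", "NAN")))
    if (length(bad)) {
      stop(sprintf("parse error at line %d: non-numeric value '%s'",
                   k, fields[bad[1L]]), call. = FALSE)
    }
    rows[[k - 1L]] <- vals
  }
  m <- do.call(rbind, rows)
  if (nrow(m) != a) {
    stop(sprintf("parse error: %d data rows but %d columns (matrix not square)",
                 nrow(m), a), call. = FALSE)
  }
  if (any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("validation error: non-finite value at row %d, column %s",
                 idx[1L], header[idx[2L]]), call. = FALSE)
  }
  dimnames(m) <- list(header, header)
  new_conn_matrix(m, subject_id = subject_id, scale = scale)
}

#' Stack a cohort of connectivity matrices into a subjects x edges table
#'
#' @param cms List of `conn_matrix` objects sharing region labels.
#' @return Numeric matrix, rownames = subject ids, colnames = canonical edge
#'   names.
#' @export
cohort_edge_table <- function(cms) {
  if (!length(cms)) stop("empty cohort", call. = FALSE)
  lab <- colnames(cms[[1L]])
  for (cm in cms) {
    if (!identical(colnames(cm), lab)) {
      stop("cohort error: region labels differ across subjects", call. = FALSE)
    }
  }
  E <- do.call(rbind, lapply(cms, vectorize_upper))
  rownames(E) <- vapply(seq_along(cms), function(k) {
    attr(cms[[k]], "subject_id") %||% names(cms)[k] %||% sprintf("sub%04d", k)
  }, character(1))
  E
}

#' Write / read a cohort edge table as CSV
#' @param edges Subjects x edges matrix.
#' @param path Output file.
#' @export
write_edge_table <- function(edges, path) {
  utils::write.csv(data.frame(subject_id = rownames(edges), edges,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Pipeline convenience: time series list -> Fisher-z connectivity matrices
#' @param ts_list Named list of timepoints x regions matrices.
#' @return List of z-scale `conn_matrix` objects.
#' @export
connectomes_from_timeseries <- function(ts_list) {
  lapply(seq_along(ts_list), function(k) {
    fisher_z(pearson_connectivity(ts_list[[k]],
                                  subject_id = names(ts_list)[k]))
  })
}
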