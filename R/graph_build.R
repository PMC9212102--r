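# Per-subject graph encoding: each region is a node, its connectivity
# profile (row of the Fisher-z matrix, diagonal 0) is the node feature, and
# the weighted adjacency is built by K-nearest neighbours in node-feature
# space, then renormalized for graph convolution.

#' K-nearest-neighbour weighted adjacency from node features
#'
#' Each node connects to the `k` nodes with smallest Euclidean distance
#' between feature rows (ties broken by lower index); the directed neighbor
#' relation is symmetrized by union (`W_ij = max(w_ij, w_ji)`). Gaussian
#' weighting uses `w = exp(-d^2 / (2 sigma^2))` with `sigma` the mean of all
#' selected (pre-symmetrization) distances; binary weighting uses 1.
#'
#' @param X Nodes x features matrix.
#' @param k Number of neighbours per node (1 <= k <= nodes-1). Default 10.
#' @param weighting "gaussian" (default) or "binary".
#' @return Symmetric nonnegative adjacency with zero diagonal; attribute
#'   `neighbors` holds the pre-symmetrization neighbour index matrix
#'   (nodes x k) and `sigma` the Gaussian bandwidth.
#' @export
knn_adjacency <- function(X, k = 10L, weighting = c("gaussian", "binary")) {
  weighting <- match.arg(weighting)
  X <- as.matrix(X)
  a <- nrow(X)
  if (k < 1L || k > a - 1L) {
    stop(sprintf("configuration error: k must lie in [1, %d], got %d",
                 a - 1L, k), call. = FALSE)
  }
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  ord <- apply(D, 1L, function(r) order(r)[seq_len(k)])  # ties -> lower index
  nb <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)
  sel_d <- D[cbind(rep(seq_len(a), each = k), as.vector(t(nb)))]
  sigma <- mean(sel_d)
  wfun <- if (weighting == "binary") {
    function(d) rep(1, length(d))
  } else if (sigma > 0) {
    function(d) exp(-d^2 / (2 * sigma^2))
  } else {
    function(d) rep(1, length(d))   # all duplicate rows: degenerate bandwidth
  }
  W <- matrix(0, a, a)
  W[cbind(rep(seq_len(a), each = k), as.vector(t(nb)))] <- wfun(sel_d)
  W <- pmax(W, t(W))
  dimnames(W) <- list(rownames(X), rownames(X))
  attr(W, "neighbors") <- nb
  attr(W, "sigma") <- sigma
  W
}

#' Renormalized adjacency for graph convolution
#'
#' `What = Dt^{-1/2} (W + I) Dt^{-1/2}` with `Dt` the degree matrix of
#' `W + I`; symmetric with spectral radius <= 1.
#'
#' @param W Symmetric nonnegative adjacency with zero diagonal.
#' @return Normalized adjacency matrix.
#' @export
normalize_adjacency <- function(W) {
  W <- as.matrix(W)
  attr(W, "neighbors") <- NULL
  attr(W, "sigma") <- NULL
  if (any(W < 0)) stop("validation error: negative edge weights", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-8) {
    stop("validation error: adjacency must be symmetric", call. = FALSE)
  }
  if (any(diag(W) != 0)) {
    stop("validation error: adjacency must have a zero diagonal", call. = FALSE)
  }
  Wt <- W + diag(nrow(W))
  dinv <- 1 / sqrt(rowSums(Wt))
  Wt * outer(dinv, dinv)
}

#' Encode one subject's connectivity matrix as a weighted graph
#'
#' @param cm Fisher-z `conn_matrix` (node features = rows).
#' @param k,weighting Passed to [knn_adjacency()].
#' @param label Optional diagnosis label.
#' @return A `subject_graph`: list with `subject_id`, `X` (node features),
#'   `W` (KNN adjacency), `What` (normalized adjacency), `label`.
#' @export
subject_graph <- function(cm, k = 10L, weighting = "gaussian", label = NULL) {
  X <- unclass(cm)
  attr(X, "subject_id") <- NULL
  attr(X, "scale") <- NULL
  W <- knn_adjacency(X, k = k, weighting = weighting)
  structure(list(
    subject_id = attr(cm, "subject_id"),
    X = X,
    W = W,
    What = normalize_adjacency(W),
    label = label
  ), class = "subject_graph")
}

#' @export
print.subject_graph <- function(x, ...) {
  cat(sprintf("subject_graph %s: %d nodes, %d edges, label %s\n",
              x$subject_id %||% "<unnamed>", nrow(x$W),
              sum(x$W[upper.tri(x$W)] > 0), x$label %||% "<none>"))
  invisible(x)
}

#' Encode a cohort of connectivity matrices as subject graphs
#'
#' @param cms List of z-scale `conn_matrix` objects with identical region
#'   labels and size.
#' @param k,weighting Passed to [knn_adjacency()].
#' @param labels Optional vector of diagnosis labels, one per subject.
#' @return List of `subject_graph` objects.
#' @export
build_cohort_graphs <- function(cms, k = 10L, weighting = "gaussian",
                                labels = NULL) {
  if (!length(cms)) stop("cohort error: empty cohort", call. = FALSE)
  lab0 <- colnames(cms[[1L]])
  for (cm in cms) {
    if (!identical(colnames(cm), lab0)) {
      stop("cohort error: region labels differ across subjects", call. = FALSE)
    }
  }
  lapply(seq_along(cms), function(i) {
    subject_graph(cms[[i]], k = k, weighting = weighting,
                  label = if (is.null(labels)) NULL else labels[i])
  })
}
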