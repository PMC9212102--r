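# Nodal topological centralities of salient regions, permutation tests for
# group differences, POMP symptom standardization, and symptom-topology
# correlations with FDR.
#
# Path-based metrics interpret an edge weight w as a capacity: the edge
# length used for shortest paths is 1/w. Negative Fisher-z edges are
# discarded at the thresholding step (path-length semantics need
# nonnegative weights).

#' Threshold a connectivity matrix to a weighted graph at fixed sparsity
#'
#' Keeps the top `round(sparsity * a*(a-1)/2)` positive edges by weight
#' (ties broken by edge index); negative edges are never retained.
#'
#' @param z Symmetric region x region matrix (Fisher-z).
#' @param sparsity Fraction of all possible edges to keep, in (0, 1).
#'   Default 0.2.
#' @return Symmetric weighted adjacency with zero diagonal.
#' @export
threshold_network <- function(z, sparsity = 0.2) {
  if (sparsity <= 0 || sparsity >= 1) {
    stop("configuration error: sparsity must lie in (0, 1)", call. = FALSE)
  }
  z <- as.matrix(z)
  a <- nrow(z)
  v <- vectorize_upper(z)
  if (!any(v > 0)) stop("degenerate network: no positive edges", call. = FALSE)
  m <- round(sparsity * length(v))
  keep <- utils::head(order(v, decreasing = TRUE), m)
  keep <- keep[v[keep] > 0]
  out <- numeric(length(v))
  out[keep] <- v[keep]
  devectorize_upper(out, a, labels = rownames(z))
}

weighted_graph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Nodal degree (strength) of a weighted graph
#'
#' Sum of incident edge weights; for binary graphs, the neighbour count.
#'
#' @param W Symmetric nonnegative adjacency.
#' @return Numeric vector, one value per node.
#' @export
nodal_degree <- function(W) {
  rowSums(as.matrix(W))
}

#' Nodal efficiency
#'
#' `E(i) = mean_{j != i} 1 / d_ij` with `d_ij` the shortest-path length
#' under edge length `1/weight`; unreachable nodes contribute 0.
#'
#' @param W Symmetric nonnegative adjacency.
#' @return Numeric vector, one value per node.
#' @export
nodal_efficiency <- function(W) {
  W <- as.matrix(W)
  n <- nrow(W)
  g <- weighted_graph(W)
  if (igraph::ecount(g) == 0L) return(numeric(n))
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1L)
}

#' Nodal betweenness centrality
#'
#' Sum over node pairs `{s, t}` (s, t != v) of the fraction of shortest
#' paths through v, under edge length `1/weight` (unnormalized).
#'
#' @param W Symmetric nonnegative adjacency.
#' @return Numeric vector, one value per node.
#' @export
nodal_betweenness <- function(W) {
  W <- as.matrix(W)
  g <- weighted_graph(W)
  if (igraph::ecount(g) == 0L) return(numeric(nrow(W)))
  unname(igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                             normalized = FALSE))
}

#' Per-subject nodal centralities of selected regions
#'
#' Thresholds each subject's z-matrix at the given sparsity and computes
#' degree, efficiency and betweenness for the selected regions.
#'
#' @param cms List of z-scale `conn_matrix` objects.
#' @param regions Integer vector of region indices (e.g. a top-10 salient
#'   set); default all regions.
#' @param sparsity Passed to [threshold_network()].
#' @return A `nodal_metric_table`: long data frame (subject_id, region,
#'   metric, value) plus a `wide` list of subjects x regions matrices per
#'   metric.
#' @export
nodal_metric_table <- function(cms, regions = NULL, sparsity = 0.2) {
  a <- nrow(cms[[1L]])
  if (is.null(regions)) regions <- seq_len(a)
  ids <- vapply(seq_along(cms), function(k) {
    attr(cms[[k]], "subject_id") %||% sprintf("sub%04d", k)
  }, character(1))
  mets <- c("degree", "efficiency", "betweenness")
  wide <- lapply(mets, function(m) {
    matrix(NA_real_, length(cms), length(regions),
           dimnames = list(ids, region_labels(a)[regions]))
  })
  names(wide) <- mets
  for (k in seq_along(cms)) {
    W <- threshold_network(unclass(cms[[k]]), sparsity)
    wide$degree[k, ] <- nodal_degree(W)[regions]
    wide$efficiency[k, ] <- nodal_efficiency(W)[regions]
    wide$betweenness[k, ] <- nodal_betweenness(W)[regions]
  }
  long <- do.call(rbind, lapply(mets, function(m) {
    data.frame(subject_id = rep(ids, times = length(regions)),
               region = rep(regions, each = length(cms)),
               metric = m, value = as.vector(wide[[m]]),
               stringsAsFactors = FALSE)
  }))
  structure(list(long = long, wide = wide, regions = regions,
                 sparsity = sparsity),
            class = "nodal_metric_table")
}

#' Two-group permutation test on mean differences
#'
#' Test statistic: difference in group means (first level minus second
#' level of `labels`). Two-tailed p-value
#' `(1 + #{|perm| >= |obs|}) / (n_perm + 1)`.
#'
#' @param values Numeric vector, or subjects x variables matrix (each column
#'   tested).
#' @param labels Two-group factor (or coercible), each group >= 2.
#' @param n_perm Number of label permutations (default 10000; below 100
#'   triggers a warning).
#' @param seed Integer seed.
#' @return Data frame (variable, observed, p).
#' @export
permutation_group_test <- function(values, labels, n_perm = 10000L,
                                   seed = 1L) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two groups are required",
                                  call. = FALSE)
  if (any(table(labels) < 2L)) stop("each group needs >= 2 subjects",
                                    call. = FALSE)
  if (n_perm < 100L) warning("configuration warning: n_perm < 100")
  n <- nrow(values)
  g1 <- labels == levels(labels)[1L]
  n1 <- sum(g1); n2 <- n - n1
  tot <- colSums(values)
  obs <- colSums(values[g1, , drop = FALSE]) / n1 -
    (tot - colSums(values[g1, , drop = FALSE])) / n2
  withr::with_seed(seed, {
    Ind <- matrix(0, n, n_perm)
    for (b in seq_len(n_perm)) Ind[sample.int(n, n1), b] <- 1
  })
  sum1 <- crossprod(Ind, values)               # n_perm x vars
  stat <- sum1 / n1 - (matrix(tot, n_perm, ncol(values), byrow = TRUE) - sum1) / n2
  exceed <- colSums(abs(stat) >= matrix(abs(obs), n_perm, ncol(values),
                                        byrow = TRUE))
  data.frame(variable = colnames(values) %||% seq_len(ncol(values)),
             observed = obs, p = (1 + exceed) / (n_perm + 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group differences in nodal centralities of salient regions
#'
#' Permutation tests (patient minus control mean) for every region x metric
#' cell of a [nodal_metric_table()], BH-FDR corrected across the whole
#' family.
#'
#' @param nmt A `nodal_metric_table` over patients and controls.
#' @param diagnosis Character vector ("patient"/"control"), one per subject.
#' @param n_perm,seed Passed to [permutation_group_test()].
#' @param q FDR level.
#' @return Data frame (region, metric, observed, p, fdr_significant); the
#'   observed statistic is patient mean minus control mean.
#' @export
salient_group_differences <- function(nmt, diagnosis, n_perm = 10000L,
                                      seed = 1L, q = 0.05) {
  labels <- factor(diagnosis, levels = c("patient", "control"))
  res <- NULL
  for (m in names(nmt$wide)) {
    r <- permutation_group_test(nmt$wide[[m]], labels, n_perm = n_perm,
                                seed = seed)
    res <- rbind(res, data.frame(region = nmt$regions, metric = m,
                                 observed = r$observed, p = r$p,
                                 stringsAsFactors = FALSE))
  }
  res$fdr_significant <- bh_fdr(res$p, q)
  rownames(res) <- NULL
  res
}

#' Percent of Maximum Possible (POMP) score
#'
#' `100 * (raw - scale_min) / (scale_max - scale_min)`; NA passes through.
#'
#' @param raw Raw scale score(s).
#' @param scale_min,scale_max Declared scale bounds.
#' @return Value(s) in `[0, 100]`.
#' @export
pomp <- function(raw, scale_min, scale_max) {
  if (any(scale_max <= scale_min)) {
    stop("validation error: scale_max must exceed scale_min", call. = FALSE)
  }
  ok <- !is.na(raw)
  if (any(raw[ok] < scale_min | raw[ok] > scale_max)) {
    stop("validation error: raw score outside declared scale bounds",
         call. = FALSE)
  }
  100 * (raw - scale_min) / (scale_max - scale_min)
}

#' Pearson correlations between nodal metrics and symptom severity
#'
#' Complete-case Pearson correlation of each metric column against each
#' symptom column, with BH-FDR across the whole metric x symptom family.
#'
#' @param metrics Subjects x variables matrix (e.g. efficiency of salient
#'   regions), or a `nodal_metric_table` (all metrics used, variables named
#'   `metric.region`).
#' @param symptoms Numeric vector of POMP scores, or a subjects x dimensions
#'   matrix/data frame (e.g. columns positive, negative).
#' @param q FDR level (default 0.05).
#' @return Data frame (variable, symptom, n, r, p, fdr_significant).
#' @export
correlate_symptoms <- function(metrics, symptoms, q = 0.05) {
  if (inherits(metrics, "nodal_metric_table")) {
    metrics <- do.call(cbind, lapply(names(metrics$wide), function(m) {
      x <- metrics$wide[[m]]
      colnames(x) <- paste(m, colnames(x), sep = ".")
      x
    }))
  }
  metrics <- as.matrix(metrics)
  if (is.null(colnames(metrics))) colnames(metrics) <- seq_len(ncol(metrics))
  if (is.null(dim(symptoms))) symptoms <- matrix(symptoms, ncol = 1L,
                                                 dimnames = list(NULL, "symptom"))
  symptoms <- as.matrix(symptoms)
  if (is.null(colnames(symptoms))) colnames(symptoms) <- seq_len(ncol(symptoms))
  res <- NULL
  for (sc in seq_len(ncol(symptoms))) {
    for (mc in seq_len(ncol(metrics))) {
      ok <- stats::complete.cases(metrics[, mc], symptoms[, sc])
      if (sum(ok) < 4L) {
        stop("analysis error: fewer than 4 complete pairs", call. = FALSE)
      }
      ct <- stats::cor.test(metrics[ok, mc], symptoms[ok, sc],
                            method = "pearson")
      res <- rbind(res, data.frame(
        variable = colnames(metrics)[mc],
        symptom = colnames(symptoms)[sc],
        n = sum(ok), r = unname(ct$estimate), p = ct$p.value,
        stringsAsFactors = FALSE))
    }
  }
  res$fdr_significant <- bh_fdr(res$p, q)
  rownames(res) <- NULL
  res
}
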