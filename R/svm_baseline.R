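# Linear maximum-margin baseline on upper-triangle edge features, with
# nested cross-validated selection of the regularization constant C and
# per-region aggregation of the learned edge weights.

#' SVM baseline configuration
#'
#' @param C_grid Candidate regularization constants (default
#'   `10^(-3:3)`, a 7-value grid).
#' @param inner_folds Inner stratified folds of the grid search (default 10).
#' @param weight_mode "abs_mean" (default) or "signed_mean" region
#'   aggregation of edge weights.
#' @param seed Integer seed for the inner fold assignment.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(C_grid = 10^(-3:3), inner_folds = 10L,
                       weight_mode = c("abs_mean", "signed_mean"),
                       seed = 1L) {
  weight_mode <- match.arg(weight_mode)
  if (!length(C_grid) || any(C_grid <= 0)) {
    stop("configuration error: C grid must be nonempty and positive",
         call. = FALSE)
  }
  structure(list(C_grid = sort(C_grid), inner_folds = as.integer(inner_folds),
                 weight_mode = weight_mode, seed = as.integer(seed)),
            class = "svm_config")
}

fit_linear_svm <- function(x, y, C) {
  e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE)
}

svm_edge_weights <- function(fit) {
  drop(t(fit$coefs) %*% fit$SV)
}

#' Train a linear SVM with nested cross-validated C selection
#'
#' Inner stratified k-fold grid search over `C_grid` maximizing balanced
#' accuracy; the model is then refit on the full training set at the chosen
#' C. The decision function is the standard hinge-loss, L2-regularized
#' linear SVM.
#'
#' @param edges Subjects x edges feature matrix (upper-triangle Fisher-z
#'   values).
#' @param labels Factor of class labels (2 classes).
#' @param config An [svm_config()].
#' @return A `linear_svm`: fitted `e1071::svm` object, `C` chosen,
#'   `inner_results` (data frame C x mean balanced accuracy, one row per
#'   candidate with per-fold columns), edge `weights`, `intercept`,
#'   `classes`, `config`.
#' @export
train_linear_svm_nested <- function(edges, labels, config = svm_config()) {
  edges <- as.matrix(edges)
  labels <- factor(labels)
  if (length(unique(labels)) < 2L) {
    stop("training error: need both classes present", call. = FALSE)
  }
  if (any(!is.finite(edges))) {
    stop("validation error: edge features must be finite", call. = FALSE)
  }
  folds <- stratified_kfold_split(labels, k = config$inner_folds,
                                  seed = config$seed)
  pos <- levels(labels)[2L]
  fold_bac <- matrix(NA_real_, length(config$C_grid), config$inner_folds,
                     dimnames = list(as.character(config$C_grid), NULL))
  for (ci in seq_along(config$C_grid)) {
    for (fi in seq_len(config$inner_folds)) {
      tr <- folds != fi
      fit <- fit_linear_svm(edges[tr, , drop = FALSE], labels[tr],
                            config$C_grid[ci])
      pred <- stats::predict(fit, edges[!tr, , drop = FALSE])
      fold_bac[ci, fi] <- confusion_metrics(pred, labels[!tr],
                                            positive = pos)$balanced_accuracy
    }
  }
  mean_bac <- rowMeans(fold_bac)
  best <- which.max(mean_bac)        # ties -> smallest C (grid is sorted)
  C_star <- config$C_grid[best]
  fit <- fit_linear_svm(edges, labels, C_star)
  structure(list(fit = fit, C = C_star,
                 inner_results = data.frame(C = config$C_grid,
                                            balanced_accuracy = mean_bac),
                 inner_fold_bac = fold_bac,
                 weights = svm_edge_weights(fit),
                 intercept = -fit$rho,
                 classes = levels(labels), config = config),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("linear_svm: C = %g (inner-CV balanced accuracy %.1f%%), %d features\n",
              x$C, max(x$inner_results$balanced_accuracy),
              length(x$weights)))
  invisible(x)
}

#' Predict classes / decision values with a trained linear SVM
#'
#' @param object A `linear_svm`.
#' @param edges Subjects x edges matrix.
#' @param type "class" (default) or "decision" (signed distance, oriented so
#'   larger values favour the second class level).
#' @param ... Unused.
#' @export
predict.linear_svm <- function(object, edges, type = c("class", "decision"),
                               ...) {
  type <- match.arg(type)
  pred <- stats::predict(object$fit, as.matrix(edges), decision.values = TRUE)
  if (type == "class") return(pred)
  dv <- drop(attr(pred, "decision.values"))
  # libsvm orients the decision value toward the first class seen; flip so
  # that larger values always favour classes[2]
  if (grepl(paste0("^", object$classes[1L], "/"), colnames(attr(pred, "decision.values"))[1L])) {
    dv <- -dv
  }
  dv
}

#' Aggregate edge weights into per-region scores with a top-10 ranking
#'
#' A region's score is the mean of the weights of its `a - 1` incident
#' edges (signed or absolute per `mode`); when a folds x edges matrix is
#' supplied, per-fold region scores are averaged across folds.
#'
#' @param w Edge weight vector of length `a*(a-1)/2`, or a folds x edges
#'   matrix.
#' @param a Number of regions.
#' @param mode "abs_mean" (default) or "signed_mean".
#' @param top_k Size of the reported top list (default 10).
#' @param region_names Optional region labels.
#' @return A `saliency_map` (see [aggregate_saliency()]) over region scores.
#' @export
region_weights <- function(w, a, mode = c("abs_mean", "signed_mean"),
                           top_k = 10L, region_names = NULL) {
  mode <- match.arg(mode)
  if (is.null(dim(w))) w <- matrix(w, nrow = 1L)
  p <- a * (a - 1L) / 2L
  if (ncol(w) != p) {
    stop(sprintf("shape error: expected %d edge weights for a=%d, got %d",
                 p, a, ncol(w)), call. = FALSE)
  }
  ei <- edge_index(a)
  scores <- t(apply(w, 1L, function(wf) {
    v <- if (mode == "abs_mean") abs(wf) else wf
    s <- numeric(a)
    s_i <- rowsum(v, ei$i)
    s_j <- rowsum(v, ei$j)
    s[as.integer(rownames(s_i))] <- s[as.integer(rownames(s_i))] + s_i
    s[as.integer(rownames(s_j))] <- s[as.integer(rownames(s_j))] + s_j
    s / (a - 1L)
  }))
  aggregate_saliency(scores, top_k = top_k, region_names = region_names)
}
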