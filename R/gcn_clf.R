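# Graph convolutional network classifier with exact CAM node saliency.
#
# Architecture (fixed topology, configurable widths):
#   H^(0) = X;  H^(l+1) = ReLU(What H^(l) Theta^(l));  pooled = mean_v H^(L);
#   logit_c = w^c . pooled + b_c
# The conv -> global-average-pooling -> single-linear-head topology makes
# class activation mapping exact: M_c(v) = sum_k w^c_k H^(L)_{v,k} and
# mean_v M_c(v) = logit_c - b_c identically.
#
# Training is plain minibatch Adam on (class-weighted) softmax cross-entropy,
# fully seeded. Minibatches of per-subject graphs are stacked into one sparse
# block-diagonal adjacency so each step is a handful of BLAS calls.

#' GCN hyperparameter configuration
#'
#' @param widths Conv layer output widths (default `c(64, 64, 128)`).
#' @param learning_rate Adam step size (default 1e-3).
#' @param weight_decay L2 penalty added to weight gradients (default 5e-4).
#' @param max_epochs Maximum training epochs (default 200).
#' @param patience Early-stopping patience on validation loss (default 20).
#' @param val_fraction Fraction of the training split held out for validation
#'   (default 0.1, stratified); 0 disables the validation split and early
#'   stopping, returning the final-epoch weights.
#' @param batch_size Minibatch size (default 32).
#' @param class_weighting "inverse_frequency" (default) or "none".
#' @param dropout Dropout rate on conv activations during training (default 0).
#' @param seed Integer seed controlling initialization, splits and shuffling.
#' @return A list of class `gcn_config`.
#' @export
gcn_config <- function(widths = c(64L, 64L, 128L),
                       learning_rate = 1e-3,
                       weight_decay = 5e-4,
                       max_epochs = 200L,
                       patience = 20L,
                       val_fraction = 0.1,
                       batch_size = 32L,
                       class_weighting = c("inverse_frequency", "none"),
                       dropout = 0,
                       seed = 1L) {
  class_weighting <- match.arg(class_weighting)
  if (length(widths) < 1L || any(widths < 1L)) {
    stop("configuration error: at least one conv layer with positive width",
         call. = FALSE)
  }
  structure(list(widths = as.integer(widths),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 batch_size = as.integer(batch_size),
                 class_weighting = class_weighting,
                 dropout = dropout,
                 seed = as.integer(seed)),
            class = "gcn_config")
}

glorot_init <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

init_gcn_params <- function(n_features, widths, n_classes = 2L) {
  dims <- c(n_features, widths)
  Theta <- lapply(seq_along(widths), function(l) glorot_init(dims[l], dims[l + 1L]))
  list(Theta = Theta,
       Wh = glorot_init(widths[length(widths)], n_classes),
       b = numeric(n_classes))
}

# Forward pass over one stacked batch. A: sparse (nb*a x nb*a) block-diagonal
# normalized adjacency; H0: stacked node features (nb*a x f).
gcn_forward_batch <- function(params, A, H0, nb, a, dropmasks = NULL) {
  L <- length(params$Theta)
  Hs <- vector("list", L + 1L)
  Ms <- vector("list", L)
  Hs[[1L]] <- H0
  H <- H0
  for (l in seq_len(L)) {
    M <- as.matrix(A %*% H)
    Z <- M %*% params$Theta[[l]]
    H <- Z * (Z > 0)
    if (!is.null(dropmasks)) H <- H * dropmasks[[l]]
    Ms[[l]] <- M
    Hs[[l + 1L]] <- H
  }
  grp <- rep(seq_len(nb), each = a)
  pooled <- rowsum(H, grp) / a
  logits <- pooled %*% params$Wh +
    matrix(params$b, nb, length(params$b), byrow = TRUE)
  list(logits = logits, pooled = pooled, Hs = Hs, Ms = Ms)
}

softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  ex <- exp(logits - m)
  ex / rowSums(ex)
}

# Class-weighted softmax cross-entropy and its logit gradient.
weighted_ce <- function(logits, y, wts) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  nll <- -log(pmax(p[cbind(seq_len(n), y)], 1e-300))
  sw <- sum(wts)
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  dlogits <- dlogits * (wts / sw)
  list(loss = sum(wts * nll) / sw, dlogits = dlogits)
}

gcn_backward_batch <- function(params, fw, A, dlogits, nb, a,
                               dropmasks = NULL) {
  L <- length(params$Theta)
  grads <- list(Theta = vector("list", L))
  grads$Wh <- crossprod(fw$pooled, dlogits)
  grads$b <- colSums(dlogits)
  dpooled <- dlogits %*% t(params$Wh)
  grp <- rep(seq_len(nb), each = a)
  dH <- dpooled[grp, , drop = FALSE] / a
  for (l in rev(seq_len(L))) {
    if (!is.null(dropmasks)) dH <- dH * dropmasks[[l]]
    dZ <- dH * (fw$Hs[[l + 1L]] > 0)
    grads$Theta[[l]] <- crossprod(fw$Ms[[l]], dZ)
    if (l > 1L) dH <- as.matrix(A %*% (dZ %*% t(params$Theta[[l]])))
  }
  grads
}

adam_init <- function(params) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros) else array(0, dim = dim(x) %||% length(x))
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v, decay) {
    if (decay) g <- g + wd * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^state$t)
    vhat <- v / (1 - beta2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (l in seq_along(params$Theta)) {
    u <- upd(params$Theta[[l]], grads$Theta[[l]],
             state$m$Theta[[l]], state$v$Theta[[l]], TRUE)
    params$Theta[[l]] <- u$p; state$m$Theta[[l]] <- u$m; state$v$Theta[[l]] <- u$v
  }
  u <- upd(params$Wh, grads$Wh, state$m$Wh, state$v$Wh, TRUE)
  params$Wh <- u$p; state$m$Wh <- u$m; state$v$Wh <- u$v
  u <- upd(params$b, grads$b, state$m$b, state$v$b, FALSE)
  params$b <- u$p; state$m$b <- u$m; state$v$b <- u$v
  list(params = params, state = state)
}

graphs_to_sparse <- function(graphs) {
  lapply(graphs, function(g) {
    methods::as(Matrix::Matrix(g$What, sparse = TRUE), "CsparseMatrix")
  })
}

#' Train a GCN graph classifier
#'
#' Minimizes class-weighted softmax cross-entropy with Adam; early stopping
#' monitors the loss on a stratified inner validation split (`val_fraction`
#' of the training data, never the test set) and the weights at the best
#' validation loss are returned. Deterministic given `config$seed`.
#'
#' @param graphs List of `subject_graph` objects.
#' @param labels Factor (or coercible) of class labels, 2 classes present.
#' @param config A [gcn_config()].
#' @return A `trained_gcn` with elements `params` (per-layer `Theta`,
#'   classifier `Wh`, biases `b`), `classes`, `history` (per-epoch train and
#'   validation loss), `best_epoch`, `config`.
#' @export
train_gcn <- function(graphs, labels, config = gcn_config()) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L || length(unique(labels)) < 2L) {
    stop("training error: need both classes present", call. = FALSE)
  }
  y <- as.integer(labels)
  a <- nrow(graphs[[1L]]$X)
  f <- ncol(graphs[[1L]]$X)
  for (g in graphs) {
    if (nrow(g$X) != a || ncol(g$X) != f) {
      stop("shape error: graphs are not homogeneous", call. = FALSE)
    }
  }
  Ws <- graphs_to_sparse(graphs)
  Xs <- lapply(graphs, `[[`, "X")
  n <- length(graphs)

  wts <- rep(1, n)
  if (config$class_weighting == "inverse_frequency") {
    tab <- table(y)
    wts <- n / (length(tab) * as.vector(tab)[y])
  }

  history <- NULL
  best <- NULL
  withr::with_seed(config$seed, {
    params <- init_gcn_params(f, config$widths)
    state <- adam_init(params)

    use_val <- config$val_fraction > 0
    val_idx <- if (use_val) {
      sort(unlist(lapply(split(seq_len(n), y), function(ix) {
        sample(ix, max(1L, round(config$val_fraction * length(ix))))
      }), use.names = FALSE))
    } else integer(0)
    train_idx <- setdiff(seq_len(n), val_idx)

    if (use_val) {
      A_val <- Matrix::bdiag(Ws[val_idx])
      H_val <- do.call(rbind, Xs[val_idx])
    }

    best <- list(loss = Inf, params = params, epoch = 0L)
    patience_left <- config$patience
    hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tot_loss <- 0; tot_w <- 0
      for (bidx in batches) {
        nb <- length(bidx)
        A <- Matrix::bdiag(Ws[bidx])
        H0 <- do.call(rbind, Xs[bidx])
        dropmasks <- NULL
        if (config$dropout > 0) {
          dropmasks <- lapply(config$widths, function(w) {
            matrix((stats::runif(nb * a * w) >= config$dropout) /
                     (1 - config$dropout), nb * a, w)
          })
        }
        fw <- gcn_forward_batch(params, A, H0, nb, a, dropmasks)
        ce <- weighted_ce(fw$logits, y[bidx], wts[bidx])
        grads <- gcn_backward_batch(params, fw, A, ce$dlogits, nb, a, dropmasks)
        st <- adam_step(params, grads, state,
                        config$learning_rate, config$weight_decay)
        params <- st$params; state <- st$state
        tot_loss <- tot_loss + ce$loss * sum(wts[bidx])
        tot_w <- tot_w + sum(wts[bidx])
      }
      vl <- if (use_val) {
        fwv <- gcn_forward_batch(params, A_val, H_val, length(val_idx), a)
        weighted_ce(fwv$logits, y[val_idx], wts[val_idx])$loss
      } else NA_real_

      hist_epoch <- c(hist_epoch, epoch)
      hist_train <- c(hist_train, tot_loss / tot_w)
      hist_val <- c(hist_val, vl)

      if (!use_val) {
        best <- list(loss = NA_real_, params = params, epoch = epoch)
      } else if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, params = params, epoch = epoch)
        patience_left <- config$patience
      } else {
        patience_left <- patience_left - 1L
        if (patience_left <= 0L) break
      }
    }
    history <- data.frame(epoch = hist_epoch, train_loss = hist_train,
                          val_loss = hist_val)
  })

  structure(list(params = best$params, classes = levels(labels),
                 n_nodes = a, n_features = f,
                 history = history, best_epoch = best$epoch,
                 config = config, trained = TRUE),
            class = "trained_gcn")
}

#' @export
print.trained_gcn <- function(x, ...) {
  cat(sprintf(
    "trained_gcn: %d conv layer(s) [%s], classes {%s}, best epoch %d\n",
    length(x$params$Theta), paste(x$config$widths, collapse = ","),
    paste(x$classes, collapse = ", "), x$best_epoch))
  invisible(x)
}

#' Forward pass: class logits and final node feature maps
#'
#' @param model A `trained_gcn`.
#' @param graphs A single `subject_graph` or a list of them.
#' @return List with `logits` (subjects x classes, colnames = classes) and
#'   `node_features` (list of nodes x width matrices, one per subject).
#' @export
gcn_forward <- function(model, graphs) {
  if (inherits(graphs, "subject_graph")) graphs <- list(graphs)
  a <- model$n_nodes
  for (g in graphs) {
    if (nrow(g$X) != a || ncol(g$X) != model$n_features) {
      stop("shape error: graph width does not match the model", call. = FALSE)
    }
  }
  Ws <- graphs_to_sparse(graphs)
  Xs <- lapply(graphs, `[[`, "X")
  n <- length(graphs)
  logits <- matrix(NA_real_, n, length(model$classes),
                   dimnames = list(NULL, model$classes))
  node_features <- vector("list", n)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 128L))
  for (ch in chunks) {
    fw <- gcn_forward_batch(model$params, Matrix::bdiag(Ws[ch]),
                            do.call(rbind, Xs[ch]), length(ch), a)
    logits[ch, ] <- fw$logits
    HL <- fw$Hs[[length(fw$Hs)]]
    for (k in seq_along(ch)) {
      node_features[[ch[k]]] <- HL[((k - 1L) * a + 1L):(k * a), , drop = FALSE]
    }
  }
  list(logits = logits, node_features = node_features)
}

#' Predict class probabilities for subject graphs
#'
#' @param object A `trained_gcn`.
#' @param graphs List of `subject_graph` objects (or a single one).
#' @param ... Unused.
#' @return Subjects x classes matrix of softmax probabilities (rows sum to 1).
#' @export
predict.trained_gcn <- function(object, graphs, ...) {
  if (is.null(object$trained) || !object$trained) {
    stop("state error: model is not trained", call. = FALSE)
  }
  softmax_rows(gcn_forward(object, graphs)$logits)
}

#' Exact CAM node activation scores for one subject graph
#'
#' `M_c(v) = sum_k w^c_k H^(L)_{v,k}`; by construction
#' `mean_v M_c(v) = logit_c - b_c` (the GAP-CAM identity).
#'
#' @param model A `trained_gcn` (conv -> GAP -> single linear head).
#' @param graph A `subject_graph`.
#' @param target_class Class name (default the second class level, by
#'   convention the patient class) or index.
#' @return Numeric vector of per-node activation values.
#' @export
cam_node_scores <- function(model, graph, target_class = NULL) {
  if (is.null(model$params$Wh) || !is.matrix(model$params$Wh)) {
    stop("unsupported architecture: exact CAM requires conv -> GAP -> linear",
         call. = FALSE)
  }
  ci <- resolve_class(model, target_class)
  fw <- gcn_forward(model, graph)
  drop(fw$node_features[[1L]] %*% model$params$Wh[, ci])
}

resolve_class <- function(model, target_class) {
  if (is.null(target_class)) return(length(model$classes))
  if (is.character(target_class)) {
    ci <- match(target_class, model$classes)
    if (is.na(ci)) stop(sprintf("unknown class '%s'", target_class),
                        call. = FALSE)
    return(ci)
  }
  as.integer(target_class)
}

#' CAM scores for a cohort (subjects x regions matrix)
#'
#' @inheritParams cam_node_scores
#' @param graphs List of `subject_graph` objects.
#' @export
cam_cohort_scores <- function(model, graphs, target_class = NULL) {
  ci <- resolve_class(model, target_class)
  fw <- gcn_forward(model, graphs)
  t(vapply(fw$node_features, function(H) drop(H %*% model$params$Wh[, ci]),
           numeric(model$n_nodes)))
}

#' Aggregate per-subject node scores into a ranked saliency map
#'
#' Scores are averaged across subjects and ranked in descending order (ties
#' broken by lower region index). The default ranks by the magnitude of the
#' mean activation: a node's saliency is the size of its contribution to the
#' class logit regardless of direction, which makes the patient-class and
#' control-class maps of a binary softmax classifier identical (in a
#' two-class head the node-wise evidence for one class is exactly the
#' evidence against the other).
#'
#' @param scores Subjects x regions matrix of node activation values.
#' @param top_k Size of the reported top list (default 10).
#' @param region_names Optional region labels.
#' @param rank_by "magnitude" (default) ranks by `|mean activation|`;
#'   "signed" ranks by the raw mean activation.
#' @return A `saliency_map`: data frame `ranking` (region, name,
#'   mean_activation, rank), `top` (indices of the top_k regions),
#'   `per_subject` (the input matrix).
#' @export
aggregate_saliency <- function(scores, top_k = 10L, region_names = NULL,
                               rank_by = c("magnitude", "signed")) {
  rank_by <- match.arg(rank_by)
  scores <- as.matrix(scores)
  if (!nrow(scores)) stop("analysis error: no subjects to aggregate",
                          call. = FALSE)
  mean_act <- colMeans(scores)
  key <- if (rank_by == "magnitude") abs(mean_act) else mean_act
  ord <- order(-key, seq_along(mean_act))
  ranking <- data.frame(
    region = ord,
    name = if (is.null(region_names)) region_labels(length(mean_act))[ord]
           else region_names[ord],
    mean_activation = mean_act[ord],
    rank = seq_along(ord), stringsAsFactors = FALSE)
  structure(list(ranking = ranking,
                 top = ord[seq_len(min(top_k, length(ord)))],
                 top_k = as.integer(top_k),
                 per_subject = scores),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("saliency_map: top %d of %d regions\n",
              x$top_k, ncol(x$per_subject)))
  print(utils::head(x$ranking, x$top_k), row.names = FALSE)
  invisible(x)
}

#' Write a saliency map as CSV (region, mean_activation, rank)
#' @param map A `saliency_map`.
#' @param path Output file.
#' @export
write_saliency <- function(map, path) {
  utils::write.csv(map$ranking, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
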