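# Cross-validation schemes, performance metrics with confidence intervals,
# and the generic CV runner shared by the GCN and SVM models.

#' Stratified k-fold assignment
#'
#' Shuffles within each class and deals subjects round-robin so per-fold
#' class proportions are within one subject of the global proportions; the
#' partition is exhaustive and disjoint.
#'
#' @param labels Class labels (factor or coercible).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k) per subject.
#' @export
stratified_kfold_split <- function(labels, k = 10L, seed = 1L) {
  labels <- factor(labels)
  if (k < 2L) stop("split error: k must be >= 2", call. = FALSE)
  if (any(table(labels) < k)) {
    stop("split error: every class needs at least k members", call. = FALSE)
  }
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      ix <- which(labels == cl)
      folds[ix[sample.int(length(ix))]] <- rep_len(seq_len(k), length(ix))
    }
  })
  folds
}

#' Leave-one-site-out split
#'
#' One loop per site containing both classes; sites with a single class
#' (e.g. a control-only site) are never used as a test set but always remain
#' in training, and are reported as skipped.
#'
#' @param site_ids Site label per subject.
#' @param labels Class labels per subject.
#' @return A list with `loops` (list of `list(site, train, test)` index
#'   vectors) and `skipped` (sites never tested).
#' @export
loso_split <- function(site_ids, labels) {
  site_ids <- as.character(site_ids)
  labels <- factor(labels)
  sites <- sort(unique(site_ids))
  testable <- sites[vapply(sites, function(s) {
    length(unique(labels[site_ids == s])) == 2L
  }, logical(1))]
  if (!length(testable)) {
    stop("split error: no site contains both classes", call. = FALSE)
  }
  loops <- lapply(testable, function(s) {
    list(site = s, train = which(site_ids != s), test = which(site_ids == s))
  })
  list(loops = loops, skipped = setdiff(sites, testable))
}

#' Confusion-matrix metrics (percent)
#'
#' Sensitivity = TP/(TP+FN) over the positive (patient) class, specificity
#' = TN/(TN+FP), balanced accuracy = their mean.
#'
#' @param predictions Predicted labels.
#' @param labels True labels (both classes must be present).
#' @param positive Positive class name (default "patient").
#' @return List with `balanced_accuracy`, `sensitivity`, `specificity` (in
#'   percent) and `counts` (TP, FN, TN, FP).
#' @export
confusion_metrics <- function(predictions, labels, positive = "patient") {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) {
    stop("metric error: both classes must be present in the labels",
         call. = FALSE)
  }
  tp <- sum(is_pos & predictions == positive)
  fn <- sum(is_pos & predictions != positive)
  tn <- sum(!is_pos & predictions != positive)
  fp <- sum(!is_pos & predictions == positive)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  list(balanced_accuracy = (sens + spec) / 2,
       sensitivity = sens, specificity = spec,
       counts = c(TP = tp, FN = fn, TN = tn, FP = fp))
}

#' Rank-based (Mann-Whitney) AUC with midrank tie handling
#'
#' @param scores Numeric scores, larger favouring the positive class.
#' @param labels True labels.
#' @param positive Positive class name (default "patient").
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, positive = "patient") {
  is_pos <- as.character(labels) == positive
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) {
    stop("metric error: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Normal-approximation 95% confidence interval across fold estimates
#'
#' @param estimates Numeric vector of per-fold values.
#' @param level Confidence level (default 0.95).
#' @return List with `mean`, `lower`, `upper`, `method`.
#' @export
confidence_interval <- function(estimates, level = 0.95) {
  m <- mean(estimates)
  se <- if (length(estimates) > 1L) {
    stats::sd(estimates) / sqrt(length(estimates))
  } else 0
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(mean = m, lower = m - zq * se, upper = m + zq * se,
       method = "normal approximation across folds")
}

# Bootstrap CI over pooled test subjects (used for LOSO reports).
bootstrap_ci_bac <- function(predictions, labels, positive, n_boot = 1000L,
                             seed = 1L, level = 0.95) {
  n <- length(labels)
  bac <- numeric(n_boot)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      ix <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[ix])) < 2L) { bac[b] <- NA; next }
      bac[b] <- confusion_metrics(predictions[ix], labels[ix],
                                  positive)$balanced_accuracy
    }
  })
  qs <- stats::quantile(bac, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE)
  list(mean = mean(bac, na.rm = TRUE), lower = unname(qs[1L]),
       upper = unname(qs[2L]),
       method = sprintf("bootstrap over test subjects (%d resamples)", n_boot))
}

# Train + predict dispatch shared by cv_evaluate(); f_train/f_test are lists
# of subject graphs (gcn) or edge matrices (svm).
fit_and_score <- function(model, f_train, y_train, f_test, model_config,
                          positive) {
  if (model == "gcn") {
    fit <- train_gcn(f_train, y_train, model_config)
    prob <- stats::predict(fit, f_test)
    pred <- fit$classes[max.col(prob)]
    scores <- prob[, positive]
  } else {
    fit <- train_linear_svm_nested(f_train, y_train, model_config)
    pred <- as.character(stats::predict(fit, f_test))
    scores <- stats::predict(fit, f_test, type = "decision")
    if (fit$classes[2L] != positive) scores <- -scores
  }
  list(fit = fit, pred = pred, scores = scores)
}

index_features <- function(features, idx) {
  if (is.matrix(features)) features[idx, , drop = FALSE] else features[idx]
}

#' Cross-validated evaluation of the GCN or SVM classifier
#'
#' Runs stratified k-fold or leave-one-site-out cross-validation, collecting
#' per-fold balanced accuracy, sensitivity, specificity and AUC, pooled
#' means with 95% CIs (normal approximation across folds; bootstrap over
#' pooled test subjects for LOSO), confusion counts, and the per-fold edge
#' weights (SVM) for region aggregation.
#'
#' @param features List of `subject_graph`s (gcn) or subjects x edges matrix
#'   (svm).
#' @param labels Class labels.
#' @param model "gcn" or "svm".
#' @param scheme "kfold" or "loso".
#' @param site_ids Site labels (required for LOSO).
#' @param k Folds for the k-fold scheme (default 10).
#' @param seed Seed for fold assignment.
#' @param model_config A [gcn_config()] or [svm_config()]; defaults created
#'   from `seed` when NULL.
#' @param positive Positive class name (default "patient").
#' @param harmonization_state Free-text provenance tag stored in the report
#'   (e.g. "before" / "after").
#' @param preprocess Optional function `(train_idx, test_idx)` returning
#'   `list(train, test)` features, applied per fold (e.g. fold-wise ComBat:
#'   fit on the training subjects only, apply to the held-out subjects).
#'   When given, `features` may be NULL.
#' @return A `cv_report`: data frame `folds`, list `pooled` (means + CIs),
#'   `confusion`, `predictions`, and (svm) `edge_weights` per fold.
#' @export
cv_evaluate <- function(features, labels, model = c("gcn", "svm"),
                        scheme = c("kfold", "loso"), site_ids = NULL,
                        k = 10L, seed = 1L, model_config = NULL,
                        positive = "patient",
                        harmonization_state = "after",
                        preprocess = NULL) {
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  if (is.null(model_config)) {
    model_config <- if (model == "gcn") gcn_config(seed = seed)
                    else svm_config(seed = seed)
  }
  if (scheme == "kfold") {
    folds <- stratified_kfold_split(labels, k = k, seed = seed)
    loops <- lapply(seq_len(k), function(fi) {
      list(site = sprintf("fold%02d", fi),
           train = which(folds != fi), test = which(folds == fi))
    })
    skipped <- character(0)
  } else {
    if (is.null(site_ids)) stop("LOSO requires site_ids", call. = FALSE)
    sp <- loso_split(site_ids, labels)
    loops <- sp$loops
    skipped <- sp$skipped
  }

  rows <- NULL
  all_pred <- character(length(labels))
  all_scores <- numeric(length(labels))
  tested <- logical(length(labels))
  edge_weights <- NULL
  for (lp in loops) {
    if (is.null(preprocess)) {
      f_train <- index_features(features, lp$train)
      f_test <- index_features(features, lp$test)
    } else {
      pp <- preprocess(lp$train, lp$test)
      f_train <- pp$train
      f_test <- pp$test
    }
    fs <- fit_and_score(model, f_train, labels[lp$train], f_test,
                        model_config, positive)
    cm <- confusion_metrics(fs$pred, labels[lp$test], positive)
    rows <- rbind(rows, data.frame(
      unit = lp$site, n_test = length(lp$test),
      balanced_accuracy = cm$balanced_accuracy,
      sensitivity = cm$sensitivity, specificity = cm$specificity,
      auc = auc(fs$scores, labels[lp$test], positive),
      TP = cm$counts["TP"], FN = cm$counts["FN"],
      TN = cm$counts["TN"], FP = cm$counts["FP"],
      stringsAsFactors = FALSE))
    all_pred[lp$test] <- fs$pred
    all_scores[lp$test] <- fs$scores
    tested[lp$test] <- TRUE
    if (model == "svm") edge_weights <- rbind(edge_weights, fs$fit$weights)
  }
  rownames(rows) <- NULL

  pooled <- list(
    balanced_accuracy = confidence_interval(rows$balanced_accuracy),
    sensitivity = confidence_interval(rows$sensitivity),
    specificity = confidence_interval(rows$specificity),
    auc = confidence_interval(rows$auc))
  if (scheme == "loso") {
    pooled$balanced_accuracy <- bootstrap_ci_bac(
      all_pred[tested], labels[tested], positive, seed = seed)
  }

  structure(list(folds = rows, pooled = pooled, model = model,
                 scheme = scheme, skipped_sites = skipped,
                 harmonization_state = harmonization_state,
                 predictions = data.frame(
                   index = which(tested), label = labels[tested],
                   predicted = all_pred[tested], score = all_scores[tested],
                   stringsAsFactors = FALSE),
                 edge_weights = edge_weights, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  p <- x$pooled$balanced_accuracy
  cat(sprintf(
    "cv_report [%s, %s, harmonization %s]: balanced accuracy %.1f%% (95%% CI %.1f-%.1f)\n",
    x$model, x$scheme, x$harmonization_state, p$mean, p$lower, p$upper))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%, AUC %.3f; %d fold(s)\n",
              x$pooled$sensitivity$mean, x$pooled$specificity$mean,
              x$pooled$auc$mean, nrow(x$folds)))
  if (length(x$skipped_sites)) {
    cat("  skipped (single-class) sites:",
        paste(x$skipped_sites, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a CV report as CSV (per-fold) and JSON (pooled summary)
#' @param report A `cv_report`.
#' @param csv_path,json_path Output files (either may be NULL).
#' @export
write_cv_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report$folds, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    pooled <- lapply(report$pooled, function(ci) {
      ci[c("mean", "lower", "upper", "method")]
    })
    jsonlite::write_json(
      list(model = report$model, scheme = report$scheme,
           harmonization_state = report$harmonization_state,
           skipped_sites = report$skipped_sites, pooled = pooled),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
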