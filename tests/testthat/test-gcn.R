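# Helpers to build tiny hand-specified models and graphs.
manual_model <- function(Theta, Wh, b, n_nodes = nrow(Theta[[1L]]),
                         classes = c("control", "patient")) {
  structure(list(params = list(Theta = Theta, Wh = Wh, b = b),
                 classes = classes, n_nodes = n_nodes,
                 n_features = nrow(Theta[[1L]]),
                 config = gcn_config(widths = vapply(Theta, ncol, integer(1))),
                 trained = TRUE),
            class = "trained_gcn")
}

manual_graph <- function(X, What) {
  structure(list(subject_id = "toy", X = X, W = What, What = What,
                 label = NULL), class = "subject_graph")
}

test_that("a one-layer forward pass matches pencil-and-paper arithmetic", {
  X <- matrix(c(1, 2,
                3, -1), 2, 2, byrow = TRUE)
  What <- matrix(c(0.5, 0.5,
                   0.5, 0.5), 2, 2)
  Theta <- matrix(c(1, 0,
                    0, -1), 2, 2, byrow = TRUE)
  Wh <- matrix(c(1, 2,
                 3, -1), 2, 2, byrow = TRUE)
  b <- c(0.1, -0.2)
  # hand: AX = [[2, 0.5], [2, 0.5]]; AX Theta = [[2, -0.5], [2, -0.5]];
  # ReLU -> [[2, 0], [2, 0]]; GAP -> (2, 0); logits = (2*1 + 0.1, 2*2 - 0.2)
  model <- manual_model(list(Theta), Wh, b)
  fw <- gcn_forward(model, manual_graph(X, What))
  expect_equal(drop(fw$logits), c(control = 2.1, patient = 3.8),
               tolerance = 1e-10)
  expect_equal(fw$node_features[[1L]], matrix(c(2, 2, 0, 0), 2, 2),
               tolerance = 1e-10)
})

test_that("an all-zero network outputs its biases and CAM is identically zero", {
  X <- withr::with_seed(1, matrix(rnorm(12), 4, 3))
  What <- normalize_adjacency(matrix(0, 4, 4) + 0)
  model <- manual_model(list(matrix(0, 3, 5)), matrix(0, 5, 2), c(0.3, -0.4),
                        n_nodes = 4L)
  g <- manual_graph(X, What)
  fw <- gcn_forward(model, g)
  expect_equal(drop(fw$logits), c(control = 0.3, patient = -0.4))
  expect_equal(cam_node_scores(model, g, "patient"), rep(0, 4))
})

test_that("logits are invariant to node permutation; feature maps permute", {
  sc <- make_small_cohort(site_sizes = list(c(3L, 3L), c(0L, 2L)),
                          n_regions = 12L, n_timepoints = 40L)
  g <- build_cohort_graphs(sc$cms, k = 4)[[1L]]
  model <- withr::with_seed(2, manual_model(
    list(matrix(rnorm(12 * 6, sd = 0.3), 12, 6)),
    matrix(rnorm(12), 6, 2), c(0, 0)))
  perm <- withr::with_seed(3, sample(12))
  # permute nodes only; feature columns untouched
  gp <- manual_graph(g$X[perm, , drop = FALSE], g$What[perm, perm])
  fw <- gcn_forward(model, g)
  fwp <- gcn_forward(model, gp)
  expect_equal(fwp$logits, fw$logits, tolerance = 1e-12)
  expect_equal(fwp$node_features[[1L]], fw$node_features[[1L]][perm, ],
               tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  sc <- make_small_cohort(site_sizes = list(c(10L, 10L), c(0L, 2L)),
                          n_regions = 15L, n_timepoints = 50L,
                          effect_size = 0.5)
  graphs <- build_cohort_graphs(sc$cms, k = 5)
  y <- sc$cohort$records$diagnosis
  cfg <- gcn_config(widths = c(8L, 8L), max_epochs = 15L, seed = 42L)
  m1 <- train_gcn(graphs, y, cfg)
  m2 <- train_gcn(graphs, y, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_error(train_gcn(graphs, rep("patient", length(y)), cfg),
               "training error")
})

test_that("a strongly separated cohort is fit to 100% training balanced accuracy", {
  sc <- make_small_cohort(site_sizes = list(c(30L, 30L), c(0L, 2L)),
                          n_regions = 30L, n_timepoints = 200L,
                          effect_size = 0.5, seed = 19L)
  graphs <- build_cohort_graphs(sc$cms, k = 8)
  y <- sc$cohort$records$diagnosis
  # pure fit-capacity check: no early stopping, no weight decay
  m <- train_gcn(graphs, y,
                 gcn_config(widths = c(32L, 32L), max_epochs = 250L,
                            val_fraction = 0, weight_decay = 0,
                            learning_rate = 3e-3, seed = 1L))
  pred <- m$classes[max.col(predict(m, graphs))]
  expect_equal(confusion_metrics(pred, y)$balanced_accuracy, 100)
})

test_that("shuffled labels yield chance-level held-out accuracy", {
  sc <- make_small_cohort(site_sizes = list(c(40L, 40L), c(0L, 2L)),
                          n_regions = 20L, n_timepoints = 60L,
                          effect_size = 0.5, seed = 29L)
  graphs <- build_cohort_graphs(sc$cms, k = 6)
  y <- withr::with_seed(77L, sample(sc$cohort$records$diagnosis))
  folds <- stratified_kfold_split(y, 4, seed = 1L)
  pred <- character(length(y))
  for (fi in 1:4) {   # pooled CV predictions for a stable chance estimate
    tr <- folds != fi
    m <- train_gcn(graphs[tr], y[tr],
                   gcn_config(widths = c(16L, 16L), max_epochs = 60L,
                              seed = 2L))
    pred[!tr] <- m$classes[max.col(predict(m, graphs[!tr]))]
  }
  bac <- confusion_metrics(pred, y)$balanced_accuracy
  expect_gte(bac, 40)
  expect_lte(bac, 60)
})

test_that("predicted probabilities are a softmax of the forward logits", {
  sc <- make_small_cohort(site_sizes = list(c(4L, 4L), c(0L, 2L)),
                          n_regions = 10L, n_timepoints = 40L)
  graphs <- build_cohort_graphs(sc$cms, k = 3)
  y <- sc$cohort$records$diagnosis
  m <- train_gcn(graphs, y, gcn_config(widths = 6L, max_epochs = 5L, seed = 3L))
  p <- predict(m, graphs[1:5])
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-9)
  expect_true(all(p > 0 & p < 1))
  lg <- gcn_forward(m, graphs[1:5])$logits
  expect_equal(p, exp(lg) / rowSums(exp(lg)), tolerance = 1e-12)

  m_untrained <- m
  m_untrained$trained <- FALSE
  expect_error(predict(m_untrained, graphs[1:2]), "state error")
})

test_that("training loss decreases on a single-layer full-batch configuration", {
  sc <- make_small_cohort(site_sizes = list(c(12L, 12L), c(0L, 2L)),
                          n_regions = 12L, n_timepoints = 60L,
                          effect_size = 0.5, seed = 4L)
  graphs <- build_cohort_graphs(sc$cms, k = 4)
  y <- sc$cohort$records$diagnosis
  m <- train_gcn(graphs, y,
                 gcn_config(widths = 8L, max_epochs = 30L, patience = 30L,
                            batch_size = 26L, learning_rate = 5e-3,
                            weight_decay = 0, seed = 5L))
  expect_true(all(diff(m$history$train_loss) < 1e-3))
  expect_lt(m$history$train_loss[nrow(m$history)], m$history$train_loss[1L])
})

test_that("the GAP-CAM identity holds exactly for trained models", {
  sc <- make_small_cohort(site_sizes = list(c(6L, 6L), c(0L, 2L)),
                          n_regions = 14L, n_timepoints = 40L)
  graphs <- build_cohort_graphs(sc$cms, k = 4)
  y <- sc$cohort$records$diagnosis
  m <- train_gcn(graphs, y, gcn_config(widths = c(8L, 8L), max_epochs = 10L,
                                       seed = 6L))
  for (g in graphs[1:6]) {
    fw <- gcn_forward(m, g)
    for (ci in 1:2) {
      cam <- cam_node_scores(m, g, ci)
      expect_equal(mean(cam), unname(fw$logits[1, ci] - m$params$b[ci]),
                   tolerance = 1e-8)
    }
  }
})

test_that("saliency aggregation ranks by magnitude with index tie-breaking", {
  # two subjects with exactly opposite scores: all means 0, rank = index order
  s <- rbind(c(1, -2, 3), c(-1, 2, -3))
  map <- aggregate_saliency(s, top_k = 2)
  expect_equal(map$ranking$region, 1:3)
  expect_equal(map$ranking$mean_activation, rep(0, 3))
  expect_equal(map$top, 1:2)

  one <- matrix(c(0.5, -3, 2), 1)
  map1 <- aggregate_saliency(one, top_k = 3)
  expect_equal(map1$ranking$region, c(2, 3, 1))          # by |activation|
  map1s <- aggregate_saliency(one, top_k = 3, rank_by = "signed")
  expect_equal(map1s$ranking$region, c(3, 1, 2))         # by signed value

  wide <- matrix(rnorm(90), 1)
  expect_length(aggregate_saliency(wide, top_k = 10)$top, 10L)
  expect_error(aggregate_saliency(matrix(numeric(0), 0, 3)), "analysis error")
})
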