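# End-to-end orchestration: synthesize (or ingest) -> connectome ->
# site-effect injection -> harmonization -> graph encoding -> cross-validated
# classification -> saliency -> nodal topology -> symptom correlations.

#' Default pipeline configuration
#'
#' A nested list mirroring the module structure; any subset can be
#' overridden via [run_pipeline()]'s `config` argument or a YAML file with
#' the same shape.
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    cohort = list(n_regions = 90L,
                  site_sizes = list(c(301L, 217L), c(0L, 340L), c(49L, 63L),
                                    c(32L, 83L), c(67L, 72L), c(56L, 132L)),
                  n_timepoints = 200L, effect_size = 0.3,
                  site_shift = 0.3, site_scale = 0.2, symptom_coupling = 0.6),
    graph = list(k = 10L, weighting = "gaussian"),
    harmonize = list(enabled = TRUE, within_folds = FALSE),
    model = list(kind = "gcn",
                 gcn = list(widths = c(64L, 64L, 128L), max_epochs = 200L),
                 svm = list()),
    cv = list(scheme = "kfold", k = 10L),
    saliency = list(top_k = 10L),
    topology = list(sparsity = 0.2, n_perm = 10000L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with sections mirroring [default_pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  merge_config(default_pipeline_config(), yaml::read_yaml(path))
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full connectome-classification pipeline on a synthetic cohort
#'
#' Stages: cohort synthesis, connectivity estimation (Pearson + Fisher-z),
#' edge-level site-effect injection, ComBat harmonization (optional, pooled
#' or fold-wise), KNN graph encoding, cross-validated classification (GCN or
#' SVM), saliency extraction (CAM or SVM region weights), nodal topology of
#' the top salient regions with permutation group tests, and POMP symptom
#' correlations. Any stage failure aborts with the stage name.
#'
#' @param config A nested list (see [default_pipeline_config()]) or a path
#'   to a YAML file; partial configurations are merged over the defaults.
#' @param out_dir Optional run directory; when given, all artifacts (subject
#'   table, CV report, saliency, topology and correlation tables, manifest)
#'   are written there.
#' @return A `pipeline_result` list: `cohort`, `site_audit` (before/after
#'   site-effect reports), `cv_report`, `saliency`, `group_differences`,
#'   `symptom_correlations`, `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- merge_config(default_pipeline_config(), config)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  pipeline_log("synth", "generating cohort (seed %d)", cfg$seed)
  scfg <- run_stage("synth", do.call(synth_config, c(cfg$cohort,
                                                     list(seed = cfg$seed))))
  cohort <- run_stage("synth", generate_cohort(scfg))
  rec <- cohort$records
  labels <- rec$diagnosis

  pipeline_log("connectome", "estimating %d connectomes", nrow(rec))
  cms <- run_stage("connectome", connectomes_from_timeseries(cohort$timeseries))
  edges_clean <- run_stage("connectome", cohort_edge_table(cms))

  pipeline_log("site_effects", "injecting per-site batch effects")
  edges_raw <- run_stage("site_effects",
                         inject_site_effects(edges_clean, rec$site_id, scfg))

  covars <- rec[, c("diagnosis", "age", "sex")]
  audit_before <- NULL
  audit_after <- NULL
  if (sum(rec$diagnosis == "control") > 0 &&
      length(unique(rec$site_id[rec$diagnosis == "control"])) > 1) {
    audit_before <- run_stage("harmonize", site_effect_scan(
      edges_raw, rec$site_id, group = rec$diagnosis, subset = "control"))
  }

  edges <- edges_raw
  combat_model <- NULL
  if (isTRUE(cfg$harmonize$enabled) && !isTRUE(cfg$harmonize$within_folds)) {
    pipeline_log("harmonize", "pooled ComBat over %d sites",
                 length(unique(rec$site_id)))
    hz <- run_stage("harmonize",
                    combat_fit_transform(edges_raw, rec$site_id, covars))
    edges <- hz$edges
    combat_model <- hz$model
    if (!is.null(audit_before)) {
      audit_after <- run_stage("harmonize", site_effect_scan(
        edges, rec$site_id, group = rec$diagnosis, subset = "control"))
    }
  }

  a <- scfg$n_regions
  make_graphs <- function(edge_mat) {
    zs <- lapply(seq_len(nrow(edge_mat)), function(i) {
      new_conn_matrix(devectorize_upper(edge_mat[i, ], a,
                                        labels = cohort$region_labels),
                      subject_id = rownames(edge_mat)[i], scale = "z")
    })
    build_cohort_graphs(zs, k = cfg$graph$k, weighting = cfg$graph$weighting,
                        labels = labels)
  }

  pipeline_log("graphs", "KNN graph encoding (k = %d, %s weights)",
               cfg$graph$k, cfg$graph$weighting)
  graphs <- run_stage("graphs", make_graphs(edges))
  zs <- lapply(graphs, function(g) {
    new_conn_matrix(g$X, subject_id = g$subject_id, scale = "z")
  })

  kind <- match.arg(cfg$model$kind, c("gcn", "svm"))
  model_config <- if (kind == "gcn") {
    do.call(gcn_config, c(cfg$model$gcn, list(seed = cfg$seed)))
  } else {
    do.call(svm_config, c(cfg$model$svm, list(seed = cfg$seed)))
  }

  preprocess <- NULL
  features <- if (kind == "gcn") graphs else edges
  if (isTRUE(cfg$harmonize$enabled) && isTRUE(cfg$harmonize$within_folds)) {
    pipeline_log("harmonize", "fold-wise ComBat (fit on train, apply to test)")
    preprocess <- function(train, test) {
      hz <- combat_fit_transform(edges_raw[train, , drop = FALSE],
                                 rec$site_id[train], covars[train, ])
      e_test <- combat_apply(hz$model, edges_raw[test, , drop = FALSE],
                             rec$site_id[test], covars[test, ])
      if (kind == "svm") return(list(train = hz$edges, test = e_test))
      list(train = make_graphs(hz$edges), test = make_graphs(e_test))
    }
    features <- NULL
  }

  pipeline_log("cv", "%s cross-validation of the %s model",
               cfg$cv$scheme, kind)
  report <- run_stage("cv", cv_evaluate(
    features, labels, model = kind, scheme = cfg$cv$scheme,
    site_ids = rec$site_id, k = cfg$cv$k, seed = cfg$seed,
    model_config = model_config, preprocess = preprocess,
    harmonization_state = if (isTRUE(cfg$harmonize$enabled)) "after" else "before"))

  pipeline_log("saliency", "extracting top-%d salient regions",
               cfg$saliency$top_k)
  saliency <- run_stage("saliency", {
    if (kind == "gcn") {
      final <- train_gcn(graphs, labels, model_config)
      aggregate_saliency(cam_cohort_scores(final, graphs, "patient"),
                         top_k = cfg$saliency$top_k,
                         region_names = cohort$region_labels)
    } else {
      region_weights(report$edge_weights, a,
                     mode = model_config$weight_mode,
                     top_k = cfg$saliency$top_k,
                     region_names = cohort$region_labels)
    }
  })

  group_diffs <- NULL
  correlations <- NULL
  if (any(rec$diagnosis == "patient")) {
    pipeline_log("topology", "nodal centralities at sparsity %.2f",
                 cfg$topology$sparsity)
    nmt <- run_stage("topology", nodal_metric_table(
      zs, regions = saliency$top, sparsity = cfg$topology$sparsity))
    group_diffs <- run_stage("topology", salient_group_differences(
      nmt, rec$diagnosis, n_perm = cfg$topology$n_perm, seed = cfg$seed))

    pipeline_log("clinical", "POMP symptom correlations")
    is_pat <- rec$diagnosis == "patient"
    pat_metrics <- lapply(nmt$wide, function(m) m[is_pat, , drop = FALSE])
    nmt_pat <- structure(list(long = NULL, wide = pat_metrics,
                              regions = nmt$regions,
                              sparsity = nmt$sparsity),
                         class = "nodal_metric_table")
    symp <- cbind(
      positive = pomp(rec$symptom_positive[is_pat], rec$scale_min[1L],
                      rec$scale_max[1L]),
      negative = pomp(rec$symptom_negative[is_pat], rec$scale_min[1L],
                      rec$scale_max[1L]))
    correlations <- run_stage("clinical", correlate_symptoms(nmt_pat, symp))
  }

  result <- structure(list(
    cohort = cohort, site_audit = list(before = audit_before,
                                       after = audit_after),
    combat_model = combat_model, cv_report = report, saliency = saliency,
    group_differences = group_diffs, symptom_correlations = correlations,
    config = cfg), class = "pipeline_result")

  if (!is.null(out_dir)) {
    pipeline_log("write", "writing artifacts to %s", out_dir)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_subject_table(rec, file.path(out_dir, "subjects.csv"))
    write_atlas(cohort$region_labels, file.path(out_dir, "atlas.tsv"))
    write_cv_report(report, file.path(out_dir, "cv_folds.csv"),
                    file.path(out_dir, "cv_summary.json"))
    write_saliency(saliency, file.path(out_dir, "saliency.csv"))
    if (!is.null(audit_before)) {
      write_site_effect_report(audit_before,
                               json_path = file.path(out_dir, "site_audit_before.json"))
    }
    if (!is.null(audit_after)) {
      write_site_effect_report(audit_after,
                               json_path = file.path(out_dir, "site_audit_after.json"))
    }
    if (!is.null(group_diffs)) {
      utils::write.csv(group_diffs, file.path(out_dir, "topology_group_tests.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    if (!is.null(correlations)) {
      utils::write.csv(correlations, file.path(out_dir, "symptom_correlations.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    manifest <- list(package_version = as.character(utils::packageVersion("connectogcn")),
                     seed = cfg$seed, config = cfg)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$cv_report)
  if (!is.null(x$site_audit$before)) print(x$site_audit$before)
  if (!is.null(x$site_audit$after)) print(x$site_audit$after)
  invisible(x)
}
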