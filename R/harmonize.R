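# Parametric empirical-Bayes ComBat harmonization of edge-level site effects,
# and a before/after audit of cross-site differences.
#
# The model per edge e and subject i of site s:
#   y_ise = alpha_e + x_i' beta_e + gamma_se + delta_se * eps_ise
# Site location gamma and scale delta are estimated per (site, edge),
# shrunk across edges via moment-matched normal / inverse-gamma priors
# (iterative conditional posterior updates), and removed while the
# covariate effects (diagnosis, age, sex, ...) and pooled variance are
# restored.

#' Fit-and-apply parametric empirical-Bayes ComBat
#'
#' @param edges Subjects x edges numeric matrix (e.g. Fisher-z values).
#' @param site_ids Site/batch label per row.
#' @param covariates Optional data frame of biological covariates to preserve
#'   (e.g. diagnosis, age, sex); expanded via `model.matrix(~ .)`.
#' @param eb Use empirical-Bayes shrinkage (default TRUE). With FALSE the raw
#'   per-site location/scale estimates are removed instead.
#' @param conv Relative convergence tolerance of the EB iterations (1e-6).
#' @param max_iter Maximum EB iterations per site (100).
#' @return List with `edges` (harmonized matrix, same shape/dimnames) and
#'   `model` (a `combat_model`: grand coefficients, pooled variance, per-site
#'   `gamma_hat`/`delta_hat`, shrunk `gamma_star`/`delta_star`, priors).
#'   With a single site the input is returned unchanged with a warning and a
#'   NULL model.
#' @export
combat_fit_transform <- function(edges, site_ids, covariates = NULL,
                                 eb = TRUE, conv = 1e-6, max_iter = 100L) {
  edges <- as.matrix(edges)
  n <- nrow(edges)
  if (length(site_ids) != n) {
    stop("shape error: one site id per subject is required", call. = FALSE)
  }
  site <- factor(as.character(site_ids))
  k <- nlevels(site)
  if (k < 2L) {
    warning("single site: returning input unchanged")
    return(list(edges = edges, model = NULL))
  }
  nj <- as.vector(table(site))
  if (any(nj < 2L)) stop("every site needs >= 2 subjects", call. = FALSE)

  B <- stats::model.matrix(~ 0 + site)
  C <- NULL
  xlevels <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covariates[] <- lapply(covariates, function(col) {
      if (is.character(col)) factor(col) else col
    })
    xlevels <- lapply(covariates, function(col) {
      if (is.factor(col)) levels(col) else NULL
    })
    C <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  }
  design <- cbind(B, C)
  if (qr(design)$rank < ncol(design)) {
    stop("design error: site + covariate design matrix is rank deficient",
         call. = FALSE)
  }

  beta <- solve(crossprod(design), crossprod(design, edges))
  site_means <- beta[seq_len(k), , drop = FALSE]
  alpha <- drop((nj / n) %*% site_means)                     # grand location
  resid <- edges - design %*% beta
  var_pooled <- pmax(colSums(resid^2) / n, 1e-12)

  stand_mean <- matrix(alpha, n, ncol(edges), byrow = TRUE)
  if (!is.null(C)) stand_mean <- stand_mean + C %*% beta[-seq_len(k), , drop = FALSE]
  sdev <- sqrt(var_pooled)
  s <- (edges - stand_mean) / matrix(sdev, n, ncol(edges), byrow = TRUE)

  g_idx <- as.integer(site)
  sum_s <- rowsum(s, g_idx)
  ssq_s <- rowsum(s^2, g_idx)
  gamma_hat <- sum_s / nj
  delta_hat <- (ssq_s - nj * gamma_hat^2) / (nj - 1L)
  delta_hat <- pmax(delta_hat, 1e-12)

  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1L, stats::var)
  d_mean <- rowMeans(delta_hat)
  d_var <- apply(delta_hat, 1L, stats::var)
  a_prior <- (2 * d_var + d_mean^2) / d_var
  b_prior <- (d_mean * d_var + d_mean^3) / d_var

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  if (eb) {
    for (j in seq_len(k)) {
      sol <- eb_shrink_site(gamma_hat[j, ], nj[j], sum_s[j, ], ssq_s[j, ],
                            gamma_bar[j], t2[j], a_prior[j], b_prior[j],
                            delta_hat[j, ], conv, max_iter)
      gamma_star[j, ] <- sol$gamma
      delta_star[j, ] <- sol$delta
    }
  }

  adj <- (s - gamma_star[g_idx, , drop = FALSE]) /
    sqrt(delta_star[g_idx, , drop = FALSE])
  out <- adj * matrix(sdev, n, ncol(edges), byrow = TRUE) + stand_mean
  dimnames(out) <- dimnames(edges)

  model <- structure(list(
    sites = levels(site), n_per_site = nj,
    alpha = alpha, beta_cov = if (is.null(C)) NULL else beta[-seq_len(k), , drop = FALSE],
    covariate_names = if (is.null(C)) NULL else colnames(C),
    covariate_levels = xlevels,
    var_pooled = var_pooled,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    priors = list(gamma_bar = gamma_bar, t2 = t2,
                  a_prior = a_prior, b_prior = b_prior),
    eb = eb
  ), class = "combat_model")
  list(edges = out, model = model)
}

# Iterative conditional posterior updates for one site's location/scale.
eb_shrink_site <- function(gamma_hat, n, sum_s, ssq_s, gamma_bar, t2,
                           a_prior, b_prior, delta_start, conv = 1e-6,
                           max_iter = 100L) {
  g_old <- gamma_hat
  d_old <- delta_start
  it <- 0L
  repeat {
    g_new <- (n * t2 * gamma_hat + d_old * gamma_bar) / (n * t2 + d_old)
    sum2 <- ssq_s - 2 * g_new * sum_s + n * g_new^2
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-8),
                  abs(d_new - d_old) / pmax(abs(d_old), 1e-8))
    g_old <- g_new
    d_old <- d_new
    it <- it + 1L
    if (change < conv || it >= max_iter) break
  }
  list(gamma = g_old, delta = pmax(d_old, 1e-12))
}

#' Apply a fitted ComBat model to new data
#'
#' Supports the fold-wise "fit on train, apply to test" mode: the grand
#' model, pooled variance and the stored per-site corrections of the
#' training fit are applied to held-out subjects. Sites unseen at training
#' time (e.g. the held-out site of a leave-one-site-out loop) have their
#' location/scale estimated from the new data under the trained grand model,
#' with the same moment-matched EB shrinkage across edges; the trained
#' covariate and variance structure is never re-fit.
#'
#' @param model A `combat_model` from [combat_fit_transform()].
#' @param edges Subjects x edges matrix.
#' @param site_ids Site labels; unknown sites need >= 2 subjects each.
#' @param covariates Covariate data frame matching the training design.
#' @return Harmonized matrix.
#' @export
combat_apply <- function(model, edges, site_ids, covariates = NULL) {
  edges <- as.matrix(edges)
  site_ids <- as.character(site_ids)
  g <- match(site_ids, model$sites)
  n <- nrow(edges)
  p <- ncol(edges)
  stand_mean <- matrix(model$alpha, n, p, byrow = TRUE)
  if (!is.null(model$beta_cov)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(model$covariate_levels)) {
      if (!is.null(model$covariate_levels[[nm]])) {
        covariates[[nm]] <- factor(covariates[[nm]],
                                   levels = model$covariate_levels[[nm]])
      }
    }
    C <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
    C <- C[, model$covariate_names, drop = FALSE]
    stand_mean <- stand_mean + C %*% model$beta_cov
  }
  sdev <- matrix(sqrt(model$var_pooled), n, p, byrow = TRUE)
  s <- (edges - stand_mean) / sdev

  gamma <- matrix(NA_real_, n, p)
  delta <- matrix(NA_real_, n, p)
  known <- !is.na(g)
  if (any(known)) {
    gamma[known, ] <- model$gamma_star[g[known], , drop = FALSE]
    delta[known, ] <- model$delta_star[g[known], , drop = FALSE]
  }
  for (new_site in unique(site_ids[!known])) {
    rows <- which(site_ids == new_site)
    if (length(rows) < 2L) {
      stop(sprintf("unknown site '%s' needs >= 2 subjects to be harmonized",
                   new_site), call. = FALSE)
    }
    ns <- length(rows)
    ss <- s[rows, , drop = FALSE]
    sum_s <- colSums(ss)
    ssq_s <- colSums(ss^2)
    g_hat <- sum_s / ns
    d_hat <- pmax((ssq_s - ns * g_hat^2) / (ns - 1L), 1e-12)
    if (model$eb) {
      d_mean <- mean(d_hat)
      d_var <- stats::var(d_hat)
      sol <- eb_shrink_site(g_hat, ns, sum_s, ssq_s,
                            gamma_bar = mean(g_hat), t2 = stats::var(g_hat),
                            a_prior = (2 * d_var + d_mean^2) / d_var,
                            b_prior = (d_mean * d_var + d_mean^3) / d_var,
                            delta_start = d_hat)
      g_hat <- sol$gamma
      d_hat <- sol$delta
    }
    gamma[rows, ] <- matrix(g_hat, ns, p, byrow = TRUE)
    delta[rows, ] <- matrix(d_hat, ns, p, byrow = TRUE)
  }
  out <- (s - gamma) / sqrt(delta) * sdev + stand_mean
  dimnames(out) <- dimnames(edges)
  out
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up procedure at level `q` via `p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical vector of flags (monotone in p).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("validation error: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH") <= q
}

# Vectorized one-way ANOVA across sites, per edge.
anova_f_per_edge <- function(edges, site) {
  g <- as.integer(site)
  k <- nlevels(site)
  n <- nrow(edges)
  nj <- as.vector(table(site))
  M <- rowsum(edges, g) / nj
  grand <- colMeans(edges)
  ssb <- colSums(nj * (M - matrix(grand, k, ncol(edges), byrow = TRUE))^2)
  sst <- colSums(edges^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ssw == 0 & ssb > 0] <- 0
  p[ssw == 0 & ssb <= 1e-300] <- 1
  list(f = f, p = p)
}

#' Audit cross-site differences per edge (one-way ANOVA + BH-FDR)
#'
#' For each edge, an F-test of the edge value across sites (within an
#' optional diagnostic subgroup), with BH-FDR at level `q`. With two sites
#' the F-test is equivalent to a pooled-variance t-test.
#'
#' @param edges Subjects x edges matrix.
#' @param site_ids Site label per row.
#' @param group Optional grouping vector (e.g. diagnosis) per row.
#' @param subset If `group` is given, the group value to analyze
#'   (e.g. "control").
#' @param q FDR level (default 0.05).
#' @return A `site_effect_report`: data frame `per_edge` (edge, F, p, flag)
#'   plus fields `n_edges`, `n_significant`, `percent_significant`, `group`.
#' @export
site_effect_scan <- function(edges, site_ids, group = NULL, subset = NULL,
                             q = 0.05) {
  edges <- as.matrix(edges)
  site_ids <- as.character(site_ids)
  label <- "all"
  if (!is.null(group) && !is.null(subset)) {
    keep <- group == subset
    edges <- edges[keep, , drop = FALSE]
    site_ids <- site_ids[keep]
    label <- as.character(subset)
  }
  site <- factor(site_ids)
  if (nlevels(site) < 2L) {
    stop("analysis error: at least 2 sites are required in the subset",
         call. = FALSE)
  }
  res <- anova_f_per_edge(edges, site)
  flag <- bh_fdr(res$p, q)
  per_edge <- data.frame(
    edge = colnames(edges) %||% sprintf("edge%05d", seq_len(ncol(edges))),
    F = res$f, p = res$p, significant = flag, stringsAsFactors = FALSE)
  structure(list(
    per_edge = per_edge,
    n_edges = ncol(edges),
    n_significant = sum(flag),
    percent_significant = 100 * mean(flag),
    group = label, q = q
  ), class = "site_effect_report")
}

#' @export
print.site_effect_report <- function(x, ...) {
  cat(sprintf(
    "site_effect_scan [%s]: %d of %d edges significant (%.1f%%) at FDR q=%g\n",
    x$group, x$n_significant, x$n_edges, x$percent_significant, x$q))
  invisible(x)
}

#' Write a site-effect report (per-edge CSV + JSON summary)
#' @param report A `site_effect_report`.
#' @param csv_path,json_path Output files (either may be NULL).
#' @export
write_site_effect_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_edge, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(group = report$group, n_edges = report$n_edges,
           n_significant = report$n_significant,
           percent_significant = report$percent_significant, q = report$q),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
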