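# Synthetic multisite cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# multisite case-control resting-state cohort in which (i) regional BOLD time
# series arise from a block-structured multivariate normal, (ii) patients show
# hypoconnectivity concentrated on a designated set of "signal" regions,
# (iii) each acquisition site imprints additive/multiplicative batch effects
# on Fisher-z edges, and (iv) negative-symptom severity tracks each patient's
# individual hypoconnectivity magnitude.

#' Configuration for the synthetic multisite cohort generator
#'
#' Defaults mirror the study conditions of a 6-site schizophrenia cohort:
#' per-site (patients, controls) sample sizes of (301,217), (0,340), (49,63),
#' (32,83), (67,72), (56,132) — one site contributing controls only — 90
#' atlas regions, 200 time points per subject, and a group effect implemented
#' as a reduction of the inter-correlation among 10 signal regions.
#'
#' @param n_regions Number of atlas regions (nodes). Default 90.
#' @param site_sizes List of length-2 integer vectors `c(n_patients,
#'   n_controls)`, one per site. Either exactly one site has zero patients
#'   (case-control cohort) or all sites have zero patients (control-only
#'   cohort, used for harmonization audits).
#' @param n_timepoints Time points per subject. Default 200.
#' @param signal_nodes Integer vector of region indices carrying the group
#'   effect. Default: 10 indices mimicking bilateral amygdala/striatal/
#'   pallidal/thalamic positions of a 90-region anatomical ordering
#'   (41, 42, 71--78); for smaller atlases, evenly spaced indices.
#' @param effect_size Reduction of the inter-signal-node correlation in
#'   patients relative to controls (population mean). Default 0.3.
#' @param site_shift Standard deviation of the per-site additive edge offsets
#'   (Fisher-z units). Default 0.3.
#' @param site_scale Spread of the per-site multiplicative edge factors
#'   (mean 1). Default 0.2.
#' @param symptom_coupling Target correlation between a patient's individual
#'   effect magnitude and their negative-symptom score. Default 0.6.
#' @param base_signal_cor Control-group correlation among signal-node pairs.
#'   Default 0.6.
#' @param block_size Size of the within-network correlation blocks. Default 15.
#' @param within_block_cor Correlation within a block. Default 0.4.
#' @param background_cor Correlation between regions of different blocks.
#'   Default 0.1.
#' @param scale_min,scale_max Declared bounds of the symptom rating scale
#'   (default 7--49, a 7-item 1..7 scale).
#' @param seed Integer seed; all sampling in [generate_cohort()] and
#'   [inject_site_effects()] derives from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_regions = 90L,
                         site_sizes = list(c(301L, 217L), c(0L, 340L),
                                           c(49L, 63L), c(32L, 83L),
                                           c(67L, 72L), c(56L, 132L)),
                         n_timepoints = 200L,
                         signal_nodes = NULL,
                         effect_size = 0.3,
                         site_shift = 0.3,
                         site_scale = 0.2,
                         symptom_coupling = 0.6,
                         base_signal_cor = 0.6,
                         block_size = 15L,
                         within_block_cor = 0.4,
                         background_cor = 0.1,
                         scale_min = 7,
                         scale_max = 49,
                         seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    site_sizes = lapply(site_sizes, function(s) as.integer(s)),
    n_timepoints = as.integer(n_timepoints),
    signal_nodes = if (is.null(signal_nodes)) {
      default_signal_nodes(as.integer(n_regions))
    } else {
      as.integer(signal_nodes)
    },
    effect_size = effect_size,
    site_shift = site_shift,
    site_scale = site_scale,
    symptom_coupling = symptom_coupling,
    base_signal_cor = base_signal_cor,
    block_size = as.integer(block_size),
    within_block_cor = within_block_cor,
    background_cor = background_cor,
    scale_min = scale_min,
    scale_max = scale_max,
    seed = as.integer(seed)
  )
  cfg$n_sites <- length(cfg$site_sizes)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

default_signal_nodes <- function(n_regions) {
  if (n_regions >= 78L) {
    # bilateral amygdala (41,42), caudate/putamen/pallidum/thalamus (71..78)
    c(41L, 42L, 71L:78L)
  } else {
    k <- min(10L, n_regions - 2L)
    if (k < 1L) return(integer(0))
    unique(as.integer(round(seq(2L, n_regions - 1L, length.out = k))))
  }
}

validate_synth_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid synth_config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (cfg$n_regions < 2L) stop_cfg("n_regions", "must be >= 2")
  if (cfg$n_sites < 1L) stop_cfg("site_sizes", "must name at least one site")
  sizes <- vapply(cfg$site_sizes, sum, integer(1))
  if (any(sizes < 2L)) stop_cfg("site_sizes", "every site needs >= 2 subjects")
  n_pat <- vapply(cfg$site_sizes, `[`, integer(1), 1L)
  if (any(n_pat < 0L)) stop_cfg("site_sizes", "counts must be nonnegative")
  if (sum(n_pat) > 0L && sum(n_pat == 0L) != 1L) {
    stop_cfg("site_sizes",
             "must have exactly one control-only site (or no patients at all)")
  }
  if (any(cfg$signal_nodes < 1L) || any(cfg$signal_nodes > cfg$n_regions)) {
    stop_cfg("signal_nodes", "indices must lie in [1, n_regions]")
  }
  if (anyDuplicated(cfg$signal_nodes)) {
    stop_cfg("signal_nodes", "indices must be distinct")
  }
  if (cfg$effect_size < 0) stop_cfg("effect_size", "must be >= 0")
  if (cfg$base_signal_cor >= 0.95 ||
      cfg$base_signal_cor <= cfg$background_cor) {
    stop_cfg("base_signal_cor",
             "must lie between background_cor and 0.95")
  }
  if (cfg$base_signal_cor - cfg$effect_size < 0) {
    stop_cfg("effect_size",
             "may not exceed base_signal_cor (correlation target must stay >= 0)")
  }
  if (cfg$site_shift < 0) stop_cfg("site_shift", "must be >= 0")
  if (cfg$site_scale < 0) stop_cfg("site_scale", "must be >= 0")
  if (abs(cfg$symptom_coupling) > 1) {
    stop_cfg("symptom_coupling", "must lie in [-1, 1]")
  }
  if (cfg$scale_max <= cfg$scale_min) {
    stop_cfg("scale_max", "must exceed scale_min")
  }
  if (cfg$n_timepoints < 3L) stop_cfg("n_timepoints", "must be >= 3")
  invisible(cfg)
}

# Block-structured control correlation matrix with a coherent signal
# subnetwork: R = background * J + block-diagonal exchangeable excesses.
# Signal nodes are detached from their anatomical block and form their own
# exchangeable subnetwork at base_signal_cor, so the matrix is positive
# (semi)definite for any signal correlation >= background - (1-background)/
# (n_signal - 1); the patient-level reduction keeps the target correlation
# >= 0, well inside that bound.
base_correlation <- function(cfg, signal_cor = cfg$base_signal_cor) {
  a <- cfg$n_regions
  blk <- ((seq_len(a) - 1L) %/% cfg$block_size) + 1L
  R <- matrix(cfg$background_cor, a, a)
  same <- outer(blk, blk, `==`)
  R[same] <- cfg$within_block_cor
  sn <- cfg$signal_nodes
  R[sn, ] <- cfg$background_cor
  R[, sn] <- cfg$background_cor
  R[sn, sn] <- signal_cor
  diag(R) <- 1
  R
}

chol_safe <- function(R) {
  lambda <- 0
  repeat {
    Rs <- if (lambda > 0) (1 - lambda) * R + lambda * diag(nrow(R)) else R
    ch <- tryCatch(chol(Rs), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    lambda <- lambda + 0.05
    if (lambda > 0.6) stop("correlation matrix could not be regularized",
                           call. = FALSE)
  }
}

#' Generate a seeded synthetic multisite cohort
#'
#' Draws one BOLD-like multivariate-normal time series per subject. Controls
#' follow the block-structured base correlation; each patient's correlation
#' among the signal nodes is reduced by an individual effect magnitude drawn
#' around `effect_size` (sd = `effect_size`/3, truncated to keep correlations
#' valid). Symptom scores for patients are filled via [generate_symptoms()].
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_cohort` with elements `records` (data frame
#'   of subject covariates and symptom scores), `timeseries` (named list of
#'   timepoints x regions matrices), `effect_magnitudes` (per-subject, 0 for
#'   controls), `region_labels`, and `config`.
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  cfg <- config
  withr::with_seed(cfg$seed, {
    R0 <- base_correlation(cfg)
    ch0 <- chol_safe(R0)
    sn <- cfg$signal_nodes

    site_id <- character(0)
    diagnosis <- character(0)
    for (s in seq_len(cfg$n_sites)) {
      np <- cfg$site_sizes[[s]][1L]
      nc <- cfg$site_sizes[[s]][2L]
      site_id <- c(site_id, rep(sprintf("site%d", s), np + nc))
      diagnosis <- c(diagnosis, rep("patient", np), rep("control", nc))
    }
    n <- length(site_id)
    subject_id <- sprintf("sub%04d", seq_len(n))
    is_pat <- diagnosis == "patient"

    age <- ifelse(is_pat, stats::rnorm(n, 28, 8), stats::rnorm(n, 31, 10))
    age <- round(pmin(pmax(age, 18), 65), 1)
    sex <- ifelse(stats::runif(n) < ifelse(is_pat, 0.65, 0.5), "M", "F")

    # individual hypoconnectivity magnitude (0 for controls); truncated so
    # the patient signal correlation stays nonnegative (PSD guarantee)
    mag <- numeric(n)
    if (any(is_pat)) {
      m <- stats::rnorm(sum(is_pat), cfg$effect_size, cfg$effect_size / 3)
      upper <- cfg$base_signal_cor - 0.005
      mag[is_pat] <- pmin(pmax(m, 0), upper)
    }

    ts <- vector("list", n)
    names(ts) <- subject_id
    tp <- cfg$n_timepoints
    a <- cfg$n_regions
    for (i in seq_len(n)) {
      Zi <- matrix(stats::rnorm(tp * a), tp, a)
      if (mag[i] > 0) {
        Ri <- base_correlation(cfg, cfg$base_signal_cor - mag[i])
        ts[[i]] <- Zi %*% chol_safe(Ri)
      } else {
        ts[[i]] <- Zi %*% ch0
      }
      colnames(ts[[i]]) <- region_labels(a)
    }

    records <- data.frame(
      subject_id = subject_id,
      site_id = site_id,
      diagnosis = diagnosis,
      age = age,
      sex = sex,
      symptom_positive = NA_real_,
      symptom_negative = NA_real_,
      scale_min = cfg$scale_min,
      scale_max = cfg$scale_max,
      stringsAsFactors = FALSE
    )
    records <- generate_symptoms(records, mag, cfg)
  })
  structure(
    list(records = records, timeseries = ts, effect_magnitudes = mag,
         region_labels = region_labels(cfg$n_regions), config = cfg),
    class = "synth_cohort"
  )
}

#' @export
print.synth_cohort <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "synth_cohort: %d subjects (%d patients / %d controls), %d sites, %d regions\n",
    nrow(r), sum(r$diagnosis == "patient"), sum(r$diagnosis == "control"),
    length(unique(r$site_id)), x$config$n_regions))
  invisible(x)
}

#' Region label vector
#'
#' @param a Number of regions.
#' @return Character vector `R001`, `R002`, ...
#' @export
region_labels <- function(a) sprintf("R%03d", seq_len(a))

#' Inject per-site additive/multiplicative batch effects into Fisher-z edges
#'
#' Each site `s` draws, once from the configured seed, a per-edge additive
#' offset `gamma[s, e] ~ N(0, site_shift^2)` and a positive multiplicative
#' factor `delta[s, e]` with mean 1 and spread `site_scale`; edge values are
#' mapped `y -> gamma + delta * y`. The input matrix is not modified.
#'
#' @param z_edges Subjects x edges matrix of Fisher-z values.
#' @param site_ids Character/factor vector, one per row of `z_edges`.
#' @param config A [synth_config()] (fields `site_shift`, `site_scale`,
#'   `seed` are used).
#' @return Matrix of the same shape, with attributes `gamma` and `delta`
#'   (site x edge matrices of the drawn parameters, rownames = site).
#' @export
inject_site_effects <- function(z_edges, site_ids, config) {
  if (nrow(z_edges) != length(site_ids)) {
    stop(sprintf("shape error: %d rows of z_edges but %d site ids",
                 nrow(z_edges), length(site_ids)), call. = FALSE)
  }
  sites <- sort(unique(as.character(site_ids)))
  p <- ncol(z_edges)
  withr::with_seed(config$seed + 777L, {
    gamma <- matrix(stats::rnorm(length(sites) * p, 0, config$site_shift),
                    length(sites), p, dimnames = list(sites, colnames(z_edges)))
    delta <- matrix(pmax(stats::rnorm(length(sites) * p, 1, config$site_scale),
                         0.05),
                    length(sites), p, dimnames = list(sites, colnames(z_edges)))
  })
  g <- match(as.character(site_ids), sites)
  out <- z_edges * delta[g, , drop = FALSE] + gamma[g, , drop = FALSE]
  dimnames(out) <- dimnames(z_edges)
  attr(out, "gamma") <- gamma
  attr(out, "delta") <- delta
  out
}

#' Fill in symptom scores coupled to individual effect magnitudes
#'
#' Patients' negative-symptom raw score is
#' `scale_min + range * (0.5 + z/6)` where
#' `z = coupling * standardized(magnitude) + sqrt(1 - coupling^2) * noise`,
#' clipped to the declared scale bounds; positive-symptom scores are
#' uncoupled noise on the same scale. Controls are left `NA`.
#'
#' @param records Subject data frame (as in [generate_cohort()]).
#' @param effect_magnitudes Numeric vector, one per record (0 for controls).
#' @param config A [synth_config()].
#' @return `records` with `symptom_positive` / `symptom_negative` filled for
#'   patients.
#' @export
generate_symptoms <- function(records, effect_magnitudes, config) {
  if (abs(config$symptom_coupling) > 1) {
    stop("configuration error: symptom_coupling must lie in [-1, 1]",
         call. = FALSE)
  }
  is_pat <- records$diagnosis == "patient"
  if (!any(is_pat)) return(records)
  m <- effect_magnitudes[is_pat]
  if (length(m) != sum(is_pat)) {
    stop("one effect magnitude per patient is required", call. = FALSE)
  }
  zm <- if (stats::sd(m) > 0) (m - mean(m)) / stats::sd(m) else numeric(length(m)) * 0
  cc <- config$symptom_coupling
  z <- cc * zm + sqrt(max(0, 1 - cc^2)) * stats::rnorm(length(m))
  rng <- config$scale_max - config$scale_min
  to_scale <- function(zz) {
    pmin(pmax(config$scale_min + rng * (0.5 + zz / 6), config$scale_min),
         config$scale_max)
  }
  records$symptom_negative[is_pat] <- round(to_scale(z), 1)
  records$symptom_positive[is_pat] <- round(to_scale(stats::rnorm(length(m))), 1)
  records
}

#' Write the subject table as CSV
#' @param records Subject data frame.
#' @param path Output file.
#' @export
write_subject_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject table written by [write_subject_table()]
#' @param path CSV file.
#' @return Data frame.
#' @export
read_subject_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write one subject's ROI time series as TSV (rows = timepoints)
#' @param ts Timepoints x regions matrix.
#' @param path Output file.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ROI time-series TSV
#' @param path TSV file with a header row of region labels.
#' @return Numeric matrix.
#' @export
read_timeseries <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE))
}

#' Write the atlas label file (index, region_name)
#' @param labels Character vector of region names.
#' @param path Output file.
#' @export
write_atlas <- function(labels, path) {
  utils::write.table(
    data.frame(index = seq_along(labels), region_name = labels),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
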