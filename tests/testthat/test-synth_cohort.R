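test_that("default configuration mirrors the six-site cohort and rejects bad fields", {
  cfg <- synth_config()
  expect_s3_class(cfg, "synth_config")
  expect_equal(cfg$n_sites, 6L)
  n_pat <- vapply(cfg$site_sizes, `[`, integer(1), 1L)
  n_con <- vapply(cfg$site_sizes, `[`, integer(1), 2L)
  expect_equal(sum(n_pat == 0L), 1L)   # one control-only site
  expect_equal(sum(n_pat), 505L)
  expect_equal(sum(n_con), 907L)
  expect_length(cfg$signal_nodes, 10L)

  expect_error(synth_config(n_regions = 1), "n_regions")
  expect_error(synth_config(site_sizes = list(c(1L, 0L), c(2L, 2L))),
               "site_sizes")
  expect_error(synth_config(site_sizes = list(c(3L, 2L), c(3L, 2L))),
               "control-only")
  expect_error(synth_config(signal_nodes = c(1L, 999L)), "signal_nodes")
  expect_error(synth_config(effect_size = 0.9), "effect_size")
  expect_error(synth_config(symptom_coupling = 1.5), "symptom_coupling")
})

test_that("generation is bitwise deterministic given the seed", {
  cfg <- synth_config(n_regions = 20L,
                      site_sizes = list(c(4L, 4L), c(0L, 5L), c(4L, 4L)),
                      n_timepoints = 50L, seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$effect_magnitudes, b$effect_magnitudes)
  # one time series per record, no constant columns, finite values
  expect_length(a$timeseries, nrow(a$records))
  expect_true(all(vapply(a$timeseries, function(m) all(is.finite(m)),
                         logical(1))))
  expect_true(all(vapply(a$timeseries,
                         function(m) min(apply(m, 2, stats::sd)) > 0,
                         logical(1))))
})

test_that("patients' signal-node correlations drop by the configured effect size", {
  sn <- seq(3L, 30L, 3L)
  cfg <- synth_config(n_regions = 40L,
                      site_sizes = list(c(40L, 38L), c(0L, 2L)),
                      signal_nodes = sn, effect_size = 0.3, seed = 3L)
  co <- generate_cohort(cfg)
  mean_signal_cor <- function(idx) {
    mean(vapply(idx, function(i) {
      r <- stats::cor(co$timeseries[[i]])[sn, sn]
      mean(r[upper.tri(r)])
    }, numeric(1)))
  }
  pat <- which(co$records$diagnosis == "patient")
  con <- which(co$records$diagnosis == "control")
  delta <- mean_signal_cor(pat) - mean_signal_cor(con)
  expect_lt(abs(delta - (-0.3)), 0.05)
})

test_that("the group effect is localized: off-signal edges are unaffected", {
  sn <- seq(3L, 30L, 3L)
  cfg <- synth_config(n_regions = 40L,
                      site_sizes = list(c(200L, 198L), c(0L, 2L)),
                      signal_nodes = sn, effect_size = 0.4, seed = 9L)
  co <- generate_cohort(cfg)
  cms <- connectomes_from_timeseries(co$timeseries)
  E <- cohort_edge_table(cms)
  is_pat <- co$records$diagnosis == "patient"
  dz <- colMeans(E[is_pat, ]) - colMeans(E[!is_pat, ])
  ei <- edge_index(cfg$n_regions)
  off_signal <- !(ei$i %in% sn) & !(ei$j %in% sn)
  expect_lt(max(abs(dz[off_signal])), 0.05)
  # and the signal edges do move
  on_signal <- (ei$i %in% sn) & (ei$j %in% sn)
  expect_lt(mean(dz[on_signal]), -0.2)
})

test_that("site-effect injection: zero parameters are the identity map", {
  cfg <- synth_config(n_regions = 10L,
                      site_sizes = list(c(0L, 3L), c(0L, 3L)),
                      site_shift = 0, site_scale = 0, seed = 1L)
  E <- matrix(rnorm(6 * 45), 6, 45)
  out <- inject_site_effects(E, rep(c("s1", "s2"), each = 3), cfg)
  expect_equal(unclass(out), E, ignore_attr = TRUE)
  expect_error(inject_site_effects(E, c("s1", "s2"), cfg), "shape error")
})

test_that("between-site edge shifts recover the drawn per-site offsets", {
  cfg <- synth_config(n_regions = 20L,
                      site_sizes = list(c(0L, 60L), c(0L, 60L)),
                      site_shift = 0.5, site_scale = 0, seed = 21L)
  co <- generate_cohort(cfg)
  E <- cohort_edge_table(connectomes_from_timeseries(co$timeseries))
  Er <- inject_site_effects(E, co$records$site_id, cfg)
  gamma <- attr(Er, "gamma")
  s1 <- co$records$site_id == "site1"
  obs <- colMeans(Er[s1, ]) - colMeans(Er[!s1, ])
  expected <- gamma["site1", ] - gamma["site2", ]
  expect_gt(stats::cor(obs, expected), 0.99)
  expect_lt(max(abs(obs - expected)), 0.12)
})

test_that("symptom scores track the planted effect magnitude at the configured coupling", {
  n <- 200L
  rec <- data.frame(subject_id = sprintf("s%03d", 1:n), site_id = "site1",
                    diagnosis = "patient", age = 30, sex = "M",
                    symptom_positive = NA_real_, symptom_negative = NA_real_,
                    scale_min = 7, scale_max = 49)
  mag <- withr::with_seed(4L, pmax(rnorm(n, 0.3, 0.1), 0))

  cfg6 <- synth_config(symptom_coupling = 0.6, seed = 1L)
  rec6 <- withr::with_seed(11L, generate_symptoms(rec, mag, cfg6))
  r6 <- stats::cor(mag, rec6$symptom_negative)
  expect_lt(abs(r6 - 0.6), 0.1)
  expect_true(all(rec6$symptom_negative >= 7 & rec6$symptom_negative <= 49))

  cfg0 <- synth_config(symptom_coupling = 0, seed = 1L)
  rec0 <- withr::with_seed(12L, generate_symptoms(rec, mag, cfg0))
  expect_lt(abs(stats::cor(mag, rec0$symptom_negative)), 0.15)

  # degenerate input: constant magnitudes explain no score variance
  recc <- withr::with_seed(13L, generate_symptoms(rec, rep(0.3, n), cfg6))
  fit <- stats::lm(recc$symptom_negative ~ rep(0.3, n))
  expect_equal(summary(fit)$r.squared, 0)

  bad <- cfg6
  bad$symptom_coupling <- 2
  expect_error(generate_symptoms(rec, mag, bad), "configuration error")
})

test_that("cohort files round-trip through the documented text formats", {
  cfg <- synth_config(n_regions = 8L, site_sizes = list(c(2L, 2L), c(0L, 2L)),
                      n_timepoints = 20L, signal_nodes = c(2L, 5L), seed = 2L)
  co <- generate_cohort(cfg)
  tab <- withr::local_tempfile(fileext = ".csv")
  write_subject_table(co$records, tab)
  expect_equal(read_subject_table(tab), co$records, tolerance = 1e-12)
  tsf <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries(co$timeseries[[1L]], tsf)
  expect_equal(read_timeseries(tsf), co$timeseries[[1L]],
               ignore_attr = TRUE, tolerance = 1e-6)
  atl <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(co$region_labels, atl)
  expect_equal(utils::read.delim(atl)$region_name, co$region_labels)
})
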