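# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately share no code with the package: shortest
# paths via Floyd-Warshall, betweenness via exhaustive simple-path
# enumeration, and fixtures built from raw distributions.

# All-pairs shortest path lengths under edge length = 1/weight.
bf_shortest_paths <- function(W) {
  n <- nrow(W)
  L <- matrix(Inf, n, n)
  L[W > 0] <- 1 / W[W > 0]
  diag(L) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (L[i, k] + L[k, j] < L[i, j]) L[i, j] <- L[i, k] + L[k, j]
      }
    }
  }
  L
}

bf_nodal_efficiency <- function(W) {
  n <- nrow(W)
  L <- bf_shortest_paths(W)
  inv <- 1 / L
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

# Enumerate all simple paths s -> t; return list(lengths, interior node sets).
bf_enumerate_paths <- function(W, s, t) {
  n <- nrow(W)
  lengths <- numeric(0)
  interiors <- list()
  walk <- function(v, visited, len) {
    if (v == t) {
      lengths[[length(lengths) + 1L]] <<- len
      interiors[[length(interiors) + 1L]] <<- setdiff(visited, c(s, t))
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (W[v, u] > 0 && !(u %in% visited)) {
        walk(u, c(visited, u), len + 1 / W[v, u])
      }
    }
  }
  walk(s, s, 0)
  list(lengths = lengths, interiors = interiors)
}

bf_nodal_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  bet <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- bf_enumerate_paths(W, s, t)
      if (!length(paths$lengths)) next
      dmin <- min(paths$lengths)
      on_short <- which(paths$lengths <= dmin + tol)
      sigma <- length(on_short)
      for (pi in on_short) {
        for (v in paths$interiors[[pi]]) bet[v] <- bet[v] + 1 / sigma
      }
    }
  }
  bet
}

# Random connected-ish weighted graph with continuous weights (no ties).
random_weighted_graph <- function(n, density = 0.5) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on <- up[stats::runif(length(up)) < density]
  W[on] <- stats::runif(length(on), 0.1, 1)
  W <- W + t(W)
  W
}

# Small synthetic cohort -> list(cohort, conn matrices, edge table).
make_small_cohort <- function(site_sizes = list(c(10L, 10L), c(0L, 4L),
                                                c(10L, 10L)),
                              n_regions = 30L, n_timepoints = 80L,
                              effect_size = 0.4, seed = 5L, ...) {
  cfg <- synth_config(n_regions = n_regions, site_sizes = site_sizes,
                      n_timepoints = n_timepoints, effect_size = effect_size,
                      seed = seed, ...)
  cohort <- generate_cohort(cfg)
  cms <- connectomes_from_timeseries(cohort$timeseries)
  list(config = cfg, cohort = cohort, cms = cms,
       edges = cohort_edge_table(cms))
}
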