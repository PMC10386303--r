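## Independent oracles and fixture builders shared across the suite.

## UPGMA oracle built from the defining property rather than the recursive
## update: the linkage between two clusters is the plain mean of all
## cross-pair distances in the ORIGINAL matrix.  At every step the closest
## pair (first found under the scan order) is merged.  Only fusion heights
## are compared against the package implementation, so the differing tie
## scan order is irrelevant.
naive_upgma_heights <- function(d0) {
  n <- nrow(d0)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        dij <- mean(d0[clusters[[i]], clusters[[j]], drop = FALSE])
        if (dij < best[1L]) best <- c(dij, i, j)
      }
    }
    heights <- c(heights, best[1L])
    merged <- c(clusters[[best[2L]]], clusters[[best[3L]]])
    clusters <- c(clusters[-c(best[2L], best[3L])], list(merged))
  }
  heights
}

## Exact two-sided rank-sum p-value by full enumeration of all
## choose(n1 + n2, n1) group labelings of the pooled ranks.
enum_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(pooled), n1)
  w_all <- apply(splits, 2L, function(ix) sum(r[ix]))
  mu <- n1 * (length(pooled) + 1) / 2
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

## Random Euclidean distance matrix over n points in `dim` dimensions.
random_euclidean_dm <- function(n, dim = 3) {
  pts <- matrix(rnorm(n * dim), nrow = n)
  rownames(pts) <- paste0("s", seq_len(n))
  euclidean_distances(pts)
}

## Random symmetric non-metric "distance" matrix (positive off-diagonal).
random_nonmetric_dm <- function(n) {
  m <- matrix(runif(n * n, 0.1, 10), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  m
}

## Tiny hand-written Kaiju fixture on disk; returns the path.
write_kaiju_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f, useBytes = TRUE)
  f
}

## Small generator configuration for fast materialized runs.
small_config <- function(seed, read_total = 2000,
                         samples = c(SRF = 2L, DCM = 2L, MES = 2L),
                         n_stations = 2L,
                         go_exclusive = c(SRF = 5L, DCM = 8L, MES = 3L)) {
  generator_config(
    n_stations = n_stations,
    samples_per_station_layer = samples,
    species_pool_size = c(Archaea = 40L, Bacteria = 120L, Viruses = 60L),
    richness_by_layer = c(SRF = 25L, DCM = 25L, MES = 60L),
    lognormal_sigma = 1.5,
    domain_mix_by_layer = matrix(
      c(0.03, 0.79, 0.18,
        0.05, 0.78, 0.17,
        0.13, 0.84, 0.03),
      nrow = 3, byrow = TRUE,
      dimnames = list(LAYERS, DOMAINS)),
    read_total_range = c(read_total, 3 * read_total),
    go_terms_shared = 60L,
    go_terms_exclusive_by_layer = go_exclusive,
    seed = seed)
}

## Hand-built dendrogram with prescribed chain heights, for stopping-rule
## tests that need exact fusion heights.
chain_dendrogram <- function(heights) {
  n <- length(heights) + 1L
  merge <- matrix(0L, n - 1L, 2L)
  merge[1L, ] <- c(-1L, -2L)
  if (n > 2L) {
    for (j in 2L:(n - 1L)) merge[j, ] <- c(-(j + 1L), j - 1L)
  }
  structure(
    list(merge = merge, height = heights,
         size = seq(2L, n),
         order = if (n == 2L) 1:2 else c(n:3, 1L, 2L),
         labels = paste0("s", seq_len(n)), n = n),
    class = "upgma_dendrogram")
}
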