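## Shared fixtures: built once per test run, in code (no binary files).

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## A small study configuration used by the slower integration tests.
## Density of features per megabase matches the generator defaults
## (60 SEs / 300 typical enhancers / 1000 genes on 10 Mb), scaled to 0.3x.
small_config <- function(...) {
  synthetic_config(genome_length = 3e6, n_genes = 300, n_ses = 18,
                   n_typical = 90,
                   group_counts = c(strong_up = 71, weak_up = 75,
                                    strong_down = 26, weak_down = 116),
                   ...)
}

## Cache a simulated small study per seed across tests in one run.
.sim_cache <- new.env(parent = emptyenv())
small_study <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_study(small_config(), seed = seed)
  .sim_cache[[key]]
}

## Memoized full-defaults study (larger; built at most once per run).
default_study <- function(seed = 1) {
  key <- paste0("d", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_study(synthetic_config(), seed = seed)
  .sim_cache[[key]]
}

## Write BED lines to a tempfile that lives until the calling frame exits.
local_bed <- function(lines, .local_envir = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = .local_envir)
  writeLines(lines, f)
  f
}

## Deterministic toy track: explicit per-base depths on one chromosome.
toy_track <- function(depth, library_size = 1e6, label = "toy",
                      chrom = "chr1") {
  CoverageTrack(setNames(list(depth), chrom), library_size, label)
}

## Brute-force Shannon entropy in bits (independent of region_entropy).
shannon_bits <- function(d, eps = 0) {
  p <- (d + eps) / sum(d + eps)
  p <- p[p > 0]
  -sum(p * log2(p))
}

## Independent Wilcoxon signed-rank oracle: full enumeration of sign
## patterns, written as a direct double loop (no rank-vector reuse from the
## implementation beyond base R's rank()).
wilcoxon_oracle <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[1:n]
    ws[m + 1] <- sum(r[bits == 1])
  }
  p_ge <- mean(ws >= W - 1e-12)
  p_le <- mean(ws <= W + 1e-12)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

## Brute-force KS statistic: scan |F_x - F_y| over a dense grid of pooled
## points and midpoints.
ks_oracle_stat <- function(x, y) {
  pts <- sort(c(x, y))
  grid <- sort(c(pts, pts - 1e-9, pts + 1e-9))
  fx <- vapply(grid, function(t) mean(x <= t), numeric(1))
  fy <- vapply(grid, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

## Best per-region Jaccard of truth regions against a called set.
best_jaccard <- function(truth, called) {
  vapply(seq_along(truth), function(i) {
    ov <- findOverlaps(truth[i], called)
    if (length(ov) == 0) return(0)
    max(vapply(subjectHits(ov), function(j) {
      wi <- width(pintersect(truth[i], called[j]))
      wi / (width(truth[i]) + width(called[j]) - wi)
    }, numeric(1)))
  }, numeric(1))
}
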