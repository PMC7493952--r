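#' Epigenetic entropy of genomic regions
#'
#' The epigenetic entropy of a region is the Shannon entropy (in bits) of
#' the probability mass function obtained by normalizing the per-base read
#' density along that region: `p_i = (d_i + eps) / sum_j (d_j + eps)`,
#' `H = -sum p_i log2 p_i`.  Low entropy means the signal is concentrated
#' in sharp peaks (high polarization); entropy `log2(L)` means perfectly
#' uniform signal.  H is invariant to any positive rescaling of the track
#' (library size and the density scale cancel in the pmf).
#'
#' The default pseudocount follows the region: `eps = 1e-3 * mean(d) +
#' 1e-9` per base, so an all-zero region is flagged rather than silently
#' scored as maximally uniform.
#'
#' @param track A [CoverageTrack()].
#' @param regions [GenomicRanges::GRanges]; each region must span at least
#'   2 bases.
#' @param eps Pseudocount per base in density units, or `NULL` for the
#'   adaptive default.  With `eps = 0`, an all-zero region is an error.
#' @param scale Density scale (has no effect on H; kept for the `mass`
#'   column).
#' @return A data.frame with one row per region: `region_id`, `chrom`,
#'   `start` (0-based), `end`, `length`, `entropy` (bits), `entropy_norm`
#'   (`H / log2(length)`), `mass` (summed density), `eps`.
#' @export
#' @examples
#' trk <- CoverageTrack(list(chr1 = c(1, 1, 2)), 1e6)
#' region_entropy(trk, GenomicRanges::GRanges("chr1:1-3"), eps = 0)$entropy
#' # 1.5 bits: p = (0.25, 0.25, 0.5)
region_entropy <- function(track, regions, eps = NULL, scale = 1e6) {
  .check_track(track)
  stopifnot(is(regions, "GRanges"))
  if (any(GenomicRanges::width(regions) < 2))
    stop("regions must span at least 2 bases")
  .check_region_bounds(track, regions)
  ids <- if (!is.null(names(regions))) names(regions) else
    paste0("region", seq_along(regions))
  n <- length(regions)
  H <- mass <- eps_used <- numeric(n)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  for (i in seq_len(n)) {
    d <- as.numeric(S4Vectors::window(track$coverage[[chrom[i]]],
                                      GenomicRanges::start(regions)[i],
                                      GenomicRanges::end(regions)[i])) *
      scale / track$library_size
    e <- if (is.null(eps)) 1e-3 * mean(d) + 1e-9 * scale /
      track$library_size else eps
    if (sum(d) == 0 && e == 0)
      stop("undefined entropy: all-zero region '", ids[i],
           "' with eps = 0")
    p <- (d + e) / sum(d + e)
    nz <- p > 0
    H[i] <- -sum(p[nz] * log2(p[nz]))
    mass[i] <- sum(d)
    eps_used[i] <- e
  }
  data.frame(region_id = ids, chrom = chrom,
             start = GenomicRanges::start(regions) - 1L,
             end = GenomicRanges::end(regions),
             length = GenomicRanges::width(regions),
             entropy = H,
             entropy_norm = H / log2(GenomicRanges::width(regions)),
             mass = mass, eps = eps_used,
             stringsAsFactors = FALSE)
}

#' Entropy differences between two libraries over fixed regions
#'
#' For every region, `delta = H_a - H_b` with both entropies computed over
#' the same interval, so the `log2(L)` length dependence cancels by
#' construction.  A positive delta means the signal in `track_a` is flatter
#' (less polarized) than in `track_b`.
#'
#' @param track_a,track_b [CoverageTrack()]s (e.g. force and control).
#' @param regions [GenomicRanges::GRanges] evaluated in both tracks.
#' @param contrast Label stored with the deltas.
#' @inheritParams region_entropy
#' @return List with `deltas` (data.frame: `region_id`, `length`,
#'   `entropy_a`, `entropy_b`, `delta`, `contrast`) and `summary`
#'   (five-number summary of delta: min, Q1, median, Q3, max).
#' @export
entropy_deltas <- function(track_a, track_b, regions,
                           contrast = paste(track_a$label, "-",
                                            track_b$label),
                           eps = NULL, scale = 1e6) {
  ha <- region_entropy(track_a, regions, eps, scale)
  hb <- region_entropy(track_b, regions, eps, scale)
  d <- data.frame(region_id = ha$region_id, length = ha$length,
                  entropy_a = ha$entropy, entropy_b = hb$entropy,
                  delta = ha$entropy - hb$entropy,
                  contrast = contrast, stringsAsFactors = FALSE)
  fn <- fivenum(d$delta)
  names(fn) <- c("min", "q1", "median", "q3", "max")
  list(deltas = d, summary = fn)
}

#' Matched-length random background regions
#'
#' Draws, for each input region, one interval of identical length placed
#' uniformly at random on the genome, rejection-sampled against an
#' exclusion set (by default the input regions themselves), so the output
#' length multiset equals the input's.  Deterministic under a seed.
#'
#' @param regions [GenomicRanges::GRanges] whose lengths are matched.
#' @param seqlengths Named vector of chromosome lengths.
#' @param seed Integer seed.
#' @param exclude [GenomicRanges::GRanges] the output must not intersect;
#'   defaults to `regions`.
#' @param max_tries Placement attempts per region before a capacity error.
#' @return [GenomicRanges::GRanges] parallel to `regions`, named
#'   `bg_<region_id>`.
#' @export
matched_background_regions <- function(regions, seqlengths, seed = 1,
                                       exclude = regions,
                                       max_tries = 1000) {
  stopifnot(is(regions, "GRanges"), length(seqlengths) >= 1)
  withr::with_seed(derive_seed(seed, 41L), {
    chroms <- names(seqlengths)
    probs <- as.numeric(seqlengths) / sum(as.numeric(seqlengths))
    w <- GenomicRanges::width(regions)
    out_ch <- character(length(regions))
    out_st <- integer(length(regions))
    placed <- exclude
    for (i in seq_along(regions)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        ch <- sample(chroms, 1, prob = probs)
        if (seqlengths[[ch]] < w[i]) next
        s <- floor(runif(1, 1, seqlengths[[ch]] - w[i] + 1))
        cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, s + w[i] - 1))
        if (!any(IRanges::overlapsAny(cand, placed,
                                      ignore.strand = TRUE))) {
          out_ch[i] <- ch; out_st[i] <- s
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("capacity error: could not place background region of length ",
             w[i], " after ", max_tries, " tries")
    }
    bg <- GenomicRanges::GRanges(out_ch, IRanges::IRanges(out_st,
                                                          width = w))
    ids <- if (!is.null(names(regions))) names(regions) else
      seq_along(regions)
    names(bg) <- paste0("bg_", ids)
    bg
  })
}

#' Wilcoxon signed-rank test
#'
#' One-sample signed-rank test on paired differences: zeros are dropped
#' (Wilcoxon convention), absolute values are ranked with mid-rank ties,
#' and W is the sum of ranks of positive differences.  For `n <= 12`
#' retained differences the p-value is exact, by enumerating all `2^n`
#' sign patterns of the observed (possibly tied) ranks; above that a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param deltas Numeric vector of differences.
#' @param alternative `"two.sided"`, `"greater"` (positive shift) or
#'   `"less"`.
#' @param exact_max Largest n for which the exact enumeration is used.
#' @return List with `statistic` (W), `n` (nonzero differences),
#'   `p_value`, `method`.
#' @export
wilcoxon_signed_rank <- function(deltas,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 exact_max = 12) {
  alternative <- match.arg(alternative)
  d <- deltas[deltas != 0]
  n <- length(d)
  if (n == 0) stop("degenerate input: all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    ## exact null: each difference is positive with prob 1/2 independently
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wnull <- as.numeric(signs %*% r)
    p_ge <- mean(Wnull >= W - 1e-12)
    p_le <- mean(Wnull <= W + 1e-12)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5
    z_ge <- (W - mu - cc) / sqrt(sigma2)
    z_le <- (W - mu + cc) / sqrt(sigma2)
    p <- switch(alternative,
                greater = pnorm(z_ge, lower.tail = FALSE),
                less = pnorm(z_le),
                two.sided = min(1, 2 * min(pnorm(z_ge, lower.tail = FALSE),
                                           pnorm(z_le))))
    method <- "normal approximation"
  }
  list(statistic = W, n = n, p_value = p, method = method)
}

#' Entropy-delta ecdf report across labeled sets
#'
#' Summarizes several labeled sets of entropy deltas (e.g. input-vs-input
#' background, force-control, force.oeEZH2-control, and their
#' matched-background counterparts): the ecdf of each set, a signed-rank
#' test of each set against zero, and a pairwise comparison of each
#' non-control set against the designated control set (both a rank-sum
#' style comparison via the KS test of the two delta samples and, when the
#' sets are paired region-by-region, a signed-rank test of their
#' difference).  The maximum p-value across the pairwise comparisons is
#' reported.
#'
#' @param delta_sets Named list of numeric delta vectors (>= 2 sets).
#' @param control Name of the control/background set; default the first.
#' @param paired Logical: are sets parallel (same regions in order)?
#' @return List with `ecdf` (long data.frame `set`, `delta`, `f`),
#'   `vs_zero` (per-set signed-rank results incl. median and BH-adjusted
#'   p), `vs_control` (per-set comparison to the control set), and
#'   `max_p_vs_control`.
#' @export
delta_ecdf_report <- function(delta_sets, control = names(delta_sets)[1],
                              paired = FALSE) {
  stopifnot(is.list(delta_sets), length(delta_sets) >= 2,
            !is.null(names(delta_sets)), control %in% names(delta_sets))
  if (any(lengths(delta_sets) == 0)) stop("empty delta set")
  ec <- do.call(rbind, lapply(names(delta_sets), function(nm) {
    s <- sort(delta_sets[[nm]])
    data.frame(set = nm, delta = s, f = seq_along(s) / length(s),
               stringsAsFactors = FALSE)
  }))
  vs_zero <- do.call(rbind, lapply(names(delta_sets), function(nm) {
    d <- delta_sets[[nm]]
    res <- tryCatch(wilcoxon_signed_rank(d), error = function(e) NULL)
    data.frame(set = nm, n = length(d), median = stats::median(d),
               W = if (is.null(res)) NA_real_ else res$statistic,
               p_value = if (is.null(res)) NA_real_ else res$p_value,
               stringsAsFactors = FALSE)
  }))
  vs_zero$p_adj_bh <- p.adjust(vs_zero$p_value, "BH")
  others <- setdiff(names(delta_sets), control)
  vs_control <- do.call(rbind, lapply(others, function(nm) {
    a <- delta_sets[[nm]]; b <- delta_sets[[control]]
    ks <- ks_two_sample(a, b)
    p_paired <- NA_real_
    if (paired && length(a) == length(b))
      p_paired <- tryCatch(wilcoxon_signed_rank(a - b)$p_value,
                           error = function(e) NA_real_)
    data.frame(set = nm, control = control,
               ks_d = ks$statistic, ks_p = ks$p_value,
               signed_rank_p = p_paired, stringsAsFactors = FALSE)
  }))
  pcols <- c(vs_control$ks_p, vs_control$signed_rank_p)
  list(ecdf = ec, vs_zero = vs_zero, vs_control = vs_control,
       max_p_vs_control = max(pcols, na.rm = TRUE))
}

#' Promoter entropy contrasts per gene group
#'
#' For every gene, computes H3K27ac entropy over the promoter window
#' `[TSS - h, TSS + h)` in each condition and reports the two contrasts
#' `dH_force = H(force) - H(control)` and `dH_force_oe =
#' H(force + oeEZH2) - H(control)`; per gene group, a paired signed-rank
#' test asks whether preserving EZH2 shifts promoter entropy beyond the
#' force effect alone.
#'
#' @param track_control,track_force,track_force_oe H3K27ac
#'   [CoverageTrack()]s per condition.
#' @param tss TSS [GenomicRanges::GRanges] named by gene id.
#' @param gene_groups Named character vector: subgroup label per gene id.
#' @param half_width Promoter half-width h (default 2500 bases).
#' @inheritParams region_entropy
#' @return List with `per_gene` (data.frame `gene_id`, `group`,
#'   `dh_force`, `dh_force_oe`) and `per_group` (data.frame with paired
#'   signed-rank p per group and the two median deltas).
#' @export
promoter_entropy_contrast <- function(track_control, track_force,
                                      track_force_oe, tss, gene_groups,
                                      half_width = 2500, eps = NULL,
                                      scale = 1e6) {
  stopifnot(half_width > 0, !is.null(names(gene_groups)))
  genes <- intersect(names(gene_groups), names(tss))
  g <- tss[genes]
  chrom <- as.character(GenomicRanges::seqnames(g))
  center <- GenomicRanges::start(g) - 1
  lens <- track_control$seqlengths[chrom]
  win <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(
                                  pmax(1, center - half_width + 1),
                                  pmin(lens, center + half_width)))
  names(win) <- genes
  h_ctrl <- region_entropy(track_control, win, eps, scale)$entropy
  h_force <- region_entropy(track_force, win, eps, scale)$entropy
  h_oe <- region_entropy(track_force_oe, win, eps, scale)$entropy
  per_gene <- data.frame(gene_id = genes,
                         group = unname(gene_groups[genes]),
                         dh_force = h_force - h_ctrl,
                         dh_force_oe = h_oe - h_ctrl,
                         stringsAsFactors = FALSE)
  per_group <- do.call(rbind, lapply(split(per_gene, per_gene$group),
                                     function(d) {
    p <- tryCatch(wilcoxon_signed_rank(d$dh_force_oe -
                                         d$dh_force)$p_value,
                  error = function(e) NA_real_)
    data.frame(group = d$group[1], n = nrow(d),
               median_dh_force = stats::median(d$dh_force),
               median_dh_force_oe = stats::median(d$dh_force_oe),
               paired_p = p, stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  list(per_gene = per_gene, per_group = per_group)
}
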