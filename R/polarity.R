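#' Orient super-enhancers against flanking H3K27me3
#'
#' Measures mean normalized H3K27me3 density in windows of `flank_width`
#' bases immediately left and right of each SE and flags SEs whose right
#' flank is stronger for horizontal flipping, so that after orientation the
#' H3K27me3-bounded side is canonical-left.  Flanks truncated at a genome
#' edge use the on-genome part; an entirely off-genome flank counts as 0
#' with a warning.  Ties are not flipped.
#'
#' @param ses [GenomicRanges::GRanges] of super-enhancers.
#' @param me3_track H3K27me3 [CoverageTrack()].
#' @param flank_width Flank window width in bases (default 20000).
#' @param scale Density scale.
#' @return `ses` with added metadata columns `left_flank_me3`,
#'   `right_flank_me3`, `flipped`.
#' @export
orient_ses <- function(ses, me3_track, flank_width = 20000, scale = 1e6) {
  .check_track(me3_track)
  stopifnot(is(ses, "GRanges"), flank_width > 0)
  chrom <- as.character(GenomicRanges::seqnames(ses))
  lens <- me3_track$seqlengths[chrom]
  s <- GenomicRanges::start(ses); e <- GenomicRanges::end(ses)
  flank_mean <- function(from, to) {
    cf <- pmax(1, from); ct <- pmin(lens, to)
    empty <- ct < cf
    if (any(empty))
      warning(sum(empty), " zero-width flank(s) at genome edge; treated as 0")
    m <- numeric(length(ses))
    if (any(!empty)) {
      w <- GenomicRanges::GRanges(chrom[!empty],
                                  IRanges::IRanges(cf[!empty], ct[!empty]))
      m[!empty] <- region_density(me3_track, w, "mean", scale)
    }
    m
  }
  left <- flank_mean(s - flank_width, s - 1)
  right <- flank_mean(e + 1, e + flank_width)
  ses$left_flank_me3 <- left
  ses$right_flank_me3 <- right
  ses$flipped <- right > left
  ses
}

#' Center-aligned, length-sorted SE signal heatmap
#'
#' Builds the classic SE heatmap matrix: each row is the log2-transformed
#' normalized density over a fixed window centered on the SE midpoint, rows
#' flagged `flipped` are reversed so the H3K27me3-bounded side faces left,
#' and rows are sorted by SE length, longest first.  Positions outside the
#' genome are missing.
#'
#' @param ses Oriented SEs from [orient_ses()] (must carry `flipped`).
#' @param track [CoverageTrack()] to plot.
#' @param window Window width in bases; default longest SE plus
#'   `2 * flank_pad`.
#' @param flank_pad Padding beyond the longest SE when `window` is NULL.
#' @param log2_eps Pseudocount inside the log2 (density units).
#' @param bin Optional bin width; NULL plots per-base columns.
#' @param scale Density scale.
#' @return Numeric matrix, rows named by SE (length-sorted descending),
#'   values `log2(density + eps)`.
#' @export
center_aligned_heatmap <- function(ses, track, window = NULL,
                                   flank_pad = 20000, log2_eps = 0.01,
                                   bin = NULL, scale = 1e6) {
  stopifnot(is(ses, "GRanges"), !is.null(ses$flipped))
  if (is.null(window))
    window <- max(GenomicRanges::width(ses)) + 2 * flank_pad
  if (is.null(bin)) bin <- 1
  n_bins <- ceiling(window / bin)
  ord <- order(GenomicRanges::width(ses), decreasing = TRUE)
  ses <- ses[ord]
  center <- GenomicRanges::start(ses) - 1 +
    floor(GenomicRanges::width(ses) / 2)
  mat <- .binned_window_matrix(track,
                               as.character(GenomicRanges::seqnames(ses)),
                               center, n_bins, bin, scale)
  flip <- ses$flipped
  mat[flip, ] <- mat[flip, n_bins:1, drop = FALSE]
  mat <- log2(mat + log2_eps)
  rownames(mat) <- if (!is.null(names(ses))) names(ses) else
    paste0("SE", seq_along(ses))
  mat
}

#' Fixed-bin-count SE signal matrix and aggregate
#'
#' Divides every SE body into the same number of bins regardless of length
#' (plus optional fixed-width flank bins on each side, after orientation)
#' and records mean normalized density per bin, so SEs of different lengths
#' become comparable rows; the aggregate curve is the column mean.  SE
#' bodies shorter than `body_bins` bases are binned by proportional base
#' weighting.
#'
#' @param ses Oriented SEs from [orient_ses()].
#' @param track [CoverageTrack()].
#' @param body_bins Number of within-SE bins B (default 100).
#' @param flank_bins Flank bins per side F (default 20); 0 disables flanks.
#' @param flank_width Total flank width per side in bases.
#' @param scale Density scale.
#' @return List with `matrix` (SEs x (F + B + F)), `aggregate` (column
#'   means), `is_body` (logical column mask).
#' @export
binned_se_matrix <- function(ses, track, body_bins = 100, flank_bins = 20,
                             flank_width = 20000, scale = 1e6) {
  stopifnot(is(ses, "GRanges"), body_bins >= 2, !is.null(ses$flipped))
  .check_track(track)
  n <- length(ses)
  ncol_tot <- body_bins + 2 * flank_bins
  mat <- matrix(NA_real_, n, ncol_tot)
  chrom <- as.character(GenomicRanges::seqnames(ses))
  for (i in seq_len(n)) {
    len <- track$seqlengths[[chrom[i]]]
    s0 <- GenomicRanges::start(ses)[i] - 1          # 0-based body start
    e0 <- GenomicRanges::end(ses)[i]                # 0-based body end
    body <- .proportional_bins(track, chrom[i], s0, e0, body_bins)
    row <- body
    if (flank_bins > 0) {
      lf <- .proportional_bins(track, chrom[i],
                               max(0, s0 - flank_width), s0, flank_bins)
      rf <- .proportional_bins(track, chrom[i], e0,
                               min(len, e0 + flank_width), flank_bins)
      row <- c(lf, body, rf)
    }
    if (isTRUE(ses$flipped[i])) row <- rev(row)
    mat[i, ] <- row
  }
  mat <- mat * scale / track$library_size
  rownames(mat) <- if (!is.null(names(ses))) names(ses) else
    paste0("SE", seq_len(n))
  is_body <- rep(c(FALSE, TRUE, FALSE),
                 c(flank_bins, body_bins, flank_bins))
  list(matrix = mat, aggregate = colMeans(mat, na.rm = TRUE),
       is_body = is_body)
}

## Mean raw depth in `nb` equal bins over the 0-based half-open interval
## [s0, e0); fractional bin boundaries are handled by weighting each base
## by the fraction of it inside the bin (exact for any region length).
.proportional_bins <- function(track, chrom, s0, e0, nb) {
  w <- e0 - s0
  if (w <= 0) return(rep(NA_real_, nb))
  v <- as.numeric(S4Vectors::window(track$coverage[[chrom]], s0 + 1, e0))
  if (w %% nb == 0) {
    return(colMeans(matrix(v, nrow = w / nb)))
  }
  edges <- seq(0, w, length.out = nb + 1)
  cum <- c(0, cumsum(v))
  ## integral of the piecewise-constant depth from 0 to position x
  integ <- function(x) {
    f <- floor(x)
    cum[f + 1] + (x - f) * ifelse(f < w, v[f + 1], 0)
  }
  ui <- integ(edges)
  diff(ui) / diff(edges)
}

#' Overlap accounting between labeled SE sets
#'
#' Two SEs from different sets overlap when they share at least one base.
#' Each SE is assigned the combination of other sets it overlaps (its Venn
#' class); an SE overlapping at least one SE in every other set is
#' "shared".  Duplicate intervals within a set are removed with a warning.
#'
#' @param se_sets Named list of 2 or 3 [GenomicRanges::GRanges].
#' @return List per set with `n`, `unique`, `shared`, and `classes` (table
#'   of Venn-class labels such as `"A+B"`).
#' @export
se_set_overlap <- function(se_sets) {
  stopifnot(is.list(se_sets), length(se_sets) %in% c(2, 3),
            !is.null(names(se_sets)))
  nms <- names(se_sets)
  se_sets <- lapply(nms, function(nm) {
    g <- se_sets[[nm]]
    d <- duplicated(paste0(GenomicRanges::seqnames(g), ":",
                           GenomicRanges::start(g), "-",
                           GenomicRanges::end(g)))
    if (any(d)) {
      warning(sum(d), " duplicate interval(s) in set ", nm, " removed")
      g <- g[!d]
    }
    g
  })
  names(se_sets) <- nms
  out <- list()
  for (a in nms) {
    ga <- se_sets[[a]]
    hit <- sapply(setdiff(nms, a), function(b)
      IRanges::overlapsAny(ga, se_sets[[b]], ignore.strand = TRUE))
    if (is.null(dim(hit))) hit <- matrix(hit, ncol = length(nms) - 1)
    cls <- apply(hit, 1, function(h) {
      others <- setdiff(nms, a)[h]
      paste(c(a, others), collapse = "+")
    })
    out[[a]] <- list(n = length(ga),
                     unique = sum(rowSums(hit) == 0),
                     shared = sum(rowSums(hit) == length(nms) - 1),
                     classes = table(cls))
  }
  out
}
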