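## Binned mean density over arbitrary windows, clipped at genome edges.
## Returns a matrix rows x n_bins with NA where a bin falls off the genome.
.binned_window_matrix <- function(track, chrom, center, n_bins, bin_width,
                                  scale = 1e6) {
  n <- length(center)
  out <- matrix(NA_real_, n, n_bins)
  half <- n_bins * bin_width / 2
  for (ch in unique(chrom)) {
    len <- track$seqlengths[[ch]]
    if (is.null(len)) stop("chromosome not in track: ", ch)
    rows <- which(chrom == ch)
    ## bin j covers [center - half + (j-1)*bw, ... + bw)
    starts <- outer(center[rows] - half, (seq_len(n_bins) - 1) * bin_width,
                    "+") + 1          # 1-based
    ends <- starts + bin_width - 1
    cs <- pmax(1, pmin(starts, len + 1))
    ce <- pmax(0, pmin(ends, len))
    ok <- ce >= cs
    vw <- IRanges::Views(track$coverage[[ch]],
                         start = as.integer(cs[ok]),
                         end = as.integer(ce[ok]))
    vals <- matrix(NA_real_, length(rows), n_bins)
    vals[ok] <- IRanges::viewMeans(vw)
    ## bins only partially on the genome are kept as the mean of the
    ## retained bases; fully off-genome bins stay NA
    out[rows, ] <- vals
  }
  out * scale / track$library_size
}

#' TSS-centered occupancy profile for a gene group
#'
#' Computes mean normalized density in fixed-width bins across a window
#' centered on each gene's TSS, orients rows so transcription runs left to
#' right (minus-strand rows are reversed), and averages columns across
#' genes.  Window bins truncated at a genome edge contribute only their
#' on-genome bases; fully off-genome bins are missing and excluded from the
#' aggregate means.
#'
#' @param track A [CoverageTrack()].
#' @param tss TSS [GenomicRanges::GRanges] named by gene id.
#' @param genes Character vector of gene ids to profile (default: all in
#'   `tss`).  Genes absent from `tss` are skipped with a warning.
#' @param half_width Window half-width W in bases (1 Mb window: 5e5).
#' @param bin Bin width b in bases; must divide `2 * half_width`.
#' @param orient_strand Reverse minus-strand rows (default TRUE).
#' @param scale Density scale.
#' @return List with `matrix` (genes x bins), `aggregate` (column means,
#'   NA-excluded), `bin_centers` (offsets from TSS), `skipped` (number of
#'   requested genes missing from `tss`).
#' @export
tss_profile <- function(track, tss, genes = NULL, half_width = 5e5,
                        bin = 1000, orient_strand = TRUE, scale = 1e6) {
  .check_track(track)
  if ((2 * half_width) %% bin != 0) stop("bin must divide 2 * half_width")
  if (is.null(genes)) genes <- names(tss)
  missing <- setdiff(genes, names(tss))
  if (length(missing))
    warning(length(missing), " gene(s) absent from TSS table; skipped")
  genes <- intersect(genes, names(tss))
  g <- tss[genes]
  n_bins <- as.integer(2 * half_width / bin)
  mat <- .binned_window_matrix(track,
                               as.character(GenomicRanges::seqnames(g)),
                               GenomicRanges::start(g) - 1, # 0-based center
                               n_bins, bin, scale)
  if (orient_strand) {
    neg <- as.character(GenomicRanges::strand(g)) == "-"
    mat[neg, ] <- mat[neg, n_bins:1, drop = FALSE]
  }
  rownames(mat) <- genes
  list(matrix = mat,
       aggregate = colMeans(mat, na.rm = TRUE),
       bin_centers = seq(-half_width + bin / 2, half_width - bin / 2,
                         by = bin),
       skipped = length(missing))
}

#' Per-gene central-window binding differences and their ecdf
#'
#' For each gene, the difference in mean normalized density between two
#' libraries over the window `[TSS - h, TSS + h)`; the empirical
#' distribution of these differences summarizes condition-induced binding
#' change around promoters.
#'
#' @param track_a,track_b [CoverageTrack()]s (difference is a minus b,
#'   e.g. stress minus control).
#' @param tss TSS [GenomicRanges::GRanges] named by gene id.
#' @param genes Gene ids (default all).
#' @param half_width Central window half-width h (default 5000 bases).
#' @param scale Density scale.
#' @return List with `delta` (named per-gene differences) and `ecdf`
#'   (a data.frame of sorted `delta`, `f` suitable for plotting).
#' @export
central_window_difference <- function(track_a, track_b, tss, genes = NULL,
                                      half_width = 5000, scale = 1e6) {
  stopifnot(half_width > 0)
  if (is.null(genes)) genes <- names(tss)
  genes <- intersect(genes, names(tss))
  g <- tss[genes]
  chrom <- as.character(GenomicRanges::seqnames(g))
  center <- GenomicRanges::start(g) - 1
  lens <- track_a$seqlengths[chrom]
  win <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(
                                  pmax(1, center - half_width + 1),
                                  pmin(lens, center + half_width)))
  delta <- region_density(track_a, win, "mean", scale) -
    region_density(track_b, win, "mean", scale)
  names(delta) <- genes
  s <- sort(delta)
  list(delta = delta,
       ecdf = data.frame(delta = s, f = seq_along(s) / length(s)))
}
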