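#' Stitch enhancer peaks into candidate regions
#'
#' ROSE-style stitching: peaks on the same chromosome whose gap
#' (`next start - previous end`) is at most `stitch_distance` are merged
#' transitively.  With a TSS table and `tss_exclusion > 0`, peaks lying
#' fully within `+/- tss_exclusion` of any TSS are dropped before
#' stitching.
#'
#' @param peaks A [GenomicRanges::GRanges] of enhancer peaks.
#' @param stitch_distance Maximum gap to merge across; ROSE default 12500.
#' @param tss Optional TSS [GenomicRanges::GRanges].
#' @param tss_exclusion Half-width of the promoter exclusion window; 0
#'   disables it (ROSE default off here).
#' @return A [GenomicRanges::GRanges] of stitched regions, sorted, with a
#'   `n_constituents` column and the constituent peaks in
#'   `S4Vectors::metadata(x)$constituents` (a GRangesList-like split).
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500, tss = NULL,
                         tss_exclusion = 0) {
  if (stitch_distance < 0) stop("stitch_distance must be non-negative")
  stopifnot(is(peaks, "GRanges"))
  if (tss_exclusion > 0 && !is.null(tss)) {
    win <- GenomicRanges::resize(tss, width = 2 * tss_exclusion + 1,
                                 fix = "center")
    drop <- IRanges::overlapsAny(peaks, win, type = "within",
                                 ignore.strand = TRUE)
    peaks <- peaks[!drop]
  }
  if (length(peaks) == 0) return(GenomicRanges::GRanges())
  peaks <- GenomicRanges::sort(GenomicRanges::granges(peaks),
                               ignore.strand = TRUE)
  ## gap <= d  <=>  overlap after widening each peak by d/2 each side;
  ## use reduce with min.gapwidth = d + 1 (merges gaps strictly < d + 1)
  merged <- GenomicRanges::reduce(peaks,
                                  min.gapwidth = stitch_distance + 1,
                                  ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(peaks, merged, ignore.strand = TRUE)
  merged$n_constituents <- tabulate(S4Vectors::subjectHits(hits),
                                    nbins = length(merged))
  S4Vectors::metadata(merged)$constituents <-
    S4Vectors::split(peaks, S4Vectors::subjectHits(hits))
  merged
}

#' Score stitched regions against input
#'
#' ROSE's default ranking quantity: summed normalized ChIP density minus
#' summed normalized input density over each region (density units x
#' bases); negative values are floored at 0 before ranking.
#'
#' @param regions Stitched regions ([GenomicRanges::GRanges]).
#' @param chip_track,input_track [CoverageTrack()]s for the ChIP and input
#'   libraries.
#' @param scale Density scale passed to [region_density()].
#' @return `regions` with added `score` and `rank` (1 = highest score)
#'   metadata columns.
#' @export
score_regions <- function(regions, chip_track, input_track, scale = 1e6) {
  s <- region_density(chip_track, regions, "sum", scale) -
    region_density(input_track, regions, "sum", scale)
  regions$score <- pmax(0, s)
  regions$rank <- rank(-regions$score, ties.method = "first")
  regions
}

#' Super-enhancer cutoff at the rank-curve inflection
#'
#' Sorts scores ascending and finds the geometric inflection of the
#' ranked-signal curve: with global slope `m = (y_N - y_1) / (N - 1)`, the
#' cutoff sits at the first index whose forward difference exceeds `m`
#' (equivalent to the slope-1 tangent point on axes rescaled to the unit
#' square).  Regions scoring strictly above the cutoff are super-enhancers.
#'
#' @param scores Numeric vector of region scores (length >= 3).
#' @return List with `cutoff` (score at the inflection) and `is_super`
#'   (logical vector parallel to `scores`).
#' @export
se_cutoff <- function(scores) {
  n <- length(scores)
  if (n < 3) stop("need at least 3 regions to locate an inflection")
  y <- sort(scores)
  m <- (y[n] - y[1]) / (n - 1)
  idx <- which(diff(y) > m)
  ## no forward difference ever exceeds the global slope (flat or exactly
  ## linear curve): no inflection, no super-enhancers
  cutoff <- if (length(idx) == 0) Inf else y[idx[1]]
  list(cutoff = cutoff, is_super = scores > cutoff)
}

#' Call super-enhancers from peaks and coverage
#'
#' Full ROSE-style pass: stitch peaks, score stitched regions against
#' input, and flag super-enhancers above the rank-curve inflection.
#'
#' @inheritParams stitch_peaks
#' @inheritParams score_regions
#' @return A [GenomicRanges::GRanges] of stitched regions with `score`,
#'   `rank`, `is_super` columns; super-enhancers are `x[x$is_super]`.
#' @export
call_super_enhancers <- function(peaks, chip_track, input_track,
                                 stitch_distance = 12500, tss = NULL,
                                 tss_exclusion = 0, scale = 1e6) {
  regions <- stitch_peaks(peaks, stitch_distance, tss, tss_exclusion)
  if (length(regions) == 0) return(regions)
  regions <- score_regions(regions, chip_track, input_track, scale)
  if (length(regions) < 3) {
    regions$is_super <- rep(FALSE, length(regions))
    return(regions)
  }
  cut <- se_cutoff(regions$score)
  regions$is_super <- cut$is_super
  S4Vectors::metadata(regions)$cutoff <- cut$cutoff
  regions
}

#' Naive threshold peak caller (synthetic mode)
#'
#' Intended for simulated coverage only: bins the normalized density, keeps
#' bins above the q-th percentile, merges runs closer than `merge_gap`, and
#' drops regions narrower than `min_width`.
#'
#' @param track A [CoverageTrack()].
#' @param q Percentile threshold on binned density (default 80: on the
#'   dense synthetic genomes this sits in the gap between Poisson
#'   background and enhancer signal, above the upper tail of background
#'   bin means).
#' @param min_width Minimum peak width in bases.
#' @param merge_gap Merge peaks separated by at most this many bases.
#' @param bin Bin width in bases for thresholding.
#' @return A [GenomicRanges::GRanges] of peaks.
#' @export
call_peaks_naive <- function(track, q = 80, min_width = 200,
                             merge_gap = 100, bin = 50) {
  .check_track(track)
  out <- list()
  for (ch in names(track$coverage)) {
    len <- track$seqlengths[[ch]]
    nb <- floor(len / bin)
    if (nb < 1) next
    starts <- (seq_len(nb) - 1L) * bin + 1L
    vw <- IRanges::Views(track$coverage[[ch]], start = starts,
                         end = starts + bin - 1L)
    mu <- IRanges::viewMeans(vw)
    thr <- quantile(mu, q / 100, names = FALSE)
    above <- S4Vectors::Rle(mu > thr)
    ir <- methods::as(above, "IRanges")   # runs of TRUE, in bin units
    if (length(ir) == 0) next
    ir <- IRanges::IRanges((IRanges::start(ir) - 1L) * bin + 1L,
                           IRanges::end(ir) * bin)
    ir <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1)
    ir <- ir[IRanges::width(ir) >= min_width]
    if (length(ir))
      out[[ch]] <- GenomicRanges::GRanges(ch, ir)
  }
  if (length(out) == 0) return(GenomicRanges::GRanges())
  do.call(c, unname(out))
}
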