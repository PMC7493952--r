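#' @importFrom methods is
#' @importFrom stats quantile rpois rnorm runif rlnorm dnorm ecdf fivenum
#'   p.adjust pnorm wilcox.test ks.test setNames complete.cases
#' @importFrom utils read.table write.table head tail
NULL

#' Coverage track with library-size metadata
#'
#' A `CoverageTrack` bundles per-base read depth (stored run-length encoded,
#' one [S4Vectors::Rle] per chromosome) with the total number of mappable
#' reads in the library and a human-readable label.  Depth is kept raw;
#' normalized read density (depth divided by mappable reads, scaled
#' per-million by default) is computed on query via [normalized_density()].
#'
#' @param coverage A named list or [IRanges::RleList] of non-negative
#'   per-base depth vectors, one element per chromosome.
#' @param library_size Total mappable reads in the library (positive).
#' @param label Library identifier, e.g. `"H3K27ac_force_rep1"`.
#'
#' @return An object of class `CoverageTrack` with elements `coverage`
#'   (RleList), `library_size`, `label` and `seqlengths` (named integer
#'   vector of chromosome lengths).
#' @export
#' @examples
#' trk <- CoverageTrack(list(chr1 = c(2, 0, 4)), library_size = 2e6)
#' normalized_density(trk, GenomicRanges::GRanges("chr1:1-3"))
CoverageTrack <- function(coverage, library_size, label = "track") {
  if (is.list(coverage)) {
    coverage <- lapply(coverage, function(x) {
      if (is(x, "Rle")) x else S4Vectors::Rle(as.numeric(x))
    })
    coverage <- methods::as(coverage, "RleList")
  }
  if (!is(coverage, "RleList"))
    stop("'coverage' must be a list or RleList of per-base depths")
  if (is.null(names(coverage)) || any(names(coverage) == ""))
    stop("coverage elements must be named by chromosome")
  if (any(vapply(coverage, function(x) min(S4Vectors::runValue(x)) < 0,
                 logical(1))))
    stop("coverage values must be non-negative")
  if (!is.numeric(library_size) || length(library_size) != 1 ||
      is.na(library_size) || library_size <= 0)
    stop("'library_size' must be a single positive number")
  structure(
    list(coverage = coverage,
         library_size = as.numeric(library_size),
         label = as.character(label),
         seqlengths = vapply(coverage, length, numeric(1))),
    class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack '%s': %d chromosome(s), %.3g bases, library size %.4g\n",
              x$label, length(x$coverage), sum(x$seqlengths), x$library_size))
  invisible(x)
}

.check_track <- function(track) {
  if (!is(track, "CoverageTrack")) stop("expected a CoverageTrack")
  track
}

.check_region_bounds <- function(track, region) {
  chrom <- as.character(GenomicRanges::seqnames(region))
  bad <- !(chrom %in% names(track$coverage))
  if (any(bad))
    stop("region chromosome(s) not in track: ",
         paste(unique(chrom[bad]), collapse = ", "))
  lens <- track$seqlengths[chrom]
  if (any(GenomicRanges::start(region) < 1) ||
      any(GenomicRanges::end(region) > lens))
    stop("region outside genome bounds")
  invisible(TRUE)
}

#' Per-base normalized read density over a region
#'
#' Density is raw depth divided by the library's total mappable reads and
#' multiplied by `scale` (per-million by default), returned base by base in
#' genome (left-to-right) orientation.
#'
#' @param track A [CoverageTrack()].
#' @param region A length-one [GenomicRanges::GRanges].
#' @param scale Multiplier applied to depth / library_size; default `1e6`.
#' @return Numeric vector, one value per base of `region`.
#' @export
normalized_density <- function(track, region, scale = 1e6) {
  .check_track(track)
  stopifnot(is(region, "GRanges"), length(region) == 1, scale > 0)
  .check_region_bounds(track, region)
  chrom <- as.character(GenomicRanges::seqnames(region))
  v <- S4Vectors::window(track$coverage[[chrom]],
                         GenomicRanges::start(region),
                         GenomicRanges::end(region))
  as.numeric(v) * scale / track$library_size
}

## Mean raw depth per region, vectorized via Views (internal workhorse).
.region_view_stat <- function(track, regions, fun = c("mean", "sum")) {
  fun <- match.arg(fun)
  chrom <- as.character(GenomicRanges::seqnames(regions))
  out <- numeric(length(regions))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    vw <- IRanges::Views(track$coverage[[ch]],
                         start = GenomicRanges::start(regions)[idx],
                         end = GenomicRanges::end(regions)[idx])
    out[idx] <- if (fun == "mean") IRanges::viewMeans(vw) else
      IRanges::viewSums(vw)
  }
  out
}

#' Mean (or summed) normalized density per region
#'
#' Vectorized companion to [normalized_density()]: returns one summary value
#' per region instead of the per-base profile.
#'
#' @inheritParams normalized_density
#' @param regions A [GenomicRanges::GRanges] of any length.
#' @param stat `"mean"` or `"sum"` of the per-base density over each region.
#' @return Numeric vector parallel to `regions`.
#' @export
region_density <- function(track, regions, stat = c("mean", "sum"),
                           scale = 1e6) {
  stat <- match.arg(stat)
  .check_track(track)
  if (length(regions) == 0) return(numeric(0))
  .check_region_bounds(track, regions)
  .region_view_stat(track, regions, stat) * scale / track$library_size
}

#' Read a BED file as genomic intervals
#'
#' Accepts BED3 and wider dialects (BED6, narrowPeak as BED6+4); columns
#' beyond the sixth are ignored.  Input coordinates are BED-convention
#' 0-based half-open and are converted to the 1-based closed convention of
#' [GenomicRanges::GRanges]; [write_bed()] converts back, so round trips are
#' exact.
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges] in file order, with a `name` metadata
#'   column when a fourth column is present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0)
    return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-integer coordinates")
  bad <- which(start < 0 | end <= start)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": requires 0 <= start < end")
  strand <- rep("*", length(lines))
  if (all(nf >= 6)) {
    s <- vapply(fields, `[[`, character(1), 6)
    strand[s %in% c("+", "-")] <- s[s %in% c("+", "-")]
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1, end),
                               strand = strand)
  if (all(nf >= 4))
    gr$name <- vapply(fields, `[[`, character(1), 4)
  gr
}

#' Write genomic intervals as BED
#'
#' @param gr A [GenomicRanges::GRanges]; a `name` metadata column and a
#'   `score` column are emitted when present.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) {
    df$name <- gr$name
    df$score <- if (!is.null(gr$score)) gr$score else 0
    df$strand <- as.character(GenomicRanges::strand(gr))
    df$strand[df$strand == "*"] <- "."
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph as a coverage track
#'
#' Gaps between records are filled with depth 0; records must not overlap.
#' Chromosome lengths default to the end of the last record per chromosome
#' and can be extended with `seqlengths`.
#'
#' @param path Path to a bedGraph file.
#' @param library_size Total mappable reads for the library.
#' @param seqlengths Optional named vector of chromosome lengths.
#' @param label Library label stored in the track.
#' @return A [CoverageTrack()].
#' @export
read_bedgraph <- function(path, library_size, seqlengths = NULL,
                          label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "numeric", "numeric",
                                  "numeric"))
  if (nrow(df) == 0) stop("empty bedGraph: ", path)
  if (any(df$value < 0)) stop("negative coverage value in ", path)
  if (any(df$end <= df$start)) stop("bedGraph record with end <= start")
  cov <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$start[-1] < d$end[-nrow(d)]))
      stop("overlapping bedGraph records on ", ch)
    chrlen <- if (!is.null(seqlengths) && ch %in% names(seqlengths))
      seqlengths[[ch]] else max(d$end)
    if (max(d$end) > chrlen) stop("record beyond stated length of ", ch)
    # run-length construction: gaps are zero-depth runs
    bounds <- sort(unique(c(0, d$start, d$end, chrlen)))
    runlen <- diff(bounds)
    vals <- numeric(length(runlen))
    hit <- findInterval(bounds[-length(bounds)], d$start)
    inside <- hit > 0 & bounds[-length(bounds)] < d$end[pmax(hit, 1)]
    vals[inside] <- d$value[hit[inside]]
    keep <- runlen > 0
    cov[[ch]] <- S4Vectors::Rle(vals[keep], runlen[keep])
  }
  CoverageTrack(cov, library_size = library_size, label = label)
}

#' Write a coverage track as bedGraph
#'
#' Emits raw depth (not normalized density); zero-depth runs are omitted.
#'
#' @param track A [CoverageTrack()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  .check_track(track)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$coverage)) {
    r <- track$coverage[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)  # 0-based
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (!any(keep)) next
    writeLines(paste(ch, starts[keep], ends[keep], vals[keep], sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read a TSS table
#'
#' Expects a tab-separated file with columns `gene_id`, `chrom`, `tss`
#' (0-based position) and `strand`.
#'
#' @param path Path to the table.
#' @return A length-1-per-gene [GenomicRanges::GRanges] named by `gene_id`.
#' @export
read_tss_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id in TSS table")
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$tss + 1, width = 1),
                               strand = df$strand)
  names(gr) <- df$gene_id
  gr$gene_id <- df$gene_id
  gr
}

#' Derive a TSS table from a GTF file
#'
#' Keeps `gene` features (or `transcript` when no gene rows exist), taking
#' the 5' end per strand as the TSS and the first `gene_id` attribute seen
#' per gene.  GTF 1-based coordinates convert to the package convention.
#'
#' @param path Path to a GTF/GFF2 file.
#' @return A TSS [GenomicRanges::GRanges] as in [read_tss_table()].
#' @export
tss_from_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9)) stop("malformed GTF line")
  type <- vapply(fields, `[[`, character(1), 3)
  use <- if (any(type == "gene")) type == "gene" else type == "transcript"
  fields <- fields[use]
  if (length(fields) == 0) stop("no gene/transcript features in ", path)
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- as.numeric(vapply(fields, `[[`, character(1), 4))
  end <- as.numeric(vapply(fields, `[[`, character(1), 5))
  strand <- vapply(fields, `[[`, character(1), 7)
  attr <- vapply(fields, `[[`, character(1), 9)
  gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", attr)
  tss <- ifelse(strand == "-", end, start)  # 1-based
  keep <- !duplicated(gid)
  gr <- GenomicRanges::GRanges(chrom[keep],
                               IRanges::IRanges(tss[keep], width = 1),
                               strand = ifelse(strand[keep] %in% c("+", "-"),
                                               strand[keep], "*"))
  names(gr) <- gid[keep]
  gr$gene_id <- gid[keep]
  gr
}

#' Write / read tab-separated results tables
#'
#' Plain TSV with header; `read_results_table()` inverts it, so write/read
#' round trips are identities for data frames of atomic columns.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
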