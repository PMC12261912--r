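#' Genome layout
#'
#' An ordered set of chromosome names and lengths. The chromosome order given
#' here is the canonical sort order for every coordinate-sorted object in the
#' package (genotype matrices, panels, windows).
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (all > 0).
#' @return A `genome_layout`: a data.frame with columns `chrom`, `length`.
#' @examples
#' genome_layout(c("A01", "A02"), c(3e6, 2e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != length(length)) stop("chrom and length differ in length")
  if (any(is.na(length)) || any(length <= 0)) stop("chromosome lengths must be positive")
  structure(data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), %.3f Mb total\n",
              nrow(x), sum(x$length) / 1e6))
  print.data.frame(x, ...)
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$length[i]
}

# integer rank of each chromosome in the canonical order; errors on unknowns
chrom_rank <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  i
}

#' Region set
#'
#' Labeled genomic intervals in 0-based half-open coordinates, used for repeat
#' masks, GWAS/QTL target intervals, sliding windows and merged scan regions.
#' Intervals may overlap unless explicitly flattened.
#'
#' @param chrom Character vector.
#' @param start,end Numeric vectors; 0-based start (inclusive), end (exclusive).
#' @param label Optional character labels (recycled); default "".
#' @return A `region_set` data.frame with columns `chrom`, `start`, `end`, `label`.
#' @export
region_set <- function(chrom = character(), start = numeric(), end = numeric(),
                       label = "") {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(start) == 1) start <- rep(start, n)
  if (length(end) == 1) end <- rep(end, n)
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start, end must have equal length")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval start must be < end")
  label <- rep_len(as.character(label), length(chrom))
  structure(data.frame(chrom = chrom, start = start, end = end, label = label,
                       stringsAsFactors = FALSE),
            class = c("region_set", "data.frame"))
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d interval(s), %.3f Mb total span\n",
              nrow(x), if (nrow(x)) sum(x$end - x$start) / 1e6 else 0))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

regions_to_granges <- function(rs) {
  if (nrow(rs) == 0) {
    return(GenomicRanges::GRanges())
  }
  # GRanges is 1-based inclusive; half-open [start, end) -> start+1 .. end
  GenomicRanges::GRanges(rs$chrom, IRanges::IRanges(rs$start + 1, rs$end))
}

sites_to_granges <- function(sites) {
  GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
}

# GRanges for testing site positions against region-set intervals under the
# rule pos in [start, end): a site exactly at `end` is outside. Returns the
# ranges plus the original interval index of each (degenerate intervals that
# can contain no position are dropped).
region_query_granges <- function(rs) {
  lo <- pmax(rs$start, 1)
  hi <- rs$end - 1
  keep <- which(hi >= lo)
  list(gr = GenomicRanges::GRanges(rs$chrom[keep],
                                   IRanges::IRanges(lo[keep], hi[keep])),
       idx = keep)
}

#' Merge overlapping or adjacent intervals of a region set
#'
#' @param rs A `region_set`.
#' @param label Label assigned to merged intervals.
#' @return A `region_set` with disjoint intervals; touching intervals are merged.
#' @export
merge_regions <- function(rs, label = "merged") {
  if (nrow(rs) == 0) return(rs)
  gr <- GenomicRanges::reduce(regions_to_granges(rs))
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1, GenomicRanges::end(gr), label)
}
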