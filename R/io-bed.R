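#' Read a BED3/BED4 file into a region set
#'
#' BED coordinates are already 0-based half-open and are preserved verbatim.
#' Column 4, when present, becomes the interval label.
#'
#' @param path Path to a BED file.
#' @return A [region_set()].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(region_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3)) stop("BED line ", which(nfield < 3)[1], " has fewer than 3 columns")
  chrom <- vapply(parts, `[`, "", 1)
  start <- as.numeric(vapply(parts, `[`, "", 2))
  end <- as.numeric(vapply(parts, `[`, "", 3))
  bad <- is.na(start) | is.na(end) | start >= end
  if (any(bad)) stop("BED line ", which(bad)[1], ": start must be a number < end")
  label <- ifelse(nfield >= 4, vapply(parts, function(p) p[min(4, length(p))], ""), "")
  region_set(chrom, start, end, label)
}

#' Write a region set as BED4
#'
#' @param rs A [region_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(rs, path) {
  lab <- ifelse(rs$label == "", ".", rs$label)
  writeLines(sprintf("%s\t%d\t%d\t%s", rs$chrom, as.integer(rs$start),
                     as.integer(rs$end), lab), path)
  invisible(path)
}
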