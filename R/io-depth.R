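#' Per-site read-depth table for one sample
#'
#' @param chrom,pos,depth Vectors of equal length; `pos` is 1-based; depths
#'   are non-negative integers. Duplicate (chrom, pos) keys are an error.
#' @param sample Sample name.
#' @return A `depth_table` data.frame with columns `chrom`, `pos`, `depth` and
#'   attribute `sample`.
#' @export
depth_table <- function(chrom, pos, depth, sample = "sample") {
  chrom <- as.character(chrom); pos <- as.numeric(pos); depth <- as.numeric(depth)
  if (any(is.na(depth)) || any(depth < 0)) stop("depths must be non-negative")
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate depth record at ", sub(" ", ":", d))
  }
  out <- data.frame(chrom = chrom, pos = pos, depth = depth, stringsAsFactors = FALSE)
  attr(out, "sample") <- sample
  class(out) <- c("depth_table", "data.frame")
  out
}

#' Read a per-sample depth TSV (columns chrom, pos, depth)
#'
#' @param path Path to a tab-separated file with a `chrom  pos  depth` header
#'   or three unnamed columns; `pos` is 1-based.
#' @param sample Sample name; defaults to the file name without extension.
#' @return A [depth_table()].
#' @export
read_depth_table <- function(path, sample = sub("\\.[^.]*$", "", basename(path))) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) {
    warning("empty depth table: ", path)
    return(depth_table(character(), numeric(), numeric(), sample))
  }
  header <- grepl("chrom", first)
  d <- if (header) {
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "pos", "depth"),
                      stringsAsFactors = FALSE)
  }
  if (nrow(d) == 0) {
    warning("empty depth table: ", path)
    return(depth_table(character(), numeric(), numeric(), sample))
  }
  depth_table(d$chrom, d$pos, d$depth, sample)
}

#' Write a depth table as TSV
#' @param dt A [depth_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(dt, path) {
  utils::write.table(as.data.frame(dt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# depth per queried panel site; sites absent from the table count as depth 0
depth_at_sites <- function(dt, sites) {
  i <- match(site_key(sites), paste(dt$chrom, dt$pos, sep = ":"))
  d <- dt$depth[i]
  d[is.na(d)] <- 0
  d
}
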