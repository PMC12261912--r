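#' Gene models
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand` ("+"/"-"),
#'   `start`, `end` (0-based half-open gene span).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open). Overlapping exons of one gene are merged with a
#'   warning; exons must lie within the gene span.
#' @return A `gene_models` object.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(is.data.frame(genes), is.data.frame(exons))
  genes$chrom <- as.character(genes$chrom)
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$start >= genes$end)) stop("gene span start must be < end")
  if (nrow(exons)) {
    sp <- genes[match(exons$gene_id, genes$gene_id), ]
    if (anyNA(sp$gene_id)) stop("exon references unknown gene")
    if (any(exons$start < sp$start | exons$end > sp$end))
      stop("exon outside its gene span")
    exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
    # merge overlapping exons per gene
    merged <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
      if (nrow(e) > 1) {
        keep <- e[1, , drop = FALSE]
        for (i in 2:nrow(e)) {
          if (e$start[i] < keep$end[nrow(keep)]) {
            warning("overlapping exons merged for gene ", e$gene_id[1])
            keep$end[nrow(keep)] <- max(keep$end[nrow(keep)], e$end[i])
          } else keep <- rbind(keep, e[i, ])
        }
        keep
      } else e
    }))
    rownames(merged) <- NULL
    exons <- merged
  }
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d gene(s), %d exon(s)\n", nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

gff_attr <- function(attributes, key) {
  m <- regmatches(attributes, regexpr(paste0("(^|;)", key, "=[^;]+"), attributes))
  out <- rep(NA_character_, length(attributes))
  hit <- vapply(regmatches(attributes, gregexpr(paste0("(^|;)", key, "=[^;]+"), attributes)),
                function(x) if (length(x)) sub(paste0("^;?", key, "="), "", x[1]) else NA_character_,
                "")
  hit
}

#' Read gene models from a GFF3 file
#'
#' Gene features become gene spans; exon features are grouped under their
#' parent gene (one level of mRNA indirection is resolved). GFF3 1-based
#' inclusive coordinates are converted to 0-based half-open. Exons whose
#' parent gene cannot be resolved are skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gff <- function(path) {
  g <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  ids <- gff_attr(g$attributes, "ID")
  parents <- gff_attr(g$attributes, "Parent")
  is_gene <- g$type == "gene"
  genes <- data.frame(
    gene_id = ids[is_gene], chrom = as.character(g$seqid[is_gene]),
    strand = as.character(g$strand[is_gene]),
    start = g$start[is_gene] - 1, end = as.numeric(g$end[is_gene]),
    stringsAsFactors = FALSE)
  # map any feature ID to its gene ancestor (transcripts point at genes)
  to_gene <- function(p) {
    for (step in 1:3) {
      if (is.na(p) || p %in% genes$gene_id) return(p)
      i <- match(p, ids)
      p <- if (is.na(i)) NA_character_ else parents[i]
    }
    NA_character_
  }
  is_exon <- g$type == "exon"
  exon_gene <- vapply(parents[is_exon], to_gene, "")
  orphan <- is.na(exon_gene)
  if (any(orphan)) {
    warning(sum(orphan), " exon(s) without a resolvable parent gene skipped")
  }
  exons <- data.frame(
    gene_id = exon_gene[!orphan], chrom = as.character(g$seqid[is_exon][!orphan]),
    start = g$start[is_exon][!orphan] - 1, end = as.numeric(g$end[is_exon][!orphan]),
    stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

#' Write gene models as GFF3
#'
#' @param gmods A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(gmods, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- gmods$genes
  if (nrow(g)) {
    lines <- sprintf("%s\tcapdesign\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom, as.integer(g$start + 1), as.integer(g$end),
                     g$strand, g$gene_id)
    e <- gmods$exons
    elines <- if (nrow(e)) {
      strand <- g$strand[match(e$gene_id, g$gene_id)]
      sprintf("%s\tcapdesign\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              e$chrom, as.integer(e$start + 1), as.integer(e$end), strand,
              e$gene_id, stats::ave(seq_len(nrow(e)), e$gene_id, FUN = seq_along),
              e$gene_id)
    } else character()
    writeLines(c(lines, elines), con)
  }
  invisible(path)
}
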