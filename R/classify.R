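#' Classify loci relative to gene models
#'
#' A site is `exon` if inside any exon; else `intron` if inside any gene span;
#' else `promoter` if within `promoter_len` bp upstream of any TSS (upstream of
#' the span start for + genes, of the span end for - genes); else `intergenic`.
#' Priority: exon > intron > promoter.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based).
#' @param genes A [gene_models()] object.
#' @param cfg A [design_config()] (uses `promoter_len`).
#' @return Character vector: one of "exon", "intron", "promoter", "intergenic".
#' @export
classify_loci <- function(sites, genes, cfg = design_config()) {
  out <- rep("intergenic", nrow(sites))
  if (nrow(sites) == 0 || nrow(genes$genes) == 0) return(out)
  sgr <- sites_to_granges(sites)
  g <- genes$genes
  hit_in <- function(chrom, start, end) {
    # half-open [start, end) -> 1-based inclusive
    keep <- end > start
    gr <- GenomicRanges::GRanges(chrom[keep], IRanges::IRanges(start[keep] + 1, end[keep]))
    unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(sgr, gr)))
  }
  prom_start <- ifelse(g$strand == "+", pmax(0, g$start - cfg$promoter_len), g$end)
  prom_end <- ifelse(g$strand == "+", g$start, g$end + cfg$promoter_len)
  in_prom <- hit_in(g$chrom, prom_start, prom_end)
  out[in_prom] <- "promoter"
  in_gene <- hit_in(g$chrom, g$start, g$end)
  out[in_gene] <- "intron"
  if (nrow(genes$exons)) {
    e <- genes$exons
    out[hit_in(e$chrom, e$start, e$end)] <- "exon"
  }
  out
}

#' @rdname classify_loci
#' @param site One-row data.frame (or list) with `chrom` and `pos`.
#' @export
classify_locus <- function(site, genes, cfg = design_config()) {
  classify_loci(data.frame(chrom = site$chrom, pos = site$pos), genes, cfg)
}

#' Gene coverage of a panel
#'
#' Counts genes *located in* (>= 1 panel locus in the gene body or its
#' promoter) and genes *associated* (>= 1 panel locus within
#' `gene_assoc_radius` bp of the gene span).
#'
#' @param panel A `panel_design` or a data.frame with `chrom`, `pos`.
#' @param genes A [gene_models()] object.
#' @param cfg A [design_config()].
#' @return list with `n_genes_located_in`, `n_genes_associated`.
#' @export
gene_coverage <- function(panel, genes, cfg = design_config()) {
  loci <- if (inherits(panel, "panel_design")) panel$loci else panel
  g <- genes$genes
  if (nrow(g) == 0 || nrow(loci) == 0)
    return(list(n_genes_located_in = 0L, n_genes_associated = 0L))
  sgr <- sites_to_granges(loci)
  body_start <- ifelse(g$strand == "+", pmax(0, g$start - cfg$promoter_len), g$start)
  body_end <- ifelse(g$strand == "+", g$end, g$end + cfg$promoter_len)
  ggr_body <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(body_start + 1, body_end))
  located <- unique(S4Vectors::subjectHits(GenomicRanges::findOverlaps(sgr, ggr_body)))
  ggr_assoc <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(0, g$start - cfg$gene_assoc_radius) + 1,
                              g$end + cfg$gene_assoc_radius))
  assoc <- unique(S4Vectors::subjectHits(GenomicRanges::findOverlaps(sgr, ggr_assoc)))
  list(n_genes_located_in = length(located), n_genes_associated = length(assoc))
}
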