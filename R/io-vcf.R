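#' Read a multi-sample VCF into a genotype matrix
#'
#' Only biallelic SNP records are retained (single-nucleotide REF and ALT,
#' no comma in ALT). GT fields are mapped to alternate-allele dosage; phase
#' separators are ignored ("0|1" is "0/1"). Half-calls and any allele index
#' other than 0/1 become missing.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzip).
#' @param layout A [genome_layout()]; records on chromosomes absent from the
#'   layout are an error naming the offending record.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, layout) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    samples <- colnames(v@gt)[-1]
    if (is.null(samples)) samples <- character()
    return(genotype_matrix(
      data.frame(chrom = character(), pos = numeric(), ref = character(),
                 alt = character(), site_id = character()),
      matrix(integer(), 0, length(samples)), samples, layout))
  }
  unknown <- !(fix$CHROM %in% layout$chrom)
  if (any(unknown)) {
    k <- which(unknown)[1]
    stop(sprintf("record %s:%s is on a chromosome absent from the genome layout",
                 fix$CHROM[k], fix$POS[k]))
  }
  pos <- as.numeric(fix$POS)
  # per-chromosome position monotonicity = sorted input (chromosome blocks may
  # appear in any order; they are re-ranked against the layout)
  if (any(unlist(tapply(pos, fix$CHROM, function(p) diff(p) < 0))))
    stop("VCF positions are not sorted within chromosomes")
  keep <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  fix <- fix[keep, , drop = FALSE]
  gt <- v@gt[keep, -1, drop = FALSE]
  samples <- colnames(gt)
  sites <- data.frame(
    chrom = fix$CHROM, pos = as.numeric(fix$POS), ref = fix$REF, alt = fix$ALT,
    site_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                     paste(fix$CHROM, fix$POS, sep = "_"), fix$ID),
    stringsAsFactors = FALSE)
  # GT is the first colon-delimited field; map the diploid call to dosage
  gtfield <- sub(":.*$", "", gt)
  gtfield <- gsub("|", "/", gtfield, fixed = TRUE)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos <- map[gtfield]
  dosage <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt), dimnames = list(NULL, samples))
  genotype_matrix(sites, dosage, samples, layout)
}

#' Write a genotype matrix as a GT-only VCF 4.2 file
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path; plain-text VCF.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", gm$layout$chrom,
                       as.integer(gm$layout$length)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  if (n_sites(gm) > 0) {
    gtmap <- c("0/0", "0/1", "1/1")
    gtxt <- matrix("./.", n_sites(gm), length(gm$samples))
    ok <- !is.na(gm$dosage)
    gtxt[ok] <- gtmap[gm$dosage[ok] + 1L]
    body <- paste(gm$sites$chrom, format(gm$sites$pos, scientific = FALSE, trim = TRUE),
                  gm$sites$site_id, gm$sites$ref, gm$sites$alt, ".", "PASS", ".", "GT",
                  apply(gtxt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}
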