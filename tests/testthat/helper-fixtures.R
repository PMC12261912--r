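# tiny in-code fixtures shared across test files

toy_layout <- function() genome_layout(c("A01", "A02"), c(1e6, 5e5))

# build a genotype_matrix from a dosage matrix (sites x samples); positions
# default to 1000, 2000, ... on A01
toy_gm <- function(dosage, pos = 1000 * seq_len(nrow(dosage)),
                   chrom = rep("A01", nrow(dosage)), layout = toy_layout(),
                   ref = rep("A", nrow(dosage)), alt = rep("G", nrow(dosage))) {
  dosage <- as.matrix(dosage)
  samples <- sprintf("s%02d", seq_len(ncol(dosage)))
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      site_id = sprintf("v%03d", seq_len(nrow(dosage))))
  genotype_matrix(sites, dosage, samples, layout)
}

# independent brute-force Pearson r^2 used as the LD oracle
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2 || length(unique(a)) == 1 || length(unique(b)) == 1) return(NA_real_)
  num <- sum((a - mean(a)) * (b - mean(b)))
  (num / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))^2
}

# simple one-gene model helper
toy_genes <- function(strand = "+", start = 10000, end = 13000,
                      exons = data.frame(start = c(10000, 12000),
                                         end = c(10500, 13000))) {
  gene_models(
    data.frame(gene_id = "g1", chrom = "A01", strand = strand,
               start = start, end = end),
    data.frame(gene_id = "g1", chrom = "A01", start = exons$start,
               end = exons$end))
}
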