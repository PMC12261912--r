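#' Genotype matrix
#'
#' The central container: biallelic SNP sites by samples, holding alternate
#' allele dosages 0/1/2 with `NA` marking missing genotypes. Sites are kept
#' sorted by (canonical chromosome order, position).
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `site_id`.
#' @param dosage Integer matrix, `nrow(sites)` x `length(samples)`; values in
#'   \{0, 1, 2, NA\}.
#' @param samples Character vector of sample names.
#' @param layout A [genome_layout()] covering every site.
#' @param sort Sort sites into canonical order (default TRUE). With
#'   `sort = FALSE` unsorted input is an error.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(sites, dosage, samples, layout, sort = TRUE) {
  stopifnot(is.data.frame(sites), is.matrix(dosage))
  need <- c("chrom", "pos", "ref", "alt", "site_id")
  if (!all(need %in% names(sites))) stop("sites must have columns: ", paste(need, collapse = ", "))
  samples <- as.character(samples)
  if (nrow(sites) != nrow(dosage) || length(samples) != ncol(dosage))
    stop("dosage dimensions do not match sites/samples")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.numeric(sites$pos)
  if (any(sites$pos < 1)) stop("positions are 1-based and must be >= 1")
  if (any(sites$pos > chrom_length(layout, sites$chrom)))
    stop("site position beyond chromosome length")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  ord <- order(chrom_rank(layout, sites$chrom), sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    if (!sort) stop("sites are not sorted by (chromosome order, position)")
    sites <- sites[ord, , drop = FALSE]
    dosage <- dosage[ord, , drop = FALSE]
  }
  rownames(sites) <- NULL
  dimnames(dosage) <- list(NULL, samples)
  structure(list(sites = sites, dosage = dosage, samples = samples, layout = layout),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d site(s) x %d sample(s) on %d chromosome(s); %.2f%% missing\n",
              n_sites(x), length(x$samples), length(unique(x$sites$chrom)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm A `genotype_matrix`.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Subset a genotype matrix
#'
#' @param gm A `genotype_matrix`.
#' @param i Site indices (integer or logical).
#' @return A `genotype_matrix` restricted to the selected sites, order preserved.
#' @export
subset_sites <- function(gm, i) {
  genotype_matrix(gm$sites[i, , drop = FALSE], gm$dosage[i, , drop = FALSE],
                  gm$samples, gm$layout, sort = FALSE)
}

#' @rdname subset_sites
#' @param samples Character vector of sample names (or integer indices).
#' @export
subset_samples <- function(gm, samples) {
  j <- if (is.character(samples)) match(samples, gm$samples) else samples
  if (anyNA(j)) stop("unknown sample(s)")
  genotype_matrix(gm$sites, gm$dosage[, j, drop = FALSE], gm$samples[j],
                  gm$layout, sort = FALSE)
}

site_key <- function(sites) paste(sites$chrom, sites$pos, sep = ":")
variant_key <- function(sites) paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
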