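#' Per-site quality summaries
#'
#' For each site: missing rate (missing calls / all samples), observed
#' heterozygosity (heterozygote fraction among called genotypes), alternate
#' allele frequency p and minor allele frequency min(p, 1 - p). Statistics at
#' sites with no called genotype are `NA`.
#'
#' @param gm A `genotype_matrix`.
#' @return data.frame with one row per site: `chrom`, `pos`, `site_id`,
#'   `missing_rate`, `het`, `alt_freq`, `maf`, `n_called`.
#' @export
site_summaries <- function(gm) {
  d <- gm$dosage
  n <- ncol(d)
  called <- !is.na(d)
  n_called <- rowSums(called)
  n_het <- rowSums(d == 1L, na.rm = TRUE)
  alt <- rowSums(d, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  het <- ifelse(n_called > 0, n_het / n_called, NA_real_)
  data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos, site_id = gm$sites$site_id,
             missing_rate = (n - n_called) / n, het = het, alt_freq = p,
             maf = pmin(p, 1 - p), n_called = n_called,
             stringsAsFactors = FALSE)
}

#' @rdname site_summaries
#' @param site_index Single site index.
#' @return `site_summary()` returns the one-row summary for a single site.
#' @export
site_summary <- function(gm, site_index) {
  stopifnot(length(site_index) == 1, site_index >= 1, site_index <= n_sites(gm))
  site_summaries(subset_sites(gm, site_index))
}

#' Composite LD r-squared between two dosage vectors
#'
#' Squared Pearson correlation of unphased dosages over samples non-missing at
#' both sites (pairwise-complete). Undefined (`NA`) when fewer than two shared
#' calls remain or either vector is constant on the shared subset; undefined is
#' never reported as 0, which is a meaningful LD value.
#'
#' @param dosA,dosB Equal-length dosage vectors in \{0, 1, 2, NA\}.
#' @return list with `r2` and `n_pairs` (shared non-missing sample count).
#' @export
ld_r2 <- function(dosA, dosB) {
  if (length(dosA) != length(dosB)) stop("dosage vectors differ in length")
  ok <- !is.na(dosA) & !is.na(dosB)
  n <- sum(ok)
  if (n < 2) return(list(r2 = NA_real_, n_pairs = n))
  a <- dosA[ok]; b <- dosB[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(list(r2 = NA_real_, n_pairs = n))
  list(r2 = stats::cor(a, b)^2, n_pairs = n)
}

# vectorised r^2 between paired rows of two dosage matrices (same dims),
# pairwise-complete per row; NA where undefined
row_r2 <- function(A, B) {
  ok <- !is.na(A) & !is.na(B)
  a <- ifelse(ok, A, 0); b <- ifelse(ok, B, 0)
  n <- rowSums(ok)
  sa <- rowSums(a); sb <- rowSums(b)
  saa <- rowSums(a * a); sbb <- rowSums(b * b); sab <- rowSums(a * b)
  cov <- sab - sa * sb / n
  va <- saa - sa^2 / n
  vb <- sbb - sb^2 / n
  r2 <- cov^2 / (va * vb)
  r2[n < 2 | va <= 0 | vb <= 0] <- NA_real_
  r2
}

#' LD between consecutive same-chromosome sites
#'
#' One record per adjacent pair of sites on the same chromosome; pairs that
#' straddle a chromosome boundary are excluded.
#'
#' @param gm A `genotype_matrix` (sites sorted).
#' @return data.frame: `chrom`, `pos_a`, `pos_b`, `r2`, `n_pairs`.
#' @export
adjacent_ld_profile <- function(gm) {
  ns <- n_sites(gm)
  if (ns < 2) {
    return(data.frame(chrom = character(), pos_a = numeric(), pos_b = numeric(),
                      r2 = numeric(), n_pairs = integer()))
  }
  i <- seq_len(ns - 1)
  same <- gm$sites$chrom[i] == gm$sites$chrom[i + 1]
  i <- i[same]
  A <- gm$dosage[i, , drop = FALSE]
  B <- gm$dosage[i + 1, , drop = FALSE]
  data.frame(chrom = gm$sites$chrom[i], pos_a = gm$sites$pos[i],
             pos_b = gm$sites$pos[i + 1], r2 = row_r2(A, B),
             n_pairs = rowSums(!is.na(A) & !is.na(B)),
             stringsAsFactors = FALSE)
}

#' Write per-site summaries as TSV
#' @param summ Output of [site_summaries()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_summaries <- function(summ, path) {
  utils::write.table(summ, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
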