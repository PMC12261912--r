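#' Panel design configuration
#'
#' Every threshold the three-phase selection uses is an explicit parameter;
#' published panels of this kind report the resulting site-quality
#' distributions but not the cutoffs that produced them, so nothing here is
#' hard-coded.
#'
#' @param target_count Panel size K (loci to select).
#' @param min_spacing Minimum bp between consecutive same-chromosome backbone
#'   loci (default 1000). Interval-forced loci are exempt.
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param missing_max Maximum per-site missing rate (default 0.2).
#' @param het_max Maximum observed heterozygosity (default 0.5).
#' @param ld_r2_max Adjacent-pair r-squared at or above which one member is
#'   pruned (default 0.2).
#' @param near_variant_radius,near_variant_max Probe-context cleanliness: a
#'   site with more than `near_variant_max` other variants within
#'   `near_variant_radius` bp (default 4 within 200 bp) is removed, since
#'   polymorphism under a probe degrades hybridization.
#' @param promoter_len Promoter length upstream of the TSS in bp (default 2000,
#'   the common plant-genomics convention).
#' @param gene_assoc_radius Distance in bp within which a locus counts as
#'   associated with a gene (default 10000).
#' @param w_genic,w_maf,w_missing,w_het Locus score weights; score =
#'   `w_genic * [genic] + w_maf * maf - w_missing * missing_rate - w_het * het`.
#' @return A `design_config` list.
#' @export
design_config <- function(target_count = 40051L, min_spacing = 1000,
                          maf_min = 0.05, missing_max = 0.2, het_max = 0.5,
                          ld_r2_max = 0.2, near_variant_radius = 200,
                          near_variant_max = 4L, promoter_len = 2000,
                          gene_assoc_radius = 10000,
                          w_genic = 1, w_maf = 1, w_missing = 1, w_het = 1) {
  stopifnot(target_count >= 1, min_spacing >= 0,
            maf_min >= 0, maf_min <= 0.5,
            missing_max >= 0, missing_max <= 1,
            het_max >= 0, het_max <= 1,
            ld_r2_max >= 0, ld_r2_max <= 1,
            near_variant_radius >= 0, near_variant_max >= 0,
            promoter_len >= 0, gene_assoc_radius >= 0)
  structure(list(target_count = as.integer(target_count), min_spacing = min_spacing,
                 maf_min = maf_min, missing_max = missing_max, het_max = het_max,
                 ld_r2_max = ld_r2_max, near_variant_radius = near_variant_radius,
                 near_variant_max = as.integer(near_variant_max),
                 promoter_len = promoter_len, gene_assoc_radius = gene_assoc_radius,
                 w_genic = w_genic, w_maf = w_maf, w_missing = w_missing,
                 w_het = w_het),
            class = "design_config")
}
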