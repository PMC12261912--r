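#' Probe detection rate for one capture run
#'
#' A panel locus counts as detected when its read depth is at least
#' `min_depth`; loci absent from the depth table count as depth 0.
#'
#' @param depth A [depth_table()] for one sample.
#' @param panel A `panel_design` or loci data.frame (`chrom`, `pos`).
#' @param min_depth Detection threshold in reads (default 1: any coverage).
#' @return list with `rate` and `n_undetected`.
#' @export
detection_rate <- function(depth, panel, min_depth = 1) {
  loci <- if (inherits(panel, "panel_design")) panel$loci else panel
  if (nrow(loci) == 0) stop("empty panel")
  d <- depth_at_sites(depth, loci)
  list(rate = mean(d >= min_depth), n_undetected = sum(d < min_depth))
}

#' Mean capture depth over all panel loci
#'
#' @inheritParams detection_rate
#' @return Arithmetic mean depth (absent loci counted as 0).
#' @export
mean_panel_depth <- function(depth, panel) {
  loci <- if (inherits(panel, "panel_design")) panel$loci else panel
  if (nrow(loci) == 0) stop("empty panel")
  mean(depth_at_sites(depth, loci))
}

#' Genotype concordance between two dosage calls at the same loci
#'
#' Fraction of loci, among those called (non-missing) in both inputs, with
#' identical dosage. Symmetric; `NA` when no locus is co-called.
#'
#' @param dos_a,dos_b Equal-length dosage vectors over the same panel loci.
#' @return Fraction in \[0, 1\], or `NA` if undefined.
#' @export
genotype_concordance <- function(dos_a, dos_b) {
  if (length(dos_a) != length(dos_b)) stop("dosage vectors differ in length")
  ok <- !is.na(dos_a) & !is.na(dos_b)
  if (!any(ok)) return(NA_real_)
  mean(dos_a[ok] == dos_b[ok])
}

#' Variant-set Venn counts between chip and WGS calls
#'
#' @param chip_sites,wgs_sites data.frames with `chrom`, `pos`, `ref`, `alt`
#'   (a variant is identified by all four fields).
#' @return list: `chip_only`, `shared`, `wgs_only`.
#' @export
variant_set_venn <- function(chip_sites, wgs_sites) {
  a <- unique(variant_key(chip_sites))
  b <- unique(variant_key(wgs_sites))
  shared <- sum(a %in% b)
  list(chip_only = length(a) - shared, shared = shared,
       wgs_only = length(b) - shared)
}

#' Diagnose undetected probe loci
#'
#' Classifies each undetected locus: `sv_likely` when its WGS depth is below
#' `sv_depth_factor` times the sample's median WGS depth (deletion-type
#' structural variation is the dominant cause of probe failure);
#' else `polymorphism_interference` when more than `near_variant_max` other
#' variants lie within `near_variant_radius` bp (polymorphism under the probe);
#' else `unexplained`. Loci with no WGS depth record are `unexplained` with a
#' warning.
#'
#' @param undetected Loci data.frame (`chrom`, `pos`) of undetected probes.
#' @param wgs_depth A [depth_table()] from matched whole-genome sequencing.
#' @param all_variants A `genotype_matrix` of all known variants, used for the
#'   neighborhood polymorphism count.
#' @param cfg A [design_config()] (radius and count thresholds).
#' @param sv_depth_factor Fraction of the median WGS depth below which a locus
#'   is called `sv_likely` (default 0.25).
#' @return data.frame: `chrom`, `pos`, `wgs_depth`, `n_near_variants`, `class`.
#' @export
failed_probe_diagnosis <- function(undetected, wgs_depth, all_variants,
                                   cfg = design_config(), sv_depth_factor = 0.25) {
  if (nrow(undetected) == 0) {
    return(data.frame(chrom = character(), pos = numeric(), wgs_depth = numeric(),
                      n_near_variants = integer(), class = character()))
  }
  med <- stats::median(wgs_depth$depth)
  i <- match(site_key(undetected), paste(wgs_depth$chrom, wgs_depth$pos, sep = ":"))
  wd <- wgs_depth$depth[i]
  if (anyNA(wd)) warning(sum(is.na(wd)), " undetected locus/loci lack a WGS depth record")
  r <- cfg$near_variant_radius
  n_near <- integer(nrow(undetected))
  vs <- all_variants$sites
  for (k in seq_len(nrow(undetected))) {
    p <- vs$pos[vs$chrom == undetected$chrom[k]]
    n_near[k] <- sum(abs(p - undetected$pos[k]) <= r & p != undetected$pos[k])
  }
  cls <- ifelse(is.na(wd), "unexplained",
                ifelse(wd < sv_depth_factor * med, "sv_likely",
                       ifelse(n_near > cfg$near_variant_max,
                              "polymorphism_interference", "unexplained")))
  data.frame(chrom = undetected$chrom, pos = undetected$pos, wgs_depth = wd,
             n_near_variants = n_near, class = cls, stringsAsFactors = FALSE)
}

#' Full capture-QC report for one sample
#'
#' @param depth Chip [depth_table()] for the sample.
#' @param panel A `panel_design`.
#' @param chip_gm,wgs_gm Optional genotype matrices for the sample restricted
#'   to panel loci (one sample each) for concordance and Venn counts.
#' @param wgs_depth Optional WGS [depth_table()] for failed-probe diagnosis.
#' @param all_variants Optional `genotype_matrix` of all variants (diagnosis).
#' @param cfg A [design_config()].
#' @param min_depth Detection threshold.
#' @return list: detection rate, undetected count, mean depth, depth histogram
#'   breaks/counts, and (when inputs allow) concordance, Venn counts and the
#'   failed-probe classification table.
#' @export
capture_qc_report <- function(depth, panel, chip_gm = NULL, wgs_gm = NULL,
                              wgs_depth = NULL, all_variants = NULL,
                              cfg = design_config(), min_depth = 1) {
  dr <- detection_rate(depth, panel, min_depth)
  d <- depth_at_sites(depth, panel$loci)
  h <- graphics::hist(d, breaks = "Sturges", plot = FALSE)
  out <- list(sample = attr(depth, "sample"), detection_rate = dr$rate,
              n_undetected = dr$n_undetected, mean_depth = mean(d),
              depth_hist = data.frame(mid = h$mids, count = h$counts))
  if (!is.null(chip_gm) && !is.null(wgs_gm)) {
    ia <- match(variant_key(panel$loci), variant_key(chip_gm$sites))
    ib <- match(variant_key(panel$loci), variant_key(wgs_gm$sites))
    ok <- !is.na(ia) & !is.na(ib)
    out$concordance <- genotype_concordance(chip_gm$dosage[ia[ok], 1],
                                            wgs_gm$dosage[ib[ok], 1])
    called <- function(g, i) !is.na(i) & !is.na(g$dosage[ifelse(is.na(i), 1, i), 1]) &
      g$dosage[ifelse(is.na(i), 1, i), 1] > 0
    out$venn <- variant_set_venn(panel$loci[called(chip_gm, ia), , drop = FALSE],
                                 panel$loci[called(wgs_gm, ib), , drop = FALSE])
  }
  if (!is.null(wgs_depth) && !is.null(all_variants)) {
    und <- panel$loci[d < min_depth, c("chrom", "pos"), drop = FALSE]
    out$failed_probes <- failed_probe_diagnosis(und, wgs_depth, all_variants, cfg)
  }
  out
}
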