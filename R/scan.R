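#' Sliding windows over a genome layout
#'
#' Per chromosome of length L >= window: windows `[s, s + window)` for
#' s = 0, step, 2*step, ... while `s + window <= L`. Chromosomes shorter than
#' one window yield a single truncated window `[0, L)` rather than being
#' dropped.
#'
#' @param layout A [genome_layout()].
#' @param window_size Window width in bp (default 1 Mb).
#' @param step Step in bp (default 100 kb); must be <= `window_size`.
#' @return A [region_set()] of windows labeled by index.
#' @export
sliding_windows <- function(layout, window_size = 1e6, step = 1e5) {
  stopifnot(window_size > 0, step > 0, step <= window_size)
  out <- lapply(seq_len(nrow(layout)), function(ci) {
    L <- layout$length[ci]
    if (L < window_size) {
      data.frame(chrom = layout$chrom[ci], start = 0, end = L)
    } else {
      s <- seq(0, L - window_size, by = step)
      data.frame(chrom = layout$chrom[ci], start = s, end = s + window_size)
    }
  })
  out <- do.call(rbind, out)
  region_set(out$chrom, out$start, out$end, label = seq_len(nrow(out)))
}

# per-site alternate-allele frequency and called allele count within a group
group_site_freq <- function(gm, group) {
  d <- gm$dosage[, match(group, gm$samples), drop = FALSE]
  if (anyNA(match(group, gm$samples))) stop("unknown sample(s) in group")
  n_al <- 2 * rowSums(!is.na(d))
  p <- ifelse(n_al > 0, rowSums(d, na.rm = TRUE) / n_al, NA_real_)
  list(p = p, n = n_al)
}

# per-site unbiased heterozygosity 2p(1-p) * n/(n-1); sites with < 2 called
# alleles contribute 0 (skipped)
pi_site_component <- function(p, n) {
  ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), 0)
}

#' Nucleotide diversity of a group in one window
#'
#' pi = sum over window sites of `2*p*(1-p) * n/(n-1)` divided by the window
#' length in bp, with allele frequency p and called allele count n computed in
#' the group at each site. Invariant sites contribute 0; sites with fewer than
#' two called alleles are skipped.
#'
#' @param gm A `genotype_matrix`.
#' @param group Character vector of sample names.
#' @param window One interval: list/row with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Per-bp diversity (numeric scalar).
#' @export
pi_window <- function(gm, group, window) {
  f <- group_site_freq(gm, group)
  in_w <- gm$sites$chrom == window$chrom & gm$sites$pos >= window$start &
    gm$sites$pos < window$end
  sum(pi_site_component(f$p[in_w], f$n[in_w]), na.rm = TRUE) /
    (window$end - window$start)
}

# Hudson Fst per-site numerator and denominator
hudson_site_nd <- function(pA, nA, pB, nB) {
  ok <- nA >= 2 & nB >= 2
  N <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  D <- pA * (1 - pB) + pB * (1 - pA)
  N[!ok] <- NA; D[!ok] <- NA
  list(N = N, D = D, ok = ok)
}

#' Hudson Fst of one window (ratio of averages)
#'
#' Per site, numerator `(pA-pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)` and
#' denominator `pA(1-pB) + pB(1-pA)`; the window estimate is the ratio of the
#' summed numerators to the summed denominators over the window's usable sites
#' (both groups with >= 2 called alleles). Undefined (`NA`) when the summed
#' denominator is 0 or the window holds no usable site.
#'
#' @param gm A `genotype_matrix`.
#' @param groupA,groupB Sample-name vectors.
#' @param window As in [pi_window()].
#' @return Numeric scalar (possibly `NA`).
#' @export
fst_window <- function(gm, groupA, groupB, window) {
  fa <- group_site_freq(gm, groupA)
  fb <- group_site_freq(gm, groupB)
  in_w <- gm$sites$chrom == window$chrom & gm$sites$pos >= window$start &
    gm$sites$pos < window$end
  nd <- hudson_site_nd(fa$p[in_w], fa$n[in_w], fb$p[in_w], fb$n[in_w])
  D <- sum(nd$D, na.rm = TRUE)
  if (!any(nd$ok) || D == 0) return(NA_real_)
  sum(nd$N, na.rm = TRUE) / D
}

#' Reduction of diversity
#'
#' `ROD = 1 - pi_target / pi_reference`; undefined (`NA`) when the reference
#' diversity is 0, and such windows are excluded from thresholding.
#'
#' @param pi_target,pi_reference Per-bp diversities on the same window.
#' @return Numeric (possibly `NA`).
#' @export
rod_window <- function(pi_target, pi_reference) {
  ifelse(is.na(pi_reference) | pi_reference == 0, NA_real_,
         1 - pi_target / pi_reference)
}

#' Windowed pi / Hudson Fst / ROD selection scan
#'
#' Computes, for every sliding window, the per-bp diversity of the target and
#' reference groups, the Hudson ratio-of-averages Fst between them, and
#' `ROD = 1 - pi_target/pi_reference` (positive values mark diversity loss in
#' the target group).
#'
#' @param gm A `genotype_matrix`.
#' @param target,reference Sample-name vectors (e.g. the selected morphotype
#'   vs all other accessions).
#' @param window_size,step Window parameters in bp (defaults 1 Mb / 100 kb).
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `pi_target`,
#'   `pi_reference`, `fst`, `rod`.
#' @export
selection_scan <- function(gm, target, reference, window_size = 1e6, step = 1e5) {
  wins <- sliding_windows(gm$layout, window_size, step)
  fa <- group_site_freq(gm, target)
  fb <- group_site_freq(gm, reference)
  pit <- pi_site_component(fa$p, fa$n)
  pir <- pi_site_component(fb$p, fb$n)
  nd <- hudson_site_nd(fa$p, fa$n, fb$p, fb$n)
  rq <- region_query_granges(wins)
  hits <- GenomicRanges::findOverlaps(sites_to_granges(gm$sites), rq$gr)
  si <- S4Vectors::queryHits(hits)
  wi <- rq$idx[S4Vectors::subjectHits(hits)]
  dt <- data.table::data.table(
    w = wi, pit = pit[si], pir = pir[si], N = nd$N[si], D = nd$D[si])
  agg <- dt[, list(n_sites = .N, pit = sum(pit, na.rm = TRUE),
                   pir = sum(pir, na.rm = TRUE), N = sum(N, na.rm = TRUE),
                   D = sum(D, na.rm = TRUE), anyok = any(!is.na(D))),
            by = "w"]
  out <- data.frame(chrom = wins$chrom, start = wins$start, end = wins$end,
                    n_sites = 0L, pi_target = 0, pi_reference = 0,
                    fst = NA_real_, rod = NA_real_, stringsAsFactors = FALSE)
  len <- out$end - out$start
  out$n_sites[agg$w] <- agg$n_sites
  out$pi_target[agg$w] <- agg$pit / len[agg$w]
  out$pi_reference[agg$w] <- agg$pir / len[agg$w]
  fst <- ifelse(agg$anyok & agg$D != 0, agg$N / agg$D, NA_real_)
  out$fst[agg$w] <- fst
  out$rod <- rod_window(out$pi_target, out$pi_reference)
  out
}

#' Top-quantile window selection and region merging
#'
#' Threshold = empirical (1 - q) quantile of the defined values of `field`;
#' windows at or above the threshold are selected and overlapping or adjacent
#' selected windows are merged into regions. Output is independent of input
#' window order.
#'
#' @param stats Output of [selection_scan()] (or any data.frame with `chrom`,
#'   `start`, `end` and the chosen field).
#' @param field One of "fst", "rod" (or any numeric column name).
#' @param q Upper tail fraction (default 0.05).
#' @return A [region_set()] of merged selected regions, with the threshold in
#'   attribute `threshold`.
#' @export
top_quantile_regions <- function(stats, field = "fst", q = 0.05) {
  v <- stats[[field]]
  if (all(is.na(v))) stop("all ", field, " values are undefined")
  thr <- stats::quantile(v, 1 - q, na.rm = TRUE, names = FALSE)
  sel <- which(!is.na(v) & v >= thr)
  sel <- sel[order(stats$chrom[sel], stats$start[sel])]
  rs <- region_set(stats$chrom[sel], stats$start[sel], stats$end[sel], field)
  out <- merge_regions(rs, label = paste0(field, "_top", q))
  attr(out, "threshold") <- thr
  out
}

#' Write a selection-scan window table as TSV
#' @param stats Output of [selection_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
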