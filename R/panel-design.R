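#' Structural filtering of candidate sites
#'
#' Phase one of panel design. Removes (1) sites inside any exclusion-mask
#' interval (repeats, centromeres, rDNA) and (2) sites whose probe context is
#' polymorphism-dense: more than `near_variant_max` *other* variants within
#' `near_variant_radius` bp, a pattern associated with probe capture failure.
#'
#' @param gm A `genotype_matrix`.
#' @param masks A [region_set()] of excluded intervals (0-based half-open).
#' @param cfg A [design_config()].
#' @return The filtered `genotype_matrix` (may be empty, with a warning).
#' @export
structural_filter <- function(gm, masks, cfg = design_config()) {
  keep <- rep(TRUE, n_sites(gm))
  if (nrow(masks) > 0 && n_sites(gm) > 0) {
    q <- region_query_granges(masks)
    hits <- GenomicRanges::findOverlaps(sites_to_granges(gm$sites), q$gr)
    keep[unique(S4Vectors::queryHits(hits))] <- FALSE
  }
  # neighbor density: sites are sorted, so per chromosome the count of variants
  # in [pos - r, pos + r] comes from two findInterval passes
  r <- cfg$near_variant_radius
  pos <- gm$sites$pos
  for (ch in unique(gm$sites$chrom)) {
    i <- which(gm$sites$chrom == ch)
    p <- pos[i]
    n_near <- findInterval(p + r, p) - findInterval(p - r - 0.5, p) - 1L
    keep[i[n_near > cfg$near_variant_max]] <- FALSE
  }
  if (!any(keep)) warning("structural filter removed every site")
  subset_sites(gm, keep)
}

#' Site-quality filtering
#'
#' Phase-one companion: keeps sites with `maf >= maf_min`,
#' `missing_rate <= missing_max` and observed heterozygosity `<= het_max`.
#'
#' @inheritParams structural_filter
#' @return The filtered `genotype_matrix`.
#' @export
quality_filter <- function(gm, cfg = design_config()) {
  s <- site_summaries(gm)
  keep <- !is.na(s$maf) & s$maf >= cfg$maf_min &
    s$missing_rate <= cfg$missing_max & s$het <= cfg$het_max
  subset_sites(gm, keep)
}

#' Locus selection scores
#'
#' `score = w_genic * [genic_class != intergenic] + w_maf * maf -
#' w_missing * missing_rate - w_het * het`. With `genes = NULL` the genic term
#' is 0 for every site.
#'
#' @inheritParams structural_filter
#' @param genes A [gene_models()] object, or NULL.
#' @param summaries Optional precomputed [site_summaries()].
#' @return list with numeric `score` and character `genic_class` per site.
#' @export
locus_scores <- function(gm, genes = NULL, cfg = design_config(),
                         summaries = site_summaries(gm)) {
  genic <- if (is.null(genes)) rep("intergenic", n_sites(gm))
           else classify_loci(gm$sites, genes, cfg)
  score <- cfg$w_genic * (genic != "intergenic") + cfg$w_maf * summaries$maf -
    cfg$w_missing * summaries$missing_rate - cfg$w_het * summaries$het
  list(score = score, genic_class = genic)
}

# one pruning pass + iteration to fixed point; returns logical keep vector
ld_prune_keep <- function(gm, cfg, score) {
  keep <- rep(TRUE, n_sites(gm))
  repeat {
    idx <- which(keep)
    if (length(idx) < 2) break
    chrom <- gm$sites$chrom[idx]
    left <- idx[-length(idx)]; right <- idx[-1]
    same <- chrom[-length(chrom)] == chrom[-1]
    left <- left[same]; right <- right[same]
    if (length(left) == 0) break
    r2 <- row_r2(gm$dosage[left, , drop = FALSE], gm$dosage[right, , drop = FALSE])
    viol <- which(!is.na(r2) & r2 >= cfg$ld_r2_max)
    if (length(viol) == 0) break
    for (v in viol) {
      l <- left[v]; r <- right[v]
      # adjacency may have changed within this pass; skip stale pairs
      if (!keep[l] || !keep[r]) next
      # lower score loses; tie drops the right-hand member
      loser <- if (score[l] < score[r]) l else r
      keep[loser] <- FALSE
    }
  }
  keep
}

#' Adjacent-pair LD pruning
#'
#' Phase two. Iterates over consecutive same-chromosome pairs; whenever a pair
#' has defined r-squared `>= ld_r2_max`, the lower-scoring member is dropped
#' (ties drop the right-hand site), and pruning repeats on the new adjacencies
#' until no pair violates. The result is deterministic and guarantees every
#' defined adjacent r-squared in the output is below the threshold.
#'
#' @inheritParams structural_filter
#' @param score Optional per-site score used to pick the pair member to drop;
#'   defaults to [locus_scores()] without a genic term.
#' @return The pruned `genotype_matrix`.
#' @export
ld_prune <- function(gm, cfg = design_config(), score = NULL) {
  if (is.null(score)) score <- locus_scores(gm, NULL, cfg)$score
  subset_sites(gm, ld_prune_keep(gm, cfg, score))
}

#' Forced inclusion of target-interval loci
#'
#' For each GWAS/QTL target interval, selects the highest-scoring candidate
#' inside it (ties take the smallest coordinate). Intervals containing no
#' candidate are reported as unfillable. Forced loci are exempt from the
#' backbone spacing rule.
#'
#' @param gm Candidate `genotype_matrix` (post structural, quality and LD
#'   filters).
#' @param intervals A [region_set()] of target intervals.
#' @param cfg A [design_config()].
#' @param score Per-candidate scores; defaults as in [ld_prune()].
#' @return list with `forced_idx` (unique candidate indices) and `unfillable`
#'   (a [region_set()] of intervals without any candidate).
#' @export
force_include_intervals <- function(gm, intervals, cfg = design_config(),
                                    score = NULL) {
  if (is.null(score)) score <- locus_scores(gm, NULL, cfg)$score
  if (nrow(intervals) == 0 || n_sites(gm) == 0) {
    return(list(forced_idx = integer(),
                unfillable = if (nrow(intervals)) intervals else region_set()))
  }
  rq <- region_query_granges(intervals)
  hits <- GenomicRanges::findOverlaps(sites_to_granges(gm$sites), rq$gr)
  q <- S4Vectors::queryHits(hits); s <- rq$idx[S4Vectors::subjectHits(hits)]
  picked <- rep(NA_integer_, nrow(intervals))
  if (length(q)) {
    ord <- order(s, -score[q], gm$sites$pos[q])
    first <- !duplicated(s[ord])
    picked[s[ord][first]] <- q[ord][first]
  }
  list(forced_idx = sort(unique(picked[!is.na(picked)])),
       unfillable = intervals[is.na(picked), , drop = FALSE])
}

# largest-remainder apportionment of n slots proportional to weights
apportion_slots <- function(n, weights) {
  if (n == 0) return(integer(length(weights)))
  exact <- n * weights / sum(weights)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(exact - base), seq_along(weights))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Adjacency refinement: near-uniform spacing toward the target panel size
#'
#' Phase three. Backbone slots (`target_count` minus the forced loci) are
#' apportioned to chromosomes proportionally to length (largest-remainder
#' rounding). Each chromosome is partitioned into that many equal-width bins
#' and the highest-scoring candidate per bin is chosen (ties take the smallest
#' coordinate), skipping candidates closer than `min_spacing` to the previous
#' backbone pick. While the panel is below quota, the largest remaining
#' inter-locus gap is filled with its best eligible candidate. The output has
#' exactly `target_count` loci whenever the candidate set allows it, otherwise
#' the maximum feasible with a warning.
#'
#' @param gm Candidate `genotype_matrix`.
#' @param forced Integer indices (into `gm` sites) of interval-forced loci.
#' @param cfg A [design_config()].
#' @param score Per-candidate scores.
#' @param genic_class Per-candidate genic classes (optional, carried into the
#'   panel table).
#' @param unfillable [region_set()] of unfillable intervals, carried through.
#' @return A `panel_design` object.
#' @export
adjacency_refine <- function(gm, forced = integer(), cfg = design_config(),
                             score = NULL, genic_class = NULL,
                             unfillable = region_set()) {
  K <- cfg$target_count
  if (K <= 0) stop("target_count must be positive")
  if (length(forced) > K) stop("more forced loci than target_count")
  if (is.null(score)) score <- locus_scores(gm, NULL, cfg)$score
  if (is.null(genic_class)) genic_class <- rep(NA_character_, n_sites(gm))
  layout <- gm$layout
  pos <- gm$sites$pos
  chrom <- gm$sites$chrom
  is_forced <- rep(FALSE, n_sites(gm)); is_forced[forced] <- TRUE
  slots <- apportion_slots(K - length(forced), layout$length)

  backbone <- integer()
  for (ci in seq_len(nrow(layout))) {
    nb <- slots[ci]
    if (nb == 0) next
    ch <- layout$chrom[ci]
    cand <- which(chrom == ch & !is_forced)
    if (length(cand) == 0) next
    width <- layout$length[ci] / nb
    bin <- pmin(floor((pos[cand] - 1) / width), nb - 1)
    ord <- order(bin, -score[cand], pos[cand])
    cand <- cand[ord]; bin <- bin[ord]
    by_bin <- split(cand, bin)
    last_pos <- -Inf
    chosen <- integer(length(by_bin)); nc <- 0
    for (b in by_bin) {
      # b is sorted by score desc then pos asc; bins are processed left to
      # right so spacing only needs checking against the previous pick
      ok <- b[pos[b] - last_pos >= cfg$min_spacing & pos[b] > last_pos]
      if (length(ok)) {
        nc <- nc + 1
        chosen[nc] <- ok[1]
        last_pos <- pos[ok[1]]
      }
    }
    backbone <- c(backbone, chosen[seq_len(nc)])
  }

  # gap fill: add loci into the largest remaining inter-locus gaps until quota
  chosen_all <- c(backbone, forced)
  deficit <- K - length(chosen_all)
  if (deficit > 0) backbone <- c(backbone, gap_fill(gm, chosen_all, backbone,
                                                    is_forced, score, cfg, deficit))

  # overshoot (possible when forced loci exceed their chromosomes' share and
  # bins were already filled): drop lowest-score backbone in the most crowded
  # neighborhoods
  total <- length(backbone) + length(forced)
  while (total > K && length(backbone) > 0) {
    allp <- sort(pos[c(backbone, forced)] +
                   1e9 * chrom_rank(layout, chrom[c(backbone, forced)]))
    key <- pos[backbone] + 1e9 * chrom_rank(layout, chrom[backbone])
    i <- match(key, allp)
    nn <- pmin(c(Inf, diff(allp))[i], c(diff(allp), Inf)[i])
    drop <- order(nn, score[backbone], -pos[backbone])[1]
    backbone <- backbone[-drop]
    total <- total - 1
  }

  sel <- sort(unique(c(backbone, forced)))
  if (length(sel) < K)
    warning(sprintf("only %d of %d requested loci could be selected", length(sel), K))
  loci <- gm$sites[sel, , drop = FALSE]
  s <- site_summaries(subset_sites(gm, sel))
  loci$provenance <- ifelse(is_forced[sel], "interval_forced", "backbone")
  loci$score <- score[sel]
  loci$genic_class <- genic_class[sel]
  loci$maf <- s$maf; loci$missing_rate <- s$missing_rate; loci$het <- s$het
  rownames(loci) <- NULL
  structure(list(loci = loci, config = cfg, layout = layout,
                 unfillable = unfillable),
            class = "panel_design")
}

# fill up to `deficit` loci by repeatedly taking the largest inter-locus gap
gap_fill <- function(gm, chosen_all, backbone, is_forced, score, cfg, deficit) {
  layout <- gm$layout
  pos <- gm$sites$pos; chrom <- gm$sites$chrom
  taken <- rep(FALSE, n_sites(gm))
  taken[chosen_all] <- TRUE
  is_backbone <- rep(FALSE, n_sites(gm)); is_backbone[backbone] <- TRUE
  # gap table: chrom index, boundary positions (0 and L as virtual ends),
  # whether each boundary is a backbone locus (spacing applies)
  gaps <- list()
  for (ci in seq_len(nrow(layout))) {
    ch <- layout$chrom[ci]
    cp <- sort(pos[chosen_all][chrom[chosen_all] == ch])
    bb <- sort(pos[backbone][chrom[backbone] == ch])
    b0 <- c(0, cp); b1 <- c(cp, layout$length[ci])
    gaps[[ci]] <- data.frame(ci = ci, left = b0, right = b1,
                             left_bb = b0 %in% bb, right_bb = b1 %in% bb)
  }
  gaps <- do.call(rbind, gaps)
  gaps$len <- gaps$right - gaps$left
  gaps$alive <- TRUE
  added <- integer(deficit); na <- 0
  cand_by_chrom <- split(seq_len(n_sites(gm)), factor(chrom, layout$chrom))
  while (na < deficit) {
    alive <- which(gaps$alive)
    if (length(alive) == 0) break
    gi <- alive[order(-gaps$len[alive], gaps$ci[alive], gaps$left[alive])[1]]
    g <- gaps[gi, ]
    cand <- cand_by_chrom[[g$ci]]
    cand <- cand[!taken[cand] & !is_forced[cand] &
                   pos[cand] > g$left & pos[cand] < g$right]
    if (g$left_bb) cand <- cand[pos[cand] - g$left >= cfg$min_spacing]
    if (g$right_bb) cand <- cand[g$right - pos[cand] >= cfg$min_spacing]
    if (length(cand) == 0) { gaps$alive[gi] <- FALSE; next }
    pick <- cand[order(-score[cand], pos[cand])[1]]
    taken[pick] <- TRUE
    na <- na + 1; added[na] <- pick
    p <- pos[pick]
    gaps$alive[gi] <- FALSE
    gaps <- rbind(gaps,
                  data.frame(ci = g$ci, left = g$left, right = p,
                             left_bb = g$left_bb, right_bb = TRUE,
                             len = p - g$left, alive = TRUE),
                  data.frame(ci = g$ci, left = p, right = g$right,
                             left_bb = TRUE, right_bb = g$right_bb,
                             len = g$right - p, alive = TRUE))
  }
  added[seq_len(na)]
}

#' Design a capture panel: the full three-phase pipeline
#'
#' Composition of [structural_filter()], [quality_filter()], [ld_prune()],
#' [force_include_intervals()] and [adjacency_refine()]. Deterministic for
#' fixed inputs.
#'
#' @param gm A `genotype_matrix` of population variant calls.
#' @param masks Exclusion [region_set()] (repeats/centromeres/rDNA); may be empty.
#' @param intervals Target [region_set()] of GWAS/QTL intervals; may be empty.
#' @param genes A [gene_models()] object or NULL (no genic scoring).
#' @param cfg A [design_config()].
#' @return A `panel_design`.
#' @export
design_panel <- function(gm, masks = region_set(), intervals = region_set(),
                         genes = NULL, cfg = design_config()) {
  cand <- quality_filter(structural_filter(gm, masks, cfg), cfg)
  if (n_sites(cand) == 0) {
    warning("no candidate sites survive filtering; empty panel")
    return(adjacency_refine_empty(gm$layout, cfg, intervals))
  }
  sc <- locus_scores(cand, genes, cfg)
  keep <- ld_prune_keep(cand, cfg, sc$score)
  cand <- subset_sites(cand, keep)
  score <- sc$score[keep]; genic <- sc$genic_class[keep]
  fi <- force_include_intervals(cand, intervals, cfg, score)
  adjacency_refine(cand, fi$forced_idx, cfg, score, genic, fi$unfillable)
}

adjacency_refine_empty <- function(layout, cfg, intervals) {
  loci <- data.frame(chrom = character(), pos = numeric(), ref = character(),
                     alt = character(), site_id = character(),
                     provenance = character(), score = numeric(),
                     genic_class = character(), maf = numeric(),
                     missing_rate = numeric(), het = numeric())
  structure(list(loci = loci, config = cfg, layout = layout,
                 unfillable = intervals),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("panel_design: %d loci (%d interval-forced) on %d chromosome(s)\n",
              nrow(x$loci), sum(x$loci$provenance == "interval_forced"),
              length(unique(x$loci$chrom))))
  invisible(x)
}

#' Panel spacing statistics
#'
#' Distances between consecutive same-chromosome panel loci; chromosomes with
#' fewer than two loci contribute no distances. `n_within_10kb` counts loci
#' whose nearest same-chromosome panel neighbor is at most 10 kb away.
#'
#' @param panel A `panel_design` or a sorted loci data.frame (`chrom`, `pos`).
#' @return list: `mean_adjacent_bp`, `median_adjacent_bp`, `n_within_10kb`,
#'   `fraction_within_10kb`, `n_distances`.
#' @export
spacing_stats <- function(panel) {
  loci <- if (inherits(panel, "panel_design")) panel$loci else panel
  n <- nrow(loci)
  if (n < 2) {
    return(list(mean_adjacent_bp = NA_real_, median_adjacent_bp = NA_real_,
                n_within_10kb = 0L, fraction_within_10kb = if (n) 0 else NA_real_,
                n_distances = 0L))
  }
  i <- seq_len(n - 1)
  same <- loci$chrom[i] == loci$chrom[i + 1]
  d <- (loci$pos[i + 1] - loci$pos[i])[same]
  # nearest-neighbor distance per locus (within chromosome)
  dl <- rep(Inf, n); dr <- rep(Inf, n)
  dl[which(same) + 1] <- d
  dr[which(same)] <- d
  nn <- pmin(dl, dr)
  list(mean_adjacent_bp = mean(d), median_adjacent_bp = stats::median(d),
       n_within_10kb = sum(nn <= 10000), fraction_within_10kb = mean(nn <= 10000),
       n_distances = length(d))
}

#' Write a panel as TSV
#'
#' Columns: chrom, pos, ref, alt, site_id, provenance, score.
#'
#' @param panel A `panel_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- panel$loci[, c("chrom", "pos", "ref", "alt", "site_id", "provenance", "score")]
  out$pos <- format(out$pos, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a panel TSV written by [write_panel()]
#' @param path Path to the TSV.
#' @return data.frame of panel loci.
#' @export
read_panel <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Independently re-verify every panel-design invariant
#'
#' A deliberately simple brute-force checker, separate from the selection code
#' paths: every locus must (1) be one of the input candidate sites, (2) lie
#' outside every mask interval, (3) pass the quality thresholds recomputed
#' from the genotypes, (4) respect `min_spacing` between consecutive
#' same-chromosome *backbone* loci. (The adjacent-LD guarantee is a property
#' of the [ld_prune()] output, whose adjacencies differ from the final
#' panel's; check it there with [adjacent_ld_profile()].)
#'
#' @param panel A `panel_design`.
#' @param gm The original input `genotype_matrix`.
#' @param masks The exclusion [region_set()] used in the design.
#' @param cfg The [design_config()] used.
#' @return list of logical flags, plus `ok` (all of them).
#' @export
verify_panel <- function(panel, gm, masks, cfg = design_config()) {
  loci <- panel$loci
  idx <- match(variant_key(loci), variant_key(gm$sites))
  subset_of_input <- !anyNA(idx)
  in_mask <- FALSE
  for (k in seq_len(nrow(masks))) {
    m <- masks[k, ]
    in_mask <- in_mask || any(loci$chrom == m$chrom & loci$pos >= m$start &
                                loci$pos < m$end)
  }
  qual_ok <- TRUE
  if (subset_of_input && nrow(loci)) {
    s <- site_summaries(subset_sites(gm, idx))
    qual_ok <- all(s$maf >= cfg$maf_min & s$missing_rate <= cfg$missing_max &
                     s$het <= cfg$het_max)
  }
  spacing_ok <- TRUE
  bb <- loci[loci$provenance == "backbone", ]
  if (nrow(bb) > 1) {
    i <- seq_len(nrow(bb) - 1)
    same <- bb$chrom[i] == bb$chrom[i + 1]
    spacing_ok <- all((bb$pos[i + 1] - bb$pos[i])[same] >= cfg$min_spacing)
  }
  out <- list(subset_of_input = subset_of_input, outside_masks = !in_mask,
              quality_ok = qual_ok, spacing_ok = spacing_ok)
  out$ok <- all(unlist(out))
  out
}

#' Panel design report
#'
#' @param panel A `panel_design`.
#' @param genes Optional [gene_models()] for gene-coverage counts.
#' @return list with panel size, provenance counts, spacing statistics,
#'   genic-class fractions, gene coverage and the full configuration.
#' @export
design_report <- function(panel, genes = NULL) {
  sp <- spacing_stats(panel)
  genic <- table(factor(panel$loci$genic_class,
                        c("exon", "intron", "promoter", "intergenic")))
  rep <- list(
    n_loci = nrow(panel$loci),
    n_backbone = sum(panel$loci$provenance == "backbone"),
    n_interval_forced = sum(panel$loci$provenance == "interval_forced"),
    n_unfillable_intervals = nrow(panel$unfillable),
    spacing = sp,
    genic_fraction = as.list(genic / max(1, nrow(panel$loci))),
    config = unclass(panel$config))
  if (!is.null(genes)) rep$gene_coverage <- gene_coverage(panel, genes, panel$config)
  rep
}
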