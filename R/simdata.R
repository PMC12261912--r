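# run expr under a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Simulation configuration
#'
#' One seed drives every generator; identical configs give byte-identical
#' outputs. Defaults describe a small structured diversity panel: three
#' subpopulations at moderate differentiation (F = 0.15), common ancestral
#' alleles, gene-dense chromosomes with a repeat fraction excluded from
#' variant placement.
#'
#' @param seed Integer seed (mandatory).
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param n_subpops,n_per_subpop Population structure (default 3 x 20).
#' @param fst_param Island-model differentiation F in (0, 1) (default 0.15).
#' @param n_sites Number of variant sites (default 5000).
#' @param ancestral_freq_range Ancestral allele-frequency range (default
#'   0.05-0.95).
#' @param missing_rate Genotype missingness, completely at random (default 0.02).
#' @param gene_density Genes per Mb (default 20).
#' @param repeat_fraction Fraction of each chromosome covered by repeat masks
#'   (default 0.1).
#' @param sweep Optional list(chrom, start, end, target_subpop, residual_freq).
#' @param trait Optional list(causal_index, beta, sd, model = "quantitative" or
#'   "binary").
#' @param depth list(mean, dispersion, dropout_frac): negative-binomial capture
#'   depth with a designated fraction of structural-variant dropout loci.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       chromosomes = c(A01 = 5e6, A02 = 4e6, A03 = 3e6),
                       n_subpops = 3, n_per_subpop = 20, fst_param = 0.15,
                       n_sites = 5000, ancestral_freq_range = c(0.05, 0.95),
                       missing_rate = 0.02, gene_density = 20,
                       repeat_fraction = 0.1, sweep = NULL, trait = NULL,
                       depth = list(mean = 150, dispersion = 5, dropout_frac = 0)) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(fst_param > 0, fst_param < 1, n_sites > 0,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            repeat_fraction >= 0, repeat_fraction < 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(seed = as.integer(seed), chromosomes = chromosomes,
                 n_subpops = n_subpops, n_per_subpop = n_per_subpop,
                 fst_param = fst_param, n_sites = n_sites,
                 ancestral_freq_range = ancestral_freq_range,
                 missing_rate = missing_rate, gene_density = gene_density,
                 repeat_fraction = repeat_fraction, sweep = sweep,
                 trait = trait, depth = depth),
            class = "sim_config")
}

#' Simulate a genome: layout, gene models and repeat masks
#'
#' Genes are placed uniformly at the configured density with 1-8 exons each;
#' repeat tracts are placed without overlapping genes (with a small margin)
#' until `repeat_fraction` of each chromosome is covered. Deterministic per
#' seed.
#'
#' @param cfg A [sim_config()].
#' @return list: `layout` ([genome_layout()]), `genes` ([gene_models()]),
#'   `masks` ([region_set()]).
#' @export
simulate_genome <- function(cfg) {
  with_seed(cfg$seed + 1L, {
    layout <- genome_layout(names(cfg$chromosomes), unname(cfg$chromosomes))
    genes_l <- list(); exons_l <- list(); masks_l <- list()
    for (ci in seq_len(nrow(layout))) {
      ch <- layout$chrom[ci]; L <- layout$length[ci]
      ng <- round(cfg$gene_density * L / 1e6)
      if (ng > 0) {
        # one gene per equal-width slot: the configured density is met exactly
        # and genes never overlap
        slot <- L / ng
        if (slot < 700) stop("gene density too high for chromosome length")
        glen <- round(pmin(stats::runif(ng, 500, 5000), 0.8 * slot))
        gstart <- round(slot * (seq_len(ng) - 1) +
                          stats::runif(ng, 0, slot - glen - 1))
        gid <- sprintf("%s_g%04d", ch, seq_len(ng))
        strand <- sample(c("+", "-"), ng, replace = TRUE)
        genes_l[[ci]] <- data.frame(gene_id = gid, chrom = ch, strand = strand,
                                    start = gstart, end = gstart + glen)
        ex <- lapply(seq_len(ng), function(i) {
          ne <- sample(1:8, 1)
          cuts <- sort(sample(seq(0, glen[i]), 2 * ne))
          data.frame(gene_id = gid[i], chrom = ch,
                     start = gstart[i] + cuts[seq(1, 2 * ne, 2)],
                     end = gstart[i] + cuts[seq(2, 2 * ne, 2)])
        })
        ex <- do.call(rbind, ex)
        ex <- ex[ex$end > ex$start, ]
        exons_l[[ci]] <- ex
      }
      target <- cfg$repeat_fraction * L
      if (target > 0) {
        gs <- if (ng > 0) genes_l[[ci]]$start else numeric()
        ge <- if (ng > 0) genes_l[[ci]]$end else numeric()
        covered <- 0; tries <- 0; rep_s <- numeric(); rep_e <- numeric()
        while (covered < target && tries < 20000) {
          tries <- tries + 1
          w <- round(stats::runif(1, 5000, 50000))
          s <- round(stats::runif(1, 0, L - w))
          margin <- 200
          if (any(s < ge + margin & s + w > gs - margin)) next
          if (length(rep_s) && any(s < rep_e & s + w > rep_s)) next
          rep_s <- c(rep_s, s); rep_e <- c(rep_e, s + w)
          covered <- covered + w
        }
        if (covered < target)
          stop("cannot place repeats: density/fraction combination infeasible")
        masks_l[[ci]] <- data.frame(chrom = ch, start = rep_s, end = rep_e)
      }
    }
    genes_df <- do.call(rbind, genes_l)
    exons_df <- do.call(rbind, exons_l)
    masks_df <- do.call(rbind, masks_l)
    masks <- if (is.null(masks_df)) region_set() else
      region_set(masks_df$chrom, masks_df$start, masks_df$end, "repeat")
    genes <- if (is.null(genes_df))
      gene_models(data.frame(gene_id = character(), chrom = character(),
                             strand = character(), start = numeric(), end = numeric()),
                  data.frame(gene_id = character(), chrom = character(),
                             start = numeric(), end = numeric()))
    else gene_models(genes_df, exons_df)
    list(layout = layout, genes = genes, masks = masks)
  })
}

#' Simulate structured genotypes under the island (Balding-Nichols) model
#'
#' Per site, an ancestral frequency p is drawn uniformly from
#' `ancestral_freq_range`; each subpopulation's frequency is Beta-distributed
#' with parameters `p(1-F)/F, (1-p)(1-F)/F`, and genotypes are Binomial(2,
#' p_k). Sites are placed uniformly outside the masks and are unlinked by
#' construction. Missingness is applied completely at random.
#'
#' @param cfg A [sim_config()].
#' @param layout A [genome_layout()].
#' @param masks Optional [region_set()] excluded from site placement.
#' @return list: `gm` (`genotype_matrix`), `labels` (subpopulation of each
#'   sample), `ancestral_freq`.
#' @export
simulate_population <- function(cfg, layout, masks = region_set()) {
  with_seed(cfg$seed + 2L, {
    ns <- cfg$n_sites
    w <- layout$length / sum(layout$length)
    chrom <- sample(layout$chrom, ns, replace = TRUE, prob = w)
    pos <- floor(stats::runif(ns, 0, chrom_length(layout, chrom))) + 1
    if (nrow(masks) > 0) {
      for (it in 1:20) {
        rq <- region_query_granges(masks)
        bad <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
          GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos)), rq$gr)))
        if (length(bad) == 0) break
        chrom[bad] <- sample(layout$chrom, length(bad), replace = TRUE, prob = w)
        pos[bad] <- floor(stats::runif(length(bad), 0,
                                       chrom_length(layout, chrom[bad]))) + 1
      }
    }
    key <- paste(chrom, pos)
    while (anyDuplicated(key)) {
      d <- which(duplicated(key))
      pos[d] <- floor(stats::runif(length(d), 0, chrom_length(layout, chrom[d]))) + 1
      key <- paste(chrom, pos)
    }
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, ns, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
    nsub <- cfg$n_subpops; m <- cfg$n_per_subpop
    n <- nsub * m
    labels <- rep(paste0("pop", seq_len(nsub)), each = m)
    samples <- sprintf("%s_s%02d", labels, rep(seq_len(m), nsub))
    p <- stats::runif(ns, cfg$ancestral_freq_range[1], cfg$ancestral_freq_range[2])
    FF <- cfg$fst_param
    dosage <- matrix(NA_integer_, ns, n)
    for (k in seq_len(nsub)) {
      pk <- stats::rbeta(ns, p * (1 - FF) / FF, (1 - p) * (1 - FF) / FF)
      cols <- ((k - 1) * m + 1):(k * m)
      dosage[, cols] <- stats::rbinom(ns * m, 2, rep(pk, m))
    }
    if (cfg$missing_rate > 0)
      dosage[stats::runif(length(dosage)) < cfg$missing_rate] <- NA_integer_
    sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        site_id = paste(chrom, pos, sep = "_"),
                        stringsAsFactors = FALSE)
    ord <- order(chrom_rank(layout, chrom), pos)
    gm <- genotype_matrix(sites[ord, ], dosage[ord, , drop = FALSE], samples, layout,
                          sort = FALSE)
    names(labels) <- samples
    list(gm = gm, labels = labels, ancestral_freq = p[ord])
  })
}

#' Implant a selective sweep: reduced diversity in one group
#'
#' For sites inside the sweep region, genotypes of the target subpopulation
#' are redrawn from Binomial(2, q) with q = `residual_freq` oriented toward
#' the group's major allele, collapsing the group's local diversity to about
#' `2q(1-q)` while other groups are untouched.
#'
#' @param gm A `genotype_matrix`.
#' @param labels Named subpopulation labels (names = samples).
#' @param sweep list(chrom, start, end, target_subpop, residual_freq).
#' @param seed Integer seed.
#' @return The modified `genotype_matrix`.
#' @export
implant_sweep <- function(gm, labels, sweep, seed) {
  if (!sweep$chrom %in% gm$layout$chrom)
    stop("sweep region chromosome not in layout")
  with_seed(seed + 3L, {
    in_r <- gm$sites$chrom == sweep$chrom & gm$sites$pos >= sweep$start &
      gm$sites$pos < sweep$end
    if (!any(in_r)) {
      warning("sweep region contains no sites")
      return(gm)
    }
    tgt <- which(labels[gm$samples] == sweep$target_subpop)
    q <- sweep$residual_freq
    d <- gm$dosage
    for (i in which(in_r)) {
      row <- d[i, tgt]
      p_t <- mean(row, na.rm = TRUE) / 2
      swept_freq <- if (!is.na(p_t) && p_t >= 0.5) 1 - q else q
      miss <- is.na(row)
      newrow <- stats::rbinom(length(tgt), 2, swept_freq)
      newrow[miss] <- NA_integer_
      d[i, tgt] <- newrow
    }
    genotype_matrix(gm$sites, d, gm$samples, gm$layout, sort = FALSE)
  })
}

#' Generate a phenotype driven by one causal site
#'
#' Quantitative: `y = beta * dosage + Normal(0, sd)`. Binary:
#' `y ~ Bernoulli(logistic(alpha + beta * dosage))` with alpha solved so the
#' expected prevalence is 30%. Missing causal dosages are imputed at the site
#' mean for phenotype generation.
#'
#' @param gm A `genotype_matrix`.
#' @param trait list(causal_index, beta, sd, model = "quantitative"/"binary").
#' @param seed Integer seed.
#' @return Numeric phenotype vector named by sample.
#' @export
implant_trait <- function(gm, trait, seed) {
  g <- gm$dosage[trait$causal_index, ]
  if (length(unique(stats::na.omit(g))) < 2) stop("causal site is monomorphic")
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  with_seed(seed + 4L, {
    y <- if (identical(trait$model, "binary")) {
      alpha <- stats::uniroot(function(a) mean(stats::plogis(a + trait$beta * g)) - 0.3,
                              c(-50, 50))$root
      stats::rbinom(length(g), 1, stats::plogis(alpha + trait$beta * g))
    } else {
      trait$beta * g + stats::rnorm(length(g), 0, trait$sd)
    }
    names(y) <- gm$samples
    y
  })
}

#' Simulate capture depth tables for panel loci
#'
#' Per locus per sample, depth ~ NegativeBinomial(mean, dispersion); loci
#' designated as dropout (structural-variant) sites for a sample get depth 0
#' and are returned as ground truth.
#'
#' @param panel A `panel_design` or loci data.frame.
#' @param samples Character sample names.
#' @param depth_cfg list(mean, dispersion, dropout_frac).
#' @param seed Integer seed.
#' @return list: `tables` (named list of [depth_table()]), `dropout_sites`
#'   (named list of per-sample dropout loci data.frames).
#' @export
simulate_capture_depth <- function(panel, samples, depth_cfg, seed) {
  loci <- if (inherits(panel, "panel_design")) panel$loci else panel
  if (nrow(loci) == 0) stop("panel is empty")
  with_seed(seed + 5L, {
    tables <- list(); dropouts <- list()
    for (s in samples) {
      d <- stats::rnbinom(nrow(loci), mu = depth_cfg$mean, size = depth_cfg$dispersion)
      ndrop <- round(depth_cfg$dropout_frac * nrow(loci))
      drop_idx <- if (ndrop > 0) sort(sample(nrow(loci), ndrop)) else integer()
      d[drop_idx] <- 0
      tables[[s]] <- depth_table(loci$chrom, loci$pos, d, s)
      dropouts[[s]] <- loci[drop_idx, c("chrom", "pos"), drop = FALSE]
    }
    list(tables = tables, dropout_sites = dropouts)
  })
}

#' Simulate a full input bundle and write it to disk
#'
#' Writes genotypes.vcf, masks.bed, genes.gff3, intervals.bed, phenotype.tsv,
#' per-sample depth TSVs and truth.json (labels, sweep region, causal site,
#' dropout sites) into `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param n_intervals Number of GWAS/QTL-style target intervals to draw
#'   (default 10).
#' @return Invisibly, the list of generated in-memory objects.
#' @export
simulate_bundle <- function(cfg, dir, n_intervals = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- simulate_genome(cfg)
  pop <- simulate_population(cfg, geno$layout, geno$masks)
  gm <- pop$gm
  if (!is.null(cfg$sweep)) gm <- implant_sweep(gm, pop$labels, cfg$sweep, cfg$seed)
  truth <- list(labels = as.list(pop$labels), sweep = cfg$sweep)
  phe <- NULL
  if (!is.null(cfg$trait)) {
    phe <- implant_trait(gm, cfg$trait, cfg$seed)
    truth$causal_site <- as.list(gm$sites[cfg$trait$causal_index,
                                          c("chrom", "pos", "site_id")])
    utils::write.table(data.frame(sample = names(phe), phenotype = unname(phe)),
                       file.path(dir, "phenotype.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  ivs <- with_seed(cfg$seed + 6L, {
    ci <- sample(nrow(geno$layout), n_intervals, replace = TRUE)
    w <- round(stats::runif(n_intervals, 2e4, 2e5))
    s <- floor(stats::runif(n_intervals, 0, geno$layout$length[ci] - w))
    region_set(geno$layout$chrom[ci], s, s + w,
               sprintf("qtl%02d", seq_len(n_intervals)))
  })
  write_vcf(gm, file.path(dir, "genotypes.vcf"))
  write_bed(geno$masks, file.path(dir, "masks.bed"))
  write_bed(ivs, file.path(dir, "intervals.bed"))
  write_gff(geno$genes, file.path(dir, "genes.gff3"))
  writeLines(sprintf("%s\t%d", geno$layout$chrom, as.integer(geno$layout$length)),
             file.path(dir, "genome.tsv"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(list(layout = geno$layout, genes = geno$genes, masks = geno$masks,
                 gm = gm, labels = pop$labels, intervals = ivs, phenotype = phe,
                 truth = truth))
}
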