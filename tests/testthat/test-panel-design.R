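test_that("structural filter honors the half-open mask boundary", {
  d <- matrix(rep(c(0L, 1L, 2L, 1L), 2), 2, 4, byrow = TRUE)
  gm <- toy_gm(d, pos = c(150, 200))
  masks <- region_set("A01", 100, 200, "repeat")
  out <- structural_filter(gm, masks)
  expect_equal(out$sites$pos, 200)   # pos 150 removed; pos 200 kept (end exclusive)
})

test_that("structural filter removes polymorphism-dense probe contexts", {
  cfg <- design_config(near_variant_radius = 200, near_variant_max = 4)
  # 6 variants within 150 bp -> each has 5 neighbors -> all removed
  d <- matrix(rbinom(6 * 10, 2, 0.5), 6, 10)
  gm6 <- toy_gm(d, pos = seq(5000, 5150, length.out = 6))
  expect_warning(out6 <- structural_filter(gm6, region_set(), cfg), "every site")
  expect_equal(n_sites(out6), 0)
  # 3 variants clustered -> 2 neighbors each -> all kept
  gm3 <- toy_gm(d[1:3, ], pos = c(5000, 5050, 5100))
  expect_equal(n_sites(structural_filter(gm3, region_set(), cfg)), 3)
  # brute-force neighbor oracle on random positions
  set.seed(5)
  pos <- sort(sample(1e5, 60))
  gmr <- toy_gm(matrix(rbinom(60 * 6, 2, .5), 60, 6), pos = pos)
  out <- structural_filter(gmr, region_set(), cfg)
  nn <- vapply(pos, function(p) sum(abs(pos - p) <= 200) - 1L, 1L)
  expect_equal(out$sites$pos, pos[nn <= 4])
})

test_that("quality filter matches an independent re-filter", {
  set.seed(9)
  gm <- toy_gm(matrix(sample(c(0L, 1L, 2L, NA), 100 * 12, TRUE,
                             prob = c(.45, .2, .2, .15)), 100, 12))
  cfg <- design_config(maf_min = 0.1, missing_max = 0.2, het_max = 0.4)
  out <- quality_filter(gm, cfg)
  s <- site_summaries(gm)
  keep <- !is.na(s$maf) & s$maf >= 0.1 & s$missing_rate <= 0.2 & s$het <= 0.4
  expect_equal(out$sites$site_id, gm$sites$site_id[keep])
  # monomorphic and high-missing removed
  expect_equal(n_sites(quality_filter(toy_gm(matrix(0L, 1, 4)))), 0)
  gmm <- toy_gm(matrix(c(0L, 2L, NA, NA), 1, 4))
  expect_equal(n_sites(quality_filter(gmm, design_config(missing_max = 0.2))), 0)
})

test_that("LD pruning reaches a fixed point with deterministic tie-breaks", {
  cfg <- design_config(ld_r2_max = 0.2)
  base <- rbinom(30, 2, 0.5)
  other <- rbinom(30, 2, 0.5)
  # duplicated adjacent pair: left higher maf -> right dropped
  high <- c(rep(1L, 15), rep(0L, 8), rep(2L, 7))     # maf 0.48
  d <- rbind(high, high)
  gm <- toy_gm(d)
  score <- site_summaries(gm)$maf
  out <- ld_prune(gm, cfg, score)
  expect_equal(out$sites$pos, 1000)
  # chain of 5 identical sites -> exactly one survivor
  gm5 <- toy_gm(do.call(rbind, replicate(5, base, simplify = FALSE)))
  expect_equal(n_sites(ld_prune(gm5, cfg)), 1)
  # independent pair below threshold kept
  gm2 <- toy_gm(rbind(base, other))
  r2 <- ld_r2(base, other)$r2
  if (r2 < 0.2) expect_equal(n_sites(ld_prune(gm2, cfg)), 2)
  # post-condition on structured data: all defined adjacent r2 < threshold
  set.seed(77)
  gmr <- toy_gm(matrix(rbinom(80 * 40, 2, 0.5), 80, 40),
                pos = sort(sample(5e5, 80)))
  prof <- adjacent_ld_profile(ld_prune(gmr, cfg))
  expect_true(all(is.na(prof$r2) | prof$r2 < 0.2))
})

test_that("interval forcing picks the argmax and reports unfillable intervals", {
  set.seed(21)
  gm <- toy_gm(matrix(rbinom(10 * 8, 2, 0.5), 10, 8),
               pos = seq(1000, 10000, by = 1000))
  score <- c(0.8, 1.2, rep(0.1, 8))
  ivs <- region_set(c("A01", "A01", "A02"), c(500, 5500, 1000),
                    c(2500, 6500, 2000), c("i1", "i2", "i3"))
  fi <- force_include_intervals(gm, ivs, design_config(), score)
  expect_equal(gm$sites$pos[fi$forced_idx], c(2000, 6000))  # score 1.2 beats 0.8
  expect_equal(fi$unfillable$label, "i3")
})

test_that("adjacency refinement hits the quota with near-uniform spacing", {
  set.seed(31)
  layout <- genome_layout("A01", 1e5)
  pos <- sort(sample(seq(500, 99500), 200))
  gm <- toy_gm(matrix(rbinom(200 * 10, 2, 0.5), 200, 10), pos = pos,
               layout = layout)
  cfg <- design_config(target_count = 10, min_spacing = 1000)
  panel <- adjacency_refine(gm, integer(), cfg, score = runif(200))
  expect_equal(nrow(panel$loci), 10)
  gaps <- diff(panel$loci$pos)
  expect_true(all(gaps <= 2 * 1e5 / 10))     # within 2x the ideal spacing
  expect_true(all(gaps >= 1000))
  # candidates only in the left half: quota still met only via gap-fill
  gml <- toy_gm(matrix(rbinom(50 * 10, 2, 0.5), 50, 10),
                pos = sort(sample(seq(500, 5e4), 50)), layout = layout)
  cfg4 <- design_config(target_count = 48, min_spacing = 1000)
  expect_warning(p2 <- adjacency_refine(gml, integer(), cfg4,
                                        score = runif(50)), "selected")
  expect_lt(nrow(p2$loci), 48)
})

test_that("full pipeline is deterministic and passes the independent checker", {
  cfg <- sim_config(seed = 123, n_sites = 4000, n_per_subpop = 12)
  geno <- simulate_genome(cfg)
  pop <- simulate_population(cfg, geno$layout, geno$masks)
  ivs <- region_set(c("A01", "A02"), c(1e6, 2e6), c(1.2e6, 2.2e6), c("q1", "q2"))
  cfgd <- design_config(target_count = 400)
  p1 <- design_panel(pop$gm, geno$masks, ivs, geno$genes, cfgd)
  p2 <- design_panel(pop$gm, geno$masks, ivs, geno$genes, cfgd)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_panel(p1, f1); write_panel(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(p1$loci), 400)
  expect_true(any(p1$loci$provenance == "interval_forced"))
  v <- verify_panel(p1, pop$gm, geno$masks, cfgd)
  expect_true(v$ok)
  # masks covering everything -> empty panel with warning
  full <- region_set(geno$layout$chrom, 0, geno$layout$length)
  expect_warning(expect_warning(
    p0 <- design_panel(pop$gm, full, region_set(), NULL, cfgd),
    "empty panel"), "every site")
  expect_equal(nrow(p0$loci), 0)
})

test_that("locus classification follows exon > intron > promoter priority", {
  g <- toy_genes()   # + strand gene 10000-13000, exons [10000,10500) [12000,13000)
  cfg <- design_config(promoter_len = 2000)
  site <- function(p) data.frame(chrom = "A01", pos = p)
  expect_equal(classify_locus(site(10250), g, cfg), "exon")
  expect_equal(classify_locus(site(11000), g, cfg), "intron")
  expect_equal(classify_locus(site(9500), g, cfg), "promoter")  # upstream of + TSS
  expect_equal(classify_locus(site(50000), g, cfg), "intergenic")
  gneg <- toy_genes(strand = "-")
  expect_equal(classify_locus(site(13500), gneg, cfg), "promoter") # 500 bp past 3'-most coord
  # exon of gene A beats promoter of gene B
  two <- gene_models(
    data.frame(gene_id = c("gA", "gB"), chrom = "A01", strand = "+",
               start = c(10000, 10600), end = c(10500, 11000)),
    data.frame(gene_id = "gA", chrom = "A01", start = 10000, end = 10500))
  expect_equal(classify_locus(site(10250), two, cfg), "exon")
})

test_that("gene coverage equals a brute-force scan", {
  cfg <- design_config(promoter_len = 2000, gene_assoc_radius = 10000)
  g <- toy_genes()
  expect_equal(gene_coverage(data.frame(chrom = "A01", pos = 11000), g, cfg),
               list(n_genes_located_in = 1L, n_genes_associated = 1L))
  expect_equal(gene_coverage(data.frame(chrom = "A01", pos = 18000), g, cfg),
               list(n_genes_located_in = 0L, n_genes_associated = 1L))
  set.seed(13)
  genes <- gene_models(
    data.frame(gene_id = sprintf("g%02d", 1:50), chrom = "A01", strand = "+",
               start = seq(0, 49) * 15000, end = seq(0, 49) * 15000 + 3000),
    data.frame(gene_id = character(), chrom = character(), start = numeric(),
               end = numeric()))
  loci <- data.frame(chrom = "A01", pos = sort(sample(750000, 80)))
  got <- gene_coverage(loci, genes, cfg)
  gb <- genes$genes
  located <- sum(vapply(seq_len(50), function(i) {
    any(loci$pos > gb$start[i] - 2000 & loci$pos <= gb$end[i])
  }, TRUE))
  assoc <- sum(vapply(seq_len(50), function(i) {
    any(loci$pos > gb$start[i] - 10000 & loci$pos <= gb$end[i] + 10000)
  }, TRUE))
  expect_equal(got$n_genes_located_in, located)
  expect_equal(got$n_genes_associated, assoc)
})

test_that("spacing statistics match hand computation", {
  loci <- data.frame(chrom = "A01", pos = c(1000, 6000, 21000))
  st <- spacing_stats(loci)
  expect_equal(st$mean_adjacent_bp, 10000)
  expect_equal(st$median_adjacent_bp, 10000)
  expect_equal(st$n_within_10kb, 2)
  expect_equal(st$fraction_within_10kb, 2 / 3)
  st1 <- spacing_stats(data.frame(chrom = "A01", pos = 1000))
  expect_equal(st1$n_within_10kb, 0)
  expect_equal(st1$n_distances, 0)
  # chromosome boundaries contribute no distances
  st2 <- spacing_stats(data.frame(chrom = c("A01", "A02"), pos = c(1000, 2000)))
  expect_equal(st2$n_distances, 0)
})
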